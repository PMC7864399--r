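#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Fast path for the full inference loop: Gauss-Seidel sweeps over the
// layers (image-facing first, each seeing the freshest neighbours) with
// per-layer ISTA/FISTA proximal-gradient updates and the relative-change
// fixed-point criterion. Mirrors the R reference loop in inference.R.

namespace {

struct Layer {
  const double *D;
  int nf, nc, w, h, stride;
  int wm, hm;                       // activity spatial dims
  double lambda, eta;
};

inline void synth(const Layer &L, const double *act, double *out,
                  int W, int H) {
  std::fill(out, out + (size_t)L.nc * W * H, 0.0);
  for (int l = 0; l < L.hm; ++l)
    for (int k = 0; k < L.wm; ++k) {
      const int x0 = k * L.stride, y0 = l * L.stride;
      for (int f = 0; f < L.nf; ++f) {
        const double a = act[f + (size_t)L.nf * (k + (size_t)L.wm * l)];
        if (a == 0.0) continue;
        for (int q = 0; q < L.h; ++q) {
          const int y = y0 + q;
          for (int p = 0; p < L.w; ++p) {
            const int x = x0 + p;
            const double *Dpq = L.D + f + (size_t)L.nf * L.nc * (p + (size_t)L.w * q);
            double *O = out + (size_t)L.nc * (x + (size_t)W * y);
            for (int c = 0; c < L.nc; ++c)
              O[c] += a * Dpq[(size_t)L.nf * c];
          }
        }
      }
    }
}

inline void analyze_op(const Layer &L, const double *x, double *out,
                       int W, int H) {
  std::fill(out, out + (size_t)L.nf * L.wm * L.hm, 0.0);
  for (int l = 0; l < L.hm; ++l)
    for (int k = 0; k < L.wm; ++k) {
      const int x0 = k * L.stride, y0 = l * L.stride;
      double *O = out + (size_t)L.nf * (k + (size_t)L.wm * l);
      for (int q = 0; q < L.h; ++q) {
        const int y = y0 + q;
        for (int p = 0; p < L.w; ++p) {
          const int xx = x0 + p;
          const double *X = x + (size_t)L.nc * (xx + (size_t)W * y);
          const double *Dpq = L.D + (size_t)L.nf * L.nc * (p + (size_t)L.w * q);
          for (int c = 0; c < L.nc; ++c) {
            const double xv = X[c];
            if (xv == 0.0) continue;
            const double *Dc = Dpq + (size_t)L.nf * c;
            for (int f = 0; f < L.nf; ++f) O[f] += xv * Dc[f];
          }
        }
      }
    }
}

} // namespace

// [[Rcpp::export]]
List sdpc_infer_cpp(NumericVector image, List dicts, IntegerVector strides,
                    NumericVector lambdas, NumericVector etas, double k_fb,
                    double t_fp, int max_iter, bool fista) {
  const int nL = dicts.size();
  IntegerVector dimX = image.attr("dim");
  std::vector<Layer> L(nL);
  std::vector<int> inW(nL), inH(nL);      // spatial dims of each layer's input
  int W = dimX[1], H = dimX[2];
  std::vector<NumericVector> keep(nL);    // protect dict memory
  for (int i = 0; i < nL; ++i) {
    keep[i] = as<NumericVector>(dicts[i]);
    IntegerVector dd = keep[i].attr("dim");
    L[i].D = keep[i].begin();
    L[i].nf = dd[0]; L[i].nc = dd[1]; L[i].w = dd[2]; L[i].h = dd[3];
    L[i].stride = strides[i];
    inW[i] = W; inH[i] = H;
    L[i].wm = (W - L[i].w) / L[i].stride + 1;
    L[i].hm = (H - L[i].h) / L[i].stride + 1;
    L[i].lambda = lambdas[i];
    L[i].eta = etas[i];
    W = L[i].wm; H = L[i].hm;
  }

  std::vector<std::vector<double>> gamma(nL), y(nL), g(nL), buf_in(nL);
  for (int i = 0; i < nL; ++i) {
    size_t n = (size_t)L[i].nf * L[i].wm * L[i].hm;
    gamma[i].assign(n, 0.0);
    y[i].assign(n, 0.0);
    g[i].assign(n, 0.0);
    buf_in[i].assign((size_t)L[i].nc * inW[i] * inH[i], 0.0);
  }

  LogicalVector conv(nL);
  double tk = 1.0;
  int it = 0;
  bool diverged = false;
  int div_layer = 0;

  for (it = 1; it <= max_iter; ++it) {
    const double tk1 = fista ? (1.0 + std::sqrt(1.0 + 4.0 * tk * tk)) / 2.0 : 1.0;
    bool all_conv = true;
    for (int i = 0; i < nL; ++i) {
      const double *below = (i == 0) ? image.begin() : gamma[i - 1].data();
      const double *z = fista ? y[i].data() : gamma[i].data();
      const size_t n = gamma[i].size();
      const size_t nb = buf_in[i].size();

      // resid = below - synth(z)
      synth(L[i], z, buf_in[i].data(), inW[i], inH[i]);
      for (size_t j = 0; j < nb; ++j)
        buf_in[i][j] = below[j] - buf_in[i][j];
      analyze_op(L[i], buf_in[i].data(), g[i].data(), inW[i], inH[i]);

      const double eta = L[i].eta;
      for (size_t j = 0; j < n; ++j) g[i][j] = z[j] + eta * g[i][j];

      if (i < nL - 1 && k_fb > 0) {
        // reuse the layer-above input buffer for its prediction of layer i
        synth(L[i + 1], gamma[i + 1].data(), buf_in[i + 1].data(),
              inW[i + 1], inH[i + 1]);
        const double ke = k_fb * eta;
        for (size_t j = 0; j < n; ++j)
          g[i][j] -= ke * (z[j] - buf_in[i + 1][j]);
      }

      const double thr = eta * L[i].lambda;
      double dn = 0.0, gn = 0.0;
      bool finite = true;
      for (size_t j = 0; j < n; ++j) {
        double v = g[i][j] - thr;
        if (v < 0.0) v = 0.0;
        if (!std::isfinite(v)) { finite = false; break; }
        g[i][j] = v;
        const double d = v - gamma[i][j];
        dn += d * d;
        gn += v * v;
      }
      if (!finite) { diverged = true; div_layer = i + 1; break; }
      const bool ci = (gn == 0.0) ? (dn == 0.0)
                                  : (std::sqrt(dn / gn) < t_fp);
      conv[i] = ci;
      if (!ci) all_conv = false;

      if (fista) {
        const double mom = (tk - 1.0) / tk1;
        for (size_t j = 0; j < n; ++j)
          y[i][j] = g[i][j] + mom * (g[i][j] - gamma[i][j]);
      }
      std::swap(gamma[i], g[i]);
    }
    if (diverged) break;
    tk = tk1;
    if (all_conv) break;
  }
  if (diverged)
    stop("divergence at layer %d, iteration %d: non-finite activity",
         div_layer, it);
  if (it > max_iter) it = max_iter;

  List acts(nL);
  for (int i = 0; i < nL; ++i) {
    NumericVector a(gamma[i].begin(), gamma[i].end());
    a.attr("dim") = IntegerVector::create(L[i].nf, L[i].wm, L[i].hm);
    acts[i] = a;
  }
  return List::create(_["activities"] = acts, _["iterations"] = it,
                      _["converged"] = conv);
}
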