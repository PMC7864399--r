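#include <Rcpp.h>
using namespace Rcpp;

// Strided "valid" convolutional operators shared by all layers.
//
// Layout conventions (column-major, as stored by R):
//   dictionary atoms: [n_f, n_c, w, h]
//   activity map:     [n_f, w_m, h_m]
//   image / tensor:   [n_c, W, H]   with W = (w_m - 1) * stride + w
//
// conv_synthesize_cpp implements the transposed (synthesis) direction:
// each activity coefficient stamps its atom into the output at a
// stride-spaced offset. conv_analyze_cpp is its exact adjoint
// (a strided correlation). conv_dict_grad_cpp is the adjoint of
// synthesis with respect to the dictionary, used by the learning step.

// [[Rcpp::export]]
NumericVector conv_synthesize_cpp(NumericVector atoms, NumericVector act,
                                  int stride) {
  IntegerVector dD = atoms.attr("dim");
  IntegerVector dA = act.attr("dim");
  const int nf = dD[0], nc = dD[1], w = dD[2], h = dD[3];
  const int wm = dA[1], hm = dA[2];
  const int W = (wm - 1) * stride + w;
  const int H = (hm - 1) * stride + h;

  NumericVector out(nc * W * H);
  out.attr("dim") = IntegerVector::create(nc, W, H);

  const double *D = atoms.begin();
  const double *A = act.begin();
  double *O = out.begin();

  for (int l = 0; l < hm; ++l) {
    for (int k = 0; k < wm; ++k) {
      const int x0 = k * stride, y0 = l * stride;
      for (int f = 0; f < nf; ++f) {
        const double a = A[f + nf * (k + wm * l)];
        if (a == 0.0) continue;
        for (int q = 0; q < h; ++q) {
          const int y = y0 + q;
          for (int p = 0; p < w; ++p) {
            const int x = x0 + p;
            for (int c = 0; c < nc; ++c) {
              O[c + nc * (x + W * y)] += a * D[f + nf * (c + nc * (p + w * q))];
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector conv_analyze_cpp(NumericVector atoms, NumericVector tensor,
                               int stride) {
  IntegerVector dD = atoms.attr("dim");
  IntegerVector dX = tensor.attr("dim");
  const int nf = dD[0], nc = dD[1], w = dD[2], h = dD[3];
  const int W = dX[1], H = dX[2];
  const int wm = (W - w) / stride + 1;
  const int hm = (H - h) / stride + 1;

  NumericVector out(nf * wm * hm);
  out.attr("dim") = IntegerVector::create(nf, wm, hm);

  const double *D = atoms.begin();
  const double *X = tensor.begin();
  double *O = out.begin();

  for (int l = 0; l < hm; ++l) {
    for (int k = 0; k < wm; ++k) {
      const int x0 = k * stride, y0 = l * stride;
      for (int q = 0; q < h; ++q) {
        const int y = y0 + q;
        for (int p = 0; p < w; ++p) {
          const int x = x0 + p;
          for (int c = 0; c < nc; ++c) {
            const double xv = X[c + nc * (x + W * y)];
            if (xv == 0.0) continue;
            for (int f = 0; f < nf; ++f) {
              O[f + nf * (k + wm * l)] += xv * D[f + nf * (c + nc * (p + w * q))];
            }
          }
        }
      }
    }
  }
  return out;
}

// Gradient of 0.5 * || target - synthesize(D, act) ||^2 with respect to D,
// up to sign: returns the correlation of act with resid (= target - pred),
// shaped like the dictionary.
// [[Rcpp::export]]
NumericVector conv_dict_grad_cpp(NumericVector resid, NumericVector act,
                                 int w, int h, int stride) {
  IntegerVector dR = resid.attr("dim");
  IntegerVector dA = act.attr("dim");
  const int nc = dR[0], W = dR[1];
  const int nf = dA[0], wm = dA[1], hm = dA[2];

  NumericVector out(nf * nc * w * h);
  out.attr("dim") = IntegerVector::create(nf, nc, w, h);

  const double *R = resid.begin();
  const double *A = act.begin();
  double *O = out.begin();

  for (int l = 0; l < hm; ++l) {
    for (int k = 0; k < wm; ++k) {
      const int x0 = k * stride, y0 = l * stride;
      for (int f = 0; f < nf; ++f) {
        const double a = A[f + nf * (k + wm * l)];
        if (a == 0.0) continue;
        for (int q = 0; q < h; ++q) {
          const int y = y0 + q;
          for (int p = 0; p < w; ++p) {
            const int x = x0 + p;
            for (int c = 0; c < nc; ++c) {
              O[f + nf * (c + nc * (p + w * q))] += a * R[c + nc * (x + W * y)];
            }
          }
        }
      }
    }
  }
  return out;
}
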