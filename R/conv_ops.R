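#' Synthesize (predict) the layer below from an activity map
#'
#' Applies the transposed strided convolution `D^T * gamma`: every activity
#' coefficient stamps a copy of its atom into the output at a stride-spaced
#' position. This is the top-down prediction direction of the network.
#' No zero-padding is used: the output spatial size per axis is
#' `(map_size - 1) * stride + kernel`, so the prediction exactly tiles the
#' tensor it models.
#'
#' @param dict An [sdpc_dictionary()].
#' @param activity 3-way array `[n_features, w_m, h_m]`.
#' @return 3-way array `[n_channels, W, H]`.
#' @export
synthesize <- function(dict, activity) {
  a <- as_activity(activity)
  if (dim(a)[1] != dim(dict$atoms)[1])
    stop(sprintf("activity has %d feature planes but dictionary has %d atoms",
                 dim(a)[1], dim(dict$atoms)[1]))
  conv_synthesize_cpp(dict$atoms, a, dict$stride)
}

#' Analyze a tensor against a dictionary
#'
#' Applies the strided correlation `D * x`, the exact adjoint of
#' [synthesize()]: `<synthesize(D, u), v> == <u, analyze(D, v)>` for all
#' conforming `u`, `v`. This is the bottom-up (prediction-error driving)
#' direction.
#'
#' @param dict An [sdpc_dictionary()].
#' @param tensor 3-way array `[n_channels, W, H]`; the spatial size minus
#'   the kernel must be divisible by the stride.
#' @return 3-way array `[n_features, w_m, h_m]`.
#' @export
analyze <- function(dict, tensor) {
  x <- as_activity(tensor)
  dd <- dim(dict$atoms)
  if (dim(x)[1] != dd[2])
    stop(sprintf("tensor has %d channels but dictionary expects %d",
                 dim(x)[1], dd[2]))
  s <- dict$stride
  if ((dim(x)[2] - dd[3]) %% s != 0L || (dim(x)[3] - dd[4]) %% s != 0L ||
      dim(x)[2] < dd[3] || dim(x)[3] < dd[4])
    stop("tensor spatial size incompatible with kernel and stride")
  conv_analyze_cpp(dict$atoms, x, s)
}

# Coerce matrices to single-channel 3-way arrays; validate 3-way arrays.
as_activity <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(1L, dim(x)))
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("expected a 3-way array [channel_or_feature, x, y]")
  x
}

#' Spatial size of the activity map a dictionary produces for an input
#'
#' @param dict An [sdpc_dictionary()].
#' @param input_size Length-2 integer vector, spatial size of the tensor
#'   the dictionary analyzes.
#' @return Length-2 integer vector `c(w_m, h_m)`.
#' @export
activity_size <- function(dict, input_size) {
  dd <- dim(dict$atoms)
  s <- dict$stride
  if (any((input_size - dd[3:4]) %% s != 0L))
    stop("input size incompatible with kernel and stride; crop the input first")
  as.integer((input_size - dd[3:4]) / s + 1L)
}

#' Symmetrically crop an image so each layer's stride divides evenly
#'
#' The model uses unpadded (valid) convolutions, so the input spatial size
#' must satisfy `(size - kernel) %% stride == 0` at the first layer. Excess
#' rows/columns are removed symmetrically (the extra one, if odd, from the
#' high side).
#'
#' @param image Matrix or `[channels, W, H]` array.
#' @param dict The first-layer [sdpc_dictionary()].
#' @return The cropped image, same number of ways as the input.
#' @export
crop_to_grid <- function(image, dict) {
  x <- as_activity(image)
  dd <- dim(dict$atoms)
  s <- dict$stride
  keep <- function(n, k) {
    if (n < k) stop("image smaller than the kernel")
    r <- (n - k) %% s
    lo <- r %/% 2L
    seq.int(lo + 1L, n - (r - lo))
  }
  out <- x[, keep(dim(x)[2], dd[3]), keep(dim(x)[3], dd[4]), drop = FALSE]
  if (is.matrix(image)) out[1, , ] else out
}

#' Non-negative soft-thresholding operator
#'
#' `T_alpha(x) = x - alpha` where `x >= alpha` and `0` elsewhere. The
#' proximal operator of the L1 penalty restricted to the non-negative
#' orthant; it makes exact zeros, so "active" units are unambiguous.
#'
#' @param x Numeric vector or array.
#' @param alpha Threshold (scalar, non-negative).
#' @return Object of the same shape, elementwise `pmax(x - alpha, 0)`.
#' @export
soft_threshold <- function(x, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha < 0)
    stop("alpha must be a single non-negative number")
  y <- x - alpha
  y[y < 0] <- 0
  y
}

#' Largest eigenvalue of the analyze-synthesize operator
#'
#' Power iteration on `analyze(D, synthesize(D, .))`, the Gram operator of
#' the dictionary on the layer's activity space. Its largest eigenvalue L
#' bounds the curvature of the reconstruction term, and `1 / L` is the
#' ISTA/FISTA step size.
#'
#' @param dict An [sdpc_dictionary()].
#' @param map_size Spatial size `c(w_m, h_m)` of the activity map the
#'   operator acts on.
#' @param tol Relative convergence tolerance of the eigenvalue.
#' @param max_iter Iteration cap.
#' @return The largest eigenvalue (a positive scalar).
#' @export
lipschitz_constant <- function(dict, map_size, tol = 1e-7, max_iter = 500L) {
  if (all(dict$atoms == 0)) stop("dictionary is identically zero: degenerate operator")
  nf <- dim(dict$atoms)[1]
  # fixed probe (deterministic, dense so no eigenvector is missed)
  v <- array(sin(seq_len(nf * map_size[1] * map_size[2])),
             dim = c(nf, map_size))
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (it in seq_len(max_iter)) {
    u <- analyze(dict, synthesize(dict, v))
    lam_new <- sum(v * u)
    nrm <- sqrt(sum(u^2))
    if (nrm == 0) return(0)
    v <- u / nrm
    if (abs(lam_new - lam) <= tol * abs(lam_new)) return(lam_new)
    lam <- lam_new
  }
  lam
}
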