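#' Generate a Gabor patch
#'
#' An oriented sinusoidal carrier under a Gaussian envelope. The
#' orientation `theta` is the orientation of the stripes (the carrier
#' varies along the normal), measured from the first spatial axis toward
#' the second, so `theta` and `theta + pi` are the same stimulus.
#'
#' @param size Patch side in pixels.
#' @param theta Stripe orientation in radians.
#' @param freq Carrier frequency in cycles per pixel.
#' @param phase Carrier phase in radians (0 = even/cosine).
#' @param sigma Envelope standard deviation in pixels (default `size / 5`).
#' @param center Optional length-2 offset of the envelope center from the
#'   patch middle.
#' @return A `size x size` matrix.
#' @export
gabor_patch <- function(size, theta, freq, phase = 0, sigma = size / 5,
                        center = c(0, 0)) {
  if (freq > 0.5) stop("frequency above Nyquist (0.5 cycles/px)")
  if (freq * size < 0.5)
    stop("kernel too small for the requested frequency: less than half a cycle fits")
  r <- (size - 1) / 2
  x <- matrix(seq_len(size) - 1 - r - center[1], size, size)
  y <- t(matrix(seq_len(size) - 1 - r - center[2], size, size))
  u <- -x * sin(theta) + y * cos(theta)     # along the carrier (normal to stripes)
  env <- exp(-(x^2 + y^2) / (2 * sigma^2))
  env * cos(2 * pi * freq * u + phase)
}

#' Fit a Gabor function to a receptive-field patch
#'
#' Grid search over orientation, frequency and envelope width, with the
#' amplitude and phase solved in closed form (linear least squares on the
#' quadrature pair), followed by a golden-section refinement of the
#' orientation. The quality score is the gain in variance explained of the
#' best fit over the fit at the orthogonal orientation
#' (`R^2(theta*) - R^2(theta* + pi/2)`, clipped to `[0, 1]`): an oriented
#' atom scores near 1, while an isotropic blob -- equally well fitted at
#' every orientation -- scores near 0.
#'
#' @param atom Matrix, or `[channels, w, h]` array (channels averaged).
#' @param n_theta Number of orientations in the coarse grid.
#' @param freqs Candidate carrier frequencies (cycles per pixel).
#' @param sigmas Candidate envelope widths (pixels); default scales with
#'   the patch.
#' @return List with `theta` (radians in `[0, pi)`), `quality` in `[0, 1]`,
#'   `r2` of the best fit, and the selected `freq` and `sigma`.
#' @export
fit_gabor <- function(atom, n_theta = 60L,
                      freqs = c(0.08, 0.12, 0.18, 0.25, 0.33),
                      sigmas = NULL) {
  if (is.array(atom) && length(dim(atom)) == 3L)
    atom <- apply(atom, c(2, 3), mean)
  stopifnot(is.matrix(atom))
  w <- nrow(atom)
  if (is.null(sigmas)) sigmas <- c(w / 6, w / 5, w / 4, w / 3)
  v <- as.vector(atom)
  tss <- sum((v - mean(v))^2)
  if (tss == 0) return(list(theta = NA_real_, quality = 0, r2 = 0,
                            freq = NA_real_, sigma = NA_real_))

  r2_at <- function(theta, freq, sigma) {
    gc <- as.vector(gabor_patch(w, theta, freq, 0, sigma))
    gs <- as.vector(gabor_patch(w, theta, freq, -pi / 2, sigma))
    X <- cbind(1, gc, gs)
    fit <- stats::lm.fit(X, v)
    1 - sum(fit$residuals^2) / tss
  }
  best_over_fs <- function(theta) {
    best <- -Inf; bf <- NA; bs <- NA
    for (f in freqs) for (s in sigmas) {
      r2 <- r2_at(theta, f, s)
      if (r2 > best) { best <- r2; bf <- f; bs <- s }
    }
    c(best, bf, bs)
  }

  grid <- seq(0, pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  scores <- vapply(grid, best_over_fs, numeric(3))
  k <- which.max(scores[1, ])
  th0 <- grid[k]; f0 <- scores[2, k]; s0 <- scores[3, k]
  step <- pi / n_theta
  opt <- stats::optimize(function(th) r2_at(th, f0, s0),
                         interval = c(th0 - step, th0 + step), maximum = TRUE)
  theta <- opt$maximum %% pi
  if (pi - theta < 1e-9) theta <- 0
  r2 <- opt$objective
  r2_orth <- best_over_fs((theta + pi / 2) %% pi)[1]
  quality <- min(1, max(0, r2 - max(0, r2_orth)))
  list(theta = theta, quality = quality, r2 = r2, freq = f0, sigma = s0)
}

#' Fit orientations to every atom of a first-layer dictionary
#'
#' Atoms whose Gabor fit quality falls below `threshold` (textural,
#' low-frequency or isotropic features with no defined orientation) are
#' flagged and excluded from all orientation-space analyses.
#'
#' @param dict An [sdpc_dictionary()] (first layer).
#' @param threshold Quality threshold for keeping a feature (default 0.5).
#' @param ... Passed to [fit_gabor()].
#' @return Data frame with one row per feature: `feature`, `theta`,
#'   `quality`, `r2`, `keep`.
#' @export
orientation_bank <- function(dict, threshold = 0.5, ...) {
  nf <- dim(dict$atoms)[1]
  rows <- lapply(seq_len(nf), function(f) {
    fit <- fit_gabor(array(dict$atoms[f, , , ], dim = dim(dict$atoms)[2:4]), ...)
    data.frame(feature = f, theta = fit$theta, quality = fit$quality,
               r2 = fit$r2)
  })
  out <- do.call(rbind, rows)
  out$keep <- !is.na(out$theta) & out$quality >= threshold
  out
}
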