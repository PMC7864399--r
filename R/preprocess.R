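# Image preprocessing: local contrast normalization and ZCA whitening.

# Separable Gaussian filtering with replicate padding ("same" output).
gaussian_filter <- function(mat, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_idx <- function(n) c(rep(1L, r), seq_len(n), rep(n, r))
  m <- mat[pad_idx(nrow(mat)), , drop = FALSE]
  m <- apply(m, 2, function(col) stats::filter(col, k)[(r + 1):(length(col) - r)])
  m <- m[, pad_idx(ncol(mat)), drop = FALSE]
  t(apply(m, 1, function(row) stats::filter(row, k)[(r + 1):(length(row) - r)]))
}

#' Local contrast normalization
#'
#' Subtractive then divisive normalization with a Gaussian window, applied
#' per channel: the local (Gaussian-weighted) mean is removed, then each
#' pixel is divided by the local standard deviation of the mean-removed
#' image, floored to avoid division by zero. A constant image maps to
#' zero.
#'
#' @param image Matrix or `[channels, W, H]` array.
#' @param sigma Gaussian window standard deviation in pixels (default 2).
#' @param floor Divisive floor on the local standard deviation
#'   (default 1e-4).
#' @return Normalized image, same shape as the input.
#' @export
local_contrast_normalize <- function(image, sigma = 2, floor = 1e-4) {
  x <- as_activity(image)
  for (c in seq_len(dim(x)[1])) {
    m <- x[c, , ]
    sub <- m - gaussian_filter(m, sigma)
    sd_loc <- sqrt(pmax(gaussian_filter(sub^2, sigma), 0))
    x[c, , ] <- sub / pmax(sd_loc, floor)
  }
  if (is.matrix(image)) x[1, , ] else x
}

#' Fit a ZCA whitening transform on image patches
#'
#' Extracts all (or up to `max_patches`) square patches from the training
#' images, and computes the symmetric whitening matrix
#' `W = U diag(1 / sqrt(max(d, eig_floor))) U^T` of their covariance.
#' The eigenvalue floor regularizes directions with near-zero variance.
#'
#' @param images List of matrices or `[channels, W, H]` arrays (whitening
#'   is fitted per set, channels pooled by averaging to grayscale).
#' @param patch Patch side in pixels (default 9).
#' @param eig_floor Eigenvalue floor (default 1e-2).
#' @param max_patches Cap on the number of patches used for the fit.
#' @param seed Seed for patch subsampling.
#' @return Object of class `sdpc_zca`: the whitening matrix `W`, the patch
#'   mean, the patch side, and the center-row convolution kernel used to
#'   whiten whole images.
#' @export
fit_whitening <- function(images, patch = 9L, eig_floor = 1e-2,
                          max_patches = 20000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pats <- do.call(rbind, lapply(images, function(im) {
    m <- as_activity(im)
    m <- apply(m, c(2, 3), mean)            # pool channels
    extract_patches(m, patch)
  }))
  if (nrow(pats) > max_patches)
    pats <- pats[sample.int(nrow(pats), max_patches), , drop = FALSE]
  mu <- colMeans(pats)
  cc <- stats::cov(sweep(pats, 2, mu))
  e <- eigen(cc, symmetric = TRUE)
  W <- e$vectors %*% diag(1 / sqrt(pmax(e$values, eig_floor))) %*% t(e$vectors)
  ctr <- (patch^2 + 1) %/% 2                 # row of W for the central pixel
  kern <- matrix(W[ctr, ], patch, patch)
  structure(list(W = W, mean = mu, patch = as.integer(patch), kernel = kern),
            class = "sdpc_zca")
}

# All overlapping patch x patch patches of a matrix, one per row.
extract_patches <- function(m, patch) {
  nr <- nrow(m) - patch + 1L
  nc <- ncol(m) - patch + 1L
  if (nr < 1L || nc < 1L) stop("image smaller than the patch size")
  out <- matrix(0, nr * nc, patch^2)
  idx <- 1L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    out[idx, ] <- as.vector(m[i:(i + patch - 1L), j:(j + patch - 1L)])
    idx <- idx + 1L
  }
  out
}

#' Whiten a set of patches with a fitted ZCA transform
#'
#' @param zca An [fit_whitening()] object.
#' @param patches Matrix, one flattened patch per row.
#' @return Whitened patches (same shape); their covariance is close to the
#'   identity on the data the transform was fitted to.
#' @export
whiten_patches <- function(zca, patches) {
  sweep(patches, 2, zca$mean) %*% zca$W
}

#' Apply a fitted whitening transform to a whole image
#'
#' Convolves each channel with the central row of the ZCA matrix (a
#' decorrelating, center-surround kernel), the standard way to extend a
#' patch-fitted whitener to full images.
#'
#' @param zca An [fit_whitening()] object.
#' @param image Matrix or `[channels, W, H]` array.
#' @return Whitened image, same shape.
#' @export
whiten_image <- function(zca, image) {
  x <- as_activity(image)
  k <- zca$kernel
  r <- (nrow(k) - 1L) %/% 2L
  for (c in seq_len(dim(x)[1])) {
    m <- x[c, , ]
    pad_idx <- function(n) c(rep(1L, r), seq_len(n), rep(n, r + (nrow(k) - 1L) %% 2L))
    mp <- m[pad_idx(nrow(m)), pad_idx(ncol(m))]
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_len(nrow(k))) for (j in seq_len(ncol(k))) {
      out <- out + k[i, j] *
        mp[(i - 1L) + seq_len(nrow(m)), (j - 1L) + seq_len(ncol(m))]
    }
    x[c, , ] <- out
  }
  if (is.matrix(image)) x[1, , ] else x
}

#' Standard image preprocessing: LCN then whitening
#'
#' @param image Matrix or `[channels, W, H]` array.
#' @param lcn Apply [local_contrast_normalize()] first.
#' @param zca Optional [fit_whitening()] object to apply afterwards.
#' @param ... Passed to [local_contrast_normalize()].
#' @return Preprocessed image, approximately zero-mean.
#' @export
preprocess <- function(image, lcn = TRUE, zca = NULL, ...) {
  out <- image
  if (lcn) out <- local_contrast_normalize(out, ...)
  if (!is.null(zca)) out <- whiten_image(zca, out)
  out
}
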