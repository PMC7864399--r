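# Feedback denoising evaluation: Gaussian corruption, structural
# similarity, and sweeps over feedback strength and first-layer sparsity.

#' Corrupt an image with additive Gaussian noise
#'
#' Adds i.i.d. `N(0, sigma^2)` noise per pixel and channel. Noise is added
#' in the image's current (preprocessed, normalized) units. `sigma = 0`
#' returns the input unchanged.
#'
#' @param image Matrix or `[channels, W, H]` array.
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Optional integer seed for a reproducible noise field.
#' @return Image of the same shape.
#' @export
corrupt <- function(image, sigma, seed = NULL) {
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(image)
  if (!is.null(seed)) set.seed(seed)
  image + array(rnorm(length(image), sd = sigma), dim = dim(image))
}

# 2-D "valid" correlation of a matrix with a small kernel.
filter2_valid <- function(m, k) {
  kw <- nrow(k); kh <- ncol(k)
  nr <- nrow(m) - kw + 1L; nc <- ncol(m) - kh + 1L
  out <- matrix(0, nr, nc)
  for (i in seq_len(kw)) for (j in seq_len(kh)) {
    out <- out + k[i, j] * m[(i - 1L) + seq_len(nr), (j - 1L) + seq_len(nc)]
  }
  out
}

#' Structural similarity index between two images
#'
#' The standard windowed luminance/contrast/structure comparison with a
#' Gaussian 11x11 window (sd 1.5) and the usual stabilization constants
#' `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`, where `L` is the dynamic range.
#' Multi-channel images are scored as the mean of the per-channel indices.
#' Symmetric in its arguments; 1 for identical images.
#'
#' @param a,b Images of equal shape (matrices or `[channels, W, H]`).
#' @param data_range Dynamic range `L`; defaults to the joint range of the
#'   two images (required because the model works in normalized units).
#' @param window Window side (default 11, reduced to the image size if
#'   larger).
#' @param sigma Gaussian window standard deviation (default 1.5).
#' @return Scalar in `[-1, 1]`.
#' @export
ssim <- function(a, b, data_range = NULL, window = 11L, sigma = 1.5) {
  x <- as_activity(a); y <- as_activity(b)
  if (!identical(dim(x), dim(y))) stop("images must have identical shapes")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("images must be finite")
  if (is.null(data_range)) data_range <- max(x, y) - min(x, y)
  if (data_range <= 0) data_range <- 1
  window <- min(window, dim(x)[2], dim(x)[3])
  r <- (window - 1) / 2
  g1 <- exp(-(seq_len(window) - 1 - r)^2 / (2 * sigma^2))
  k <- outer(g1, g1); k <- k / sum(k)
  c1 <- (0.01 * data_range)^2
  c2 <- (0.03 * data_range)^2
  per_channel <- vapply(seq_len(dim(x)[1]), function(ch) {
    mx <- filter2_valid(x[ch, , ], k)
    my <- filter2_valid(y[ch, , ], k)
    sxx <- filter2_valid(x[ch, , ]^2, k) - mx^2
    syy <- filter2_valid(y[ch, , ]^2, k) - my^2
    sxy <- filter2_valid(x[ch, , ] * y[ch, , ], k) - mx * my
    mean(((2 * mx * my + c1) * (2 * sxy + c2)) /
           ((mx^2 + my^2 + c1) * (sxx + syy + c2)))
  }, numeric(1))
  mean(per_channel)
}

#' Specification of a denoising sweep
#'
#' @param sigma Noise standard deviations (default 0 to 5).
#' @param k_fb Feedback strengths (default 0 to 4).
#' @param lambda1 First-layer sparsity penalties (default 0, 1.5, 3).
#' @param n_images Cap on the number of images evaluated (`NULL` = all).
#' @param seed Base seed for the noise fields; the same field is reused
#'   across feedback and sparsity conditions at a given image and noise
#'   level, so comparisons are paired.
#' @return Object of class `sdpc_sweep_spec`.
#' @export
sweep_spec <- function(sigma = 0:5, k_fb = 0:4, lambda1 = c(0, 1.5, 3),
                       n_images = NULL, seed = 1L) {
  if (!length(sigma) || !length(k_fb) || !length(lambda1))
    stop("grids must be non-empty")
  if (any(sigma < 0)) stop("sigma must be >= 0")
  structure(list(sigma = sigma, k_fb = k_fb, lambda1 = lambda1,
                 n_images = n_images, seed = as.integer(seed)),
            class = "sdpc_sweep_spec")
}

#' Evaluate feedback denoising over a noise/feedback/sparsity sweep
#'
#' For every image and condition, the image is corrupted, inference is run
#' (no retraining), each layer's activity is back-projected to the visual
#' space, and the structural similarity of that representation with the
#' original (non-degraded, preprocessed) image is recorded, together with
#' the baseline similarity between original and noisy image.
#'
#' @param network A trained [sdpc_network()].
#' @param images List of preprocessed images.
#' @param sweep A [sweep_spec()].
#' @param config Base [inference_config()] (`k_fb` is overridden per
#'   condition).
#' @param layers Layers whose representations are scored (default all).
#' @return Object of class `sdpc_denoise`: `results` (one row per image x
#'   condition x layer, with the per-image similarity and convergence
#'   flag), `baseline` (per image and noise level), and `summary`
#'   (median and median absolute deviation per condition and layer, with
#'   the baseline median attached; similarities clipped to `[0, 1]`).
#' @export
evaluate_denoising <- function(network, images, sweep = sweep_spec(),
                               config = inference_config(),
                               layers = seq_len(network$n_layers)) {
  if (!is.null(sweep$n_images) && length(images) > sweep$n_images)
    images <- images[seq_len(sweep$n_images)]
  images <- lapply(images, function(im)
    crop_to_grid(as_activity(im), network$dictionaries[[1L]]))
  eta_cache <- lapply(stats::setNames(nm = as.character(sweep$k_fb)),
                      function(kf)
    network_step_sizes(network, images[[1L]], k_fb = as.numeric(kf),
                       eta_mode = config$eta_mode))
  res <- list(); base <- list()
  for (ix in seq_along(images)) {
    orig <- images[[ix]]
    rng <- max(orig) - min(orig)
    for (si in seq_along(sweep$sigma)) {
      s <- sweep$sigma[si]
      noisy <- corrupt(orig, s, seed = sweep$seed + 7919L * ix + 104729L * si)
      base[[length(base) + 1L]] <- data.frame(
        image = ix, sigma = s,
        ssim = ssim(orig, noisy, data_range = rng))
      for (kf in sweep$k_fb) for (l1 in sweep$lambda1) {
        net <- network
        net$lambda[1L] <- l1
        cfg <- config
        cfg$k_fb <- kf
        if (is.null(config$eta))
          cfg$eta <- eta_cache[[as.character(kf)]]
        st <- run_inference(net, noisy, cfg)
        for (ly in layers) {
          eff <- back_project(net, st$activities[[ly]], ly)
          res[[length(res) + 1L]] <- data.frame(
            image = ix, sigma = s, k_fb = kf, lambda1 = l1, layer = ly,
            ssim = ssim(orig, eff, data_range = rng),
            converged = all(st$converged))
        }
      }
    }
  }
  results <- do.call(rbind, res)
  baseline <- do.call(rbind, base)
  base_med <- stats::aggregate(ssim ~ sigma, baseline, stats::median)
  names(base_med)[2] <- "baseline"
  summ <- stats::aggregate(ssim ~ sigma + k_fb + lambda1 + layer, results,
                           function(v) c(median = stats::median(v),
                                         mad = stats::mad(v), n = length(v)))
  summ <- cbind(summ[, 1:4], as.data.frame(summ$ssim))
  summ$median <- pmin(pmax(summ$median, 0), 1)
  summ <- merge(summ, base_med, by = "sigma")
  structure(list(results = results, baseline = baseline, summary = summ),
            class = "sdpc_denoise")
}

#' Paired Wilcoxon test between two denoising conditions
#'
#' Compares per-image similarities of two conditions (rows of `results`
#' selected by noise level, feedback strength, sparsity and layer), paired
#' by image.
#'
#' @param eval An [evaluate_denoising()] result.
#' @param cond_a,cond_b Named lists with any of `sigma`, `k_fb`,
#'   `lambda1`, `layer`; `cond_b` entries default to `cond_a`'s.
#' @param alternative Passed to [stats::wilcox.test()].
#' @return The `htest` object, with the number of pairs as `n`.
#' @export
denoise_wilcoxon <- function(eval, cond_a, cond_b,
                             alternative = "two.sided") {
  pick <- function(cond) {
    r <- eval$results
    for (nm in names(cond)) r <- r[r[[nm]] == cond[[nm]], , drop = FALSE]
    r[order(r$image), ]
  }
  cond_b <- modifyList(cond_a, cond_b)
  a <- pick(cond_a); b <- pick(cond_b)
  stopifnot(nrow(a) == nrow(b), all(a$image == b$image))
  ht <- stats::wilcox.test(a$ssim, b$ssim, paired = TRUE,
                           alternative = alternative, exact = FALSE)
  ht$n <- nrow(a)
  ht
}
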