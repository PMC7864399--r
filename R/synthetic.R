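# Synthetic data: planted dictionaries, scenes sampled from the model's
# own hierarchical generative process, and contour stimuli. Everything is
# deterministic under a fixed seed, so all analyses are testable without
# external image databases.

#' Planted dictionary of oriented Gabor atoms
#'
#' Unit-norm Gabor atoms at known orientations, mirroring the oriented,
#' localized receptive fields that sparse coding learns on natural
#' images. The ground-truth orientations are recorded in the
#' `"orientations"` attribute for recovery tests.
#'
#' @param n_features Number of atoms.
#' @param kernel Kernel side (default 9).
#' @param orientations Orientations in radians; default evenly spaced on
#'   `[0, pi)`.
#' @param freq Carrier frequency in cycles per pixel (default 0.25).
#' @param sigma Envelope standard deviation (default `kernel / 5`).
#' @param phases Carrier phases; default alternates even and odd pairs.
#' @param stride Stride of the resulting dictionary.
#' @param n_channels Number of input channels (atoms replicated across
#'   channels; default 1).
#' @return An [sdpc_dictionary()] with attribute `orientations`.
#' @export
make_gabor_dictionary <- function(n_features, kernel = 9L,
                                  orientations = NULL, freq = 0.25,
                                  sigma = kernel / 5, phases = NULL,
                                  stride = 1L, n_channels = 1L) {
  if (n_features < 1L) stop("n_features must be >= 1")
  if (is.null(orientations))
    orientations <- seq(0, pi, length.out = n_features + 1L)[seq_len(n_features)]
  orientations <- rep_len(orientations, n_features)
  if (is.null(phases)) phases <- rep_len(c(0, pi / 2), n_features)
  atoms <- array(0, dim = c(n_features, n_channels, kernel, kernel))
  for (f in seq_len(n_features)) {
    g <- gabor_patch(kernel, orientations[f], freq, phases[f], sigma)
    for (c in seq_len(n_channels)) atoms[f, c, , ] <- g
  }
  d <- sdpc_dictionary(atoms, stride = stride, normalize = TRUE)
  attr(d, "orientations") <- orientations %% pi
  d
}

#' Planted second-layer dictionary of collinear Gabor chains
#'
#' Each atom places positive weight on one first-layer feature plane,
#' along the line through the kernel center at that feature's preferred
#' orientation: a layer-2 unit that predicts a short contour of aligned
#' layer-1 edges. The atom bank cycles through the supplied orientations.
#'
#' @param n_features Number of layer-2 atoms.
#' @param orientations Preferred orientations of the layer-1 features
#'   (one per layer-1 feature; e.g. the `"orientations"` attribute of
#'   [make_gabor_dictionary()]).
#' @param kernel Kernel side (default 9).
#' @param width Transverse Gaussian width of the chain profile in layer-1
#'   grid units (default 0.8).
#' @param stride Stride of the dictionary.
#' @return An [sdpc_dictionary()] with attribute `features`, the layer-1
#'   feature each atom drives.
#' @export
make_collinear_dictionary <- function(n_features, orientations, kernel = 9L,
                                      width = 0.8, stride = 1L) {
  n1 <- length(orientations)
  atoms <- array(0, dim = c(n_features, n1, kernel, kernel))
  half <- (kernel - 1) / 2
  x <- matrix(seq_len(kernel) - 1 - half, kernel, kernel)
  y <- t(x)
  for (j in seq_len(n_features)) {
    f <- ((j - 1L) %% n1) + 1L
    th <- orientations[f]
    dist_line <- abs(-x * sin(th) + y * cos(th))   # distance to the chain axis
    along <- x * cos(th) + y * sin(th)
    prof <- exp(-dist_line^2 / (2 * width^2)) *
      exp(-along^2 / (2 * (half / 1.2)^2))
    atoms[j, f, , ] <- prof
  }
  sdpc_dictionary(atoms, stride = stride, normalize = TRUE)
}

#' Sample scenes from the hierarchical generative model
#'
#' Draws a sparse non-negative top-layer activity (`n_active` strictly
#' positive entries at uniform positions, amplitudes uniform on
#' `[0.5, 1.5]`), synthesizes the layer below with additive Gaussian
#' noise rectified at zero, and renders the image with its own additive
#' noise:
#' `gamma_1 = max(D_2^T gamma_2 + eps_2, 0)`, `x = D_1^T gamma_1 + eps_1`.
#' All latents and realized noises are recorded, so the image can be
#' reconstructed from them exactly. With `d2 = NULL` a single-layer scene
#' is generated (`gamma_1` sparse directly).
#'
#' @param d1 First-layer [sdpc_dictionary()].
#' @param d2 Optional second-layer dictionary.
#' @param map_size Spatial size of the top layer's activity map.
#' @param n_active Number of strictly positive top-layer coefficients.
#' @param noise_sd Length-2 vector `c(sd_eps1, sd_eps2)` of the image- and
#'   intermediate-level noise standard deviations.
#' @param amplitude Range of the active coefficients (default
#'   `c(0.5, 1.5)`).
#' @param n Number of scenes.
#' @param seed Integer seed (deterministic generation).
#' @return List of `sdpc_scene` objects with elements `image`, `gamma1`,
#'   `gamma2`, `eps1`, `eps2`, `seed`.
#' @export
sample_hierarchical <- function(d1, d2 = NULL, map_size = c(8L, 8L),
                                n_active = 3L, noise_sd = c(0, 0),
                                amplitude = c(0.5, 1.5), n = 1L, seed = 1L) {
  set.seed(seed)
  top <- if (is.null(d2)) d1 else d2
  nf_top <- dim(top$atoms)[1]
  cells <- nf_top * prod(map_size)
  if (n_active > cells)
    stop("requested sparsity exceeds the top activity map size")
  lapply(seq_len(n), function(ix) {
    g_top <- array(0, dim = c(nf_top, map_size))
    pos <- sample.int(cells, n_active)
    g_top[pos] <- runif(n_active, amplitude[1], amplitude[2])
    if (is.null(d2)) {
      gamma1 <- g_top
      gamma2 <- NULL
      eps2 <- NULL
    } else {
      gamma2 <- g_top
      pred1 <- synthesize(d2, gamma2)
      noise2 <- if (noise_sd[2] > 0)
        array(rnorm(length(pred1), sd = noise_sd[2]), dim = dim(pred1))
      else array(0, dim = dim(pred1))
      gamma1 <- pmax(pred1 + noise2, 0)
      eps2 <- gamma1 - pred1            # realized residual after rectification
    }
    pred0 <- synthesize(d1, gamma1)
    eps1 <- if (noise_sd[1] > 0)
      array(rnorm(length(pred0), sd = noise_sd[1]), dim = dim(pred0))
    else array(0, dim = dim(pred0))
    structure(list(image = pred0 + eps1, gamma1 = gamma1, gamma2 = gamma2,
                   eps1 = eps1, eps2 = eps2, seed = seed),
              class = "sdpc_scene")
  })
}

#' Render contour stimuli: chains of aligned Gabor patches
#'
#' A chain of identically oriented Gabor patches whose centers lie along
#' the `theta` axis through the image center (with optional positional
#' jitter), on a background of randomly placed and randomly oriented
#' distractor patches.
#'
#' @param theta Contour orientation in radians.
#' @param size Image side in pixels.
#' @param chain_length Number of aligned patches (default 5).
#' @param spacing Center-to-center distance along the chain in pixels.
#' @param jitter Standard deviation of the positional jitter (pixels).
#' @param n_distractors Number of background patches (default 6).
#' @param patch Gabor patch side (default 9).
#' @param freq Carrier frequency (default 0.25).
#' @param contrast Amplitude of the chain and distractor patches
#'   (default 1); sets the stimulus scale relative to the sparsity
#'   penalties.
#' @param noise_sd Standard deviation of an additive Gaussian background
#'   (default 0.1). A non-zero background keeps the first-layer code
#'   active everywhere, as on natural images, so marginal activities are
#'   well-defined references.
#' @param n Number of images.
#' @param seed Integer seed.
#' @return List of `size x size` image matrices; each carries the chain
#'   centers in the `"centers"` attribute.
#' @export
make_contour_images <- function(theta, size = 40L, chain_length = 5L,
                                spacing = 6, jitter = 0, n_distractors = 6L,
                                patch = 9L, freq = 0.25, contrast = 1,
                                noise_sd = 0.1, n = 1L, seed = 1L) {
  set.seed(seed)
  half_span <- (chain_length - 1) / 2 * spacing
  if (half_span + patch / 2 > size / 2)
    stop("chain does not fit in the image; reduce chain_length or spacing")
  stamp <- function(img, cx, cy, g) {
    p <- nrow(g)
    hp <- (p - 1L) %/% 2L
    xr <- (round(cx) - hp):(round(cx) + hp)
    yr <- (round(cy) - hp):(round(cy) + hp)
    okx <- xr >= 1L & xr <= nrow(img)
    oky <- yr >= 1L & yr <= ncol(img)
    img[xr[okx], yr[oky]] <- img[xr[okx], yr[oky]] + g[okx, oky]
    img
  }
  g_chain <- gabor_patch(patch, theta, freq) * contrast
  lapply(seq_len(n), function(ix) {
    img <- if (noise_sd > 0) matrix(rnorm(size * size, sd = noise_sd), size, size)
           else matrix(0, size, size)
    mid <- (size + 1) / 2
    offs <- (seq_len(chain_length) - (chain_length + 1) / 2) * spacing
    cx <- mid + offs * cos(theta) + if (jitter > 0) rnorm(chain_length, sd = jitter) else 0
    cy <- mid + offs * sin(theta) + if (jitter > 0) rnorm(chain_length, sd = jitter) else 0
    for (i in seq_len(chain_length)) img <- stamp(img, cx[i], cy[i], g_chain)
    for (d in seq_len(n_distractors)) {
      th_d <- runif(1, 0, pi)
      m <- patch / 2 + 1
      img <- stamp(img, runif(1, m, size - m), runif(1, m, size - m),
                   gabor_patch(patch, th_d, freq) * contrast)
    }
    attr(img, "centers") <- cbind(x = cx, y = cy)
    img
  })
}
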