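#' Specification of one convolutional sparse-coding layer
#'
#' A layer is a bank of `n_features` convolutional atoms of size
#' `n_channels x kernel[1] x kernel[2]`, applied with a spatial `stride`,
#' and regularized by an L1 penalty `lambda` on its (non-negative)
#' activity map.
#'
#' @param n_features Number of atoms (features) in the layer.
#' @param n_channels Number of input channels the atoms see (for the first
#'   layer, the image channels; for deeper layers, the feature count of the
#'   layer below).
#' @param kernel Kernel size, a single odd-or-even integer (square kernel)
#'   or a length-2 integer vector `c(w, h)`.
#' @param stride Spatial subsampling factor (integer, at least 1, at most
#'   the kernel side so receptive fields tile or overlap).
#' @param lambda Sparsity penalty for the layer's activity (non-negative).
#' @param step_mode `"auto"` to derive the inference step size from the
#'   operator's Lipschitz constant, or `"fixed"` to use a user-supplied step.
#'
#' @return An object of class `sdpc_layer_spec`.
#' @export
layer_spec <- function(n_features, n_channels, kernel, stride = 1L,
                       lambda = 0.1, step_mode = c("auto", "fixed")) {
  step_mode <- match.arg(step_mode)
  if (length(kernel) == 1L) kernel <- c(kernel, kernel)
  kernel <- as.integer(kernel)
  n_features <- as.integer(n_features)
  n_channels <- as.integer(n_channels)
  stride <- as.integer(stride)
  if (n_features < 1L || n_channels < 1L || any(kernel < 1L))
    stop("layer sizes must all be >= 1")
  if (stride < 1L) stop("stride must be >= 1")
  if (stride > min(kernel))
    stop("stride must not exceed the kernel side (receptive fields must tile or overlap)")
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be >= 0")
  structure(
    list(n_features = n_features, n_channels = n_channels,
         kernel = kernel, stride = stride, lambda = lambda,
         step_mode = step_mode),
    class = "sdpc_layer_spec")
}

#' Construct a convolutional dictionary
#'
#' A dictionary holds one layer's bank of synaptic weights: a 4-way array
#' of atoms indexed `[feature, channel, x, y]`, shared between the
#' feedforward (analysis) and feedback (synthesis) directions.
#'
#' @param atoms 4-way numeric array `[n_features, n_channels, w, h]`.
#' @param stride Spatial stride used when the dictionary synthesizes or
#'   analyzes a tensor.
#' @param normalize If `TRUE` (default) each atom is rescaled to unit
#'   L2 norm, the invariant maintained by learning.
#'
#' @return An object of class `sdpc_dictionary` with elements `atoms` and
#'   `stride`.
#' @export
sdpc_dictionary <- function(atoms, stride = 1L, normalize = TRUE) {
  if (!is.array(atoms) || length(dim(atoms)) != 4L)
    stop("atoms must be a 4-way array [feature, channel, x, y]")
  if (!all(is.finite(atoms))) stop("atoms must be finite")
  stride <- as.integer(stride)
  if (stride < 1L) stop("stride must be >= 1")
  d <- structure(list(atoms = atoms, stride = stride),
                 class = "sdpc_dictionary")
  if (normalize) d <- normalize_atoms(d)
  d
}

#' Rescale every atom of a dictionary to unit L2 norm
#'
#' Unit atom norms remove the scale redundancy between a dictionary and its
#' coefficients; learning renormalizes after every update. An atom that is
#' identically zero cannot be normalized and is re-drawn from the standard
#' normal distribution (with a warning).
#'
#' @param dict An [sdpc_dictionary()].
#' @return The dictionary with all atom norms equal to 1.
#' @export
normalize_atoms <- function(dict) {
  a <- dict$atoms
  nf <- dim(a)[1]
  amat <- matrix(a, nrow = nf)
  nrm <- sqrt(rowSums(amat^2))
  if (any(nrm == 0)) {
    warning("zero atom(s) reinitialized from the standard normal before normalization")
    for (f in which(nrm == 0)) amat[f, ] <- rnorm(ncol(amat))
    nrm <- sqrt(rowSums(amat^2))
  }
  dict$atoms <- array(amat / nrm, dim = dim(a))
  dict
}

#' Assemble a layered sparse predictive-coding network
#'
#' @param dictionaries List of [sdpc_dictionary()] objects, ordered from the
#'   image-facing layer upward. Channel counts must chain: layer `i`'s
#'   `n_channels` equals layer `i - 1`'s `n_features`.
#' @param lambda Numeric vector of per-layer sparsity penalties.
#'
#' @return An object of class `sdpc_network`.
#' @export
sdpc_network <- function(dictionaries, lambda) {
  if (!length(dictionaries)) stop("need at least one layer")
  lambda <- as.numeric(lambda)
  if (length(lambda) != length(dictionaries))
    stop("lambda must have one entry per layer")
  if (any(!is.finite(lambda)) || any(lambda < 0))
    stop("lambda must be finite and >= 0")
  for (i in seq_along(dictionaries)) {
    if (!inherits(dictionaries[[i]], "sdpc_dictionary"))
      stop("dictionaries must be sdpc_dictionary objects")
    if (i > 1L) {
      below <- dim(dictionaries[[i - 1L]]$atoms)[1]
      here <- dim(dictionaries[[i]]$atoms)[2]
      if (below != here)
        stop(sprintf("layer %d expects %d channels but layer %d has %d features",
                     i, here, i - 1L, below))
    }
  }
  structure(list(dictionaries = dictionaries, lambda = lambda,
                 n_layers = length(dictionaries)),
            class = "sdpc_network")
}

#' Initialize a network from layer specifications
#'
#' Atoms are drawn from the standard normal distribution and L2-normalized,
#' the standard starting point for dictionary learning.
#'
#' @param specs List of [layer_spec()] objects, image-facing layer first.
#' @param seed Optional integer seed for reproducible initialization.
#' @return An `sdpc_network`.
#' @export
init_network <- function(specs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dicts <- lapply(specs, function(s) {
    a <- array(rnorm(s$n_features * s$n_channels * prod(s$kernel)),
               dim = c(s$n_features, s$n_channels, s$kernel))
    sdpc_dictionary(a, stride = s$stride)
  })
  sdpc_network(dicts, vapply(specs, `[[`, numeric(1), "lambda"))
}

#' @export
print.sdpc_network <- function(x, ...) {
  cat(sprintf("sdpc_network with %d layer(s)\n", x$n_layers))
  for (i in seq_len(x$n_layers)) {
    d <- dim(x$dictionaries[[i]]$atoms)
    cat(sprintf("  layer %d: D [%d, %d, %d, %d], stride %d, lambda %.3g\n",
                i, d[1], d[2], d[3], d[4],
                x$dictionaries[[i]]$stride, x$lambda[i]))
  }
  invisible(x)
}

#' @export
print.sdpc_dictionary <- function(x, ...) {
  d <- dim(x$atoms)
  cat(sprintf("sdpc_dictionary: %d atoms of size %d x %d x %d, stride %d\n",
              d[1], d[2], d[3], d[4], x$stride))
  invisible(x)
}
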