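#' Configuration of the sparse inference process
#'
#' @param k_fb Feedback strength: weight of the higher layer's prediction
#'   error in each hidden layer's loss. `k_fb = 0` decouples the layers
#'   into independent convolutional LASSO problems.
#' @param t_fp Fixed-point threshold on the relative change of each
#'   activity map between iterations (default 5e-3). An all-zero map with
#'   zero change counts as converged.
#' @param max_iter Iteration cap for the inference loop.
#' @param acceleration `"fista"` (Nesterov momentum with the classical
#'   `t_{k+1} = (1 + sqrt(1 + 4 t_k^2)) / 2` schedule, no restarts) or
#'   `"ista"` (plain proximal gradient).
#' @param eta_mode `"coupled"` uses the step size `1 / (L + k_fb)`, which
#'   accounts for the feedback quadratic's extra curvature and guarantees
#'   stability; `"literal"` uses `1 / L` from the reconstruction term only.
#' @param eta Optional vector of fixed per-layer step sizes overriding the
#'   Lipschitz-derived ones.
#' @param record_loss If `TRUE`, per-sweep layer losses are stored in the
#'   returned state (slower; for diagnostics).
#'
#' @return An object of class `sdpc_inference_config`.
#' @export
inference_config <- function(k_fb = 1, t_fp = 5e-3, max_iter = 500L,
                             acceleration = c("fista", "ista"),
                             eta_mode = c("coupled", "literal"),
                             eta = NULL, record_loss = FALSE) {
  acceleration <- match.arg(acceleration)
  eta_mode <- match.arg(eta_mode)
  if (!is.finite(k_fb) || k_fb < 0) stop("k_fb must be >= 0")
  if (!is.finite(t_fp) || t_fp <= 0) stop("t_fp must be > 0")
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) stop("max_iter must be >= 1")
  structure(list(k_fb = k_fb, t_fp = t_fp, max_iter = max_iter,
                 acceleration = acceleration, eta_mode = eta_mode,
                 eta = eta, record_loss = record_loss),
            class = "sdpc_inference_config")
}

#' Empty network state for an input image
#'
#' Activity maps are initialized to zero (the inference starting point);
#' shapes follow the valid-convolution grid of each layer.
#'
#' @param network An [sdpc_network()].
#' @param image Matrix or `[channels, W, H]` array, already preprocessed
#'   and cropped to the network's grid (see [crop_to_grid()]).
#' @return An object of class `sdpc_state`.
#' @export
new_state <- function(network, image) {
  x <- as_activity(image)
  acts <- vector("list", network$n_layers)
  sz <- dim(x)[2:3]
  for (i in seq_len(network$n_layers)) {
    d <- network$dictionaries[[i]]
    sz <- activity_size(d, sz)
    acts[[i]] <- array(0, dim = c(dim(d$atoms)[1], sz))
  }
  structure(list(input = x, activities = acts,
                 residuals = NULL, losses = rep(NA_real_, network$n_layers),
                 iterations = 0L,
                 converged = rep(FALSE, network$n_layers)),
            class = "sdpc_state")
}

#' Loss of one layer given the current state
#'
#' `L_i = 1/2 ||gamma_{i-1} - D_i^T gamma_i||^2
#'        + k_fb/2 ||gamma_i - D_{i+1}^T gamma_{i+1}||^2
#'        + lambda_i ||gamma_i||_1`,
#' with `gamma_0` the input image and no feedback term at the top layer.
#' With `k_fb = 0` this is the convolutional LASSO objective of layer `i`.
#'
#' @param network An [sdpc_network()].
#' @param state An [new_state()]/[run_inference()] state.
#' @param layer_index Layer (1-based, image-facing layer first).
#' @param k_fb Feedback strength (default 0).
#' @param lambda Optional override of the layer's sparsity penalty.
#' @return Non-negative scalar.
#' @export
layer_loss <- function(network, state, layer_index, k_fb = 0, lambda = NULL) {
  L <- network$n_layers
  if (layer_index < 1L || layer_index > L) stop("layer index out of range")
  if (is.null(lambda)) lambda <- network$lambda[layer_index]
  below <- if (layer_index == 1L) state$input else state$activities[[layer_index - 1L]]
  g <- state$activities[[layer_index]]
  pred <- synthesize(network$dictionaries[[layer_index]], g)
  loss <- 0.5 * sum((below - pred)^2) + lambda * sum(abs(g))
  if (layer_index < L && k_fb > 0) {
    pred_above <- synthesize(network$dictionaries[[layer_index + 1L]],
                             state$activities[[layer_index + 1L]])
    loss <- loss + 0.5 * k_fb * sum((g - pred_above)^2)
  }
  loss
}

# One proximal-gradient update of layer i evaluated at the point `z`
# (the activity itself for ISTA, the extrapolated point for FISTA).
step_layer <- function(network, state, i, z, eta, k_fb) {
  d <- network$dictionaries[[i]]
  below <- if (i == 1L) state$input else state$activities[[i - 1L]]
  g <- z + eta * analyze(d, below - synthesize(d, z))
  if (i < network$n_layers && k_fb > 0) {
    pred_above <- synthesize(network$dictionaries[[i + 1L]],
                             state$activities[[i + 1L]])
    g <- g - k_fb * eta * (z - pred_above)
  }
  soft_threshold(g, eta * network$lambda[i])
}

#' One plain-ISTA inference step for a single layer
#'
#' Updates layer `layer_index` of the state once, holding all other layers
#' fixed: a gradient step on the layer loss followed by non-negative
#' soft thresholding.
#'
#' @inheritParams layer_loss
#' @param config An [inference_config()].
#' @return The updated (non-negative) activity map for that layer.
#' @export
inference_step <- function(network, state, layer_index, config = inference_config()) {
  if (layer_index < 1L || layer_index > network$n_layers)
    stop("layer index out of range")
  eta <- infer_steps(network, state, config)[layer_index]
  g <- step_layer(network, state, layer_index,
                  state$activities[[layer_index]], eta, config$k_fb)
  if (any(!is.finite(g)))
    stop(sprintf("divergence at layer %d: non-finite activity", layer_index))
  g
}

# Per-layer step sizes: 1 / L (literal) or 1 / (L + k_fb) below the top
# layer (coupled), unless fixed by config$eta.
infer_steps <- function(network, state, config) {
  L <- network$n_layers
  if (!is.null(config$eta)) {
    eta <- rep_len(as.numeric(config$eta), L)
    if (any(eta <= 0)) stop("fixed step sizes must be > 0")
    return(eta)
  }
  map_sizes <- lapply(state$activities, function(a) dim(a)[2:3])
  network_step_sizes(network, map_sizes = map_sizes, k_fb = config$k_fb,
                     eta_mode = config$eta_mode)
}

#' Per-layer inference step sizes for a network
#'
#' Computes each layer's Lipschitz constant (largest eigenvalue of its
#' analyze-synthesize operator) and returns the resulting step sizes.
#' Useful to precompute once and pass as `eta` to [inference_config()]
#' when running inference on many images of identical size.
#'
#' @param network An [sdpc_network()].
#' @param image Example image (used for the map sizes), or supply
#'   `map_sizes` directly.
#' @param map_sizes Optional list of per-layer spatial activity sizes.
#' @param k_fb Feedback strength (enters the coupled step size).
#' @param eta_mode `"coupled"` (`1 / (L + k_fb)` below the top layer) or
#'   `"literal"` (`1 / L`).
#' @param safety Multiplier (>= 1) applied to each Lipschitz constant;
#'   a value slightly above 1 keeps the step valid if the dictionary
#'   drifts between recomputations (as during learning).
#' @return Numeric vector of per-layer step sizes.
#' @export
network_step_sizes <- function(network, image = NULL, map_sizes = NULL,
                               k_fb = 0, eta_mode = c("coupled", "literal"),
                               safety = 1) {
  eta_mode <- match.arg(eta_mode)
  L <- network$n_layers
  if (is.null(map_sizes)) {
    x <- crop_to_grid(as_activity(image), network$dictionaries[[1L]])
    sz <- dim(x)[2:3]
    map_sizes <- vector("list", L)
    for (i in seq_len(L)) {
      sz <- activity_size(network$dictionaries[[i]], sz)
      map_sizes[[i]] <- sz
    }
  }
  vapply(seq_len(L), function(i) {
    lip <- safety * lipschitz_constant(network$dictionaries[[i]],
                                       map_sizes[[i]])
    extra <- if (eta_mode == "coupled" && i < L) k_fb else 0
    1 / (lip + extra)
  }, numeric(1))
}

#' Run sparse inference to a fixed point
#'
#' Iterates proximal-gradient sweeps over the layers (image-facing layer
#' first, each layer seeing the freshest neighbours) until the relative
#' change of every activity map falls below `config$t_fp`, or `max_iter`
#' is reached (in which case the `converged` flags stay `FALSE`; never
#' silent). FISTA momentum is applied per layer.
#'
#' @param network An [sdpc_network()].
#' @param image Matrix or `[channels, W, H]` array (preprocessed; cropped
#'   automatically to the first layer's grid).
#' @param config An [inference_config()].
#' @return An `sdpc_state` with converged activities, residuals
#'   `eps_i = gamma_{i-1} - D_i^T gamma_i`, per-layer losses, the iteration
#'   count and per-layer convergence flags.
#' @export
run_inference <- function(network, image, config = inference_config()) {
  image <- crop_to_grid(as_activity(image), network$dictionaries[[1L]])
  state <- new_state(network, image)
  L <- network$n_layers
  eta <- infer_steps(network, state, config)
  fista <- config$acceleration == "fista"

  if (!config$record_loss) {
    # compiled fast path (identical update order and criterion)
    out <- sdpc_infer_cpp(image,
                          lapply(network$dictionaries, `[[`, "atoms"),
                          vapply(network$dictionaries, `[[`, integer(1), "stride"),
                          network$lambda, eta, config$k_fb, config$t_fp,
                          config$max_iter, fista)
    state$activities <- out$activities
    state$iterations <- out$iterations
    state$converged <- as.logical(out$converged)
    return(finalize_state(network, state, config))
  }

  y <- state$activities        # extrapolated points
  tk <- 1
  loss_hist <- if (config$record_loss) list() else NULL

  for (it in seq_len(config$max_iter)) {
    conv <- logical(L)
    tk1 <- if (fista) (1 + sqrt(1 + 4 * tk^2)) / 2 else 1
    for (i in seq_len(L)) {
      old <- state$activities[[i]]
      z <- if (fista) y[[i]] else old
      g <- step_layer(network, state, i, z, eta[i], config$k_fb)
      if (any(!is.finite(g)))
        stop(sprintf("divergence at layer %d, iteration %d: non-finite activity", i, it))
      if (fista) y[[i]] <- g + ((tk - 1) / tk1) * (g - old)
      state$activities[[i]] <- g
      dn <- sqrt(sum((g - old)^2))
      gn <- sqrt(sum(g^2))
      conv[i] <- if (gn == 0) dn == 0 else (dn / gn) < config$t_fp
    }
    tk <- tk1
    if (config$record_loss)
      loss_hist[[it]] <- vapply(seq_len(L), function(i)
        layer_loss(network, state, i, config$k_fb), numeric(1))
    state$iterations <- it
    if (all(conv)) { state$converged <- conv; break }
    state$converged <- conv
  }

  if (config$record_loss)
    state$loss_history <- do.call(rbind, loss_hist)
  finalize_state(network, state, config)
}

# Populate residuals and per-layer losses of a finished state.
finalize_state <- function(network, state, config) {
  L <- network$n_layers
  state$residuals <- lapply(seq_len(L), function(i) {
    below <- if (i == 1L) state$input else state$activities[[i - 1L]]
    below - synthesize(network$dictionaries[[i]], state$activities[[i]])
  })
  state$losses <- vapply(seq_len(L), function(i)
    layer_loss(network, state, i, config$k_fb), numeric(1))
  state
}

#' @export
print.sdpc_state <- function(x, ...) {
  cat(sprintf("sdpc_state: %d layer(s), %d iteration(s), converged: %s\n",
              length(x$activities), x$iterations,
              paste(x$converged, collapse = " ")))
  for (i in seq_along(x$activities)) {
    g <- x$activities[[i]]
    cat(sprintf("  layer %d: [%s], %d active (%.1f%%), loss %.4g\n", i,
                paste(dim(g), collapse = ", "), sum(g > 0),
                100 * mean(g > 0), x$losses[i]))
  }
  invisible(x)
}
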