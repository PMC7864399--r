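#' Configuration of dictionary learning
#'
#' Defaults follow the reference training regime: heavy-ball momentum 0.9,
#' batches of 10 images with the gradient averaged over the batch, and
#' per-layer learning rates.
#'
#' @param epochs Number of passes over the training set (>= 1).
#' @param lr Per-layer learning rates (recycled to the number of layers).
#' @param momentum Heavy-ball momentum coefficient on the dictionary
#'   gradient, in `[0, 1)`.
#' @param batch_size Images per batch; the dictionary is updated once per
#'   batch with the averaged gradient.
#' @param seed Integer seed controlling batch shuffling (and nothing else).
#' @param max_growth Abort threshold: if one update would grow an atom's
#'   norm by more than this factor before renormalization, the learning
#'   rate is considered unstable.
#' @param shuffle Shuffle image order each epoch.
#' @return An object of class `sdpc_train_config`.
#' @export
train_config <- function(epochs = 250L, lr = c(1e-4, 5e-3), momentum = 0.9,
                         batch_size = 10L, seed = NULL, max_growth = 10,
                         shuffle = TRUE) {
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (any(lr < 0)) stop("learning rates must be >= 0")
  if (momentum < 0 || momentum >= 1) stop("momentum must be in [0, 1)")
  structure(list(epochs = epochs, lr = lr, momentum = momentum,
                 batch_size = as.integer(batch_size), seed = seed,
                 max_growth = max_growth, shuffle = shuffle),
            class = "sdpc_train_config")
}

#' One local Hebbian-style dictionary update
#'
#' The gradient of the layer's reconstruction loss with respect to the
#' dictionary is the correlation of the layer's activity with its
#' prediction residual (`target - synthesize(dict, activity)`); the update
#' moves the atoms along that correlation, applies heavy-ball momentum,
#' and renormalizes every atom to unit L2 norm.
#'
#' @param dict An [sdpc_dictionary()].
#' @param activity The layer's converged activity map.
#' @param target The tensor the layer predicts (the input image for layer
#'   1, the activity below otherwise).
#' @param lr Learning rate.
#' @param momentum Momentum coefficient.
#' @param velocity Previous momentum buffer (array shaped like the atoms),
#'   or `NULL` at the first step.
#' @param max_growth Error threshold on pre-normalization atom-norm growth.
#' @return List with elements `dict` (updated, atoms unit norm) and
#'   `velocity` (the new momentum buffer).
#' @export
dictionary_update <- function(dict, activity, target, lr, momentum = 0,
                              velocity = NULL, max_growth = 10) {
  act <- as_activity(activity)
  tgt <- as_activity(target)
  dd <- dim(dict$atoms)
  resid <- tgt - synthesize(dict, act)
  grad <- conv_dict_grad_cpp(resid, act, dd[3], dd[4], dict$stride)
  if (is.null(velocity)) velocity <- array(0, dim = dd)
  velocity <- momentum * velocity + grad
  new_atoms <- dict$atoms + lr * velocity
  nf <- dd[1]
  old_n <- sqrt(rowSums(matrix(dict$atoms, nrow = nf)^2))
  new_n <- sqrt(rowSums(matrix(new_atoms, nrow = nf)^2))
  if (any(new_n > max_growth * pmax(old_n, .Machine$double.eps)))
    stop("dictionary update exploded (atom norm growth exceeded max_growth); reduce the learning rate")
  dict$atoms <- new_atoms
  list(dict = normalize_atoms(dict), velocity = velocity)
}

#' Match a learned dictionary against a reference dictionary
#'
#' For every reference atom, finds the best-matching learned atom under
#' greedy bipartite assignment, scoring each pair by the peak absolute
#' normalized cross-correlation over relative spatial displacements. The
#' displacement maximum is essential for convolutional dictionaries: the
#' generative model is invariant to translating an atom while
#' counter-translating its activations, so a perfectly recovered atom may
#' sit off-center in its kernel.
#'
#' @param learned,reference [sdpc_dictionary()] objects (or 4-way atom
#'   arrays) with identically shaped atoms.
#' @param max_shift Largest displacement searched per axis (default half
#'   the kernel).
#' @return Numeric vector: for each reference atom, the matched
#'   correlation in `[0, 1]`.
#' @export
dictionary_match <- function(learned, reference, max_shift = NULL) {
  A <- if (inherits(learned, "sdpc_dictionary")) learned$atoms else learned
  B <- if (inherits(reference, "sdpc_dictionary")) reference$atoms else reference
  stopifnot(identical(dim(A)[-1], dim(B)[-1]))
  k <- dim(A)[3]
  if (is.null(max_shift)) max_shift <- k %/% 2
  unit <- function(v) v / sqrt(sum(v^2))
  shift_corr <- function(a, b) {
    best <- 0
    for (dx in -max_shift:max_shift) for (dy in -max_shift:max_shift) {
      ia <- max(1, 1 + dx):min(k, k + dx); ib <- ia - dx
      ja <- max(1, 1 + dy):min(k, k + dy); jb <- ja - dy
      ov <- abs(sum(a[, ia, ja] * b[, ib, jb]))
      if (ov > best) best <- ov
    }
    best
  }
  na <- dim(A)[1]; nb <- dim(B)[1]
  C <- matrix(0, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb))
    C[i, j] <- shift_corr(unit(array(A[i, , , ], dim(A)[2:4])),
                          unit(array(B[j, , , ], dim(B)[2:4])))
  out <- numeric(nb)
  for (s in seq_len(min(na, nb))) {
    ix <- which(C == max(C), arr.ind = TRUE)[1, ]
    out[ix[2]] <- C[ix[1], ix[2]]
    C[ix[1], ] <- -1
    C[, ix[2]] <- -1
  }
  out
}

#' Train a network by alternating inference and dictionary learning
#'
#' For every batch, inference is run to a fixed point on each image (with
#' the configured feedback strength, 1 by default as in the reference
#' regime), the per-layer dictionary gradients are averaged over the
#' batch, and one momentum update with atom renormalization is applied
#' per layer.
#'
#' @param images List of preprocessed images (matrices or
#'   `[channels, W, H]` arrays of identical shape).
#' @param network Initial [sdpc_network()] (e.g. from [init_network()]).
#' @param tc A [train_config()].
#' @param ic An [inference_config()]; its `k_fb` is used during learning.
#' @param verbose Print one line per epoch.
#' @return List with elements `network` (trained) and `history` (one row
#'   per epoch: per-layer mean loss, mean fraction of active units, and
#'   the fraction of converged inferences).
#' @export
sdpc_train <- function(images, network, tc = train_config(),
                       ic = inference_config(), verbose = FALSE) {
  if (!is.null(tc$seed)) set.seed(tc$seed)
  L <- network$n_layers
  lr <- rep_len(tc$lr, L)
  velocity <- vector("list", L)
  n <- length(images)
  hist_rows <- vector("list", tc$epochs)

  for (ep in seq_len(tc$epochs)) {
    # step sizes recomputed once per epoch; the 10% margin on the
    # Lipschitz constants keeps the step valid as the atoms drift
    ic$eta <- network_step_sizes(network, images[[1L]], k_fb = ic$k_fb,
                                 eta_mode = ic$eta_mode, safety = 1.1)
    ord <- if (tc$shuffle) sample.int(n) else seq_len(n)
    batches <- split(ord, ceiling(seq_along(ord) / tc$batch_size))
    loss_acc <- matrix(0, n, L)
    act_frac <- conv_frac <- numeric(n)
    img_i <- 0L
    for (b in batches) {
      grads <- lapply(seq_len(L), function(i)
        array(0, dim = dim(network$dictionaries[[i]]$atoms)))
      for (ix in b) {
        st <- run_inference(network, images[[ix]], ic)
        if (any(!is.finite(st$losses)))
          stop(sprintf("non-finite loss during training (epoch %d, image %d)", ep, ix))
        for (i in seq_len(L)) {
          d <- network$dictionaries[[i]]
          dd <- dim(d$atoms)
          grads[[i]] <- grads[[i]] +
            conv_dict_grad_cpp(st$residuals[[i]], st$activities[[i]],
                               dd[3], dd[4], d$stride) / length(b)
        }
        img_i <- img_i + 1L
        loss_acc[img_i, ] <- st$losses
        act_frac[img_i] <- mean(st$activities[[1L]] > 0)
        conv_frac[img_i] <- all(st$converged)
      }
      for (i in seq_len(L)) {
        if (is.null(velocity[[i]]))
          velocity[[i]] <- array(0, dim = dim(grads[[i]]))
        velocity[[i]] <- tc$momentum * velocity[[i]] + grads[[i]]
        d <- network$dictionaries[[i]]
        new_atoms <- d$atoms + lr[i] * velocity[[i]]
        nf <- dim(new_atoms)[1]
        old_n <- sqrt(rowSums(matrix(d$atoms, nrow = nf)^2))
        new_n <- sqrt(rowSums(matrix(new_atoms, nrow = nf)^2))
        if (any(new_n > tc$max_growth * pmax(old_n, .Machine$double.eps)))
          stop("dictionary update exploded; reduce the learning rate")
        d$atoms <- new_atoms
        network$dictionaries[[i]] <- normalize_atoms(d)
      }
    }
    hist_rows[[ep]] <- c(epoch = ep,
                         stats::setNames(colMeans(loss_acc), paste0("loss_l", seq_len(L))),
                         active_frac_l1 = mean(act_frac),
                         converged_frac = mean(conv_frac))
    if (verbose)
      message(sprintf("epoch %d: loss %s, l1 active %.3f", ep,
                      paste(sprintf("%.4g", colMeans(loss_acc)), collapse = "/"),
                      mean(act_frac)))
  }
  list(network = network, history = as.data.frame(do.call(rbind, hist_rows)))
}
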