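#' Effective dictionary: a layer's atoms back-projected to image space
#'
#' The effective dictionary composes the synthesis (feedback) operators of
#' all layers below: each layer-`i` atom, itself a pattern over layer
#' `i - 1` features, is rendered as a visual-space patch. These patches
#' are the model's receptive fields. The spatial support grows with depth:
#' `k_eff(i) = k_eff(i-1) + (k_i - 1) * prod(strides below i)`, with
#' `k_eff(1) = k_1`.
#'
#' @param network An [sdpc_network()].
#' @param layer_index Layer whose atoms to back-project.
#' @return 4-way array `[n_features, image_channels, k_eff, k_eff]`.
#' @export
effective_dictionary <- function(network, layer_index) {
  if (layer_index < 1L || layer_index > network$n_layers)
    stop("layer index out of range")
  d <- network$dictionaries[[layer_index]]
  if (layer_index == 1L) return(d$atoms)
  nf <- dim(d$atoms)[1]
  patches <- lapply(seq_len(nf), function(f) {
    # one atom, viewed as an activity map of the layer below
    act <- array(d$atoms[f, , , ], dim = dim(d$atoms)[2:4])
    for (i in rev(seq_len(layer_index - 1L)))
      act <- synthesize(network$dictionaries[[i]], act)
    act
  })
  out <- array(0, dim = c(nf, dim(patches[[1L]])))
  for (f in seq_len(nf)) out[f, , , ] <- patches[[f]]
  out
}

#' Back-project an activity map into the visual space
#'
#' `gamma_i^eff = D_i^eff^T gamma_i`: composes the synthesis operators of
#' layers `i, i-1, ..., 1`, turning a deep activity map into the image it
#' represents (the layer's "representation" of the input). Linear in the
#' activity; for layer 1 it coincides with [synthesize()].
#'
#' @param network An [sdpc_network()].
#' @param activity 3-way array of layer `layer_index` activities.
#' @param layer_index The layer the activity belongs to.
#' @return Image-shaped array `[channels, W, H]`.
#' @export
back_project <- function(network, activity, layer_index) {
  if (layer_index < 1L || layer_index > network$n_layers)
    stop("layer index out of range")
  out <- as_activity(activity)
  for (i in rev(seq_len(layer_index)))
    out <- synthesize(network$dictionaries[[i]], out)
  out
}
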