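# Shared study setup for the scaled-down experiments: a two-layer toy
# network mirroring the natural-image architecture (9x9 kernels, first
# layer stride 2, lambda = (0.4, 1.2), trained with feedback strength 1
# on scenes from the model's own generative process). Built once per test
# run and cached.

study_env <- new.env(parent = emptyenv())

study_dictionaries <- function() {
  d1 <- make_gabor_dictionary(8, 9, stride = 2)
  d2 <- make_collinear_dictionary(12, attr(d1, "orientations"), 9)
  list(d1 = d1, d2 = d2)
}

# Top-layer amplitudes are scaled so intermediate activities are order 1,
# the scale the reference sparsity penalties assume.
study_scenes <- function(n, seed) {
  dd <- study_dictionaries()
  sample_hierarchical(dd$d1, dd$d2, map_size = c(5, 5), n_active = 3,
                      noise_sd = c(0.02, 0.02), amplitude = c(3, 6),
                      n = n, seed = seed)
}

study_network <- function() {
  if (!is.null(study_env$net)) return(study_env$net)
  imgs <- lapply(study_scenes(200, seed = 101), `[[`, "image")
  net0 <- init_network(list(layer_spec(8, 1, 9, 2, lambda = 0.4),
                            layer_spec(12, 8, 9, 1, lambda = 1.2)),
                       seed = 55)
  fit <- sdpc_train(imgs, net0,
                    train_config(epochs = 10, lr = 0.05, momentum = 0.9,
                                 batch_size = 10, seed = 9),
                    inference_config(k_fb = 1, max_iter = 100))
  study_env$net <- fit$network
  study_env$net
}
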