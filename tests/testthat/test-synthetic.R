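# Synthetic generators: planted dictionaries, hierarchical scenes,
# contour stimuli.

test_that("planted Gabor dictionaries are unit-norm, deterministic, recoverable", {
  d <- make_gabor_dictionary(4, 9, orientations = c(0, pi / 4, pi / 2, 3 * pi / 4))
  norms <- sqrt(rowSums(matrix(d$atoms, nrow = 4)^2))
  expect_equal(norms, rep(1, 4), tolerance = 1e-12)
  expect_identical(d$atoms,
                   make_gabor_dictionary(4, 9,
                     orientations = c(0, pi / 4, pi / 2, 3 * pi / 4))$atoms)
  # round-trip through the Gabor fit
  for (f in 1:4) {
    fit <- fit_gabor(array(d$atoms[f, , , ], c(1, 9, 9)))
    expect_lt(orientation_diff(fit$theta, attr(d, "orientations")[f]) * 180 / pi, 3)
  }
  expect_error(make_gabor_dictionary(2, 3, freq = 0.05), "frequency")
})

test_that("hierarchical scenes satisfy the generative algebra exactly", {
  d1 <- make_gabor_dictionary(4, 9)
  d2 <- make_collinear_dictionary(6, attr(d1, "orientations"), 9)
  scenes <- sample_hierarchical(d1, d2, map_size = c(5, 5), n_active = 3,
                                noise_sd = c(0.05, 0.05), n = 5, seed = 110)
  for (sc in scenes) {
    expect_equal(sum(sc$gamma2 > 0), 3)
    expect_true(all(sc$gamma1 >= 0))
    # x = D1^T gamma1 + eps1 exactly
    expect_lt(max(abs(sc$image - (synthesize(d1, sc$gamma1) + sc$eps1))), 1e-10)
    # gamma1 = D2^T gamma2 + eps2 exactly (eps2 holds the rectified residual)
    expect_lt(max(abs(sc$gamma1 - (synthesize(d2, sc$gamma2) + sc$eps2))), 1e-10)
  }
  # determinism
  s2 <- sample_hierarchical(d1, d2, map_size = c(5, 5), n_active = 3,
                            noise_sd = c(0.05, 0.05), n = 5, seed = 110)
  expect_identical(scenes[[3]]$image, s2[[3]]$image)
  expect_error(sample_hierarchical(d1, d2, map_size = c(2, 2), n_active = 1e5),
               "sparsity")
})

test_that("a noiseless single active unit renders one effective atom", {
  d1 <- make_gabor_dictionary(4, 9)
  d2 <- make_collinear_dictionary(4, attr(d1, "orientations"), 9)
  sc <- sample_hierarchical(d1, d2, map_size = c(3, 3), n_active = 1,
                            noise_sd = c(0, 0), n = 1, seed = 111)[[1]]
  net <- sdpc_network(list(d1, d2), lambda = c(0, 0))
  expect_equal(sc$image, back_project(net, sc$gamma2, 2), tolerance = 1e-12)
})

test_that("inference recovers planted supports on noiseless scenes", {
  d1 <- make_gabor_dictionary(4, 9, orientations = c(0, pi / 4, pi / 2, 3 * pi / 4))
  scenes <- sample_hierarchical(d1, NULL, map_size = c(8, 8), n_active = 2,
                                noise_sd = c(0, 0), n = 20, seed = 112)
  net <- sdpc_network(list(d1), lambda = 0.05)
  eta <- network_step_sizes(net, scenes[[1]]$image)
  cfg <- inference_config(k_fb = 0, max_iter = 300, t_fp = 1e-5, eta = eta)
  prec <- sapply(scenes, function(sc) {
    st <- run_inference(net, sc$image, cfg)
    g <- st$activities[[1]]
    # top-|support| estimated positions vs planted support
    truth <- which(sc$gamma1 > 0)
    est <- order(g, decreasing = TRUE)[seq_along(truth)]
    mean(est %in% truth)
  })
  expect_gte(mean(prec), 0.9)
})

test_that("contour images: collinear centers, rotation, matched-filter response", {
  imgs <- make_contour_images(0, size = 40, chain_length = 5, spacing = 6,
                              jitter = 0, n_distractors = 0, noise_sd = 0,
                              n = 1, seed = 113)
  ctr <- attr(imgs[[1]], "centers")
  # jitter 0: centers exactly collinear along the theta axis
  expect_equal(ctr[, "y"], rep(20.5, 5))
  expect_equal(diff(ctr[, "x"]), rep(6, 4))
  # rotating theta by 90 degrees rotates the image
  im0 <- imgs[[1]]
  im90 <- make_contour_images(pi / 2, size = 40, chain_length = 5, spacing = 6,
                              jitter = 0, n_distractors = 0, noise_sd = 0,
                              n = 1, seed = 113)[[1]]
  expect_equal(sum(im90^2), sum(im0^2), tolerance = 1e-9)
  expect_gt(cor(as.vector(t(im0)), as.vector(im90)), 0.99)
  # layer-1 inference responds maximally at chain positions for the
  # matching orientation feature
  d1 <- make_gabor_dictionary(4, 9, orientations = c(0, pi / 4, pi / 2, 3 * pi / 4))
  net <- sdpc_network(list(d1), lambda = 0.1)
  st <- run_inference(net, imgs[[1]], inference_config(k_fb = 0, max_iter = 150))
  g <- st$activities[[1]]
  by_feature <- apply(g, 1, max)
  expect_equal(which.max(by_feature), 1L)        # the 0-degree feature wins
  top <- which(g[1, , ] == max(g[1, , ]), arr.ind = TRUE)[1, ]
  d_to_chain <- min(sqrt((ctr[, "x"] - 4 - top[1])^2 +
                         (ctr[, "y"] - 4 - top[2])^2))
  expect_lte(d_to_chain, 2)
  # chain fitting is validated
  expect_error(make_contour_images(0, size = 20, chain_length = 9, spacing = 6),
               "does not fit")
})

test_that("generators are deterministic under a fixed seed", {
  a <- make_contour_images(pi / 6, n = 3, jitter = 0.5, seed = 114)
  b <- make_contour_images(pi / 6, n = 3, jitter = 0.5, seed = 114)
  expect_identical(a, b)
})
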