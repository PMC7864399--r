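# Sparse inference: losses, single steps, fixed points, and the LASSO
# equivalence with the dense formulation when feedback is off.

make_toy_net <- function(lambda = 0.05, seed = 30) {
  d1 <- rand_dict(2, 1, 3, stride = 1, seed = seed)
  sdpc_network(list(d1), lambda = lambda)
}

test_that("layer loss reduces to the expected closed forms", {
  net <- make_toy_net(lambda = 0.3)
  img <- array(rnorm(1 * 6 * 6), c(1, 6, 6))
  st <- new_state(net, img)
  # all activities zero -> loss = 0.5 ||input||^2
  expect_equal(layer_loss(net, st, 1), 0.5 * sum(img^2))
  # top layer, k_fb irrelevant: reconstruction + L1 exactly
  st$activities[[1]] <- rand_act(2, 4, 4, seed = 31, nonneg = TRUE)
  pred <- synthesize(net$dictionaries[[1]], st$activities[[1]])
  expect_equal(layer_loss(net, st, 1, k_fb = 2),
               0.5 * sum((img - pred)^2) + 0.3 * sum(st$activities[[1]]))
  expect_error(layer_loss(net, st, 3), "out of range")
})

test_that("two-layer loss matches independent term-by-term evaluation", {
  d1 <- rand_dict(2, 1, 3, stride = 1, seed = 32)
  d2 <- rand_dict(3, 2, 2, stride = 1, seed = 33)
  net <- sdpc_network(list(d1, d2), lambda = c(0.1, 0.2))
  img <- array(rnorm(36), c(1, 6, 6))
  st <- new_state(net, img)
  st$activities[[1]] <- rand_act(2, 4, 4, seed = 34, nonneg = TRUE)
  st$activities[[2]] <- rand_act(3, 3, 3, seed = 35, nonneg = TRUE)
  pred1 <- oracle_synthesize(d1$atoms, st$activities[[1]], 1)
  pred2 <- oracle_synthesize(d2$atoms, st$activities[[2]], 1)
  k_fb <- 1.5
  expect_equal(layer_loss(net, st, 1, k_fb = k_fb),
               0.5 * sum((img - pred1)^2) +
                 0.5 * k_fb * sum((st$activities[[1]] - pred2)^2) +
                 0.1 * sum(abs(st$activities[[1]])))
})

test_that("a huge sparsity penalty keeps the zero state fixed", {
  net <- make_toy_net(lambda = 1e3)
  img <- array(rnorm(36), c(1, 6, 6))
  st <- new_state(net, img)
  g <- inference_step(net, st, 1)
  expect_true(all(g == 0))
})

test_that("with orthonormal atoms and no penalty one step solves least squares", {
  # stride = kernel side: non-overlapping patches, operator has orthonormal columns
  d <- rand_dict(1, 1, 3, stride = 3, seed = 36)
  net <- sdpc_network(list(d), lambda = 0)
  img <- array(rnorm(36), c(1, 6, 6))
  st <- new_state(net, img)
  g <- inference_step(net, st, 1, inference_config(k_fb = 0))
  ls <- analyze(d, img)           # least-squares coefficients (orthonormal)
  expect_equal(g, pmax(ls, 0) * 1, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(dim(g), dim(ls))
})

test_that("plain-ISTA single-layer loss sequence is non-increasing", {
  net <- make_toy_net(lambda = 0.1)
  img <- array(rnorm(64), c(1, 8, 8))
  st <- run_inference(net, img,
                      inference_config(k_fb = 0, acceleration = "ista",
                                       max_iter = 60, record_loss = TRUE))
  dl <- diff(st$loss_history[, 1])
  expect_true(all(dl <= 1e-10))
})

test_that("FISTA reaches an objective no worse than ISTA at equal budget", {
  net <- make_toy_net(lambda = 0.1)
  img <- array(rnorm(64), c(1, 8, 8))
  cfg <- function(acc) inference_config(k_fb = 0, acceleration = acc,
                                        max_iter = 40, t_fp = 1e-12)
  st_f <- run_inference(net, img, cfg("fista"))
  st_i <- run_inference(net, img, cfg("ista"))
  expect_lte(st_f$losses[1], st_i$losses[1] + 1e-8)
})

test_that("zero image converges immediately to the zero state", {
  net <- make_toy_net()
  st <- run_inference(net, array(0, c(1, 6, 6)))
  expect_true(all(st$activities[[1]] == 0))
  expect_true(all(st$converged))
  expect_equal(st$iterations, 1L)
})

test_that("inference is deterministic: identical runs give identical states", {
  net <- make_toy_net()
  img <- array(rnorm(64), c(1, 8, 8))
  s1 <- run_inference(net, img)
  s2 <- run_inference(net, img)
  expect_identical(s1$activities, s2$activities)
  expect_identical(s1$losses, s2$losses)
})

test_that("compiled and reference inference loops agree exactly", {
  d1 <- rand_dict(2, 1, 3, stride = 1, seed = 37)
  d2 <- rand_dict(3, 2, 2, stride = 1, seed = 38)
  net <- sdpc_network(list(d1, d2), lambda = c(0.05, 0.05))
  img <- array(rnorm(36), c(1, 6, 6))
  for (acc in c("fista", "ista")) for (kf in c(0, 1)) {
    fast <- run_inference(net, img, inference_config(
      k_fb = kf, acceleration = acc, max_iter = 50))
    slow <- run_inference(net, img, inference_config(
      k_fb = kf, acceleration = acc, max_iter = 50, record_loss = TRUE))
    expect_equal(fast$activities, slow$activities, tolerance = 1e-14)
    expect_equal(fast$iterations, slow$iterations)
  }
})

test_that("with k_fb = 0 the converged activity attains the dense LASSO objective", {
  d <- rand_dict(2, 1, 3, stride = 1, seed = 39)
  lambda <- 0.05
  net <- sdpc_network(list(d), lambda = lambda)
  set.seed(40)
  img <- array(rnorm(36), c(1, 6, 6))
  st <- run_inference(net, img, inference_config(k_fb = 0, t_fp = 1e-9,
                                                 max_iter = 5000))
  M <- oracle_toeplitz(d$atoms, c(4, 4), 1)
  ref <- oracle_nn_lasso(M, as.vector(img), lambda)
  ours <- 0.5 * sum((as.vector(img) - M %*% as.vector(st$activities[[1]]))^2) +
    lambda * sum(st$activities[[1]])
  expect_lt((ours - ref$objective) / max(1e-12, abs(ref$objective)), 1e-6)
})

test_that("k_fb = 0 decouples the layers: joint run equals layer-1-only run", {
  d1 <- rand_dict(2, 1, 3, stride = 1, seed = 41)
  d2 <- rand_dict(3, 2, 2, stride = 1, seed = 42)
  net2 <- sdpc_network(list(d1, d2), lambda = c(0.05, 0.05))
  net1 <- sdpc_network(list(d1), lambda = 0.05)
  img <- array(rnorm(36), c(1, 6, 6))
  cfg <- inference_config(k_fb = 0, t_fp = 1e-7, max_iter = 2000)
  g_joint <- run_inference(net2, img, cfg)$activities[[1]]
  g_alone <- run_inference(net1, img, cfg)$activities[[1]]
  expect_equal(g_joint, g_alone, tolerance = 1e-4)
})

test_that("activities from inference are always non-negative", {
  set.seed(43)
  for (rep in 1:5) {
    d <- rand_dict(3, 1, 3, stride = sample(1:2, 1))
    net <- sdpc_network(list(d), lambda = runif(1, 0, 0.3))
    img <- array(rnorm(49), c(1, 7, 7))
    st <- run_inference(net, img, inference_config(k_fb = 0, max_iter = 30))
    expect_gte(min(st$activities[[1]]), 0)
  }
})

test_that("non-convergence within max_iter is reported, never silent", {
  net <- make_toy_net(lambda = 0.01)
  img <- array(rnorm(144), c(1, 12, 12))
  st <- run_inference(net, img, inference_config(k_fb = 0, max_iter = 2,
                                                 t_fp = 1e-10))
  expect_false(all(st$converged))
  expect_equal(st$iterations, 2L)
})
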