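# Orientation fitting, interaction-map construction and circular
# statistics.

test_that("fit_gabor recovers planted orientations within 3 degrees", {
  for (deg in c(0, 30, 45, 90, 135)) {
    g <- gabor_patch(9, deg * pi / 180, 0.25)
    fit <- fit_gabor(g)
    expect_lt(orientation_diff(fit$theta, deg * pi / 180) * 180 / pi, 3)
    expect_gte(fit$quality, 0.9)
  }
})

test_that("fit_gabor rejects an isotropic blob and respects 90-degree rotation", {
  blob <- exp(-outer((-4:4)^2, (-4:4)^2, `+`) / 8)
  expect_lt(fit_gabor(blob)$quality, 0.5)
  g <- gabor_patch(9, 30 * pi / 180, 0.25)
  g_rot <- t(g)[, 9:1]                    # 90-degree rotation
  f0 <- fit_gabor(g)
  f90 <- fit_gabor(g_rot)
  expect_lt(orientation_diff(f90$theta, f0$theta + pi / 2) * 180 / pi, 3)
})

test_that("orientation_bank keeps oriented atoms and drops unoriented ones", {
  d <- make_gabor_dictionary(4, 9, orientations = c(0, pi / 4, pi / 2, 3 * pi / 4))
  d$atoms[4, , , ] <- exp(-outer((-4:4)^2, (-4:4)^2, `+`) / 8)
  d <- normalize_atoms(d)
  bank <- orientation_bank(d)
  expect_true(all(bank$keep[1:3]))
  expect_false(bank$keep[4])
  expect_lt(orientation_diff(bank$theta[2], pi / 4) * 180 / pi, 3)
})

test_that("top-activated neighborhoods: centers, borders, ties, sort oracle", {
  a <- array(0, c(2, 11, 11))
  a[1, 6, 6] <- 2
  crops <- extract_top_neighborhoods(a, 1, k = 1, window = 5)
  expect_length(crops, 1)
  expect_equal(attr(crops, "centers")[1, ], c(x = 6, y = 6))
  expect_equal(dim(crops[[1]]), c(2L, 5L, 5L))
  # two equal maxima: both returned, scan order (x then y)
  a[1, 3, 9] <- 2
  crops2 <- extract_top_neighborhoods(a, 1, k = 2, window = 5)
  expect_equal(unname(attr(crops2, "centers")), rbind(c(3, 9), c(6, 6)))
  # centers at the border are skipped for the next-ranked valid ones
  b <- array(0, c(1, 9, 9))
  b[1, 1, 1] <- 5; b[1, 5, 5] <- 1
  crops3 <- extract_top_neighborhoods(b, 1, k = 1, window = 5)
  expect_equal(unname(attr(crops3, "centers")[1, ]), c(5, 5))
  # random map: matches a full-sort oracle on valid positions
  set.seed(90)
  r <- array(runif(1 * 12 * 12), c(1, 12, 12))
  crops4 <- extract_top_neighborhoods(r, 1, k = 10, window = 5)
  plane <- r[1, , ]
  valid <- which(row(plane) >= 3 & row(plane) <= 10 &
                 col(plane) >= 3 & col(plane) <= 10, arr.ind = TRUE)
  ord <- valid[order(-plane[valid]), ][1:10, ]
  expect_equal(unname(attr(crops4, "centers")), unname(ord))
})

test_that("marginal activity averages outside the excluded window", {
  a <- array(3.5, c(2, 9, 9))
  expect_equal(unname(marginal_activity(a, c(5, 5), 5)), c(3.5, 3.5))
  a2 <- array(0, c(1, 9, 9)); a2[1, 4:6, 4:6] <- 7
  expect_equal(unname(marginal_activity(a2, c(5, 5), 5)), 0)
  set.seed(91)
  a3 <- array(runif(81), c(1, 9, 9))
  m <- matrix(a3[1, , ], 9, 9)
  mask <- matrix(TRUE, 9, 9); mask[3:7, 3:7] <- FALSE
  expect_equal(unname(marginal_activity(a3, c(5, 5), 5)), mean(m[mask]))
  expect_error(marginal_activity(a3, c(5, 5), 9), "whole map")
  expect_error(marginal_activity(a3, c(2, 5), 5), "strictly inside")
})

test_that("normalized activity implements the marginal contrast formula", {
  crop <- array(2, c(2, 3, 3))
  expect_true(all(normalized_activity(crop, c(2, 2)) == 0))
  expect_true(all(normalized_activity(crop, c(1, 1)) == 1))
  set.seed(92)
  cr <- array(runif(18), c(2, 3, 3))
  marg <- c(0.4, 0.7)
  out <- normalized_activity(cr, marg)
  for (f in 1:2)
    expect_equal(out[f, , ], (cr[f, , ] - marg[f]) / marg[f])
  expect_error(normalized_activity(cr, c(0, 0.5), floor = 0), "floor")
})

test_that("circular averages equal the direct complex sums", {
  # single term at 30 degrees: resulting orientation 30 degrees, mod 1/n
  cr <- array(0, c(2, 3, 3)); cr[1, 2, 2] <- 1
  cf <- circular_average(list(cr), c(pi / 6, pi / 3))
  expect_equal(Arg(cf[2, 2]), pi / 6)
  expect_equal(Mod(cf[2, 2]), 1 / 2)
  # equal weights at +theta and -theta: real-axis resultant
  cr2 <- array(1, c(2, 1, 1))
  cf2 <- circular_average(list(cr2), c(pi / 6, -pi / 6))
  expect_equal(Arg(cf2[1, 1]), 0)
  # equal weights at 0 and 90 degrees: 45 degrees, a * sqrt(2) / 2
  a_val <- 0.7
  cr3 <- array(a_val, c(2, 1, 1))
  cf3 <- circular_average(list(cr3), c(0, pi / 2))
  expect_equal(Arg(cf3[1, 1]), pi / 4)
  expect_equal(Mod(cf3[1, 1]), a_val * sqrt(2) / 2)
  # random fields against the brute-force oracle, any order of terms
  set.seed(93)
  crops <- lapply(1:3, function(i) array(rnorm(5 * 3 * 3), c(5, 3, 3)))
  th <- runif(5, 0, pi)
  cf4 <- circular_average(crops, th)
  ors <- lapply(crops, oracle_circular, thetas = th)
  re <- Reduce(`+`, lapply(ors, function(o) o$mod * cos(o$theta))) / 3
  im <- Reduce(`+`, lapply(ors, function(o) o$mod * sin(o$theta))) / 3
  expect_equal(Re(cf4), re, tolerance = 1e-9)
  expect_equal(Im(cf4), im, tolerance = 1e-9)
  # permutation invariance
  perm <- sample(5)
  crops_p <- lapply(crops, function(cr) cr[perm, , , drop = FALSE])
  expect_equal(circular_average(crops_p, th[perm]), cf4, tolerance = 1e-9)
  expect_error(circular_average(crops, numeric(0)), "empty")
})

test_that("co-linearity deviation wraps on the orientation circle", {
  tb <- matrix(pi / 6, 3, 3)
  expect_true(all(colinearity_deviation(tb, pi / 6) == 0))
  expect_equal(colinearity_deviation(tb, pi / 6 + pi / 2)[1, 1], pi / 2)
  expect_equal(colinearity_deviation(tb, pi / 6 + pi)[1, 1], 0, tolerance = 1e-12)
  expect_true(all(colinearity_deviation(tb, 2.1) >= 0 &
                  colinearity_deviation(tb, 2.1) <= pi / 2))
})

test_that("co-circular reference matches the inscribed-angle oracle", {
  for (th in c(0, pi / 7, pi / 4, pi / 2, 2)) {
    ref <- cocircular_reference(9, th)
    orc <- oracle_cocircular(9, th)
    expect_lt(max(orientation_diff(ref, orc)), 1e-9)
  }
  # positions on the theta_c axis reduce to the co-linear reference
  ref0 <- cocircular_reference(9, 0)
  expect_true(all(orientation_diff(ref0[, 5], 0) < 1e-12))
  # a map equal to the reference has zero co-circularity deviation
  expect_true(all(cocircularity_deviation(ref0, 0) < 1e-9))
})

test_that("region masks are disjoint, symmetric, and swap under rotation", {
  m0 <- region_masks(9, 0)
  expect_true(all(m0$end[c(1:3, 7:9), 5]))         # axis cells are end-zone
  expect_equal(m0$end, m0$end[9:1, ])              # left-right symmetric
  expect_false(any(m0$end & m0$side))
  expect_false(any((m0$end | m0$side) & m0$center))
  m90 <- region_masks(9, pi / 2)
  expect_equal(m90$end, m0$side)
  expect_equal(m90$side, m0$end)
  expect_equal(sum(m0$center), 9)
})

test_that("feedback ratios: identical maps give 1, doubled magnitude gives 2", {
  set.seed(94)
  fake_map <- function(mag_scale = 1, theta_shift = 0) {
    cf <- matrix(complex(modulus = runif(81, 0.5, 1),
                         argument = runif(81, -pi, pi)), 9, 9)
    structure(list(complex = cf,
                   theta_bar = (Arg(cf) + theta_shift) %% pi,
                   magnitude = Mod(cf) * mag_scale,
                   theta_c = pi / 5, feature = 1L,
                   marginal_theta_bar = pi / 3, marginal_magnitude = 0.2,
                   window = 9L, double_angle = FALSE,
                   n_crops = 10L, n_images = 1L),
              class = "sdpc_interaction_map")
  }
  base <- fake_map()
  fr_same <- feedback_ratios(base, base)
  expect_true(all(abs(fr_same$per_region$r_a - 1) < 1e-12))
  expect_true(all(abs(fr_same$per_region$r_colin - 1) < 1e-12))
  doubled <- base; doubled$magnitude <- 2 * base$magnitude
  fr2 <- feedback_ratios(doubled, base)
  expect_true(all(abs(fr2$per_region$r_a - 2) < 1e-12))
  # planted end-zone boost: r_a(end) matches the planted factor
  masks <- region_masks(9, base$theta_c)
  boosted <- base
  boosted$magnitude[masks$end] <- 3 * boosted$magnitude[masks$end]
  fr3 <- feedback_ratios(boosted, base)
  expect_equal(fr3$per_region$r_a[fr3$per_region$region == "end"], 3)
  expect_equal(fr3$per_region$r_a[fr3$per_region$region == "center"], 1)
})

test_that("interaction_map runs end-to-end and is 90-degree equivariant", {
  # synthetic activity: one strong oriented blob on feature 1 (theta = 0)
  bank <- data.frame(feature = 1:2, theta = c(0, pi / 2),
                     quality = c(1, 1), r2 = c(1, 1), keep = c(TRUE, TRUE))
  set.seed(95)
  g <- array(runif(2 * 15 * 15, 0, 0.2), c(2, 15, 15))
  g[1, 8, 4:12] <- seq(2.8, 2, length.out = 9)  # line of feature-1 activity
  m <- interaction_map(g, bank, 1, k = 3, window = 5)
  expect_s3_class(m, "sdpc_interaction_map")
  expect_true(all(is.finite(m$theta_bar)))
  expect_true(all(m$magnitude >= 0))
  expect_equal(m$theta_c, 0)
  # rotate the scene by 90 degrees: swap features and transpose space
  g_rot <- array(0, dim(g))
  g_rot[2, , ] <- t(g[1, , ])[, 15:1]
  g_rot[1, , ] <- t(g[2, , ])[, 15:1]
  m_rot <- interaction_map(g_rot, bank, 2, k = 3, window = 5)
  expect_equal(m_rot$theta_c, pi / 2)
  # magnitudes rotate with the scene
  rot_mat <- function(x) t(x)[, 5:1]
  expect_equal(m_rot$magnitude, rot_mat(m$magnitude), tolerance = 1e-9)
})
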