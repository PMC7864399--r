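# Independent oracles used across the suite. These deliberately avoid the
# package's operator implementations: plain nested loops, dense matrix
# algebra and direct complex sums.

# Brute-force strided transposed convolution (quadruple sum), looping over
# every index. Reference for synthesize().
oracle_synthesize <- function(atoms, act, stride) {
  dd <- dim(atoms); da <- dim(act)
  W <- (da[2] - 1) * stride + dd[3]
  H <- (da[3] - 1) * stride + dd[4]
  out <- array(0, c(dd[2], W, H))
  for (f in seq_len(dd[1])) for (k in seq_len(da[2])) for (l in seq_len(da[3]))
    for (ch in seq_len(dd[2])) for (p in seq_len(dd[3])) for (q in seq_len(dd[4]))
      out[ch, (k - 1) * stride + p, (l - 1) * stride + q] <-
        out[ch, (k - 1) * stride + p, (l - 1) * stride + q] +
        act[f, k, l] * atoms[f, ch, p, q]
  out
}

# Dense Toeplitz materialization of the synthesis operator: one column per
# activity coefficient, built with the loop oracle.
oracle_toeplitz <- function(atoms, map_size, stride) {
  dd <- dim(atoms)
  n_in <- dd[1] * prod(map_size)
  probe <- array(0, c(dd[1], map_size))
  cols <- vector("list", n_in)
  for (j in seq_len(n_in)) {
    e <- probe; e[j] <- 1
    cols[[j]] <- as.vector(oracle_synthesize(atoms, e, stride))
  }
  do.call(cbind, cols)
}

# Generic dense proximal-gradient solver for the non-negative LASSO
#   min 0.5 ||y - M b||^2 + lambda ||b||_1  s.t. b >= 0
# with FISTA acceleration. Independent of the package's operators.
oracle_nn_lasso <- function(M, y, lambda, max_iter = 5000, tol = 1e-12) {
  Lc <- max(eigen(crossprod(M), symmetric = TRUE, only.values = TRUE)$values)
  eta <- 1 / Lc
  b <- by <- numeric(ncol(M))
  tk <- 1
  obj <- function(b) 0.5 * sum((y - M %*% b)^2) + lambda * sum(abs(b))
  last <- obj(b)
  for (it in seq_len(max_iter)) {
    g <- by + eta * as.vector(crossprod(M, y - M %*% by))
    bn <- pmax(g - eta * lambda, 0)
    tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
    by <- bn + ((tk - 1) / tk1) * (bn - b)
    b <- bn
    tk <- tk1
    cur <- obj(b)
    if (abs(last - cur) < tol * max(1, abs(cur)) && it > 10) break
    last <- cur
  }
  list(b = b, objective = obj(b))
}

# Direct complex-sum circular statistics for one normalized crop.
oracle_circular <- function(crop, thetas) {
  n <- length(thetas)
  w <- dim(crop)[2]; h <- dim(crop)[3]
  re <- im <- matrix(0, w, h)
  for (j in seq_len(n)) {
    re <- re + crop[j, , ] * cos(thetas[j])
    im <- im + crop[j, , ] * sin(thetas[j])
  }
  list(theta = atan2(im / n, re / n), mod = sqrt((re / n)^2 + (im / n)^2))
}

# Co-circular reference via the inscribed-angle rule: the tangent at
# position (x, y) of the circle through the origin with orientation
# theta_c there is the reflection of theta_c about the chord direction.
oracle_cocircular <- function(window, theta_c) {
  half <- (window - 1) %/% 2
  out <- matrix(theta_c, window, window)
  for (i in seq_len(window)) for (j in seq_len(window)) {
    x <- i - half - 1; y <- j - half - 1
    if (x == 0 && y == 0) next
    out[i, j] <- (2 * atan2(y, x) - theta_c) %% pi
  }
  out
}

# Naive windowed SSIM: explicit loop over Gaussian windows.
oracle_ssim <- function(a, b, data_range, window = 11, sigma = 1.5) {
  r <- (window - 1) / 2
  g1 <- exp(-(seq_len(window) - 1 - r)^2 / (2 * sigma^2))
  k <- outer(g1, g1); k <- k / sum(k)
  c1 <- (0.01 * data_range)^2; c2 <- (0.03 * data_range)^2
  nr <- nrow(a) - window + 1; nc <- ncol(a) - window + 1
  vals <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    wa <- a[i:(i + window - 1), j:(j + window - 1)]
    wb <- b[i:(i + window - 1), j:(j + window - 1)]
    mx <- sum(k * wa); my <- sum(k * wb)
    vx <- sum(k * wa^2) - mx^2; vy <- sum(k * wb^2) - my^2
    vxy <- sum(k * wa * wb) - mx * my
    vals[i, j] <- ((2 * mx * my + c1) * (2 * vxy + c2)) /
      ((mx^2 + my^2 + c1) * (vx + vy + c2))
  }
  mean(vals)
}

# Greedy bipartite matching of learned to planted atoms by absolute
# normalized cross-correlation; rows of both matrices are unit norm.
match_correlations <- function(learned, planted) {
  C <- abs(learned %*% t(planted))
  best <- numeric(nrow(planted))
  for (i in seq_len(nrow(planted))) {
    ix <- which(C == max(C), arr.ind = TRUE)[1, ]
    best[ix[2]] <- C[ix[1], ix[2]]
    C[ix[1], ] <- -1
    C[, ix[2]] <- -1
  }
  best
}

# Small random dictionary/activity fixtures.
rand_dict <- function(nf, nc, k, stride = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sdpc_dictionary(array(rnorm(nf * nc * k * k), c(nf, nc, k, k)),
                  stride = stride)
}
rand_act <- function(nf, wm, hm, seed = NULL, nonneg = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  a <- array(rnorm(nf * wm * hm), c(nf, wm, hm))
  if (nonneg) a <- abs(a)
  a
}
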