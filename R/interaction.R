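# Interaction maps: association-field analogues around top-activated
# first-layer units, and the circular statistics that quantify how
# feedback reorganizes them.

#' Circular difference between two orientations (period pi)
#'
#' @param a,b Orientations in radians.
#' @return Elementwise deviation in `[0, pi/2]`.
#' @export
orientation_diff <- function(a, b) {
  d <- abs(a - b) %% pi
  pmin(d, pi - d)
}

#' Extract windows around the most strongly activated units
#'
#' Finds the `k` largest strictly positive entries of one feature plane
#' (ties broken deterministically by scan order: first spatial axis, then
#' second) whose windows fit inside the map; centers too close to the
#' border are skipped and replaced by the next-ranked ones.
#'
#' @param activity 3-way activity array `[n_features, w_m, h_m]`.
#' @param feature Feature plane whose maxima define the centers.
#' @param k Number of neighborhoods requested (default 10).
#' @param window Odd window side (default 9).
#' @return List of `[n_features, window, window]` crops; the attribute
#'   `centers` holds one `(x, y)` row per crop. May hold fewer than `k`
#'   crops if fewer valid centers exist.
#' @export
extract_top_neighborhoods <- function(activity, feature, k = 10L, window = 9L) {
  stopifnot(window %% 2L == 1L, k >= 1L)
  a <- as_activity(activity)
  plane <- a[feature, , ]
  half <- (window - 1L) %/% 2L
  wm <- nrow(plane); hm <- ncol(plane)
  xs <- as.vector(row(plane)); ys <- as.vector(col(plane))
  v <- as.vector(plane)
  ord <- order(-v, xs, ys)
  ord <- ord[v[ord] > 0]
  valid <- xs[ord] > half & xs[ord] <= wm - half &
           ys[ord] > half & ys[ord] <= hm - half
  ord <- ord[valid]
  take <- utils::head(ord, k)
  crops <- lapply(take, function(ix) {
    cx <- xs[ix]; cy <- ys[ix]
    a[, (cx - half):(cx + half), (cy - half):(cy + half), drop = FALSE]
  })
  attr(crops, "centers") <- cbind(x = xs[take], y = ys[take])
  crops
}

#' Marginal activity of each feature outside an excluded window
#'
#' The spatial mean of a feature plane over all positions outside the
#' window centered at `center`; the reference level against which the
#' activity inside the neighborhood is judged.
#'
#' @param activity 3-way activity array.
#' @param center `(x, y)` center of the excluded window.
#' @param window Odd window side.
#' @param features Optional subset of feature indices.
#' @return Named numeric vector, one marginal per requested feature.
#' @export
marginal_activity <- function(activity, center, window, features = NULL) {
  a <- as_activity(activity)
  if (is.null(features)) features <- seq_len(dim(a)[1])
  half <- (window - 1L) %/% 2L
  wm <- dim(a)[2]; hm <- dim(a)[3]
  xr <- (center[1] - half):(center[1] + half)
  yr <- (center[2] - half):(center[2] + half)
  if (any(xr < 1L) || any(xr > wm) || any(yr < 1L) || any(yr > hm))
    stop("excluded window must lie strictly inside the map")
  n_out <- wm * hm - window^2
  if (n_out <= 0L) stop("window covers the whole map: marginal undefined")
  vapply(features, function(f) {
    plane <- a[f, , ]
    (sum(plane) - sum(plane[xr, yr])) / n_out
  }, numeric(1))
}

#' Normalize a cropped neighborhood by marginal activities
#'
#' `a[theta, x, y] = (crop[theta, x, y] - marginal[theta]) / marginal[theta]`:
#' positive where the local activity exceeds its feature's marginal level,
#' negative where it falls below. Marginals are floored to avoid division
#' by zero.
#'
#' @param crop `[n_features, window, window]` array.
#' @param marginals One marginal per feature of the crop.
#' @param floor Lower bound applied to the marginals (scalar or one value
#'   per feature); typically a small fraction of each plane's maximum.
#' @return Array shaped like `crop`.
#' @export
normalized_activity <- function(crop, marginals, floor = 1e-12) {
  stopifnot(length(marginals) == dim(crop)[1])
  m <- pmax(marginals, floor)
  if (any(m <= 0)) stop("zero marginal without a positive floor")
  sweep(sweep(crop, 1, m, `-`), 1, m, `/`)
}

#' Complex circular average of normalized crops over orientations
#'
#' Each normalized activity is given the phase of its feature's preferred
#' orientation, `a[theta, x, y] * exp(1i * theta)`, summed over the kept
#' features and divided by their number; fields from several crops (and
#' images) are averaged arithmetically before any argument or modulus is
#' taken. With `double_angle = TRUE` the phase is `2 * theta`, the classic
#' mapping of the half-circle of orientations onto the full circle (the
#' resulting argument is halved when read as an orientation).
#'
#' @param crops List of normalized `[n_kept, window, window]` arrays.
#' @param thetas Preferred orientations of the kept features (radians).
#' @param double_angle Use `exp(2i * theta)` phases.
#' @return Complex `window x window` matrix (the mean complex field).
#' @export
circular_average <- function(crops, thetas, double_angle = FALSE) {
  if (!length(thetas)) stop("empty feature set")
  if (!length(crops)) stop("no crops to average")
  mult <- if (double_angle) 2 else 1
  ph <- exp(1i * mult * thetas)
  n <- length(thetas)
  acc <- 0
  for (cr in crops) {
    stopifnot(dim(cr)[1] == n)
    w <- dim(cr)[2]; h <- dim(cr)[3]
    f <- matrix(0i, w, h)
    for (j in seq_len(n)) f <- f + cr[j, , ] * ph[j]
    acc <- acc + f / n
  }
  acc / length(crops)
}

#' Compute the interaction map for one central preferred orientation
#'
#' The full pipeline: for every activity map, crop `k` windows around the
#' top-activated units of the central feature, normalize each crop by the
#' per-feature marginal activity (computed outside that crop's window),
#' phase-weight by the kept features' orientations and average the complex
#' fields over crops and images. The result holds, per window position,
#' the resulting orientation `theta_bar` (argument) and magnitude
#' (modulus) of the mean field, plus the marginal resulting orientation
#' (from the raw marginal activities) used by the co-linearity ratios.
#'
#' @param gammas A single first-layer activity array or a list of them
#'   (one per image).
#' @param bank [orientation_bank()] data frame; only kept features enter
#'   the average.
#' @param feature Central feature index (must be a kept feature of `bank`).
#' @param k Crops per image (default 10).
#' @param window Odd window side (default 9, the extent of the
#'   second-layer kernels).
#' @param double_angle Passed to [circular_average()].
#' @param marginal_floor Marginals are floored at `marginal_floor` times
#'   each feature plane's maximum.
#' @return Object of class `sdpc_interaction_map`.
#' @export
interaction_map <- function(gammas, bank, feature, k = 10L, window = 9L,
                            double_angle = FALSE, marginal_floor = 1e-6) {
  if (!is.list(gammas)) gammas <- list(gammas)
  kept <- bank[bank$keep, , drop = FALSE]
  if (!nrow(kept)) stop("empty feature set: no kept orientations in the bank")
  if (!feature %in% kept$feature)
    stop("central feature must be a kept feature of the orientation bank")
  theta_c <- kept$theta[kept$feature == feature]
  mult <- if (double_angle) 2 else 1

  acc <- matrix(0i, window, window)
  n_crops <- 0L
  n_images <- 0L
  marg_acc <- numeric(nrow(kept))
  for (g in gammas) {
    g <- as_activity(g)
    crops <- extract_top_neighborhoods(g, feature, k = k, window = window)
    if (!length(crops)) next
    plane_max <- vapply(kept$feature, function(f) max(g[f, , ]), numeric(1))
    centers <- attr(crops, "centers")
    normed <- vector("list", length(crops))
    for (ci in seq_along(crops)) {
      marg <- marginal_activity(g, centers[ci, ], window, kept$feature)
      marg_acc <- marg_acc + marg
      normed[[ci]] <- normalized_activity(
        crops[[ci]][kept$feature, , , drop = FALSE], marg,
        floor = pmax(marginal_floor * plane_max, .Machine$double.xmin))
    }
    acc <- acc + circular_average(normed, kept$theta, double_angle) * length(crops)
    n_crops <- n_crops + length(crops)
    n_images <- n_images + 1L
  }
  if (n_crops == 0L) stop("no valid neighborhoods found in any activity map")
  cf <- acc / n_crops
  marg_mean <- marg_acc / n_crops
  marg_cf <- sum(marg_mean * exp(1i * mult * kept$theta)) / nrow(kept)
  structure(list(
    complex = cf,
    theta_bar = (Arg(cf) / mult) %% pi,
    magnitude = Mod(cf),
    theta_c = theta_c,
    feature = feature,
    marginal_theta_bar = (Arg(marg_cf) / mult) %% pi,
    marginal_magnitude = Mod(marg_cf),
    window = as.integer(window),
    double_angle = double_angle,
    n_crops = n_crops, n_images = n_images),
    class = "sdpc_interaction_map")
}

#' @export
print.sdpc_interaction_map <- function(x, ...) {
  cat(sprintf(
    "sdpc_interaction_map: %dx%d window, theta_c = %.1f deg, %d crops from %d image(s)\n",
    x$window, x$window, x$theta_c * 180 / pi, x$n_crops, x$n_images))
  invisible(x)
}

#' Co-linearity deviation of an interaction map
#'
#' Per-position circular difference (period pi) between the central
#' preferred orientation and the map's resulting orientation; 0 where the
#' field is perfectly co-linear, pi/2 where orthogonal.
#'
#' @param map An [interaction_map()] result, or a matrix of orientations.
#' @param theta_c Central orientation (taken from the map if missing).
#' @return Matrix of deviations in `[0, pi/2]`.
#' @export
colinearity_deviation <- function(map, theta_c = NULL) {
  tb <- if (inherits(map, "sdpc_interaction_map")) map$theta_bar else map
  if (is.null(theta_c)) theta_c <- map$theta_c
  orientation_diff(theta_c, tb)
}

#' Co-circular reference orientations for a window
#'
#' For each window position, the tangent orientation of the circle that
#' passes through the window center with orientation `theta_c` there: the
#' orientation a perfectly co-circular element at that position would
#' take. Positions on the `theta_c` axis through the center (zero
#' curvature) take the co-linear reference `theta_c` itself, as does the
#' center.
#'
#' @param window Odd window side.
#' @param theta_c Central orientation in radians.
#' @return `window x window` matrix of orientations in `[0, pi)`.
#' @export
cocircular_reference <- function(window, theta_c) {
  stopifnot(window %% 2L == 1L)
  half <- (window - 1L) %/% 2L
  xc <- matrix(-half:half, window, window)
  yc <- t(xc)
  # circle center (x_co, y_co): on the normal of theta_c through the
  # origin, equidistant from the origin and from (xc, yc)
  den <- 2 * (cos(theta_c) * yc - sin(theta_c) * xc)
  ref <- matrix(theta_c, window, window)
  ok <- abs(den) > 1e-9              # off the theta_c axis (finite curvature)
  t_par <- (xc^2 + yc^2) / ifelse(ok, den, 1)
  x_co <- -t_par * sin(theta_c)
  y_co <- t_par * cos(theta_c)
  ref[ok] <- atan2(yc[ok] - y_co[ok], xc[ok] - x_co[ok]) + pi / 2
  ref %% pi
}

#' Co-circularity deviation of an interaction map
#'
#' Circular difference (period pi) between the map's resulting orientation
#' and the co-circular reference orientation at each position (see
#' [cocircular_reference()]).
#'
#' @inheritParams colinearity_deviation
#' @return Matrix of deviations in `[0, pi/2]`.
#' @export
cocircularity_deviation <- function(map, theta_c = NULL) {
  if (inherits(map, "sdpc_interaction_map")) {
    tb <- map$theta_bar
    if (is.null(theta_c)) theta_c <- map$theta_c
    window <- map$window
  } else {
    tb <- map
    window <- nrow(tb)
  }
  orientation_diff(cocircular_reference(window, theta_c), tb)
}

#' End-zone, side-zone and center masks of an interaction window
#'
#' The end-zone covers the axis of the central preferred orientation
#' (positions within `half_angle` of it), the side-zone the orthogonal
#' axis, and the center the classical-receptive-field block in the middle.
#' Cells exactly on the 45-degree diagonals between the two sectors belong
#' to neither, so the masks are disjoint and rotating `theta_c` by 90
#' degrees swaps end and side zones.
#'
#' @param window Odd window side.
#' @param theta_c Central orientation in radians.
#' @param half_angle Angular half-width of each sector (default pi/4).
#' @param center_block Side of the central block (default 3).
#' @return List of three logical `window x window` masks: `end`, `side`,
#'   `center`.
#' @export
region_masks <- function(window, theta_c, half_angle = pi / 4,
                         center_block = 3L) {
  stopifnot(window %% 2L == 1L)
  half <- (window - 1L) %/% 2L
  xc <- matrix(-half:half, window, window)
  yc <- t(xc)
  cb <- (center_block - 1L) %/% 2L
  center <- abs(xc) <= cb & abs(yc) <= cb
  pos_angle <- atan2(yc, xc) %% pi
  d <- orientation_diff(pos_angle, theta_c)
  tol <- 1e-9
  list(end = d < half_angle - tol & !center,
       side = d > half_angle + tol & !center,
       center = center)
}

#' Feedback-induced ratios between two interaction maps
#'
#' Compares an interaction map computed with feedback against the map for
#' the same images and central orientation without feedback. Reported per
#' region (end-zone, side-zone, center; medians over region positions):
#' the activity ratio `r_a = |a_fb| / |a_0|`, and the co-linearity and
#' co-circularity ratios, each the ratio of the map's deviation scaled by
#' its marginal deviation (`theta_tilde = deviation_marginal /
#' deviation_map`, a precision-like quantity that exceeds 1 when the
#' neighborhood is more organized than its surround) between the two
#' feedback conditions. Ratios above 1 mean more active (resp. more
#' co-linear, more co-circular) with feedback than without.
#'
#' @param map_fb Map computed with feedback.
#' @param map_base Map for the same stimuli without feedback (`k_fb = 0`).
#' @param half_angle,center_block Passed to [region_masks()].
#' @return List with `per_region` (data frame: region, r_a, r_colin,
#'   r_cocir, n_positions), the full `r_a` field, and `n_excluded`, the
#'   number of positions dropped for zero denominators.
#' @export
feedback_ratios <- function(map_fb, map_base, half_angle = pi / 4,
                            center_block = 3L) {
  stopifnot(map_fb$window == map_base$window)
  theta_c <- map_base$theta_c
  w <- map_base$window

  ra_field <- map_fb$magnitude / map_base$magnitude
  colin_fb <- colinearity_deviation(map_fb)
  colin_0 <- colinearity_deviation(map_base)
  marg_colin_fb <- orientation_diff(theta_c, map_fb$marginal_theta_bar)
  marg_colin_0 <- orientation_diff(theta_c, map_base$marginal_theta_bar)
  cocir_fb <- cocircularity_deviation(map_fb)
  cocir_0 <- cocircularity_deviation(map_base)
  ref <- cocircular_reference(w, theta_c)
  marg_cocir_fb <- stats::median(orientation_diff(ref, map_fb$marginal_theta_bar))
  marg_cocir_0 <- stats::median(orientation_diff(ref, map_base$marginal_theta_bar))

  r_colin_field <- (marg_colin_fb / colin_fb) / (marg_colin_0 / colin_0)
  r_cocir_field <- (marg_cocir_fb / cocir_fb) / (marg_cocir_0 / cocir_0)

  masks <- region_masks(w, theta_c, half_angle, center_block)
  ok_a <- map_base$magnitude > 0
  ok_colin <- colin_fb > 0 & colin_0 > 0 & marg_colin_0 > 0
  ok_cocir <- cocir_fb > 0 & cocir_0 > 0 & marg_cocir_0 > 0
  per_region <- do.call(rbind, lapply(names(masks), function(nm) {
    m <- masks[[nm]]
    data.frame(region = nm,
               r_a = stats::median(ra_field[m & ok_a]),
               r_colin = stats::median(r_colin_field[m & ok_colin]),
               r_cocir = stats::median(r_cocir_field[m & ok_cocir]),
               n_positions = sum(m))
  }))
  list(per_region = per_region, r_a = ra_field,
       n_excluded = sum(!(ok_a & ok_colin & ok_cocir)))
}

#' Interaction-map feedback analysis across orientations
#'
#' Runs inference on a set of images at several feedback strengths,
#' computes the interaction map of every kept orientation for each
#' strength, and tabulates the per-region feedback ratios against the
#' `k_fb = 0` baseline.
#'
#' @param network A trained [sdpc_network()].
#' @param images List of preprocessed images.
#' @param bank [orientation_bank()] of the first-layer dictionary.
#' @param k_fb Feedback strengths to evaluate; 0 is added as the baseline
#'   if absent.
#' @param config Base [inference_config()] (its `k_fb` is overridden).
#' @param k,window Passed to [interaction_map()].
#' @return List with `ratios` (data frame: k_fb, feature, theta_c, region,
#'   r_a, r_colin, r_cocir) and `maps` (nested list of interaction maps,
#'   by feedback strength then feature).
#' @export
association_field_analysis <- function(network, images, bank,
                                       k_fb = c(0, 1), config = inference_config(),
                                       k = 10L, window = 9L) {
  k_fb <- sort(unique(c(0, k_fb)))
  kept <- bank[bank$keep, , drop = FALSE]
  maps <- list()
  for (kf in k_fb) {
    cfg <- config
    cfg$k_fb <- kf
    if (is.null(cfg$eta))
      cfg$eta <- network_step_sizes(network, images[[1L]], k_fb = kf,
                                    eta_mode = cfg$eta_mode)
    gammas <- lapply(images, function(im)
      run_inference(network, im, cfg)$activities[[1L]])
    maps[[as.character(kf)]] <- lapply(kept$feature, function(f)
      interaction_map(gammas, bank, f, k = k, window = window))
  }
  base <- maps[["0"]]
  rows <- list()
  for (kf in setdiff(k_fb, 0)) {
    mk <- maps[[as.character(kf)]]
    for (j in seq_along(mk)) {
      fr <- feedback_ratios(mk[[j]], base[[j]])$per_region
      fr$k_fb <- kf
      fr$feature <- kept$feature[j]
      fr$theta_c <- kept$theta[j]
      rows[[length(rows) + 1L]] <- fr
    }
  }
  list(ratios = do.call(rbind, rows), maps = maps)
}

#' Quiver-style plot of an interaction map
#'
#' Draws one oriented segment per window position, angle `theta_bar` and
#' color mapped to the magnitude (saturated at `zlim`).
#'
#' @param x An [interaction_map()] result.
#' @param zlim Magnitude saturation bounds (default the data range).
#' @param ... Unused.
#' @export
plot.sdpc_interaction_map <- function(x, zlim = NULL, ...) {
  w <- x$window
  if (is.null(zlim)) zlim <- range(x$magnitude)
  mag <- pmin(pmax(x$magnitude, zlim[1]), zlim[2])
  sc <- if (diff(zlim) > 0) (mag - zlim[1]) / diff(zlim) else mag * 0
  cols <- grDevices::gray(1 - 0.9 * sc)
  graphics::plot(NULL, xlim = c(0.5, w + 0.5), ylim = c(0.5, w + 0.5),
                 asp = 1, xlab = "x", ylab = "y",
                 main = sprintf("interaction map, theta_c = %.0f deg",
                                x$theta_c * 180 / pi))
  for (i in seq_len(w)) for (j in seq_len(w)) {
    th <- x$theta_bar[i, j]
    dx <- 0.4 * cos(th); dy <- 0.4 * sin(th)
    graphics::segments(i - dx, j - dy, i + dx, j + dy,
                       col = cols[i, j], lwd = 2)
  }
  invisible(x)
}
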