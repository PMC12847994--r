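# Nuclear-pore labeling-efficiency assay: double-ring template, candidate
# detection, maximum-likelihood 3D pose fitting, segment counting and the
# truncated-binomial model for the effective labeling efficiency p_LE.

#' Nuclear-pore double-ring template
#'
#' Segment-anchor geometry of the Nup96 calibration structure: two parallel
#' rings of `n_segments_per_ring` anchors each (8-fold symmetric by default),
#' separated axially by `ring_spacing`.
#'
#' @param ring_diameter Ring diameter in nm (default 107).
#' @param ring_spacing Axial ring separation in nm (default 50).
#' @param n_segments_per_ring Anchors per ring (default 8).
#' @param twist_deg Angular offset of the nucleoplasmic ring (default 0).
#' @return An `npc_template` list; `npc_template_anchors()` materialises the
#'   16 anchor positions.
#' @export
npc_template <- function(ring_diameter = 107, ring_spacing = 50,
                         n_segments_per_ring = 8, twist_deg = 0) {
  if (ring_diameter <= 0 || ring_spacing <= 0) abort("geometry must be positive")
  structure(list(ring_diameter = ring_diameter, ring_spacing = ring_spacing,
                 n_segments_per_ring = as.integer(n_segments_per_ring),
                 twist_deg = twist_deg),
            class = "npc_template")
}

#' Anchor positions of a nuclear-pore template
#'
#' @param template An [npc_template()].
#' @param ring_diameter,ring_spacing Optional overrides (used when geometry is
#'   refined during fitting).
#' @return Matrix `2 * n_segments_per_ring` x 3 of anchors in the template
#'   frame (z = symmetry axis); rows ordered cytoplasmic ring first.
#' @export
npc_template_anchors <- function(template, ring_diameter = NULL, ring_spacing = NULL) {
  d <- ring_diameter %||% template$ring_diameter
  s <- ring_spacing %||% template$ring_spacing
  nseg <- template$n_segments_per_ring
  ang1 <- (seq_len(nseg) - 1) * 2 * pi / nseg
  ang2 <- ang1 + template$twist_deg * pi / 180
  r <- d / 2
  rbind(
    cbind(r * cos(ang1), r * sin(ang1), rep(s / 2, nseg)),
    cbind(r * cos(ang2), r * sin(ang2), rep(-s / 2, nseg))
  )
}

#' Detect nuclear-pore candidates in a subunit table
#'
#' Groups subunit positions by DBSCAN and keeps groups that are large enough
#' and spatially compact enough to be single pores. Alternatively a
#' pre-defined ROI assignment can be supplied instead of auto-detection.
#'
#' @param subunits Subunit tibble (see [merge_subunits()]) or any tibble with
#'   `x, y, z` columns.
#' @param group_eps DBSCAN distance in nm (default 100; large enough to
#'   bridge the two rings, smaller than typical pore-to-pore spacing).
#' @param min_points Minimum subunits per group (default 6).
#' @param max_extent Maximum spatial extent (largest pairwise distance, nm) of
#'   a group (default 250); larger groups are discarded as merged/background.
#' @param roi Optional integer vector of group ids (one per subunit row, NA =
#'   unassigned) that replaces DBSCAN detection, e.g. from external ROIs.
#' @return Nested tibble `candidate_id, n_points, data` where `data` holds
#'   the subunit rows of each retained group.
#' @export
detect_npc_candidates <- function(subunits, group_eps = 100, min_points = 6,
                                  max_extent = 250, roi = NULL) {
  if (group_eps <= 0) abort("`group_eps` must be > 0")
  xyz <- as_xyz(subunits)
  labels <- if (is.null(roi)) {
    dbscan_labels(xyz, eps = group_eps, min_pts = 1)
  } else {
    stopifnot(length(roi) == nrow(subunits))
    ifelse(is.na(roi), 0L, as.integer(roi))
  }
  subunits$.group <- labels
  groups <- subunits |>
    dplyr::filter(.data$.group > 0) |>
    dplyr::group_by(.data$.group) |>
    tidyr::nest() |>
    dplyr::ungroup()
  keep <- vapply(groups$data, function(g) {
    if (nrow(g) < min_points) return(FALSE)
    max(dist(as_xyz(g))) <= max_extent
  }, logical(1))
  groups <- groups[keep, , drop = FALSE]
  tibble(candidate_id = seq_len(nrow(groups)),
         n_points = vapply(groups$data, nrow, integer(1)),
         data = groups$data)
}

# Deterministic multi-start grid: the 26 unit directions of the cube
# ({-1,0,1}^3 minus the origin) restricted to z >= 0, equatorial directions
# lifted slightly so the upper-hemisphere parameterization stays regular.
axis_start_grid <- function() {
  g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  g <- g[rowSums(abs(g)) > 0 & g[, "z"] >= 0, , drop = FALSE]
  g[g[, "z"] == 0, "z"] <- 0.25
  g / sqrt(rowSums(g^2))
}

# Quasi-uniform upper-hemisphere directions (Fibonacci lattice).
axis_fibonacci_grid <- function(n = 32) {
  i <- seq_len(n) - 0.5
  z <- i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Closed-form pose initialisation for a fixed axis direction: rotate the
# points so the axis is z, split the two rings along z, fit the ring center
# by an algebraic (Kasa) circle fit, and read the in-plane rotation off the
# phase of the nseg-th angular harmonic.
init_pose_for_axis <- function(P, axis, nseg) {
  Ra <- rotation_align_z(axis)
  L <- P %*% Ra
  t <- L[, 3]
  s <- mean(t)
  for (it in 1:3) {
    hi <- t[t > s]; lo <- t[t <= s]
    if (length(hi) == 0 || length(lo) == 0) break
    s <- (mean(hi) + mean(lo)) / 2
  }
  xy <- L[, 1:2, drop = FALSE]
  A <- cbind(xy, 1)
  b <- -(xy[, 1]^2 + xy[, 2]^2)
  sol <- tryCatch(qr.solve(A, b),
                  error = function(e) c(-2 * mean(xy[, 1]), -2 * mean(xy[, 2]), 0))
  cx <- -sol[1] / 2
  cy <- -sol[2] / 2
  th <- atan2(xy[, 2] - cy, xy[, 1] - cx)
  phi <- atan2(sum(sin(nseg * th)), sum(cos(nseg * th))) / nseg
  c_world <- as.numeric(Ra %*% c(cx, cy, s))
  c(c_world, axis[1] / axis[3], axis[2] / axis[3], phi)
}

# Pose parameters: center (3), axis tangent-plane coordinates a1, a2 with
# axis = (a1, a2, 1)/norm (upper hemisphere), spin phi (radians), optionally
# log-geometry. Builds a fast negative log-likelihood closure over the fixed
# points (the optimizer calls it thousands of times per fit).
make_npc_pose_nll <- function(points, template, sigma, outlier_weight,
                              log_unif_dens, free_geometry = FALSE) {
  P <- points
  nseg <- template$n_segments_per_ring
  twist <- template$twist_deg * pi / 180
  d0 <- template$ring_diameter
  s0 <- template$ring_spacing
  function(par) {
    .npc_nll_cpp(par, P, nseg, twist, d0, s0, sigma, outlier_weight,
                 log_unif_dens, free_geometry)
  }
}

#' Fit the double-ring template to the points of one pore
#'
#' Maximum-likelihood rigid fit of the 16-anchor double-ring template: each
#' point is modeled as drawn from a mixture of an isotropic Gaussian centered
#' at its nearest segment anchor and a uniform outlier component. The pose
#' (center, symmetry axis, in-plane rotation) is found from a deterministic
#' set of starts: for every candidate axis (the smallest principal component
#' of the points plus cube-grid and Fibonacci-hemisphere directions) the
#' center and spin are initialised in closed form (axial ring split, Kasa
#' circle fit, phase of the `nseg`-th angular harmonic), the starts are
#' scored and refined on a smoothed (coarse-sigma) likelihood, and the best
#' are polished at the target sigma with Nelder-Mead restarts; with
#' `free_geometry = TRUE` the ring diameter and spacing are refined jointly
#' in a final pass. The axis sign is fixed to non-negative z (it is not
#' identifiable from the geometry).
#'
#' @param points Tibble with `x, y, z` (nm) or an n x 3 matrix; at least 4
#'   points are required for the pose to be identifiable.
#' @param template An [npc_template()].
#' @param sigma Gaussian scale of the anchor mixture in nm (default 5:
#'   localization error plus the within-segment site offsets).
#' @param outlier_weight Mixture weight of the uniform component (default 0.1).
#' @param free_geometry Also refine ring diameter and spacing (default FALSE).
#' @param n_spin_starts Extra centroid-centered spin-scan starts added for
#'   the principal-component axis (default 8, spanning one symmetry sector);
#'   insurance against a degenerate closed-form initialisation.
#' @param refine_top Number of best grid starts refined by the local
#'   optimizer (default 5).
#' @return An `npc_fit` list: `center`, `axis` (unit, z >= 0), `rotation`
#'   (template-to-world), `in_plane_deg`, `diameter`, `spacing`, `loglik`,
#'   `n_points`, `converged`.
#' @export
fit_npc_template <- function(points, template = npc_template(), sigma = 5,
                             outlier_weight = 0.1, free_geometry = FALSE,
                             n_spin_starts = 8, refine_top = 5) {
  P <- as_xyz(points)
  if (nrow(P) < 4) abort("pose is unidentifiable with fewer than 4 points")
  stopifnot(inherits(template, "npc_template"))
  pad <- 50
  vol <- prod(apply(P, 2, function(v) diff(range(v)) + 2 * pad))
  log_unif <- -log(vol)
  nll <- make_npc_pose_nll(P, template, sigma, outlier_weight, log_unif)
  # graduated refinement: the nearest-anchor mixture is rugged at the target
  # sigma, so grid starts are scored and first refined on a smoothed
  # (large-sigma) surface before polishing at the target sigma
  sigma_coarse <- max(sigma, 12)
  nll_coarse <- make_npc_pose_nll(P, template, sigma_coarse, outlier_weight, log_unif)
  centroid <- colMeans(P)
  # the symmetry axis of a double ring is the direction of smallest spread,
  # so the smallest principal component makes an excellent extra start
  pca_axis <- tryCatch({
    ev <- eigen(stats::cov(P), symmetric = TRUE)$vectors[, 3]
    if (ev[3] < 0) ev <- -ev
    if (ev[3] < 0.05) ev <- c(ev[1], ev[2], 0.05) / sqrt(sum(c(ev[1], ev[2], 0.05)^2))
    matrix(ev, nrow = 1)
  }, error = function(e) NULL)
  axes <- rbind(pca_axis, axis_start_grid(), axis_fibonacci_grid())
  nseg <- template$n_segments_per_ring
  sector <- 2 * pi / nseg
  spins <- (seq_len(n_spin_starts) - 1) * sector / n_spin_starts
  # one closed-form start per axis, plus a centroid-centered spin scan for
  # the principal-component axis (cheap insurance against a degenerate
  # circle fit)
  start_pars <- lapply(seq_len(nrow(axes)), function(i)
    init_pose_for_axis(P, axes[i, ], nseg))
  for (phi in spins) {
    a <- axes[1, ]
    start_pars[[length(start_pars) + 1]] <- c(centroid, a[1] / a[3], a[2] / a[3], phi)
  }
  scores <- vapply(start_pars, nll_coarse, numeric(1))
  best_idx <- order(scores)[seq_len(min(refine_top, length(scores)))]
  best <- NULL
  converged <- FALSE
  refine <- function(par0, fn, maxit = 500) {
    opt <- tryCatch(
      optim(par0, fn, method = "Nelder-Mead",
            control = list(maxit = maxit, reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(opt)) return(NULL)
    # Nelder-Mead stagnates on narrow valleys; restart from the optimum
    for (restart in 1:2) {
      opt2 <- tryCatch(
        optim(opt$par, fn, method = "Nelder-Mead",
              control = list(maxit = maxit, reltol = 1e-8)),
        error = function(e) NULL)
      if (is.null(opt2) || opt2$value >= opt$value - 1e-8) break
      opt <- opt2
    }
    opt
  }
  coarse_opts <- list()
  for (r in best_idx) {
    opt_c <- tryCatch(
      optim(start_pars[[r]], nll_coarse, method = "Nelder-Mead",
            control = list(maxit = 300, reltol = 1e-7)),
      error = function(e) NULL)
    if (!is.null(opt_c)) coarse_opts[[length(coarse_opts) + 1]] <- opt_c
  }
  if (length(coarse_opts) == 0) abort("template fit failed on all starts")
  coarse_opts <- coarse_opts[order(vapply(coarse_opts, `[[`, numeric(1), "value"))]
  for (opt_c in coarse_opts[seq_len(min(3, length(coarse_opts)))]) {
    opt <- refine(opt_c$par, nll)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
    if (opt$convergence == 0) converged <- TRUE
  }
  if (is.null(best)) abort("template fit failed on all starts")
  diameter <- template$ring_diameter
  spacing <- template$ring_spacing
  par <- unname(best$par)
  value <- best$value
  if (free_geometry) {
    nll_g <- make_npc_pose_nll(P, template, sigma, outlier_weight, log_unif,
                               free_geometry = TRUE)
    # data-driven geometry start in the fitted frame: axial ring split gives
    # the spacing, mean radial distance the diameter
    axis0 <- c(par[4], par[5], 1)
    axis0 <- axis0 / sqrt(sum(axis0^2))
    local <- sweep(P, 2, par[1:3]) %*%
      (rotation_align_z(axis0) %*% rotation_z(par[6]))
    tt <- local[, 3]
    s_init <- if (any(tt > 0) && any(tt < 0)) {
      max(mean(tt[tt > 0]) - mean(tt[tt < 0]), 5)
    } else {
      spacing
    }
    d_init <- max(2 * mean(sqrt(local[, 1]^2 + local[, 2]^2)), 10)
    for (g0 in list(c(diameter, spacing), c(d_init, s_init))) {
      opt_g <- refine(c(par, log(g0[1]), log(g0[2])), nll_g, maxit = 700)
      if (!is.null(opt_g) && opt_g$value <= value) {
        par <- opt_g$par[1:6]
        diameter <- exp(opt_g$par[7])
        spacing <- exp(opt_g$par[8])
        value <- opt_g$value
        converged <- converged || opt_g$convergence == 0
      }
    }
  }
  axis <- c(par[4], par[5], 1)
  axis <- axis / sqrt(sum(axis^2))
  R <- rotation_align_z(axis) %*% rotation_z(par[6])
  structure(list(
    center = par[1:3], axis = axis, rotation = R,
    in_plane_deg = (par[6] * 180 / pi) %% (360 / template$n_segments_per_ring),
    diameter = diameter, spacing = spacing,
    loglik = -value, n_points = nrow(P), converged = converged,
    template = template, sigma = sigma, outlier_weight = outlier_weight
  ), class = "npc_fit")
}

#' @export
print.npc_fit <- function(x, ...) {
  cat(sprintf(
    "<npc_fit> %d points | center (%.1f, %.1f, %.1f) nm | tilt %.1f deg | spacing %.1f nm | logLik %.1f\n",
    x$n_points, x$center[1], x$center[2], x$center[3],
    acos(pmin(1, x$axis[3])) * 180 / pi, x$spacing, x$loglik))
  invisible(x)
}

#' Count labeled segments of a fitted pore
#'
#' Transforms the points into the fitted template frame, assigns each to its
#' nearest segment anchor, and marks a segment as labeled when at least one
#' assigned point lies within `tol` of the anchor. The cytoplasmic and
#' nucleoplasmic rings are reported separately via the `ring` column.
#'
#' @param fit An `npc_fit` from [fit_npc_template()].
#' @param points The points used in the fit (tibble with `x, y, z`; an
#'   optional `n_traces` column is summed per segment for visit-rate
#'   estimation).
#' @param tol Distance tolerance in nm for calling a segment labeled
#'   (default 15, below half the ~41 nm inter-anchor chord).
#' @return Tibble `segment, ring, labeled, n_points, n_traces` with one row
#'   per template segment (cytoplasmic ring first).
#' @export
count_labeled_segments <- function(fit, points, tol = 15) {
  stopifnot(inherits(fit, "npc_fit"))
  P <- as_xyz(points)
  nseg <- fit$template$n_segments_per_ring
  anchors <- npc_template_anchors(fit$template, ring_diameter = fit$diameter,
                                  ring_spacing = fit$spacing)
  local <- sweep(P, 2, fit$center) %*% fit$rotation
  d2 <- outer(rowSums(local^2), rowSums(anchors^2), "+") - 2 * local %*% t(anchors)
  nearest <- apply(d2, 1, which.min)
  dmin <- sqrt(pmax(0, d2[cbind(seq_len(nrow(P)), nearest)]))
  within <- dmin <= tol
  n_traces_col <- if (is.data.frame(points) && "n_traces" %in% names(points)) {
    points$n_traces
  } else {
    rep(1L, nrow(P))
  }
  seg <- seq_len(2 * nseg)
  tibble(
    segment = seg,
    ring = rep(c("cytoplasmic", "nucleoplasmic"), each = nseg),
    labeled = vapply(seg, function(s) any(within & nearest == s), logical(1)),
    n_points = vapply(seg, function(s) sum(within & nearest == s), integer(1)),
    n_traces = vapply(seg, function(s) sum(n_traces_col[within & nearest == s]),
                      numeric(1))
  )
}

#' Predicted distribution of labeled-segment counts
#'
#' A segment with `s` independent tag sites is labeled with probability
#' `q = 1 - (1 - p)^s`; the number of labeled segments among `m` is then
#' Binomial(`m`, `q`). With `kmin > 0` the law is left-truncated and
#' renormalised to `k >= kmin`, modeling that pores without any labeled
#' segment cannot be detected.
#'
#' @param p Per-site effective labeling probability in `[0, 1]`.
#' @param m Total number of segments (default 16).
#' @param s Tag sites per segment (default 2).
#' @param kmin Smallest observable count (default 0).
#' @return Tibble `k, prob` over `k = kmin..m`; `prob` sums to 1.
#' @export
predicted_segment_distribution <- function(p, m = 16, s = 2, kmin = 0) {
  if (p < 0 || p > 1) abort("`p` must be in [0, 1]")
  stopifnot(kmin >= 0, kmin <= m)
  q <- 1 - (1 - p)^s
  k <- kmin:m
  prob <- dbinom(k, m, q)
  total <- sum(prob)
  if (total <= 0) {
    # all mass below kmin (p == 0 with truncation): degenerate at kmin
    prob <- c(1, rep(0, length(k) - 1))
  } else {
    prob <- prob / total
  }
  tibble(k = k, prob = prob)
}

ple_loglik <- function(p, counts_k, k_values, m, s, kmin) {
  pred <- predicted_segment_distribution(p, m = m, s = s, kmin = kmin)
  lp <- log(pred$prob[match(k_values, pred$k)])
  if (any(!is.finite(lp) & counts_k > 0)) return(-Inf)
  sum(counts_k * lp, na.rm = TRUE)
}

#' Estimate the effective labeling efficiency from segment counts
#'
#' Maximum-likelihood fit of the (optionally left-truncated) binomial
#' segment-count model to per-pore labeled-segment counts. The likelihood is
#' profiled on a coarse grid (step 0.001) and polished by golden-section
#' search; the standard error comes from the curvature of the log-likelihood
#' at the optimum, with a nonparametric bootstrap over pores as fallback.
#'
#' @param k Integer vector of labeled-segment counts, one per pore
#'   (`0..m`). Alternatively supply `histogram`.
#' @param histogram Counts of pores with `0..m` labeled segments (length
#'   `m + 1`), used instead of `k` when given.
#' @param kmin Truncation threshold: only pores with `k >= kmin` enter the
#'   fit (default 1, since fully unlabeled pores are undetectable).
#' @param s Tag sites per segment (default 2).
#' @param m Segments per pore (default 16).
#' @param n_boot Bootstrap resamples for the fallback standard error.
#' @return A `ple_estimate` list: `p_le`, `stderr`, `n_npcs`, `histogram`,
#'   `kmin`, `s`, `m`, `loglik`, `boundary`. Supports [tidy()], [glance()]
#'   and [autoplot()].
#' @export
estimate_labeling_efficiency <- function(k = NULL, histogram = NULL, kmin = 1,
                                         s = 2, m = 16, n_boot = 1000) {
  if (is.null(histogram)) {
    if (is.null(k)) abort("supply `k` (per-pore counts) or `histogram`")
    if (any(k < 0 | k > m)) abort(sprintf("`k` values must lie in 0..%d", m))
    histogram <- tabulate(k + 1L, nbins = m + 1L)
  }
  if (length(histogram) != m + 1) abort(sprintf("`histogram` must have %d counts (k = 0..%d)", m + 1, m))
  k_values <- kmin:m
  counts_k <- histogram[k_values + 1L]
  n_used <- sum(counts_k)
  if (n_used == 0) abort("no pores with k >= kmin; nothing to fit")
  if (sum(counts_k[k_values < m]) == 0) {
    # all observed pores fully labeled: boundary estimate
    est <- structure(list(p_le = 1, stderr = 0, n_npcs = sum(histogram),
                          histogram = histogram, kmin = kmin, s = s, m = m,
                          loglik = 0, boundary = TRUE), class = "ple_estimate")
    return(est)
  }
  grid <- seq(0.001, 0.999, by = 0.001)
  ll <- vapply(grid, ple_loglik, numeric(1), counts_k = counts_k,
               k_values = k_values, m = m, s = s, kmin = kmin)
  p0 <- grid[which.max(ll)]
  opt <- optimize(ple_loglik, interval = c(max(1e-6, p0 - 0.002), min(1 - 1e-6, p0 + 0.002)),
                  counts_k = counts_k, k_values = k_values, m = m, s = s,
                  kmin = kmin, maximum = TRUE, tol = 1e-7)
  p_hat <- opt$maximum
  h <- 1e-4
  ll2 <- (ple_loglik(min(p_hat + h, 1 - 1e-9), counts_k, k_values, m, s, kmin) -
            2 * ple_loglik(p_hat, counts_k, k_values, m, s, kmin) +
            ple_loglik(max(p_hat - h, 1e-9), counts_k, k_values, m, s, kmin)) / h^2
  stderr <- if (is.finite(ll2) && ll2 < 0) 1 / sqrt(-ll2) else NA_real_
  if (!is.finite(stderr)) {
    # bootstrap over pores
    pool <- rep(k_values, counts_k)
    boots <- vapply(seq_len(n_boot), function(b) {
      res <- sample(pool, length(pool), replace = TRUE)
      cnt <- vapply(k_values, function(kk) sum(res == kk), numeric(1))
      g <- vapply(grid, ple_loglik, numeric(1), counts_k = cnt,
                  k_values = k_values, m = m, s = s, kmin = kmin)
      grid[which.max(g)]
    }, numeric(1))
    stderr <- sd(boots)
  }
  structure(list(p_le = p_hat, stderr = stderr, n_npcs = sum(histogram),
                 histogram = histogram, kmin = kmin, s = s, m = m,
                 loglik = opt$objective, boundary = FALSE),
            class = "ple_estimate")
}

#' @export
print.ple_estimate <- function(x, ...) {
  cat(sprintf("<ple_estimate> p_LE = %.1f%% +/- %.1f%% (n = %d structures%s)\n",
              100 * x$p_le, 100 * x$stderr, x$n_npcs,
              if (isTRUE(x$boundary)) ", boundary" else ""))
  invisible(x)
}

#' Summarise pore geometry across fits
#'
#' Robust (median) estimate of the fitted ring spacing and diameter across
#' pores, with a bootstrap standard error.
#'
#' @param fits List of `npc_fit` objects fitted with `free_geometry = TRUE`.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap.
#' @return Tibble `parameter, estimate, se, n` with rows `ring_spacing` and
#'   `ring_diameter` (nm). With a single fit `se` is `NA`.
#' @export
estimate_npc_geometry <- function(fits, n_boot = 1000, seed = 1) {
  fits <- Filter(function(f) inherits(f, "npc_fit"), fits)
  if (length(fits) == 0) abort("no successful fits supplied")
  spacing <- vapply(fits, function(f) f$spacing, numeric(1))
  diameter <- vapply(fits, function(f) f$diameter, numeric(1))
  boot_se <- function(v) {
    if (length(v) < 2) return(NA_real_)
    withr::with_seed(seed, {
      sd(vapply(seq_len(n_boot), function(b)
        median(sample(v, length(v), replace = TRUE)), numeric(1)))
    })
  }
  tibble(
    parameter = c("ring_spacing", "ring_diameter"),
    estimate = c(median(spacing), median(diameter)),
    se = c(boot_se(spacing), boot_se(diameter)),
    n = length(fits)
  )
}

#' Mean number of site visits per tag site
#'
#' Estimated from segment-level trace counts: the mean over labeled segments
#' of (assigned trace count / sites per segment). Dividing by the full
#' `sites_per_segment` assumes every site of a labeled segment is occupied;
#' under partial labeling only `s p / (1 - (1 - p)^s)` sites are occupied on
#' average, so supplying `p_le` replaces the divisor by that expectation and
#' removes the downward bias.
#'
#' @param segment_counts One tibble from [count_labeled_segments()] or a list
#'   of them (pooled).
#' @param sites_per_segment Tag sites per segment (default 2).
#' @param p_le Optional labeling efficiency used to correct the divisor for
#'   partial site occupancy (default `NULL`: no correction).
#' @return One-row tibble `mean_visits_per_site, n_segments`.
#' @export
site_visit_rate <- function(segment_counts, sites_per_segment = 2, p_le = NULL) {
  if (is.data.frame(segment_counts)) segment_counts <- list(segment_counts)
  pooled <- dplyr::bind_rows(segment_counts)
  lab <- pooled[pooled$labeled, , drop = FALSE]
  if (nrow(lab) == 0) abort("no labeled segments; visit rate undefined")
  divisor <- if (is.null(p_le)) {
    sites_per_segment
  } else {
    sites_per_segment * p_le / (1 - (1 - p_le)^sites_per_segment)
  }
  tibble(mean_visits_per_site = mean(lab$n_traces / divisor),
         n_segments = nrow(lab))
}

#' Run the full labeling-efficiency assay on a localization table
#'
#' Convenience pipeline: per-trace combination, spatial subunit merge,
#' candidate detection, per-pore template fitting and segment counting, and
#' the truncated-binomial efficiency fit.
#'
#' @param localizations Raw localization tibble (`tid, x, y, z`).
#' @param template An [npc_template()].
#' @param merge_eps Site-merge distance in nm (default 1).
#' @param group_eps,min_points,max_extent Candidate detection parameters, see
#'   [detect_npc_candidates()].
#' @param tol Segment-labeling tolerance in nm (default 15).
#' @param kmin Truncation threshold of the efficiency fit (default 1).
#' @param sites_per_segment Tag sites per segment (default 2).
#' @param free_geometry Refine ring diameter/spacing per pore (default FALSE).
#' @param ... Further arguments passed to [fit_npc_template()].
#' @return List with `ple` (a `ple_estimate`), `fits`, `segment_counts`,
#'   `candidates`, `visit_rate` and `subunits`.
#' @export
run_npc_assay <- function(localizations, template = npc_template(),
                          merge_eps = 1, group_eps = 100, min_points = 6,
                          max_extent = 250, tol = 15, kmin = 1,
                          sites_per_segment = 2, free_geometry = FALSE, ...) {
  sites <- combine_traces(localizations)
  subunits <- merge_subunits(sites, eps = merge_eps)
  candidates <- detect_npc_candidates(subunits, group_eps = group_eps,
                                      min_points = min_points,
                                      max_extent = max_extent)
  if (nrow(candidates) == 0) abort("no pore candidates detected")
  fits <- vector("list", nrow(candidates))
  segs <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    pts <- candidates$data[[i]]
    fits[[i]] <- fit_npc_template(pts, template = template,
                                  free_geometry = free_geometry, ...)
    segs[[i]] <- count_labeled_segments(fits[[i]], pts, tol = tol)
  }
  k <- vapply(segs, function(s) sum(s$labeled), integer(1))
  m <- 2L * template$n_segments_per_ring
  ple <- estimate_labeling_efficiency(k = k, kmin = kmin,
                                      s = sites_per_segment, m = m)
  list(ple = ple, fits = fits, segment_counts = segs, candidates = candidates,
       visit_rate = site_visit_rate(segs, sites_per_segment = sites_per_segment,
                                    p_le = ple$p_le),
       subunits = subunits)
}
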