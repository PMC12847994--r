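# Rigid tag-square fitting for RyR2 tetramer position/orientation recovery,
# and the detection-probability algebra linking per-subunit labeling to
# tetramer detection.

#' Tag-square template of a tetramer
#'
#' The four fluorescent-protein tag sites of an RyR2 homotetramer form a
#' square: side ~16 nm rotated 45 degrees relative to the tetramer outline
#' for the GFP insertion, side ~20 nm approximately aligned with the outline
#' corners for the TagRFP insertion.
#'
#' @param tag_kind `"GFP16"` or `"RFP20"`.
#' @param side Optional side length override in nm (defaults 16 / 20).
#' @return A `tag_template` list with `corners` (4 x 3 matrix, centroid at
#'   the origin, z = 0 plane), `side`, `offset_angle_deg`.
#' @export
tag_template <- function(tag_kind = c("GFP16", "RFP20"), side = NULL) {
  tag_kind <- match.arg(tag_kind)
  defaults <- list(GFP16 = list(side = 16, offset = 45),
                   RFP20 = list(side = 20, offset = 0))
  side <- side %||% defaults[[tag_kind]]$side
  if (side <= 0) abort("`side` must be > 0")
  offset <- defaults[[tag_kind]]$offset
  # tetramer outline corners sit on the diagonals (45, 135, ...); the tag
  # square is rotated by `offset` relative to the outline
  ang <- (c(45, 135, 225, 315) + offset) * pi / 180
  r <- side / sqrt(2)
  structure(list(
    tag_kind = tag_kind, side = side, offset_angle_deg = offset,
    corners = cbind(r * cos(ang), r * sin(ang), 0)
  ), class = "tag_template")
}

# All injective assignments of n points to the 4 template corners.
corner_assignments <- function(n) {
  perms4 <- as.matrix(expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))
  perms4 <- perms4[apply(perms4, 1, function(r) length(unique(r)) == 4), , drop = FALSE]
  unique(perms4[, seq_len(n), drop = FALSE])
}

#' Fit the tag-square template to 3 or 4 subunit positions
#'
#' Over all injective assignments of the observed points to template
#' corners, computes the least-squares rigid superposition (centroid
#' alignment plus optimal proper rotation, Kabsch) and returns the
#' assignment with minimal RMSD. With 3 points the predicted position of the
#' missing fourth corner is reported as well. The recovered orientation is
#' only defined modulo the C4 symmetry of the square; compare rotations with
#' [rotation_angle_between()] using `symmetry_fold = 4`.
#'
#' @param points 3 or 4 positions (tibble with `x, y, z` or matrix, nm);
#'   pairwise distances must be below `max_pair_dist`.
#' @param template A [tag_template()].
#' @param max_pair_dist Plausibility gate on pairwise distances in nm
#'   (default 40).
#' @return A `tetramer_fit` list: `center`, `rotation` (template-to-world),
#'   `quaternion`, `matched_corners`, `rmsd`, `n_points`, `tag_kind`,
#'   `predicted_corner` (world position of the unobserved corner, `NULL` for
#'   4-point fits).
#' @export
fit_tetramer <- function(points, template = tag_template("GFP16"),
                         max_pair_dist = 40) {
  P <- as_xyz(points)
  n <- nrow(P)
  if (n < 3) abort("pose is unidentifiable with fewer than 3 points")
  if (n > 4) abort("at most 4 points (one tetramer) can be fitted")
  stopifnot(inherits(template, "tag_template"))
  if (max(dist(P)) > max_pair_dist) {
    abort(sprintf("pairwise distance exceeds %.0f nm; not a single tetramer", max_pair_dist))
  }
  # degenerate-configuration gate: max triangle area over point triples
  tri_area <- function(a, b, c) {
    v1 <- b - a; v2 <- c - a
    cr <- c(v1[2] * v2[3] - v1[3] * v2[2], v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
    0.5 * sqrt(sum(cr^2))
  }
  triples <- utils::combn(n, 3)
  areas <- apply(triples, 2, function(ix) tri_area(P[ix[1], ], P[ix[2], ], P[ix[3], ]))
  if (max(areas) < 1) abort("points are (near-)collinear; pose is degenerate")
  assigns <- corner_assignments(n)
  best <- NULL
  for (r in seq_len(nrow(assigns))) {
    corners <- template$corners[assigns[r, ], , drop = FALSE]
    cc <- colMeans(corners); pc <- colMeans(P)
    R <- kabsch_rotation(sweep(corners, 2, cc), sweep(P, 2, pc))
    fittedv <- sweep(sweep(corners, 2, cc) %*% t(R), 2, pc, "+")
    rmsd <- sqrt(mean(rowSums((fittedv - P)^2)))
    if (is.null(best) || rmsd < best$rmsd) {
      best <- list(rmsd = rmsd, R = R, assign = assigns[r, ], cc = cc, pc = pc)
    }
  }
  # translation of the template frame: world = R (corner - 0) + t with the
  # template centroid at the origin
  t_vec <- best$pc - as.numeric(best$R %*% best$cc)
  predicted <- NULL
  if (n == 3) {
    missing_corner <- setdiff(1:4, best$assign)
    predicted <- as.numeric(best$R %*% template$corners[missing_corner, ]) + t_vec
  }
  structure(list(
    center = t_vec, rotation = best$R,
    quaternion = rotation_to_quaternion(best$R),
    matched_corners = as.integer(best$assign), rmsd = best$rmsd,
    n_points = n, tag_kind = template$tag_kind,
    predicted_corner = predicted, template = template
  ), class = "tetramer_fit")
}

#' @export
print.tetramer_fit <- function(x, ...) {
  cat(sprintf("<tetramer_fit> %s, %d points, rmsd %.2f nm, center (%.1f, %.1f, %.1f) nm\n",
              x$tag_kind, x$n_points, x$rmsd, x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

#' Decompose a tetramer orientation error
#'
#' Compares an estimated rotation against the generating one, reduced by the
#' full proper symmetry group of the square (4 rotations about the normal
#' plus 4 in-plane flips), and decomposes the residual into interpretable
#' parts: the total 3D rotation angle, the tilt of the recovered square
#' normal, and the in-plane orientation error (the angle between the true
#' and the estimated corner directions after projection onto the true square
#' plane) which is the quantity usually read off an overlay of the receptor
#' outline.
#'
#' @param R_est,R_true 3x3 proper rotation matrices (template-to-world).
#' @param symmetry_fold Cyclic order of the template (default 4).
#' @return One-row tibble `total_deg, axis_deg, in_plane_deg`.
#' @export
tetramer_orientation_error <- function(R_est, R_true, symmetry_fold = 4) {
  total <- rotation_angle_between(R_est, R_true, symmetry_fold = symmetry_fold,
                                  include_flips = TRUE)
  n_est <- R_est %*% c(0, 0, 1)
  n_true <- R_true %*% c(0, 0, 1)
  axis_deg <- acos(pmin(1, abs(sum(n_est * n_true)))) * 180 / pi
  # corner-direction azimuth error in the true square plane, minimised over
  # the symmetry images of the corner
  u_true <- as.numeric(R_true %*% c(1, 0, 0))
  in_plane <- Inf
  for (k in seq_len(symmetry_fold) - 1L) {
    for (flip in c(FALSE, TRUE)) {
      S <- rotation_about_axis(c(0, 0, 1), 2 * pi * k / symmetry_fold)
      if (flip) S <- S %*% rotation_about_axis(c(1, 0, 0), pi)
      u_est <- as.numeric(R_est %*% S %*% c(1, 0, 0))
      proj <- u_est - sum(u_est * n_true) * as.numeric(n_true)
      norm_p <- sqrt(sum(proj^2))
      if (norm_p < 1e-9) next
      ang <- acos(pmin(1, pmax(-1, sum(proj * u_true) / norm_p))) * 180 / pi
      in_plane <- min(in_plane, ang)
    }
  }
  tibble(total_deg = total, axis_deg = axis_deg, in_plane_deg = in_plane)
}

#' Probability of detecting a complex from its labeled subunits
#'
#' A complex is detected when at least one of its `n` subunits is labeled
#' and detected: `1 - (1 - p)^n`.
#'
#' @param p Per-subunit effective labeling probability in `[0, 1]`.
#' @param n Subunits per complex (default 4).
#' @return Detection probability.
#' @examples
#' detection_probability(0.512)  # ~0.943: a ~94% RyR2 detection chance
#' @export
detection_probability <- function(p, n = 4) {
  if (any(p < 0 | p > 1)) abort("`p` must be in [0, 1]")
  1 - (1 - p)^n
}

#' Distribution of labeled subunits per tetramer
#'
#' Binomial(`n`, `p`) mass function of the number of labeled subunits.
#'
#' @param p Per-subunit labeling probability in `[0, 1]`.
#' @param n Subunits per complex (default 4).
#' @return Tibble `k, prob` over `k = 0..n`.
#' @export
subunit_count_pmf <- function(p, n = 4) {
  if (p < 0 || p > 1) abort("`p` must be in [0, 1]")
  tibble(k = 0:n, prob = dbinom(0:n, n, p))
}

#' Estimate labeling efficiency from labeled-subunit counts
#'
#' Maximum-likelihood fit of a zero-truncated Binomial(`n`, `p`) to the
#' observed numbers of complexes with `1..n` labeled subunits (complexes
#' with zero labeled subunits are undetectable). Standard error from the
#' curvature of the log-likelihood.
#'
#' @param counts Numeric vector of length `n`: numbers of complexes with
#'   `1, 2, ..., n` labeled subunits.
#' @param n Subunits per complex (default 4).
#' @return A `ple_estimate` (see [estimate_labeling_efficiency()]) with
#'   `m = n`, `s = 1`, `kmin = 1`.
#' @export
estimate_ple_from_subunit_counts <- function(counts, n = 4) {
  if (length(counts) != n) abort(sprintf("`counts` must have %d entries (k = 1..%d)", n, n))
  if (sum(counts) == 0) abort("all counts are zero")
  estimate_labeling_efficiency(histogram = c(0, counts), kmin = 1, s = 1, m = n)
}
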