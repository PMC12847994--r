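# broom-style tidy()/glance() methods for the fitted objects.

#' Tidy a labeling-efficiency estimate
#'
#' One row per labeled-segment count with observed and model-predicted
#' frequencies (predictions conditioned on `k >= kmin`).
#'
#' @param x A `ple_estimate`.
#' @param ... Unused.
#' @return Tibble `k, n_observed, prop_observed, prop_predicted`.
#' @export
tidy.ple_estimate <- function(x, ...) {
  k <- 0:x$m
  pred <- predicted_segment_distribution(x$p_le, m = x$m, s = x$s, kmin = x$kmin)
  n_used <- sum(x$histogram[(x$kmin:x$m) + 1])
  tibble(
    k = k,
    n_observed = x$histogram,
    prop_observed = ifelse(k >= x$kmin, x$histogram / n_used, NA_real_),
    prop_predicted = pred$prob[match(k, pred$k)]
  )
}

#' Glance at a labeling-efficiency estimate
#'
#' @param x A `ple_estimate`.
#' @param ... Unused.
#' @return One-row tibble `p_le, stderr, n, kmin, loglik, boundary`.
#' @export
glance.ple_estimate <- function(x, ...) {
  tibble(p_le = x$p_le, stderr = x$stderr, n = x$n_npcs, kmin = x$kmin,
         loglik = x$loglik, boundary = x$boundary)
}

#' Tidy cluster statistics
#'
#' @param x A `cluster_stats`.
#' @param ... Unused.
#' @return Per-cluster tibble `cluster, size_su, size_corrected, size_ryr2,
#'   large`.
#' @export
tidy.cluster_stats <- function(x, ...) x$sizes

#' Glance at cluster statistics
#'
#' @param x A `cluster_stats`.
#' @param ... Unused.
#' @return One-row tibble of the summary statistics.
#' @export
glance.cluster_stats <- function(x, ...) {
  tibble(
    n_clusters = x$n_clusters, n_subunits = x$n_subunits,
    mean_su = x$mean_su, mean_su_gt1 = x$mean_su_gt1,
    mean_su_corrected = x$mean_su_corrected,
    mean_ryr2 = x$mean_ryr2, mean_ryr2_gt1 = x$mean_ryr2_gt1,
    frac_in_large = x$frac_in_large,
    frac_large_clusters = x$frac_large_clusters,
    frac_top3 = x$frac_top3,
    large_threshold = x$large_threshold, p_le = x$p_le
  )
}

#' Tidy a nuclear-pore template fit
#'
#' @param x An `npc_fit`.
#' @param ... Unused.
#' @return One-row tibble with pose and geometry parameters.
#' @export
tidy.npc_fit <- function(x, ...) {
  tibble(
    center_x = x$center[1], center_y = x$center[2], center_z = x$center[3],
    axis_x = x$axis[1], axis_y = x$axis[2], axis_z = x$axis[3],
    tilt_deg = acos(pmin(1, x$axis[3])) * 180 / pi,
    in_plane_deg = x$in_plane_deg,
    diameter = x$diameter, spacing = x$spacing,
    loglik = x$loglik, n_points = x$n_points, converged = x$converged
  )
}

#' Tidy a tetramer fit
#'
#' @param x A `tetramer_fit`.
#' @param ... Unused.
#' @return One-row tibble with center, quaternion, rmsd and bookkeeping.
#' @export
tidy.tetramer_fit <- function(x, ...) {
  tibble(
    center_x = x$center[1], center_y = x$center[2], center_z = x$center[3],
    q_w = x$quaternion[1], q_x = x$quaternion[2], q_y = x$quaternion[3],
    q_z = x$quaternion[4],
    rmsd = x$rmsd, n_points = x$n_points, tag_kind = x$tag_kind
  )
}

#' Tidy a nearest-neighbor group comparison
#'
#' @param x An `nn_comparison`.
#' @param ... Unused.
#' @return Tibble of pairwise Tukey HSD results.
#' @export
tidy.nn_comparison <- function(x, ...) x$tukey

#' Glance at a nearest-neighbor group comparison
#'
#' @param x An `nn_comparison`.
#' @param ... Unused.
#' @return One-row tibble `anova_F, anova_p, n_groups`.
#' @export
glance.nn_comparison <- function(x, ...) {
  tibble(anova_F = x$anova_F, anova_p = x$anova_p,
         n_groups = length(x$n_per_group))
}
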