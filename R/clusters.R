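# Functional RyR2 cluster analysis: fire-diffuse-fire DBSCAN grouping and
# cluster statistics with labeling-efficiency correction.

#' Group subunits into functionally coupled clusters
#'
#' DBSCAN on the 3D subunit positions with the calcium-signaling distance
#' criterion: receptors within `eps` of each other can activate one another
#' via calcium-induced calcium release, so chains of such links form one
#' functional cluster. With the default `min_pts = 1` isolated subunits form
#' singleton clusters and the labels equal the connected components of the
#' eps-adjacency graph.
#'
#' @param subunits Subunit tibble (see [merge_subunits()]) or any tibble
#'   with `x, y, z` columns.
#' @param eps Coupling distance in nm (default 100).
#' @param min_pts DBSCAN minimum neighborhood size (default 1).
#' @return The input tibble with an integer `cluster` column appended
#'   (0 marks noise, only possible when `min_pts > 1`).
#' @export
cluster_subunits <- function(subunits, eps = 100, min_pts = 1) {
  if (eps <= 0) abort("`eps` must be > 0")
  if (nrow(subunits) == 0) {
    subunits$cluster <- integer(0)
    return(subunits)
  }
  xyz <- as_xyz(subunits)
  subunits$cluster <- dbscan_labels(xyz, eps = eps, min_pts = min_pts)
  subunits
}

#' Cluster statistics with labeling-efficiency correction
#'
#' Computes subunit-count statistics per cluster and the derived quantities:
#' mean subunits per cluster (all clusters and clusters with more than one
#' subunit), labeling-efficiency-corrected sizes (`size / p_le`), converted
#' RyR2 counts (`corrected / 4`, one tag site per protomer of the
#' homotetramer), and large-cluster fractions.
#'
#' @param clustered Tibble with a `cluster` column, from [cluster_subunits()],
#'   or a bare integer vector of cluster labels.
#' @param p_le Effective labeling efficiency in `(0, 1]` used for the
#'   correction.
#' @param large_threshold Measured-subunit count at or above which a cluster
#'   is "large" (default 50, i.e. >= 12.5 RyR2s at full labeling).
#' @param subunits_per_complex Tag sites per complex (default 4).
#' @return A `cluster_stats` list with per-cluster `sizes` tibble and summary
#'   fields (`n_clusters`, `mean_su`, `mean_su_gt1`, `mean_su_corrected`,
#'   `mean_ryr2`, `mean_ryr2_gt1`, `frac_in_large`, `frac_large_clusters`,
#'   `frac_top3`, ...). Supports [tidy()] and [glance()].
#' @export
compute_cluster_stats <- function(clustered, p_le = 1, large_threshold = 50,
                                  subunits_per_complex = 4) {
  if (p_le <= 0 || p_le > 1) abort("`p_le` must be in (0, 1]")
  labels <- if (is.data.frame(clustered)) {
    if (!"cluster" %in% names(clustered)) abort("`clustered` must have a `cluster` column")
    clustered$cluster
  } else {
    as.integer(clustered)
  }
  labels <- labels[labels > 0]
  if (length(labels) == 0) abort("no clustered subunits")
  sizes <- as.integer(table(labels))
  sizes_tbl <- tibble(
    cluster = as.integer(names(table(labels))),
    size_su = sizes,
    size_corrected = sizes / p_le,
    size_ryr2 = sizes / p_le / subunits_per_complex,
    large = sizes >= large_threshold
  )
  n_su <- sum(sizes)
  top3 <- sum(sort(sizes, decreasing = TRUE)[seq_len(min(3, length(sizes)))])
  structure(list(
    sizes = sizes_tbl,
    n_clusters = length(sizes),
    n_subunits = n_su,
    mean_su = mean(sizes),
    mean_su_gt1 = if (any(sizes > 1)) mean(sizes[sizes > 1]) else NA_real_,
    mean_su_corrected = mean(sizes) / p_le,
    mean_ryr2 = mean(sizes) / p_le / subunits_per_complex,
    mean_ryr2_gt1 = if (any(sizes > 1))
      mean(sizes[sizes > 1]) / p_le / subunits_per_complex else NA_real_,
    frac_in_large = sum(sizes[sizes >= large_threshold]) / n_su,
    frac_large_clusters = mean(sizes >= large_threshold),
    frac_top3 = top3 / n_su,
    large_threshold = large_threshold,
    p_le = p_le,
    subunits_per_complex = subunits_per_complex
  ), class = "cluster_stats")
}

#' @export
print.cluster_stats <- function(x, ...) {
  cat(sprintf(
    paste0("<cluster_stats> %d clusters, %d subunits\n",
           "  mean size: %.1f SU (measured), %.1f SU (corrected, p_LE = %.2f), %.1f RyR2\n",
           "  large (>= %d SU): %.1f%% of clusters, holding %.1f%% of subunits\n"),
    x$n_clusters, x$n_subunits, x$mean_su, x$mean_su_corrected, x$p_le,
    x$mean_ryr2, x$large_threshold, 100 * x$frac_large_clusters,
    100 * x$frac_in_large))
  invisible(x)
}

#' Convert subunit counts to RyR2 counts
#'
#' Pure arithmetic behind the reported cluster sizes: a raw subunit count is
#' divided by the labeling efficiency and by the number of tag sites per
#' tetramer; a count that is already per-RyR2 is only divided by the
#' efficiency. Rounding to one decimal (half away from zero) is applied at
#' report time only, via [report_round()].
#'
#' @param x Mean subunits per cluster (`input = "su"`) or mean RyR2s per
#'   cluster (`input = "ryr2"`).
#' @param p_le Effective labeling efficiency in `(0, 1]`.
#' @param input Whether `x` is a subunit or an RyR2 count.
#' @param subunits_per_complex Tag sites per complex (default 4).
#' @return RyR2s per cluster (unrounded).
#' @examples
#' su_to_ryr2(58.8, p_le = 1)            # 14.7
#' report_round(su_to_ryr2(16.5, p_le = 1))   # 4.1
#' su_to_ryr2(4.1, p_le = 0.5, input = "ryr2")  # 8.2
#' @export
su_to_ryr2 <- function(x, p_le = 1, input = c("su", "ryr2"),
                       subunits_per_complex = 4) {
  input <- match.arg(input)
  if (p_le <= 0 || p_le > 1) abort("`p_le` must be in (0, 1]")
  if (input == "su") x / p_le / subunits_per_complex else x / p_le
}
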