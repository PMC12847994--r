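# Reading/writing localization tables and the two-level reduction of raw
# MINFLUX localizations: per-trace combination into docking-strand sites,
# then spatial merging of sites that reappear into unique subunit locations.

#' Read a localization table
#'
#' Reads a delimited table of raw MINFLUX localizations with mandatory
#' columns `tid, x, y, z` (trace ID and 3D position in nm) and an optional
#' `t` column (seconds). Any further columns are preserved untouched.
#'
#' @param path Path to the file.
#' @param dialect `"auto"` (by extension), `"csv"` or `"tsv"`.
#' @return A tibble with at least columns `tid, x, y, z`.
#' @export
read_localizations <- function(path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (dialect == "auto") {
    dialect <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  reader <- if (dialect == "tsv") readr::read_tsv else readr::read_csv
  tbl <- suppressWarnings(
    reader(path, show_col_types = FALSE, progress = FALSE)
  )
  if (nrow(tbl) == 0) abort(sprintf("empty localization table: %s", path))
  validate_localizations(tbl)
}

validate_localizations <- function(tbl) {
  required <- c("tid", "x", "y", "z")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    abort(sprintf("localization table is missing mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  for (col in c("x", "y", "z")) {
    v <- tbl[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v))
      if (length(bad) > 0) {
        abort(sprintf("non-numeric coordinate in column `%s` at row %d", col, bad[1]))
      }
      tbl[[col]] <- parsed
    }
    if (any(!is.finite(tbl[[col]]))) {
      abort(sprintf("non-finite coordinate in column `%s` at row %d",
                    col, which(!is.finite(tbl[[col]]))[1]))
    }
  }
  if (!is.numeric(tbl$tid)) {
    parsed <- suppressWarnings(as.numeric(tbl$tid))
    if (any(is.na(parsed))) abort("column `tid` must be numeric")
    tbl$tid <- parsed
  }
  if (any(tbl$tid < 0)) abort("`tid` values must be >= 0")
  as_tibble(tbl)
}

#' Write a localization table
#'
#' @param table Tibble with columns `tid, x, y, z` (nm) and optionally `t`.
#' @param path Output path.
#' @param dialect `"auto"` (by extension), `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path, dialect = c("auto", "csv", "tsv")) {
  dialect <- match.arg(dialect)
  validate_localizations(table)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "csv"
  }
  if (dialect == "tsv") readr::write_tsv(table, path) else readr::write_csv(table, path)
  invisible(path)
}

#' Combine raw localizations into docking-strand sites
#'
#' Repeated raw localizations sharing a MINFLUX trace ID originate from one
#' DNA-PAINT imager bound to one docking strand; they are combined into a
#' single site at their per-axis arithmetic mean. The per-axis sample
#' standard deviation is recorded as the spread (0 for single-localization
#' traces).
#'
#' @param table Localization tibble (`tid, x, y, z`, see
#'   [read_localizations()]).
#' @param min_locs Minimum localizations per trace; shorter traces are
#'   dropped (default 1, i.e. no trace-length filter).
#' @return Site tibble `site_id, x, y, z, n_locs, n_traces, spread_x,
#'   spread_y, spread_z` with one row per retained trace (`n_traces` is 1 at
#'   this stage; it counts merged traces after [merge_subunits()]).
#' @export
combine_traces <- function(table, min_locs = 1) {
  table <- validate_localizations(table)
  if (nrow(table) == 0) abort("localization table is empty")
  sd0 <- function(v) if (length(v) < 2) 0 else sd(v)
  sites <- table |>
    dplyr::group_by(.data$tid) |>
    dplyr::summarise(
      n_locs = dplyr::n(),
      spread_x = sd0(.data$x), spread_y = sd0(.data$y), spread_z = sd0(.data$z),
      x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_locs >= min_locs) |>
    dplyr::arrange(.data$tid)
  tibble(
    site_id = seq_len(nrow(sites)), tid = sites$tid,
    x = sites$x, y = sites$y, z = sites$z,
    n_locs = as.integer(sites$n_locs), n_traces = 1L,
    spread_x = sites$spread_x, spread_y = sites$spread_y, spread_z = sites$spread_z
  )
}

#' Merge reappearing docking-strand sites into subunit locations
#'
#' A marker molecule that is visited by several imagers produces several
#' sites at (nearly) the same position. Sites are grouped by DBSCAN on their
#' 3D positions; with `min_pts = 1` (the default) this equals the connected
#' components of the eps-adjacency graph. Each group is collapsed to its
#' localization-count-weighted mean position.
#'
#' @param sites Site tibble from [combine_traces()].
#' @param eps Merge distance in nm (default 1).
#' @param min_pts DBSCAN minimum neighborhood size (default 1).
#' @return Subunit tibble `subunit_id, x, y, z, n_sites_merged, n_locs_total,
#'   n_traces`.
#' @export
merge_subunits <- function(sites, eps = 1, min_pts = 1) {
  if (eps <= 0) abort("`eps` must be > 0")
  if (nrow(sites) == 0) {
    return(tibble(subunit_id = integer(0), x = numeric(0), y = numeric(0),
                  z = numeric(0), n_sites_merged = integer(0),
                  n_locs_total = integer(0), n_traces = integer(0)))
  }
  xyz <- as_xyz(sites)
  labels <- dbscan_labels(xyz, eps = eps, min_pts = min_pts)
  keep <- labels > 0
  s <- sites[keep, , drop = FALSE]
  s$.cluster <- labels[keep]
  w_mean <- function(v, w) sum(v * w) / sum(w)
  n_traces_col <- s$n_traces %||% rep(1L, nrow(s))
  s$.n_traces <- n_traces_col
  out <- s |>
    dplyr::group_by(.data$.cluster) |>
    dplyr::summarise(
      x = w_mean(.data$x, .data$n_locs),
      y = w_mean(.data$y, .data$n_locs),
      z = w_mean(.data$z, .data$n_locs),
      n_sites_merged = dplyr::n(),
      n_locs_total = sum(.data$n_locs),
      n_traces = sum(.data$.n_traces),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$.cluster)
  tibble(subunit_id = seq_len(nrow(out)), x = out$x, y = out$y, z = out$z,
         n_sites_merged = as.integer(out$n_sites_merged),
         n_locs_total = as.integer(out$n_locs_total),
         n_traces = as.integer(out$n_traces))
}

#' Per-axis median localization precision
#'
#' Summarises trace-level precision as the median over traces (with at least
#' two localizations) of the per-axis sample standard deviation.
#'
#' @param table Localization tibble.
#' @return One-row tibble `median_sd_x, median_sd_y, median_sd_z, n_traces`
#'   (nm; `n_traces` counts traces entering the medians).
#' @export
precision_summary <- function(table) {
  table <- validate_localizations(table)
  counts <- table(table$tid)
  multi <- names(counts)[counts >= 2]
  if (length(multi) == 0) {
    abort("precision is undefined: no trace has >= 2 localizations")
  }
  sub <- table[as.character(table$tid) %in% multi, , drop = FALSE]
  per_trace <- sub |>
    dplyr::group_by(.data$tid) |>
    dplyr::summarise(sx = sd(.data$x), sy = sd(.data$y), sz = sd(.data$z),
                     .groups = "drop")
  tibble(
    median_sd_x = median(per_trace$sx),
    median_sd_y = median(per_trace$sy),
    median_sd_z = median(per_trace$sz),
    n_traces = nrow(per_trace)
  )
}
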