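# Simulated appearance of EM-derived cluster layouts under partial labeling,
# 2D Gaussian rendering, blob/puncta finding and nearest-neighbor group
# comparison.

#' Simulate how a cluster layout appears under MINFLUX with partial labeling
#'
#' Expands the layout to tag sites, retains each independently with
#' probability `p_su`, and adds independent per-axis Gaussian localization
#' error.
#'
#' @param layout A `cluster_layout` tibble (see [make_lattice_layout()]).
#' @param p_su Per-subunit retention probability (default 0.5).
#' @param sigma Localization error SD in nm (default 3).
#' @param seed Integer seed.
#' @return Tibble `site_id, complex_id, x, y, z` of simulated subunit
#'   positions (nm).
#' @export
simulate_cluster_appearance <- function(layout, p_su = 0.5, sigma = 3, seed = 1) {
  if (nrow(layout) == 0) abort("`layout` is empty")
  if (p_su < 0 || p_su > 1) abort("`p_su` must be in [0, 1]")
  if (sigma < 0) abort("`sigma` must be >= 0")
  withr::with_seed(seed, {
    sites <- expand_layout_to_tag_sites(layout)
    keep <- runif(nrow(sites)) < p_su
    sites <- sites[keep, , drop = FALSE]
    n <- nrow(sites)
    if (n > 0 && sigma > 0) {
      sites$x <- sites$x + rnorm(n, 0, sigma)
      sites$y <- sites$y + rnorm(n, 0, sigma)
      sites$z <- sites$z + rnorm(n, 0, sigma)
    }
    sites$site_id <- seq_len(nrow(sites))
    sites
  })
}

#' Render points into a 2D super-resolution intensity image
#'
#' Sum of unit-integral isotropic 2D Gaussians sampled on a pixel grid (the
#' per-pixel mass is the exact Gaussian integral over the pixel, renormalised
#' over the finite stamp window), so the image integral equals the point
#' count.
#'
#' @param points Tibble with `x, y` (z ignored) or a matrix; nm.
#' @param pixel_size Pixel size in nm (default 3).
#' @param gauss_sigma Rendering kernel SD in nm (default 4).
#' @param pad Margin around the data in nm (default `3 * gauss_sigma +
#'   2 * pixel_size`).
#' @return A `minflux_image`: numeric matrix (rows = y, columns = x) with
#'   attributes `pixel_size` and `origin` (nm position of the outer corner of
#'   pixel \[1,1\]).
#' @export
render_2d <- function(points, pixel_size = 3, gauss_sigma = 4, pad = NULL) {
  if (pixel_size <= 0 || gauss_sigma <= 0) abort("`pixel_size` and `gauss_sigma` must be > 0")
  xy <- if (is.matrix(points)) points[, 1:2, drop = FALSE] else as_xyz(points, ndim = 2)
  if (nrow(xy) == 0) abort("no points to render")
  pad <- pad %||% (3 * gauss_sigma + 2 * pixel_size)
  x0 <- min(xy[, 1]) - pad
  y0 <- min(xy[, 2]) - pad
  nx <- ceiling((max(xy[, 1]) + pad - x0) / pixel_size)
  ny <- ceiling((max(xy[, 2]) + pad - y0) / pixel_size)
  img <- matrix(0, nrow = ny, ncol = nx)
  half_w <- ceiling(4 * gauss_sigma / pixel_size)
  for (i in seq_len(nrow(xy))) {
    cx <- (xy[i, 1] - x0) / pixel_size  # pixel-space position
    cy <- (xy[i, 2] - y0) / pixel_size
    jx <- max(1, floor(cx) - half_w + 1):min(nx, floor(cx) + half_w + 1)
    jy <- max(1, floor(cy) - half_w + 1):min(ny, floor(cy) + half_w + 1)
    gx <- pnorm(jx, cx, gauss_sigma / pixel_size) - pnorm(jx - 1, cx, gauss_sigma / pixel_size)
    gy <- pnorm(jy, cy, gauss_sigma / pixel_size) - pnorm(jy - 1, cy, gauss_sigma / pixel_size)
    stamp <- outer(gy, gx)
    img[jy, jx] <- img[jy, jx] + stamp / sum(stamp)
  }
  structure(img, pixel_size = pixel_size, origin = c(x = x0, y = y0),
            class = c("minflux_image", "matrix", "array"))
}

#' Find puncta in a rendered image
#'
#' Blob finding on a rendered super-resolution image: Gaussian pre-blur
#' (SD `blur_size` pixels), thresholding at `threshold` robust background
#' standard deviations above the background level, connected-component
#' labeling, and intensity-weighted centroids in nm. The background SD is a
#' robust MAD estimate; on sparse synthetic renders, where most pixels are
#' exactly zero and the global MAD collapses, the MAD over the occupied
#' pixels provides the scale (with 5% of the blurred dynamic range as a
#' last resort).
#'
#' @param image A `minflux_image` from [render_2d()] (or a plain matrix with
#'   `pixel_size`/`origin` attributes).
#' @param threshold Threshold in background-SD units (default 1.0).
#' @param blur_size Pre-blur SD in pixels (default 2.0).
#' @return Tibble `punctum_id, x, y, n_pixels, intensity` (positions in nm);
#'   zero rows when nothing exceeds the threshold.
#' @export
find_puncta <- function(image, threshold = 1.0, blur_size = 2.0) {
  px <- attr(image, "pixel_size") %||% 1
  origin <- attr(image, "origin") %||% c(x = 0, y = 0)
  m <- unclass(image)
  attributes(m) <- list(dim = dim(m))
  empty <- tibble(punctum_id = integer(0), x = numeric(0), y = numeric(0),
                  n_pixels = integer(0), intensity = numeric(0))
  if (length(m) == 0 || max(m) <= 0) return(empty)
  blurred <- if (blur_size > 0) {
    # zero-pad so the Gaussian brush always fits and no intensity wraps
    # around the (circular) filter boundary, then crop back
    k <- 2 * ceiling(3 * blur_size) + 2
    padded <- matrix(0, nrow(m) + 2 * k, ncol(m) + 2 * k)
    padded[k + seq_len(nrow(m)), k + seq_len(ncol(m))] <- m
    EBImage::gblur(padded, sigma = blur_size)[k + seq_len(nrow(m)),
                                              k + seq_len(ncol(m))]
  } else {
    m
  }
  bg <- median(blurred)
  # robust noise scale: the global MAD collapses on sparse synthetic images
  # where most pixels are exactly zero, so the MAD over the occupied support
  # provides the floor; 5% of the dynamic range is the last resort
  support <- blurred > max(blurred) * 1e-6
  noise <- max(mad(blurred), mad(blurred[support]))
  if (noise <= 0) noise <- 0.05 * (max(blurred) - bg)
  cut <- bg + threshold * noise
  mask <- blurred > cut
  if (!any(mask)) return(empty)
  labels <- EBImage::bwlabel(mask)
  lab_vec <- as.integer(labels)
  keep <- lab_vec > 0
  w <- m[keep]
  # fall back to the blurred intensity as weight if the raw image is zero
  # over a component (possible for very diffuse blobs)
  wb <- blurred[keep]
  rowi <- ((seq_along(lab_vec) - 1) %% nrow(m) + 1)[keep]
  coli <- ((seq_along(lab_vec) - 1) %/% nrow(m) + 1)[keep]
  lab <- lab_vec[keep]
  agg <- tibble(lab = lab, row = rowi, col = coli, w = w, wb = wb) |>
    dplyr::group_by(.data$lab) |>
    dplyr::summarise(
      wsum = sum(.data$w),
      x_px = if (sum(.data$w) > 0) sum(.data$col * .data$w) / sum(.data$w)
             else sum(.data$col * .data$wb) / sum(.data$wb),
      y_px = if (sum(.data$w) > 0) sum(.data$row * .data$w) / sum(.data$w)
             else sum(.data$row * .data$wb) / sum(.data$wb),
      n_pixels = dplyr::n(), .groups = "drop")
  tibble(
    punctum_id = seq_len(nrow(agg)),
    x = origin[["x"]] + (agg$x_px - 0.5) * px,
    y = origin[["y"]] + (agg$y_px - 0.5) * px,
    n_pixels = as.integer(agg$n_pixels),
    intensity = agg$wsum
  )
}

#' Nearest-neighbor distances of 2D points
#'
#' Euclidean distance from each point to its nearest other point.
#'
#' @param points Tibble with `x, y` or an n x 2 matrix (n >= 2).
#' @return Numeric vector of nearest-neighbor distances, one per point.
#' @export
nn_distances <- function(points) {
  xy <- if (is.matrix(points)) points[, 1:2, drop = FALSE] else as_xyz(points, ndim = 2)
  n <- nrow(xy)
  if (n < 2) abort("at least 2 points are required for nearest-neighbor distances")
  d <- as.matrix(dist(xy))
  diag(d) <- Inf
  unname(apply(d, 1, min))
}

#' Compare nearest-neighbor distance groups (one-way ANOVA + Tukey HSD)
#'
#' Standard one-way ANOVA across the groups followed by Tukey's Honestly
#' Significant Difference test over all group pairs.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each with >= 2
#'   values), or a data frame with columns `distance` and `group`.
#' @return An `nn_comparison` list: `anova_F`, `anova_p`, `tukey` tibble
#'   (`pair, diff, lwr, upr, p_adj`), `group_medians`, `n_per_group`.
#'   Supports [tidy()] and [glance()].
#' @export
compare_nn_groups <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("distance", "group") %in% names(groups)))
    df <- tibble(distance = groups$distance, group = as.factor(groups$group))
  } else {
    if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
    df <- tibble(distance = unlist(groups, use.names = FALSE),
                 group = factor(rep(names(groups), lengths(groups)),
                                levels = names(groups)))
  }
  if (nlevels(df$group) < 2) abort("at least 2 groups are required")
  if (any(table(df$group) < 2)) abort("each group needs at least 2 values")
  fit <- aov(distance ~ group, data = df)
  s <- summary(fit)[[1]]
  F_val <- s[["F value"]][1]
  p_val <- s[["Pr(>F)"]][1]
  if (!is.finite(F_val)) abort("ANOVA F is undefined (zero within-group variance)")
  tk <- TukeyHSD(fit)$group
  tukey <- tibble(pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
                  upr = tk[, "upr"], p_adj = tk[, "p adj"])
  med <- tapply(df$distance, df$group, median)
  structure(list(
    anova_F = F_val, anova_p = p_val, tukey = tukey,
    group_medians = tibble(group = names(med), median = as.numeric(med)),
    n_per_group = as.integer(table(df$group))
  ), class = "nn_comparison")
}

#' @export
print.nn_comparison <- function(x, ...) {
  cat(sprintf("<nn_comparison> one-way ANOVA F = %.2f, p = %.3g; %d pairwise Tukey HSD comparisons\n",
              x$anova_F, x$anova_p, nrow(x$tukey)))
  invisible(x)
}

#' Rendered-image puncta nearest-neighbor pipeline
#'
#' Convenience wrapper: render 2D, find puncta, return their
#' nearest-neighbor distances. Used to compare MINFLUX-resolution rendering
#' (3 nm pixels, 4 nm kernel) against widefield-like rendering (5 nm pixels,
#' ~10 nm kernel) of the same simulated subunit positions.
#'
#' @param points Subunit positions (tibble with `x, y`).
#' @param pixel_size,gauss_sigma Rendering parameters, see [render_2d()].
#' @param threshold,blur_size Blob-finding parameters, see [find_puncta()].
#' @return List with `puncta` (tibble), `nn` (numeric vector), `median_nn`,
#'   and `render_params`.
#' @export
puncta_nn_pipeline <- function(points, pixel_size = 3, gauss_sigma = 4,
                               threshold = 1.0, blur_size = 2.0) {
  img <- render_2d(points, pixel_size = pixel_size, gauss_sigma = gauss_sigma)
  puncta <- find_puncta(img, threshold = threshold, blur_size = blur_size)
  if (nrow(puncta) < 2) abort("fewer than 2 puncta found; cannot compute distances")
  nn <- nn_distances(puncta)
  list(puncta = puncta, nn = nn, median_nn = median(nn),
       render_params = list(pixel_size = pixel_size, gauss_sigma = gauss_sigma,
                            threshold = threshold, blur_size = blur_size))
}
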