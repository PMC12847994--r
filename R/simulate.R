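# Seeded generators of ground-truth structures (nuclear-pore fields, tetramer
# layouts) and the raw MINFLUX localization tables an acquisition of them
# would produce.

#' Localization noise model
#'
#' Describes the per-localization error of the simulated acquisition: an
#' isotropic (or per-axis) Gaussian displacement plus an optional uniform
#' background component standing in for spurious localizations.
#'
#' @param sigma Per-axis localization standard deviation in nm; a scalar is
#'   recycled to all three axes. MINFLUX DNA-PAINT traces reach ~2 nm median
#'   per-axis precision, so 2-3 nm is the realistic range.
#' @param outlier_fraction Proportion of localizations in `[0, 1]` replaced by
#'   draws from a broad uniform background over the simulated field.
#' @return A `noise_model` list.
#' @export
noise_model <- function(sigma = c(2, 2, 2), outlier_fraction = 0) {
  if (length(sigma) == 1) sigma <- rep(sigma, 3)
  stopifnot(length(sigma) == 3)
  if (any(sigma < 0) || !all(is.finite(sigma))) {
    abort("`sigma` components must be finite and >= 0")
  }
  if (outlier_fraction < 0 || outlier_fraction > 1) {
    abort("`outlier_fraction` must be in [0, 1]")
  }
  structure(list(sigma = as.numeric(sigma), outlier_fraction = outlier_fraction),
            class = "noise_model")
}

#' Site-visit model
#'
#' Number of distinct binding events (trace IDs) per detected site and raw
#' localizations per visit. Conditional on a site being detected at all, the
#' visit count is either fixed or zero-truncated Poisson with the stated
#' conditional mean; the default mean of 1.18 matches the site-visit counts
#' observed for Nup96 calibration data.
#'
#' @param law `"zero-truncated-poisson"` or `"fixed"`.
#' @param mean_visits Conditional mean number of visits per detected site
#'   (>= 1). Under `"fixed"` it is rounded to the nearest integer.
#' @param locs_per_visit Expected raw localizations per visit (>= 1); each
#'   visit yields `1 + Poisson(locs_per_visit - 1)` localizations.
#' @return A `visit_model` list.
#' @export
visit_model <- function(law = c("zero-truncated-poisson", "fixed"),
                        mean_visits = 1.18, locs_per_visit = 1) {
  law <- match.arg(law)
  if (mean_visits < 1) abort("`mean_visits` must be >= 1")
  if (locs_per_visit < 1) abort("`locs_per_visit` must be >= 1")
  structure(list(law = law, mean_visits = mean_visits,
                 locs_per_visit = locs_per_visit),
            class = "visit_model")
}

#' Nuclear-pore field simulation configuration
#'
#' Geometry, labeling and acquisition parameters for a synthetic field of
#' Nup96-style nuclear pore complexes. Each pore carries two rings of
#' `n_segments_per_ring` segments with `sites_per_segment` tag sites per
#' segment (32 sites under the defaults), a random 3D pose with bounded tilt,
#' and independent per-site labeling with probability `p_le`.
#'
#' @param n_npcs Number of pores in the field.
#' @param ring_diameter Ring diameter in nm (default 107, the established
#'   Nup96 ring geometry).
#' @param ring_spacing Axial distance between the cytoplasmic and
#'   nucleoplasmic rings in nm (default 50).
#' @param n_segments_per_ring Segments per ring (default 8).
#' @param sites_per_segment Tag sites per segment (default 2).
#' @param twist_deg Angular offset between the two rings in degrees.
#' @param site_angle_offset_deg Total angular separation (degrees, in-ring)
#'   between the sites of one segment; with the default 9 degrees the two
#'   sites of a segment sit ~8 nm apart, well clear of the ~41 nm
#'   inter-segment chord.
#' @param p_le Effective per-site labeling probability in `[0, 1]`.
#' @param max_tilt_deg Upper bound of the pose tilt from the optical axis;
#'   tilt is uniform on `[0, max_tilt_deg]`, azimuth and spin uniform.
#' @param npc_pitch Center-to-center pitch (nm) of the jittered grid on which
#'   pores are placed; keeps neighboring pores resolvable by the candidate
#'   detector.
#' @param noise A [noise_model()].
#' @param visits A [visit_model()].
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration and seed.
#' @return An `npc_sim_config` list.
#' @export
npc_sim_config <- function(n_npcs,
                           ring_diameter = 107,
                           ring_spacing = 50,
                           n_segments_per_ring = 8,
                           sites_per_segment = 2,
                           twist_deg = 0,
                           site_angle_offset_deg = 9,
                           p_le = 0.6,
                           max_tilt_deg = 30,
                           npc_pitch = 300,
                           noise = noise_model(),
                           visits = visit_model(),
                           seed = 1) {
  if (n_npcs < 1) abort("`n_npcs` must be >= 1")
  if (p_le < 0 || p_le > 1) abort("`p_le` must be in [0, 1]")
  if (ring_diameter <= 0 || ring_spacing <= 0 || npc_pitch <= 0) {
    abort("geometry parameters must be positive")
  }
  if (n_segments_per_ring < 1 || sites_per_segment < 1) {
    abort("segment/site counts must be >= 1")
  }
  stopifnot(inherits(noise, "noise_model"), inherits(visits, "visit_model"))
  structure(list(
    n_npcs = as.integer(n_npcs), ring_diameter = ring_diameter,
    ring_spacing = ring_spacing,
    n_segments_per_ring = as.integer(n_segments_per_ring),
    sites_per_segment = as.integer(sites_per_segment),
    twist_deg = twist_deg, site_angle_offset_deg = site_angle_offset_deg,
    p_le = p_le, max_tilt_deg = max_tilt_deg, npc_pitch = npc_pitch,
    noise = noise, visits = visits, seed = as.integer(seed)
  ), class = "npc_sim_config")
}

# Tag sites of one pore in its template frame (z = symmetry axis, origin at
# the pore center). Returns a tibble with segment bookkeeping.
npc_template_sites <- function(config) {
  nseg <- config$n_segments_per_ring
  s <- config$sites_per_segment
  r <- config$ring_diameter / 2
  half <- config$ring_spacing / 2
  site_offsets <- if (s == 1) 0 else
    seq(-0.5, 0.5, length.out = s) * config$site_angle_offset_deg
  rings <- tibble(ring = c("cytoplasmic", "nucleoplasmic"),
                  z = c(half, -half),
                  twist = c(0, config$twist_deg))
  out <- tidyr::expand_grid(rings, seg = seq_len(nseg), site = seq_len(s))
  ang <- ((out$seg - 1) * 360 / nseg + out$twist + site_offsets[out$site]) * pi / 180
  out$segment <- (match(out$ring, rings$ring) - 1L) * nseg + out$seg
  tibble(
    segment = out$segment, ring = out$ring, site_in_segment = out$site,
    x = r * cos(ang), y = r * sin(ang), z = out$z
  )
}

# Expand labeled ground-truth sites into a raw localization table: each
# labeled site gets >= 1 visits (distinct TIDs), each visit >= 1 noisy
# localizations. `field_box` is a 3x2 matrix of ranges for outlier draws.
expand_sites_to_localizations <- function(sites, noise, visits, field_box) {
  labeled <- sites[sites$labeled, , drop = FALSE]
  n_lab <- nrow(labeled)
  if (n_lab == 0) {
    return(list(
      localizations = tibble(tid = integer(0), x = numeric(0), y = numeric(0),
                             z = numeric(0), site_id = integer(0)),
      visits = tibble(tid = integer(0), site_id = integer(0), n_locs = integer(0))
    ))
  }
  nv <- switch(visits$law,
    "zero-truncated-poisson" = rztpois(n_lab, ztpois_rate(visits$mean_visits)),
    "fixed" = rep(max(1L, as.integer(round(visits$mean_visits))), n_lab)
  )
  visit_site <- rep(labeled$site_id, nv)
  n_visits <- length(visit_site)
  tid <- seq_len(n_visits)
  nl <- 1L + rpois(n_visits, visits$locs_per_visit - 1)
  loc_site <- rep(visit_site, nl)
  loc_tid <- rep(tid, nl)
  n_locs <- length(loc_tid)
  pos <- as.matrix(sites[match(loc_site, sites$site_id), c("x", "y", "z")])
  err <- matrix(rnorm(3 * n_locs), ncol = 3) %*% diag(noise$sigma)
  pos <- pos + err
  if (noise$outlier_fraction > 0) {
    is_out <- runif(n_locs) < noise$outlier_fraction
    n_out <- sum(is_out)
    if (n_out > 0) {
      pos[is_out, ] <- cbind(runif(n_out, field_box[1, 1], field_box[1, 2]),
                             runif(n_out, field_box[2, 1], field_box[2, 2]),
                             runif(n_out, field_box[3, 1], field_box[3, 2]))
    }
  }
  list(
    localizations = tibble(tid = loc_tid, x = pos[, 1], y = pos[, 2],
                           z = pos[, 3], site_id = loc_site),
    visits = tibble(tid = tid, site_id = visit_site, n_locs = as.integer(nl))
  )
}

#' Simulate a field of nuclear pore complexes under MINFLUX acquisition
#'
#' Draws a random 3D pose for each pore (azimuth and spin uniform, tilt
#' uniform up to `max_tilt_deg`), places its tag sites, labels each site
#' independently with probability `p_le`, and expands every labeled site into
#' one or more DNA-PAINT binding events (distinct trace IDs) with noisy raw
#' localizations. Coordinates are nm in a right-handed frame with z up.
#'
#' @param config An [npc_sim_config()].
#' @return A `minflux_sim` list with elements
#'   \describe{
#'     \item{localizations}{tibble `tid, x, y, z, site_id` (the `site_id`
#'       column is the ground-truth provenance of each trace; real data will
#'       not carry it).}
#'     \item{sites}{ground-truth tag sites with `site_id, complex_id, segment,
#'       ring, x, y, z, labeled`.}
#'     \item{complexes}{per-pore centers, axes and spin angles.}
#'     \item{visits}{tid-to-site map with localization counts per visit.}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' sim <- make_npc_ensemble(npc_sim_config(n_npcs = 4, seed = 7))
#' nrow(sim$sites)   # 4 pores x 32 sites
#' @export
make_npc_ensemble <- function(config) {
  stopifnot(inherits(config, "npc_sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_npcs
    ncols <- ceiling(sqrt(n))
    grid_i <- (seq_len(n) - 1) %% ncols
    grid_j <- (seq_len(n) - 1) %/% ncols
    pitch <- config$npc_pitch
    centers <- cbind(
      x = grid_i * pitch + runif(n, -0.13, 0.13) * pitch,
      y = grid_j * pitch + runif(n, -0.13, 0.13) * pitch,
      z = runif(n, -50, 50)
    )
    azim <- runif(n, 0, 2 * pi)
    tilt <- runif(n, 0, config$max_tilt_deg * pi / 180)
    spin <- runif(n, 0, 2 * pi)
    template <- npc_template_sites(config)
    tmpl_xyz <- as.matrix(template[, c("x", "y", "z")])
    site_list <- vector("list", n)
    for (i in seq_len(n)) {
      axis <- c(sin(tilt[i]) * cos(azim[i]), sin(tilt[i]) * sin(azim[i]), cos(tilt[i]))
      R <- rotation_align_z(axis) %*% rotation_z(spin[i])
      world <- tmpl_xyz %*% t(R)
      site_list[[i]] <- tibble(
        complex_id = i, segment = template$segment, ring = template$ring,
        site_in_segment = template$site_in_segment,
        x = world[, 1] + centers[i, 1],
        y = world[, 2] + centers[i, 2],
        z = world[, 3] + centers[i, 3]
      )
    }
    sites <- dplyr::bind_rows(site_list)
    sites$site_id <- seq_len(nrow(sites))
    sites$labeled <- runif(nrow(sites)) < config$p_le
    sites <- dplyr::relocate(sites, "site_id")
    complexes <- tibble(
      complex_id = seq_len(n), x = centers[, 1], y = centers[, 2], z = centers[, 3],
      axis_x = sin(tilt) * cos(azim), axis_y = sin(tilt) * sin(azim),
      axis_z = cos(tilt), spin_deg = spin * 180 / pi, tilt_deg = tilt * 180 / pi
    )
    field_box <- rbind(range(sites$x) + c(-50, 50),
                       range(sites$y) + c(-50, 50),
                       range(sites$z) + c(-50, 50))
    expanded <- expand_sites_to_localizations(sites, config$noise, config$visits,
                                              field_box)
    structure(list(localizations = expanded$localizations, sites = sites,
                   complexes = complexes, visits = expanded$visits,
                   config = config),
              class = "minflux_sim")
  })
}

#' @export
print.minflux_sim <- function(x, ...) {
  cat(sprintf(
    "<minflux_sim> %d complexes, %d ground-truth sites (%d labeled), %d localizations in %d traces\n",
    nrow(x$complexes), nrow(x$sites), sum(x$sites$labeled),
    nrow(x$localizations), nrow(x$visits)))
  invisible(x)
}

#' Square-lattice tetramer layout
#'
#' Places tetramer centers on a planar square lattice and retains each with
#' probability `occupancy`; a seeded stand-in for cluster layouts traced from
#' EM tomography. The default pitch of 30 nm reflects close packing of the
#' ~27 nm RyR2 footprint.
#'
#' @param n_rows,n_cols Lattice dimensions (both >= 1).
#' @param pitch Lattice pitch in nm (> 0).
#' @param occupancy Retention probability in `(0, 1]`.
#' @param tag_kind `"GFP16"` (16 nm tag square, rotated 45 degrees to the
#'   tetramer outline) or `"RFP20"` (20 nm tag square, corner-aligned).
#' @param seed Integer seed.
#' @return A `cluster_layout` tibble with columns `tetramer_id, x, y, z,
#'   angle_deg, tag_kind`.
#' @examples
#' make_lattice_layout(2, 2, pitch = 30, occupancy = 1, tag_kind = "GFP16")
#' @export
make_lattice_layout <- function(n_rows, n_cols, pitch = 30, occupancy = 1,
                                tag_kind = c("RFP20", "GFP16"), seed = 1) {
  tag_kind <- match.arg(tag_kind)
  if (n_rows < 1 || n_cols < 1) abort("lattice must have at least one row and one column")
  if (pitch <= 0) abort("`pitch` must be > 0")
  if (occupancy <= 0 || occupancy > 1) abort("`occupancy` must be in (0, 1]")
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(row = seq_len(n_rows), col = seq_len(n_cols))
    keep <- runif(nrow(grid)) < occupancy
    grid <- grid[keep, , drop = FALSE]
    out <- tibble(
      tetramer_id = seq_len(nrow(grid)),
      x = (grid$col - 1) * pitch,
      y = (grid$row - 1) * pitch,
      z = 0,
      angle_deg = 0,
      tag_kind = tag_kind
    )
    class(out) <- c("cluster_layout", class(out))
    out
  })
}

#' Read a cluster layout from CSV
#'
#' Reads a tetramer layout table with columns `tetramer_id, x, y, z,
#' angle_deg, tag_kind` (nm / degrees), the on-disk form of the layouts
#' produced by [make_lattice_layout()]. Two small synthetic example layouts
#' ship with the package under `inst/extdata/` (a square lattice and an
#' irregular cluster; both are synthetic stand-ins, not traced from
#' experimental data).
#'
#' @param path Path to a layout CSV.
#' @return A `cluster_layout` tibble.
#' @examples
#' lay <- read_cluster_layout(system.file("extdata",
#'   "synthetic_lattice_layout.csv", package = "minfluxr"))
#' @export
read_cluster_layout <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("tetramer_id", "x", "y", "z", "angle_deg", "tag_kind")
  missing_cols <- setdiff(needed, names(tbl))
  if (length(missing_cols) > 0) {
    abort(sprintf("layout is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(round(tbl[, c("x", "y", "z")], 6))) {
    abort("tetramer centers must be pairwise distinct")
  }
  out <- as_tibble(tbl[needed])
  class(out) <- c("cluster_layout", class(out))
  out
}

#' Expand a tetramer layout to its tag binding sites
#'
#' Each tetramer contributes the 4 corners of its tag square: side 16 nm at
#' 45 degrees to the tetramer outline for GFP-tagged subunits, side 20 nm
#' aligned with the outline corners for TagRFP-tagged subunits. Corners are
#' rotated by the per-tetramer in-plane angle (and the plane normal given by
#' optional `nx, ny, nz` columns) and translated to the tetramer center.
#'
#' @param layout A `cluster_layout` tibble (see [make_lattice_layout()]).
#' @return Tibble `site_id, complex_id, x, y, z` of tag-site positions (nm).
#' @examples
#' lay <- make_lattice_layout(1, 1, tag_kind = "GFP16")
#' sites <- expand_layout_to_tag_sites(lay)
#' sqrt(sites$x^2 + sites$y^2)  # 16/sqrt(2) = 11.31 nm from center
#' @export
expand_layout_to_tag_sites <- function(layout) {
  if (nrow(layout) == 0) {
    return(tibble(site_id = integer(0), complex_id = integer(0),
                  x = numeric(0), y = numeric(0), z = numeric(0)))
  }
  if (!all(c("x", "y", "z", "angle_deg", "tag_kind") %in% names(layout))) {
    abort("`layout` must have columns x, y, z, angle_deg, tag_kind")
  }
  out <- vector("list", nrow(layout))
  has_normal <- all(c("nx", "ny", "nz") %in% names(layout))
  for (i in seq_len(nrow(layout))) {
    tmpl <- tag_template(layout$tag_kind[i])
    corners <- tmpl$corners %*% t(rotation_z(layout$angle_deg[i] * pi / 180))
    if (has_normal) {
      corners <- corners %*% t(rotation_align_z(
        c(layout$nx[i], layout$ny[i], layout$nz[i])))
    }
    out[[i]] <- tibble(
      complex_id = layout$tetramer_id[i],
      x = corners[, 1] + layout$x[i],
      y = corners[, 2] + layout$y[i],
      z = corners[, 3] + layout$z[i]
    )
  }
  res <- dplyr::bind_rows(out)
  res$site_id <- seq_len(nrow(res))
  dplyr::relocate(res, "site_id")
}

#' Simulate MINFLUX acquisition of a tetramer layout
#'
#' Expands the layout to tag sites, retains each site independently with
#' probability `p_su`, and expands retained sites into visits and noisy
#' localizations exactly as [make_npc_ensemble()] does.
#'
#' @param layout A `cluster_layout` tibble.
#' @param p_su Per-subunit retention (labeling + detection) probability.
#' @param noise A [noise_model()].
#' @param visits A [visit_model()].
#' @param seed Integer seed.
#' @return A `minflux_sim` list (see [make_npc_ensemble()]); `sites` carries
#'   `complex_id` = tetramer id.
#' @export
make_tetramer_field <- function(layout, p_su = 0.5, noise = noise_model(3),
                                visits = visit_model(), seed = 1) {
  if (nrow(layout) == 0) abort("`layout` is empty")
  if (p_su < 0 || p_su > 1) abort("`p_su` must be in [0, 1]")
  withr::with_seed(seed, {
    sites <- expand_layout_to_tag_sites(layout)
    sites$labeled <- runif(nrow(sites)) < p_su
    field_box <- rbind(range(sites$x) + c(-50, 50),
                       range(sites$y) + c(-50, 50),
                       range(sites$z) + c(-50, 50))
    expanded <- expand_sites_to_localizations(sites, noise, visits, field_box)
    structure(list(localizations = expanded$localizations, sites = sites,
                   complexes = tibble(complex_id = layout$tetramer_id,
                                      x = layout$x, y = layout$y, z = layout$z,
                                      angle_deg = layout$angle_deg),
                   visits = expanded$visits,
                   config = list(p_su = p_su, noise = noise, visits = visits,
                                 seed = seed)),
              class = "minflux_sim")
  })
}
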