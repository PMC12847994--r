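# Internal geometry, clustering and counting-distribution primitives.

`%||%` <- rlang::`%||%`

# Coerce a points argument (tibble/data.frame with x,y,z or a numeric matrix)
# to an n x 3 numeric matrix.
as_xyz <- function(points, ndim = 3) {
  if (is.matrix(points)) {
    m <- points
  } else if (is.data.frame(points)) {
    cols <- c("x", "y", "z")[seq_len(ndim)]
    missing_cols <- setdiff(cols, names(points))
    if (length(missing_cols) > 0) {
      abort(sprintf("`points` is missing coordinate column(s): %s",
                    paste(missing_cols, collapse = ", ")))
    }
    m <- as.matrix(points[cols])
  } else {
    abort("`points` must be a data frame with x/y/z columns or a numeric matrix")
  }
  storage.mode(m) <- "double"
  if (ncol(m) != ndim) abort(sprintf("`points` must have %d coordinate columns", ndim))
  if (!all(is.finite(m))) abort("coordinates must be finite")
  m
}

# Neighbor lists within `eps` (inclusive), self included.
# Dense dist matrix for small n, cell-grid lookup for large n.
eps_neighbor_list <- function(xyz, eps) {
  n <- nrow(xyz)
  if (n == 0) return(list())
  if (n <= 2500) {
    d <- as.matrix(dist(xyz))
    return(lapply(seq_len(n), function(i) which(d[i, ] <= eps)))
  }
  cell <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / eps)
  key <- function(cx, cy, cz) paste(cx, cy, cz, sep = "_")
  buckets <- split(seq_len(n), key(cell[, 1], cell[, 2], cell[, 3]))
  idx <- new.env(parent = emptyenv())
  for (k in names(buckets)) assign(k, buckets[[k]], envir = idx)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  eps2 <- eps^2
  lapply(seq_len(n), function(i) {
    cand <- integer(0)
    for (r in seq_len(nrow(offs))) {
      k <- key(cell[i, 1] + offs[r, 1], cell[i, 2] + offs[r, 2], cell[i, 3] + offs[r, 3])
      if (exists(k, envir = idx, inherits = FALSE)) {
        cand <- c(cand, get(k, envir = idx, inherits = FALSE))
      }
    }
    d2 <- (xyz[cand, 1] - xyz[i, 1])^2 + (xyz[cand, 2] - xyz[i, 2])^2 +
      (xyz[cand, 3] - xyz[i, 3])^2
    cand[d2 <= eps2]
  })
}

# Classic DBSCAN. Returns integer labels 1..k; 0 marks noise (never produced
# when min_pts = 1, where the result equals the connected components of the
# eps-adjacency graph).
dbscan_labels <- function(xyz, eps, min_pts = 1) {
  stopifnot(eps > 0, min_pts >= 1)
  n <- nrow(xyz)
  if (n == 0) return(integer(0))
  nb <- eps_neighbor_list(xyz, eps)
  core <- lengths(nb) >= min_pts
  labels <- integer(n)
  cl <- 0L
  queue <- integer(n)
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue[1] <- i
    head_ptr <- 1L
    tail_ptr <- 1L
    while (head_ptr <= tail_ptr) {
      j <- queue[head_ptr]
      head_ptr <- head_ptr + 1L
      for (k in nb[[j]]) {
        if (labels[k] == 0L) {
          labels[k] <- cl
          if (core[k]) {
            tail_ptr <- tail_ptr + 1L
            queue[tail_ptr] <- k
          }
        }
      }
    }
  }
  labels
}

## ---- rotations ------------------------------------------------------------

rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s_ <- sin(angle)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * c_ + s_ * K + (1 - c_) * tcrossprod(u)
}

rotation_z <- function(angle) rotation_about_axis(c(0, 0, 1), angle)

# Rotation carrying the +z unit vector onto `axis` (minimal-angle rotation).
rotation_align_z <- function(axis) {
  a <- axis / sqrt(sum(axis^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * a[3] - z[3] * a[2], z[3] * a[1] - z[1] * a[3], z[1] * a[2] - z[2] * a[1])
  s <- sqrt(sum(v^2))
  c_ <- sum(z * a)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # 180 degrees about x
  }
  rotation_about_axis(v / s, atan2(s, c_))
}

# Angle (radians) of the rotation R.
rotation_angle <- function(R) {
  tr <- sum(diag(R))
  acos(pmin(1, pmax(-1, (tr - 1) / 2)))
}

# Least-squares proper rotation R with R %*% p_i ~ q_i (points pre-centered).
kabsch_rotation <- function(P, Q) {
  H <- crossprod(P, Q)           # sum p q^T
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
}

#' Angular distance between two rotations, modulo a template symmetry
#'
#' Computes the rotation angle of `R1 %*% t(R2)`, minimised over the
#' symmetry rotations of the template: the `symmetry_fold` rotations about
#' its symmetry axis and, with `include_flips = TRUE`, also the in-plane
#' two-fold axes. A flat square of indistinguishable corners is invariant
#' under the full proper dihedral group (4 rotations about the normal plus 4
#' flips), so tetramer orientation errors should be computed with
#' `include_flips = TRUE`; without contextual information the flip is not
#' recoverable from corner positions alone.
#'
#' @param R1,R2 3x3 proper rotation matrices.
#' @param symmetry_fold Order of the cyclic symmetry group about `axis`
#'   (4 for a square, 1 for no symmetry reduction).
#' @param axis Symmetry axis in the template frame (default +z).
#' @param include_flips Also minimise over the in-plane two-fold axes of the
#'   dihedral group (default FALSE).
#' @return Angle in degrees.
#' @export
rotation_angle_between <- function(R1, R2, symmetry_fold = 1, axis = c(0, 0, 1),
                                   include_flips = FALSE) {
  stopifnot(symmetry_fold >= 1)
  syms <- lapply(seq_len(symmetry_fold) - 1L, function(k)
    rotation_about_axis(axis, 2 * pi * k / symmetry_fold))
  if (include_flips) {
    # in-plane C2 axes interleaved at half the sector angle
    u0 <- if (abs(axis[3]) < 0.9) {
      v <- c(axis[2], -axis[1], 0)
      v / sqrt(sum(v^2))
    } else {
      c(1, 0, 0)
    }
    flips <- lapply(seq_len(symmetry_fold) - 1L, function(k) {
      u <- as.numeric(rotation_about_axis(axis, pi * k / symmetry_fold) %*% u0)
      rotation_about_axis(u, pi)
    })
    syms <- c(syms, flips)
  }
  angles <- vapply(syms, function(S) rotation_angle(R1 %*% S %*% t(R2)),
                   numeric(1))
  min(angles) * 180 / pi
}

rotation_to_quaternion <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s, (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1
    k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

## ---- zero-truncated Poisson ----------------------------------------------

# Rate lambda such that the zero-truncated Poisson mean lambda/(1-exp(-lambda))
# equals `m` (m >= 1; m = 1 corresponds to the degenerate point mass at 1).
ztpois_rate <- function(m) {
  stopifnot(m >= 1)
  if (m < 1 + 1e-12) return(0)
  uniroot(function(l) l / (1 - exp(-l)) - m, c(1e-10, 4 * m + 10), tol = 1e-12)$root
}

rztpois <- function(n, lambda) {
  if (n == 0) return(integer(0))
  if (lambda <= 0) return(rep(1L, n))
  as.integer(qpois(runif(n, exp(-lambda), 1), lambda))
}

# Half-away-from-zero rounding used for reported values (avoids the
# round-half-even drift of base round()).
#' Round half away from zero
#'
#' Report-time rounding used for printed summary numbers (e.g. converted
#' RyR2-per-cluster counts), so that ties round away from zero rather than to
#' the nearest even digit.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
report_round <- function(x, digits = 1) {
  pow <- 10^digits
  sign(x) * floor(abs(x) * pow + 0.5) / pow
}
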