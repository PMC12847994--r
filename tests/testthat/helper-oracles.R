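# Independent brute-force oracles used across the suite.

# Connected components of the eps-adjacency graph by O(n^2) union-find.
brute_force_components <- function(xyz, eps) {
  n <- nrow(xyz)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= eps) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Normalise a partition labeling so two labelings can be compared directly.
canonical_partition <- function(labels) {
  match(labels, unique(labels))
}

# O(n^2) nearest-neighbor distances.
brute_force_nn <- function(xy) {
  n <- nrow(xy)
  vapply(seq_len(n), function(i) {
    min(sqrt(rowSums((xy[-i, , drop = FALSE] -
                        matrix(xy[i, ], n - 1, 2, byrow = TRUE))^2)))
  }, numeric(1))
}

# Exhaustive-grid rotation search oracle for the tetramer fit: best RMSD over
# a fine grid of rotations (axis-angle sampling) and all corner assignments.
grid_search_tetramer_rmsd <- function(points, corners, n_axis = 60, n_angle = 36) {
  best <- Inf
  set.seed(99)
  axes <- matrix(rnorm(n_axis * 3), ncol = 3)
  axes <- axes / sqrt(rowSums(axes^2))
  angles <- seq(0, 2 * pi, length.out = n_angle + 1)[-(n_angle + 1)]
  perms <- list()
  perm_mat <- as.matrix(expand.grid(a = 1:4, b = 1:4, c = 1:4, d = 1:4))
  perm_mat <- perm_mat[apply(perm_mat, 1, function(r) length(unique(r)) == 4), ]
  n <- nrow(points)
  perm_mat <- unique(perm_mat[, seq_len(n), drop = FALSE])
  pc <- colMeans(points)
  for (r in seq_len(nrow(perm_mat))) {
    corn <- corners[perm_mat[r, ], , drop = FALSE]
    cc <- colMeans(corn)
    corn_c <- sweep(corn, 2, cc)
    pts_c <- sweep(points, 2, pc)
    for (i in seq_len(n_axis)) {
      for (a in angles) {
        R <- rot_axis_angle(axes[i, ], a)
        rmsd <- sqrt(mean(rowSums((corn_c %*% t(R) - pts_c)^2)))
        if (rmsd < best) best <- rmsd
      }
    }
  }
  best
}

rot_axis_angle <- function(u, angle) {
  u <- u / sqrt(sum(u^2))
  c_ <- cos(angle); s_ <- sin(angle)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) * c_ + s_ * K + (1 - c_) * tcrossprod(u)
}
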