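# Independent brute-force oracles used to validate the accelerated
# geometry kernels, plus small fixture generators. Everything here is
# deliberately naive (dense loops, closed forms) and shares no code with
# the implementation paths it checks.

row_norms_test <- function(m) sqrt(rowSums(m^2))

# Moller-Trumbore intersection of one ray against every triangle
# (vectorized over triangles, independent of the BVH implementation);
# returns the smallest t >= eps and the hit point, or NULL.
oracle_raycast <- function(vertices, faces, origin, dir, eps = 1e-9) {
  v0 <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - v0
  e2 <- vertices[faces[, 3], , drop = FALSE] - v0
  cross_vec <- function(m, w) cbind(m[, 2] * w[3] - m[, 3] * w[2],
                                    m[, 3] * w[1] - m[, 1] * w[3],
                                    m[, 1] * w[2] - m[, 2] * w[1])
  p <- -cross_vec(e2, dir)           # dir x e2 per triangle
  det <- rowSums(e1 * p)
  s <- sweep(-v0, 2, -origin)        # origin - v0
  u <- rowSums(s * p) / det
  q <- cbind(s[, 2] * e1[, 3] - s[, 3] * e1[, 2],
             s[, 3] * e1[, 1] - s[, 1] * e1[, 3],
             s[, 1] * e1[, 2] - s[, 2] * e1[, 1])
  v <- as.numeric(q %*% dir) / det
  t <- rowSums(e2 * q) / det
  ok <- abs(det) >= 1e-14 & u >= 0 & u <= 1 & v >= 0 & (u + v) <= 1 & t >= eps
  if (!any(ok)) return(NULL)
  best <- min(t[ok])
  list(t = best, point = origin + best * dir)
}

# Exhaustive O(n^2) nearest neighbour with lowest-index tie-breaking.
oracle_nn <- function(query, target) {
  idx <- integer(nrow(query))
  dist <- numeric(nrow(query))
  for (i in seq_len(nrow(query))) {
    d2 <- colSums((t(target) - query[i, ])^2)
    idx[i] <- which.min(d2)  # which.min returns the first (lowest) index on ties
    dist[i] <- sqrt(d2[idx[i]])
  }
  list(index = idx, distance = dist)
}

oracle_hausdorff <- function(a, b) {
  dab <- max(oracle_nn(a, b)$distance)
  dba <- max(oracle_nn(b, a)$distance)
  max(dab, dba)
}

# 4x4 homogeneous matrix product oracle for transform composition.
oracle_compose_matrix <- function(t2, t1) {
  transform_matrix(t2) %*% transform_matrix(t1)
}

# Random triangle soup in the unit box scaled to `size`, with triangle
# edge lengths ~ size/5 so a rectangle above it gets a mix of hits and
# misses.
random_triangle_soup <- function(n_tri, seed, size = 10) {
  set.seed(seed)
  anchor <- matrix(runif(3 * n_tri, 0, size), n_tri, 3)
  v1 <- anchor + matrix(runif(3 * n_tri, -size / 5, size / 5), n_tri, 3)
  v2 <- anchor + matrix(runif(3 * n_tri, -size / 5, size / 5), n_tri, 3)
  triangle_mesh(rbind(anchor, v1, v2),
                cbind(seq_len(n_tri), n_tri + seq_len(n_tri), 2L * n_tri + seq_len(n_tri)))
}

icosphere_mesh <- function(radius, subdivisions = 3) {
  base <- ersr:::icosphere(subdivisions)
  triangle_mesh(base$vertices * radius, base$faces)
}

# A small closed, feature-rich surface whose irregular sampling makes
# rigid registration well posed (used by the ICP recovery tests).
structured_cloud <- function(n = 1200, seed = 4, mesh_seed = 7) {
  mesh <- make_truth_mesh(mesh_seed, subdivisions = 3)
  cl <- sample_surface_points(mesh, n, seed = seed)
  sweep(cl, 2, colMeans(cl))
}
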