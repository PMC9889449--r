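# High-resolution projection rectangles (HRPR): user-defined offset
# rectangles carrying a dense uniform grid that is ray-cast onto the CT-
# and scanner-derived meshes. Because both meshes receive the *same* grid,
# the two resulting clouds have identical cardinality and approximate
# index-wise correspondence -- the "equal resolution" that makes ICP
# between a coarse CT surface and a dense scanner surface well behaved.

#' Build a high-resolution projection rectangle (HRPR)
#'
#' The user picks three corner points on (or near) the surface; the first
#' edge `p2 - p1` fixes the in-plane `u` axis, the second edge `p3 - p2`
#' is orthogonalized against it to give `v` (picked corners are never
#' exactly perpendicular). The rectangle plane is then translated by
#' `offset_d` along its normal, away from the surface, and grid nodes are
#' later projected back along `-normal`.
#'
#' Which of the two plane normals points away from the mesh is decided by
#' a geometric test, not by corner winding (a "clockwise" convention is
#' viewer dependent): probe points on the rectangle (centre and quarter
#' points; the full grid as a fallback on sparse meshes) are offset by
#' `offset_d` along each candidate normal and rays cast back along
#' `-normal`. The orientation with more hits wins; on ties, the one whose
#' hit distances stay closest to `offset_d` (i.e. whose rays return to
#' the picked surface). If neither orientation hits the mesh the
#' rectangle does not face it and construction fails.
#'
#' @param p1,p2,p3 Corner points (length-3, mm). `p1 -> p2` is the first
#'   edge, `p2 -> p3` supplies the second extent.
#' @param offset_d Offset distance from the pick plane, mm (>= 0).
#' @param spacing Grid step, mm (> 0).
#' @param mesh The [triangle_mesh()] the rectangle must face (used for the
#'   orientation test; usually the scanner mesh).
#' @return An object of class `hrpr` with fields `origin`, `u_axis`,
#'   `v_axis`, `normal`, `extent_u`, `extent_v`, `offset_d`, `spacing`.
#' @export
build_hrpr <- function(p1, p2, p3, offset_d, spacing, mesh) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2); p3 <- as.numeric(p3)
  stopifnot(length(p1) == 3L, length(p2) == 3L, length(p3) == 3L)
  if (!is.finite(offset_d) || offset_d < 0) stop("offset_d must be >= 0", call. = FALSE)
  if (!is.finite(spacing) || spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  e1 <- p2 - p1
  e2 <- p3 - p2
  extent_u <- vnorm(e1)
  if (extent_u < 1e-12) stop("collinear corners: first edge has zero length", call. = FALSE)
  u <- e1 / extent_u
  v_raw <- e2 - sum(e2 * u) * u
  extent_v <- vnorm(v_raw)
  cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  if (extent_v < 1e-9 * max(extent_u, 1) || vnorm(cr) < 1e-9 * extent_u * vnorm(e2))
    stop("collinear corners: rectangle is degenerate", call. = FALSE)
  v <- v_raw / extent_v
  n0 <- cr / vnorm(cr)
  bvh <- mesh_bvh(mesh)
  # probe points on the pick plane: centre plus the four quarter points
  fr <- rbind(c(.5, .5), c(.25, .25), c(.75, .25), c(.25, .75), c(.75, .75))
  probes <- outer(rep(1, nrow(fr)), p1) + (fr[, 1] * extent_u) %o% u +
    (fr[, 2] * extent_v) %o% v
  score <- function(n, pts) {
    r <- .cpp_bvh_raycast(bvh, sweep(pts, 2L, -offset_d * n),
                          matrix(rep(-n, each = nrow(pts)), nrow(pts), 3L), 1e-9)
    c(hits = sum(r$hit), dev = if (any(r$hit)) mean(abs(r$t[r$hit] - offset_d)) else Inf)
  }
  s_plus <- score(n0, probes)
  s_minus <- score(-n0, probes)
  if (s_plus[1] == 0 && s_minus[1] == 0) {
    # sparse meshes can slip through the probe rays: fall back to the full grid
    nd <- c(floor(extent_u / spacing + 1e-9) + 1L, floor(extent_v / spacing + 1e-9) + 1L)
    ij <- expand.grid(i = 0:(nd[1] - 1L), j = 0:(nd[2] - 1L))
    nodes <- outer(rep(1, nrow(ij)), p1) + (ij$i * spacing) %o% u + (ij$j * spacing) %o% v
    s_plus <- score(n0, nodes)
    s_minus <- score(-n0, nodes)
    if (s_plus[1] == 0 && s_minus[1] == 0)
      stop("rectangle does not face mesh", call. = FALSE)
  }
  # more hits wins; on equal hits the orientation whose rays return to the
  # picked surface (hit distance ~ offset_d) is the one facing the mesh
  normal <- if (s_plus[1] > s_minus[1] ||
                (s_plus[1] == s_minus[1] && s_plus[2] <= s_minus[2])) n0 else -n0
  structure(list(origin = p1 + offset_d * normal, u_axis = u, v_axis = v,
                 normal = normal, extent_u = extent_u, extent_v = extent_v,
                 offset_d = offset_d, spacing = spacing),
            class = "hrpr")
}

#' @export
print.hrpr <- function(x, ...) {
  n <- hrpr_grid_dims(x)
  cat(sprintf("hrpr: %.1f x %.1f mm, spacing %.3f mm (%d x %d = %d nodes), offset %.1f mm\n",
              x$extent_u, x$extent_v, x$spacing, n[1], n[2], prod(n), x$offset_d))
  invisible(x)
}

hrpr_grid_dims <- function(h) {
  # closed interval: both boundary rows/columns included
  c(floor(h$extent_u / h$spacing + 1e-9) + 1L, floor(h$extent_v / h$spacing + 1e-9) + 1L)
}

#' Generate the uniform grid carried by an HRPR
#'
#' Nodes lie at `origin + i * spacing * u_axis + j * spacing * v_axis` for
#' all `i, j >= 0` with `i * spacing <= extent_u`, `j * spacing <=
#' extent_v` (closed interval, so both boundary rows are included). Order
#' is row-major with `i` fastest, which downstream code relies on for
#' correspondence bookkeeping.
#'
#' @param h An [build_hrpr()] object.
#' @return n x 3 matrix of grid node coordinates (on the offset plane).
#' @export
generate_grid <- function(h) {
  stopifnot(inherits(h, "hrpr"))
  nd <- hrpr_grid_dims(h)
  ij <- expand.grid(i = 0:(nd[1] - 1L), j = 0:(nd[2] - 1L))  # i fastest
  outer(rep(1, nrow(ij)), h$origin) +
    (ij$i * h$spacing) %o% h$u_axis + (ij$j * h$spacing) %o% h$v_axis
}

#' Project an HRPR grid onto a mesh surface
#'
#' Each grid node casts a ray along `-normal`; among all intersections the
#' one nearest the offset plane (smallest positive ray parameter) is kept,
#' which selects the superficial (outer) surface when a model still
#' contains inner shells. Intersections closer than `1e-9` mm are ignored
#' as self-intersection noise. Nodes whose rays miss the mesh are absent
#' from the returned points but recorded in the hit mask.
#'
#' @param h An [build_hrpr()] object.
#' @param mesh Target [triangle_mesh()].
#' @param min_hit_fraction Raise an error when fewer than this fraction of
#'   nodes hit the mesh (default 0.5) -- a symptom of a badly placed
#'   rectangle.
#' @param mesh_transform Optional [rigid_transform()]: project onto
#'   `mesh_transform(mesh)` without materializing the moved mesh (rays are
#'   cast in the mesh's own frame and hits mapped back, which preserves
#'   the mesh's cached acceleration structure across repeated calls).
#' @return Object of class `projected_cloud`: `points` (h x 3 on-surface
#'   hits, row-major grid order), `grid_index` (h x 2 one-based `(i, j)`
#'   node indices), `hit_mask` (full-grid logical, `i` fastest), `t`
#'   (ray parameters, mm).
#' @export
project_grid <- function(h, mesh, min_hit_fraction = 0.5, mesh_transform = NULL) {
  stopifnot(inherits(h, "hrpr"), inherits(mesh, "triangle_mesh"))
  nodes <- generate_grid(h)
  n <- nrow(nodes)
  dirs <- matrix(rep(-h$normal, each = n), n, 3L)
  if (!is.null(mesh_transform)) {
    inv <- invert_transform(mesh_transform)
    nodes_c <- apply_transform(inv, nodes)
    dirs_c <- dirs %*% t(inv$rotation)
  } else {
    nodes_c <- nodes
    dirs_c <- dirs
  }
  r <- .cpp_bvh_raycast(mesh_bvh(mesh), nodes_c, dirs_c, 1e-9)
  hit <- r$hit
  if (mean(hit) < min_hit_fraction)
    stop(sprintf("rectangle poorly placed: only %.0f%% of grid nodes hit the mesh",
                 100 * mean(hit)), call. = FALSE)
  pts <- r$points[hit, , drop = FALSE]
  if (!is.null(mesh_transform)) pts <- apply_transform(mesh_transform, pts)
  nd <- hrpr_grid_dims(h)
  idx <- which(hit)
  gi <- cbind(((idx - 1L) %% nd[1]) + 1L, ((idx - 1L) %/% nd[1]) + 1L)
  structure(list(points = pts, grid_index = gi, hit_mask = hit, t = r$t[hit],
                 grid_dims = nd, hrpr = h),
            class = "projected_cloud")
}

#' @export
print.projected_cloud <- function(x, ...) {
  cat(sprintf("projected_cloud: %d / %d grid nodes hit\n", nrow(x$points),
              length(x$hit_mask)))
  invisible(x)
}

#' Project HRPRs onto two meshes, keeping only jointly hit nodes
#'
#' The equal-resolution step: every rectangle grid is projected onto both
#' meshes and only nodes hit on *both* are kept, in identical row-major
#' node order, then concatenated across rectangles. The two returned
#' clouds therefore always have the same cardinality and index-wise
#' approximate correspondence -- the property that lets a plain
#' point-to-point ICP refine the landmark pre-registration.
#'
#' @param hrprs A single [build_hrpr()] object or a list of them.
#' @param mesh_a,mesh_b Target meshes (conventionally: `mesh_a` the
#'   CT-derived mesh already moved by the stage-1 landmark transform,
#'   `mesh_b` the scanner mesh the rectangles were defined on).
#' @param min_points Error when fewer than this many nodes survive on
#'   both meshes combined (default 100).
#' @param transform_a,transform_b Optional [rigid_transform()]s applied
#'   virtually to the meshes (see [project_grid()]).
#' @return List with `cloud_a`, `cloud_b` (equal-size n x 3 matrices),
#'   `n_per_rectangle`, and the per-rectangle `projected_cloud` pairs.
#' @export
project_pair <- function(hrprs, mesh_a, mesh_b, min_points = 100,
                         transform_a = NULL, transform_b = NULL) {
  if (inherits(hrprs, "hrpr")) hrprs <- list(hrprs)
  stopifnot(length(hrprs) >= 1L)
  ca <- list(); cb <- list(); nper <- integer(length(hrprs))
  for (k in seq_along(hrprs)) {
    pa <- project_grid(hrprs[[k]], mesh_a, min_hit_fraction = 0, mesh_transform = transform_a)
    pb <- project_grid(hrprs[[k]], mesh_b, min_hit_fraction = 0, mesh_transform = transform_b)
    both <- pa$hit_mask & pb$hit_mask
    ca[[k]] <- pa$points[both[pa$hit_mask], , drop = FALSE]
    cb[[k]] <- pb$points[both[pb$hit_mask], , drop = FALSE]
    nper[k] <- sum(both)
  }
  cloud_a <- do.call(rbind, ca)
  cloud_b <- do.call(rbind, cb)
  if (nrow(cloud_a) < min_points)
    stop(sprintf("insufficient overlap: only %d grid nodes hit both meshes", nrow(cloud_a)),
         call. = FALSE)
  list(cloud_a = cloud_a, cloud_b = cloud_b, n_per_rectangle = nper)
}
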