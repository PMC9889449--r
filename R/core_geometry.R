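# Core 3-d types: triangle meshes and proper rigid transforms.
# Point clouds are plain n x 3 numeric matrices (mm); row order is stable and
# meaningful, since downstream correspondence bookkeeping is index based.

#' Construct a triangle mesh
#'
#' A triangle mesh is a list with an `n x 3` vertex matrix (mm) and an
#' `m x 3` integer face matrix of 1-based vertex indices. Construction
#' validates indices and removes duplicate and degenerate (zero-area)
#' faces; meshes are assumed to be pre-cleaned *outer* surfaces (inner
#' shells from e.g. CT segmentation must be removed upstream, otherwise
#' surface matching can lock onto the wrong sheet).
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates in mm.
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @return An object of class `triangle_mesh`.
#' @examples
#' m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                    matrix(c(1, 2, 3), 1))
#' m
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as_point_matrix(vertices, "vertices")
  if (is.data.frame(faces)) faces <- as.matrix(faces)
  if (is.null(dim(faces)) && length(faces) == 3L) faces <- matrix(faces, 1L, 3L)
  if (!is.matrix(faces) || ncol(faces) != 3L)
    stop("'faces' must be an m x 3 matrix of vertex indices", call. = FALSE)
  storage.mode(faces) <- "integer"
  if (nrow(faces) == 0L) stop("mesh has no faces", call. = FALSE)
  if (anyNA(faces) || min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range", call. = FALSE)
  # drop faces with repeated vertices or (numerically) zero area
  a <- vertices[faces[, 1], , drop = FALSE]
  e1 <- vertices[faces[, 2], , drop = FALSE] - a
  e2 <- vertices[faces[, 3], , drop = FALSE] - a
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- row_norms(cr)
  keep <- area2 > 1e-12 &
    faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] & faces[, 1] != faces[, 3]
  faces <- faces[keep, , drop = FALSE]
  lo <- pmin(faces[, 1], faces[, 2], faces[, 3])
  hi <- pmax(faces[, 1], faces[, 2], faces[, 3])
  mid <- faces[, 1] + faces[, 2] + faces[, 3] - lo - hi
  ord <- order(lo, mid, hi)  # radix sort; duplicates are adjacent after ordering
  dup <- logical(nrow(faces))
  dup[ord] <- c(FALSE, diff(lo[ord]) == 0L & diff(mid[ord]) == 0L & diff(hi[ord]) == 0L)
  faces <- faces[!dup, , drop = FALSE]
  if (nrow(faces) == 0L) stop("all faces degenerate", call. = FALSE)
  out <- structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
  attr(out, "cache") <- new.env(parent = emptyenv())
  out
}

#' @export
print.triangle_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n", nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bbox [mm]: x %.2f..%.2f  y %.2f..%.2f  z %.2f..%.2f\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(x)
}

#' Is a mesh a closed (watertight) single-component surface?
#'
#' Checks that every undirected edge is shared by exactly two faces and that
#' the face adjacency graph has a single connected component.
#'
#' @param mesh A [triangle_mesh()].
#' @return `TRUE` or `FALSE`.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  mult <- tabulate(match(key, key))
  if (any(mult[mult > 0L] != 2L)) return(FALSE)
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  comp <- igraph::components(g)
  sum(tabulate(comp$membership[sort(unique(c(f)))]) > 0L) == 1L
}

#' Construct a proper rigid transform
#'
#' A rigid transform stores a 3 x 3 rotation `R` and a translation `t`
#' (mm) and acts on column points as `p' = R p + t`. Construction rejects
#' reflections (`det(R) = -1`): gluing two surfaces together as mirror
#' images is a classic failure mode of surface registration on mixed
#' inner/outer shells, and no stage of this pipeline may produce one.
#'
#' @param rotation 3 x 3 orthonormal matrix with determinant +1.
#' @param translation numeric length-3 vector, mm.
#' @return An object of class `rigid_transform`.
#' @seealso [apply_transform()], [compose_transforms()], [invert_transform()]
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3 x 3", call. = FALSE)
  storage.mode(rotation) <- "double"
  translation <- as.numeric(translation)
  if (length(translation) != 3L || !all(is.finite(translation)))
    stop("translation must be a finite length-3 vector", call. = FALSE)
  if (!all(is.finite(rotation))) stop("rotation contains non-finite values", call. = FALSE)
  ortho_dev <- max(abs(crossprod(rotation) - diag(3)))
  if (ortho_dev > 1e-6)
    stop(sprintf("rotation is not orthonormal (deviation %.2e)", ortho_dev), call. = FALSE)
  d <- det(rotation)
  if (d < 0) stop("improper transform: rotation has determinant -1 (reflection)", call. = FALSE)
  if (abs(d - 1) > 1e-9) {
    # mild numeric drift: re-project onto SO(3)
    s <- svd(rotation)
    rotation <- s$u %*% t(s$v)
  }
  structure(list(rotation = rotation, translation = translation), class = "rigid_transform")
}

#' Identity rigid transform
#' @return A [rigid_transform()] with `R = I`, `t = 0`.
#' @export
identity_transform <- function() rigid_transform()

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("rigid_transform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Apply a rigid transform to points or a mesh
#'
#' @param transform A [rigid_transform()].
#' @param x An n x 3 point matrix or a [triangle_mesh()].
#' @return Object of the same kind with transformed coordinates; point
#'   count and order are preserved.
#' @export
apply_transform <- function(transform, x) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(x, "triangle_mesh")) {
    v <- apply_transform(transform, x$vertices)
    return(triangle_mesh(v, x$faces))
  }
  p <- as_point_matrix(x, "x")
  sweep(p %*% t(transform$rotation), 2L, -transform$translation)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(t2, t1)` is the transform that applies `t1` first
#' and then `t2`, i.e. the chain read right to left, matching matrix
#' notation `T2 T1 p`.
#'
#' @param t2,t1 [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transforms <- function(t2, t1) {
  stopifnot(inherits(t2, "rigid_transform"), inherits(t1, "rigid_transform"))
  rigid_transform(t2$rotation %*% t1$rotation,
                  as.numeric(t2$rotation %*% t1$translation) + t2$translation)
}

#' Invert a rigid transform
#' @param transform A [rigid_transform()].
#' @return The inverse [rigid_transform()].
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.numeric(rt %*% transform$translation))
}

#' Convert between rigid transforms and 4 x 4 homogeneous matrices
#'
#' The homogeneous form is row-major with the rotation in the upper-left
#' block and translation in the last column, acting on column vectors;
#' this is also the on-disk JSON convention ([write_transform()]).
#'
#' @param transform A [rigid_transform()].
#' @return `transform_matrix()`: a 4 x 4 matrix. `transform_from_matrix()`:
#'   a [rigid_transform()].
#' @export
transform_matrix <- function(transform) {
  m <- diag(4)
  m[1:3, 1:3] <- transform$rotation
  m[1:3, 4] <- transform$translation
  m
}

#' @rdname transform_matrix
#' @param m A 4 x 4 homogeneous matrix.
#' @export
transform_from_matrix <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(4L, 4L))) stop("expected a 4 x 4 matrix", call. = FALSE)
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("bottom row of a rigid homogeneous matrix must be (0, 0, 0, 1)", call. = FALSE)
  rot <- m[1:3, 1:3]
  dev <- max(abs(crossprod(rot) - diag(3)))
  if (dev > 1e-3) stop(sprintf("rotation block not orthonormal (deviation %.2e)", dev),
                       call. = FALSE)
  if (det(rot) < 0) stop("improper transform: determinant -1", call. = FALSE)
  if (dev > 1e-6) {
    warning(sprintf("re-orthonormalizing rotation (deviation %.2e)", dev))
    s <- svd(rot)
    rot <- s$u %*% t(s$v)
  }
  rigid_transform(rot, m[1:3, 4])
}

#' Random proper rigid transform
#'
#' Uniform random rotation axis, rotation angle uniform on
#' `[0, max_angle_deg]`, translation uniform in the cube of half-width
#' `max_translation`. Used for simulation fixtures and property tests.
#'
#' @param max_angle_deg Maximum rotation angle, degrees.
#' @param max_translation Maximum per-axis |translation|, mm.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A [rigid_transform()].
#' @export
random_rigid_transform <- function(max_angle_deg = 180, max_translation = 50, seed = NULL) {
  with_seed(seed, {
    ax <- rnorm(3)
    ax <- ax / vnorm(ax)
    ang <- stats::runif(1, 0, max_angle_deg * pi / 180)
    rigid_transform(rotation_about_axis(ax, ang),
                    stats::runif(3, -max_translation, max_translation))
  })
}

# Rodrigues rotation about a unit axis by `angle` radians.
rotation_about_axis <- function(axis, angle) {
  k <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}
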