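# Internal helpers: input coercion, seeded evaluation, per-object caches.

# Coerce anything point-like to an n x 3 double matrix and validate.
as_point_matrix <- function(x, arg = deparse(substitute(x))) {
  if (inherits(x, "triangle_mesh")) x <- x$vertices
  if (is.data.frame(x)) x <- as.matrix(x[, c("x", "y", "z")])
  if (is.null(dim(x)) && length(x) == 3L) x <- matrix(as.numeric(x), 1L, 3L)
  if (!is.matrix(x) || ncol(x) != 3L)
    stop(sprintf("'%s' must be an n x 3 matrix of coordinates", arg), call. = FALSE)
  storage.mode(x) <- "double"
  if (!all(is.finite(x)))
    stop(sprintf("'%s' contains non-finite coordinates", arg), call. = FALSE)
  dimnames(x) <- NULL
  x
}

# Run code under a temporary RNG state; restores (or removes) .Random.seed.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Meshes and landmark sets carry an environment so expensive acceleration
# structures (BVH, kd-tree external pointers) are built once per object and
# shared across copies. External pointers do not survive serialization, so
# validity is re-checked on every access.
obj_cache <- function(x) attr(x, "cache")

cache_fetch <- function(x, key, build) {
  env <- attr(x, "cache")
  if (is.null(env)) return(build())
  val <- env[[key]]
  if (!is.null(val) && .cpp_xptr_valid(val)) return(val)
  val <- build()
  env[[key]] <- val
  val
}

mesh_bvh <- function(mesh) {
  cache_fetch(mesh, "bvh", function() .cpp_bvh_build(mesh$vertices, mesh$faces))
}

points_kdtree <- function(points, host = NULL) {
  if (is.null(host)) return(.cpp_kdtree_build(points))
  cache_fetch(host, "kdtree", function() .cpp_kdtree_build(points))
}

vnorm <- function(v) sqrt(sum(v^2))

row_norms <- function(m) sqrt(rowSums(m^2))
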