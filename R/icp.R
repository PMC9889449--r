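# Point-to-point iterative closest point refinement.

#' Nearest-neighbour correspondences between two point clouds
#'
#' For every query point, the index of the closest target point and the
#' distance to it. Search uses a kd-tree whose results are contractually
#' identical to exhaustive search; exact distance ties resolve to the
#' lowest target index.
#'
#' @param query,target n x 3 / m x 3 point matrices.
#' @return List with `index` (1-based into `target`) and `distance` (mm).
#' @export
nearest_neighbors <- function(query, target) {
  query <- as_point_matrix(query, "query")
  target <- as_point_matrix(target, "target")
  if (nrow(target) == 0L) stop("empty target", call. = FALSE)
  .cpp_kdtree_query(.cpp_kdtree_build(target), query)
}

#' Iterative closest point rigid registration
#'
#' Alternates nearest-neighbour correspondence with the least-squares
#' rigid fit of [fit_landmark_transform()] on the matched pairs, starting
#' from `init`. The iteration stops when the RMS of matched distances
#' changes by less than `tol` between successive iterations, or at
#' `max_iter`. With full (untrimmed) correspondences the matched RMS is
#' monotonically non-increasing, the classical alternating-minimization
#' guarantee; the history is returned so callers can verify it.
#'
#' ICP is a local method: from a grossly wrong initialization it will
#' converge monotonically to a wrong local minimum. In the ERSR pipeline
#' the stage-1 landmark transform provides the required coarse alignment.
#'
#' @param src,dst Point clouds (n, m >= 3). The returned transform maps
#'   `src` toward `dst`.
#' @param init Initial [rigid_transform()] (default identity).
#' @param max_iter Maximum iterations (default 100). `0` returns `init`.
#' @param tol Stop when `|RMS_k - RMS_{k-1}| < tol` (mm, default 1e-6).
#' @param trim_fraction Drop this fraction of the worst correspondences
#'   before each fit (robustness for partial overlap; default 0 = plain
#'   ICP, and only the untrimmed variant guarantees a monotone RMS).
#' @return Object of class `icp_result`: `transform`, `rms_history` (RMS
#'   of matched distances at each iteration, after applying the current
#'   transform), `iterations`, `converged` (stopped by `tol`).
#' @export
icp_register <- function(src, dst, init = identity_transform(), max_iter = 100,
                         tol = 1e-6, trim_fraction = 0) {
  src <- as_point_matrix(src, "src")
  dst <- as_point_matrix(dst, "dst")
  if (nrow(src) < 3L || nrow(dst) < 3L) stop("need >= 3 points in both clouds", call. = FALSE)
  stopifnot(inherits(init, "rigid_transform"), trim_fraction >= 0, trim_fraction < 1)
  tree <- .cpp_kdtree_build(dst)
  trans <- init
  rms_history <- numeric(0)
  converged <- FALSE
  iter <- 0L
  prev_rms <- Inf
  while (iter < max_iter) {
    iter <- iter + 1L
    moved <- apply_transform(trans, src)
    nn <- .cpp_kdtree_query(tree, moved)
    keep <- seq_len(nrow(src))
    if (trim_fraction > 0) {
      q <- stats::quantile(nn$distance, 1 - trim_fraction, names = FALSE, type = 1)
      keep <- which(nn$distance <= q)
    }
    rms <- sqrt(mean(nn$distance[keep]^2))
    rms_history <- c(rms_history, rms)
    if (abs(prev_rms - rms) < tol) {
      converged <- TRUE
      break
    }
    prev_rms <- rms
    trans <- fit_landmark_transform(src[keep, , drop = FALSE],
                                    dst[nn$index[keep], , drop = FALSE])
  }
  structure(list(transform = trans, rms_history = rms_history, iterations = iter,
                 converged = converged),
            class = "icp_result")
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf("icp_result: %d iterations, final RMS %.6g mm, %sconverged\n",
              x$iterations,
              if (length(x$rms_history)) x$rms_history[length(x$rms_history)] else NA,
              if (x$converged) "" else "NOT "))
  invisible(x)
}
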