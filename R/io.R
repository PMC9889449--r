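# Readers and writers: STL (ASCII + binary), PLY (ASCII, optional per-vertex
# scalar), landmark CSV/JSON, rigid-transform JSON, pipeline config JSON.

#' Read a triangle mesh from STL or PLY
#'
#' Format is chosen by extension (`.stl` / `.ply`); STL flavour (ASCII vs
#' binary) is detected from the file content. STL stores independent
#' triangles, so exactly coincident vertices are welded on read to
#' recover shared connectivity. Binary STL stores 32-bit floats; expect
#' ~1e-5 relative coordinate precision through that route.
#'
#' @param path File path.
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = read_stl(path),
         ply = read_ply(path),
         stop("unsupported mesh format '", ext, "' (use .stl or .ply)", call. = FALSE))
}

#' Write a triangle mesh to STL or PLY
#'
#' @param mesh A [triangle_mesh()].
#' @param path Output path; extension selects the format.
#' @param binary For STL: write the binary flavour (default) or ASCII.
#' @param scalar Optional per-vertex numeric vector stored as a `quality`
#'   property (PLY only) -- used to export distance maps for external
#'   colour-map rendering.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = TRUE, scalar = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         stl = write_stl(mesh, path, binary = binary),
         ply = write_ply(mesh, path, scalar = scalar),
         stop("unsupported mesh format '", ext, "'", call. = FALSE))
  invisible(path)
}

stl_is_binary <- function(path) {
  head <- readBin(path, "raw", n = 80L)
  if (length(head) < 80L) return(FALSE)
  if (identical(rawToChar(head[1:5]), "solid")) {
    # some binary files abuse a "solid" header; trust the size arithmetic
    con <- file(path, "rb"); on.exit(close(con))
    invisible(readBin(con, "raw", 80L))
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    sz <- file.size(path)
    return(!is.na(n) && n >= 0 && sz == 84 + 50 * as.numeric(n))
  }
  TRUE
}

read_stl <- function(path) {
  if (stl_is_binary(path)) {
    con <- file(path, "rb"); on.exit(close(con))
    invisible(readBin(con, "raw", 80L))
    n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (is.na(n) || n <= 0) stop("malformed binary STL: bad triangle count", call. = FALSE)
    rec <- readBin(con, "raw", n = 50L * n)
    if (length(rec) < 50L * n)
      stop(sprintf("malformed binary STL: truncated at byte %d", 84L + length(rec)),
           call. = FALSE)
    m <- matrix(rec, nrow = 50L)
    fl <- readBin(as.vector(m[1:48, ]), "double", n = 12L * n, size = 4L,
                  endian = "little")
    tri <- matrix(fl, ncol = 12L, byrow = TRUE)[, 4:12, drop = FALSE]  # drop normals
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (!length(vl) || length(vl) %% 3L != 0L)
      stop(sprintf("malformed ASCII STL '%s': %d vertex lines (not a multiple of 3)",
                   path, length(vl)), call. = FALSE)
    co <- suppressWarnings(vapply(strsplit(trimws(vl), "\\s+"), function(p)
      as.numeric(p[2:4]), numeric(3)))
    if (anyNA(co)) stop("malformed ASCII STL: non-numeric vertex coordinates", call. = FALSE)
    tri <- matrix(as.vector(co), ncol = 9L, byrow = TRUE)
  }
  # corners in per-triangle order, welded by exact coordinate match so the
  # first-use vertex order (and hence a write -> read round trip) is stable
  n <- nrow(tri)
  verts <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
                 tri[, 7:9, drop = FALSE])
  ord <- as.vector(rbind(seq_len(n), n + seq_len(n), 2L * n + seq_len(n)))
  verts <- verts[ord, , drop = FALSE]
  # group exactly equal coordinate triples via a radix sort (no string keys)
  o <- order(verts[, 1], verts[, 2], verts[, 3], method = "radix")
  vo <- verts[o, , drop = FALSE]
  m3 <- nrow(verts)
  new_grp <- c(TRUE, vo[-1L, 1] != vo[-m3, 1] | vo[-1L, 2] != vo[-m3, 2] |
                 vo[-1L, 3] != vo[-m3, 3])
  grp <- integer(m3)
  grp[o] <- cumsum(new_grp)
  keep_pos <- which(!duplicated(grp))  # first use of each vertex, original order
  uid_of_grp <- integer(max(grp))
  uid_of_grp[grp[keep_pos]] <- seq_along(keep_pos)
  faces <- matrix(uid_of_grp[grp], ncol = 3L, byrow = TRUE)
  triangle_mesh(verts[keep_pos, , drop = FALSE], faces)
}

write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]; c3 <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c3 - a
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- nrm / row_norms(nrm)
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    # 12 float32 + 2 attribute bytes per 50-byte record, assembled in bulk
    fl <- writeBin(as.numeric(t(cbind(nrm, a, b, c3))), raw(), size = 4L,
                   endian = "little")
    rec <- rbind(matrix(fl, nrow = 48L), matrix(raw(2L * nrow(f)), nrow = 2L))
    writeBin(as.vector(rec), con)
  } else {
    fmt <- function(m) apply(m, 1L, function(r) sprintf("%.9g %.9g %.9g", r[1], r[2], r[3]))
    lines <- c("solid ersr",
               as.vector(rbind(paste("facet normal", fmt(nrm)),
                               "outer loop",
                               paste("vertex", fmt(a)),
                               paste("vertex", fmt(b)),
                               paste("vertex", fmt(c3)),
                               "endloop", "endfacet")),
               "endsolid ersr")
    writeLines(lines, path)
  }
  invisible(path)
}

read_ply <- function(path) {
  txt <- readLines(path, warn = FALSE)
  endh <- match("end_header", trimws(txt))
  if (is.na(endh)) stop("malformed PLY: no end_header", call. = FALSE)
  header <- trimws(txt[seq_len(endh)])
  if (any(grepl("^format\\s+binary", header)))
    stop("binary PLY is not supported; export ASCII PLY", call. = FALSE)
  nv <- as.integer(sub("^element vertex\\s+", "", grep("^element vertex", header, value = TRUE)))
  nf <- as.integer(sub("^element face\\s+", "", grep("^element face", header, value = TRUE)))
  if (!length(nv) || !length(nf)) stop("malformed PLY: missing elements", call. = FALSE)
  body <- txt[(endh + 1L):length(txt)]
  if (length(body) < nv + nf)
    stop(sprintf("malformed PLY: expected %d body lines, found %d", nv + nf, length(body)),
         call. = FALSE)
  vparts <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  v <- t(vapply(vparts, function(p) as.numeric(p[1:3]), numeric(3)))
  fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  f <- t(vapply(fparts, function(p) {
    if (p[1] != "3") stop("only triangle faces supported", call. = FALSE)
    as.integer(p[2:4]) + 1L
  }, integer(3)))
  triangle_mesh(v, f)
}

write_ply <- function(mesh, path, scalar = NULL) {
  v <- mesh$vertices
  f <- mesh$faces
  if (!is.null(scalar) && length(scalar) != nrow(v))
    stop("scalar must have one value per vertex", call. = FALSE)
  header <- c("ply", "format ascii 1.0", "comment ersr export",
              sprintf("element vertex %d", nrow(v)),
              "property double x", "property double y", "property double z",
              if (!is.null(scalar)) "property double quality",
              sprintf("element face %d", nrow(f)),
              "property list uchar int vertex_indices", "end_header")
  vm <- if (is.null(scalar)) v else cbind(v, scalar)
  vlines <- apply(vm, 1L, function(r) paste(sprintf("%.9g", r), collapse = " "))
  flines <- apply(f - 1L, 1L, function(r) paste(c(3L, r), collapse = " "))
  writeLines(c(header, vlines, flines), path)
  invisible(path)
}

#' Read / write landmark sets (CSV or JSON)
#'
#' CSV has columns `name,x,y,z,role` and optionally `frame`; the JSON
#' schema is `{"frame": ..., "landmarks": [{"name", "x", "y", "z",
#' "role"}, ...]}`. Duplicate names and missing columns are errors.
#'
#' @param path File path (`.csv` or `.json`).
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    df <- as.data.frame(j$landmarks)
    frame <- j$frame
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
    frame <- if ("frame" %in% names(df)) unique(df$frame)[1] else NULL
  }
  need <- c("name", "x", "y", "z", "role")
  if (!all(need %in% names(df)))
    stop("landmark file must have columns ", paste(need, collapse = ","), call. = FALSE)
  landmark_set(df$name, as.matrix(df[, c("x", "y", "z")]), df$role, frame = frame)
}

#' @rdname read_landmarks
#' @param landmarks A [landmark_set()].
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  ext <- tolower(tools::file_ext(path))
  df <- data.frame(name = landmarks$names, x = landmarks$coords[, 1],
                   y = landmarks$coords[, 2], z = landmarks$coords[, 3],
                   role = landmarks$roles)
  if (ext == "json") {
    jsonlite::write_json(list(frame = landmarks$frame, landmarks = df), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    if (!is.null(landmarks$frame)) df$frame <- landmarks$frame
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write rigid transforms as JSON
#'
#' On disk a transform is a 4 x 4 row-major homogeneous matrix acting on
#' column vectors, stored under `"matrix"` with a self-describing
#' `"convention"` field. Reading enforces the `(0,0,0,1)` bottom row and
#' a proper orthonormal rotation block (re-orthonormalized with a warning
#' when the deviation is between 1e-6 and 1e-3; rejected beyond that or
#' when the determinant is negative).
#'
#' @param path File path.
#' @return A [rigid_transform()].
#' @export
read_transform <- function(path) {
  j <- jsonlite::fromJSON(path)
  m <- j$matrix
  if (is.null(m)) stop("transform JSON must contain a 'matrix' field", call. = FALSE)
  transform_from_matrix(matrix(as.numeric(t(m)), 4L, 4L, byrow = TRUE))
}

#' @rdname read_transform
#' @param transform A [rigid_transform()].
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "rigid_transform"))
  jsonlite::write_json(
    list(convention = "4x4 row-major homogeneous matrix acting on column points (mm)",
         matrix = transform_matrix(transform)),
    path, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read a pipeline configuration (JSON)
#'
#' Fields: `dicom_mesh`, `scanner_mesh`, `dicom_landmarks`,
#' `scanner_landmarks` (paths), optional `palpated_landmarks`, `hrprs`
#' (inline list of `{p1, p2, p3, offset_d, spacing}` or a path to a JSON
#' list), optional `icp` (`max_iter`, `tol`, `trim_fraction`),
#' `evaluation` (`n_bins`, `direction`), `seed`, `out_dir`. All
#' referenced paths (relative to the config file's directory) must
#' exist at load time.
#'
#' @param path Config path.
#' @return A named list with loaded objects, class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (is.null(p) || file.exists(p)) p else file.path(base, p)
  for (field in c("dicom_mesh", "scanner_mesh", "dicom_landmarks", "scanner_landmarks",
                  "palpated_landmarks")) {
    p <- resolve(cfg[[field]])
    if (is.null(p)) {
      if (field != "palpated_landmarks")
        stop("config missing required field '", field, "'", call. = FALSE)
      next
    }
    if (!file.exists(p)) stop("config path does not exist: ", p, call. = FALSE)
    cfg[[field]] <- p
  }
  if (is.character(cfg$hrprs)) {
    p <- resolve(cfg$hrprs)
    if (!file.exists(p)) stop("HRPR spec file does not exist: ", p, call. = FALSE)
    cfg$hrprs <- jsonlite::fromJSON(p, simplifyDataFrame = FALSE)
  }
  cfg$seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}
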