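# PLY / OBJ mesh export and PLY import.

#' Write a mesh to PLY
#'
#' Writes vertices, per-vertex normals and triangular faces in the
#' Stanford PLY format, ASCII or binary little-endian.
#'
#' @param mesh A `triangle_mesh`.
#' @param path Output file path.
#' @param format `"ascii"` or `"binary"` (binary_little_endian 1.0).
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, format = c("ascii", "binary")) {
  format <- match.arg(format)
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  header <- c(
    "ply",
    sprintf("format %s 1.0",
            if (format == "ascii") "ascii" else "binary_little_endian"),
    "comment terraced marching-cubes surface (voxel coordinates)",
    sprintf("element vertex %d", nv),
    "property float x", "property float y", "property float z",
    "property float nx", "property float ny", "property float nz",
    sprintf("element face %d", nf),
    "property list uchar int vertex_indices",
    "end_header")
  vdat <- cbind(mesh$vertices, mesh$normals)
  if (format == "ascii") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(apply(vdat, 1, function(r) paste(format(r, digits = 9,
                                                       scientific = FALSE,
                                                       trim = TRUE),
                                                collapse = " ")), con)
    writeLines(paste(3L, mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                     mesh$faces[, 3] - 1L), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    writeBin(as.numeric(t(vdat)), con, size = 4L, endian = "little")
    fm <- t(mesh$faces - 1L)
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(fm[, i]), con, size = 4L, endian = "little")
    }
  }
  invisible(path)
}

#' Write a mesh to Wavefront OBJ
#'
#' @inheritParams write_ply
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  v <- apply(mesh$vertices, 1, function(r)
    paste("v", paste(format(r, digits = 9, trim = TRUE), collapse = " ")))
  vn <- apply(mesh$normals, 1, function(r)
    paste("vn", paste(format(r, digits = 9, trim = TRUE), collapse = " ")))
  f <- apply(mesh$faces, 1, function(r)
    paste("f", paste(sprintf("%d//%d", r, r), collapse = " ")))
  writeLines(c("# terraced marching-cubes surface", v, vn, f), path)
  invisible(path)
}

#' Read a PLY mesh
#'
#' Reads ASCII or binary little-endian PLY files with float vertex
#' positions, optional float normals, and triangular faces — i.e. the
#' files produced by [write_ply()] and by common mesh tools.
#'
#' @param path PLY file path.
#' @param spacing Voxel spacing to attach to the mesh (mm).
#' @return A [triangle_mesh()].
#' @export
read_ply <- function(path, spacing = 0.3) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("not a PLY file (no end_header): ", path)
    header <- c(header, line)
    if (line == "end_header") break
  }
  if (header[1] != "ply") stop("not a PLY file: ", path)
  fmt <- grep("^format ", header, value = TRUE)
  binary <- grepl("binary_little_endian", fmt)
  elems <- grep("^element ", header)
  parse_elem <- function(k) {
    parts <- strsplit(header[elems[k]], " +")[[1]]
    upto <- if (k < length(elems)) elems[k + 1] - 1L else length(header) - 1L
    props <- grep("^property ", header[(elems[k] + 1):upto], value = TRUE)
    list(name = parts[2], n = as.integer(parts[3]), props = props)
  }
  els <- lapply(seq_along(elems), parse_elem)
  names(els) <- vapply(els, `[[`, "", "name")
  ve <- els[["vertex"]]; fe <- els[["face"]]
  if (is.null(ve) || is.null(fe)) stop("PLY without vertex/face elements: ", path)
  np <- length(ve$props)
  pnames <- vapply(strsplit(ve$props, " +"), function(p) p[3], "")
  if (binary) {
    vdat <- matrix(readBin(con, "numeric", n = ve$n * np, size = 4L,
                           endian = "little"), ncol = np, byrow = TRUE)
    faces <- matrix(0L, fe$n, 3L)
    for (i in seq_len(fe$n)) {
      cnt <- as.integer(readBin(con, "raw", n = 1L))
      idx <- readBin(con, "integer", n = cnt, size = 4L, endian = "little")
      if (cnt != 3L) stop("non-triangular PLY face")
      faces[i, ] <- idx + 1L
    }
  } else {
    txt <- readLines(con)
    vdat <- matrix(scan(text = txt[seq_len(ve$n)], quiet = TRUE),
                   ncol = np, byrow = TRUE)
    frows <- lapply(strsplit(txt[ve$n + seq_len(fe$n)], " +"), as.integer)
    if (any(vapply(frows, `[`, 0L, 1L) != 3L)) stop("non-triangular PLY face")
    faces <- do.call(rbind, lapply(frows, function(r) r[2:4] + 1L))
  }
  colnames(vdat) <- pnames
  verts <- vdat[, c("x", "y", "z"), drop = FALSE]
  normals <- if (all(c("nx", "ny", "nz") %in% pnames))
    vdat[, c("nx", "ny", "nz"), drop = FALSE] else NULL
  triangle_mesh(verts, faces, normals = normals, spacing = spacing)
}
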