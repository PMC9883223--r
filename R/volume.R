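# Volume container and readers/writers for the formats a CBCT pipeline
# meets: DICOM series, NIfTI, NRRD, and raw arrays with a JSON sidecar.

#' Construct a CBCT-like volume
#'
#' @param data 3D numeric array of intensities (arbitrary units).
#' @param spacing Per-axis voxel edge length in mm (length 1 or 3);
#'   the acquisition geometry emulated throughout is 0.3 mm isotropic.
#' @param meta Optional list of format metadata (source, anisotropy flag).
#' @return An object of class `cbct_volume`.  The axis convention is the
#'   one used for all landmark work: +x subject-left, +y
#'   subject-backward, +z up.
#' @export
cbct_volume <- function(data, spacing = 0.3, meta = list()) {
  stopifnot(length(dim(data)) == 3L, all(dim(data) >= 2L))
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  if (any(spacing <= 0)) stop("voxel spacing must be positive")
  meta$anisotropic <- length(unique(spacing)) > 1L
  structure(list(data = data, spacing = spacing,
                 axis_convention = "+x left, +y backward, +z up",
                 meta = meta),
            class = "cbct_volume")
}

#' @export
print.cbct_volume <- function(x, ...) {
  cat(sprintf("cbct_volume: %s voxels, spacing %s mm%s\n",
              paste(dim(x$data), collapse = " x "),
              paste(format(x$spacing), collapse = " x "),
              if (isTRUE(x$meta$anisotropic)) " (anisotropic)" else ""))
  invisible(x)
}

#' Load a volume from disk
#'
#' @param path File (NIfTI, NRRD, raw) or directory (DICOM series).
#' @param format One of `"nifti"`, `"nrrd"`, `"dicom_dir"`,
#'   `"raw"` (raw binary with a JSON sidecar `{shape, dtype, spacing}`
#'   at `<path>.json` or with the extension replaced by `.json`).
#'   Guessed from the path when omitted.
#' @return A [cbct_volume()].  DICOM slices are ordered by slice
#'   position, never by filename.  Anisotropic spacing is accepted and
#'   flagged in `meta$anisotropic`.
#' @export
load_volume <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (dir.exists(path)) "dicom_dir"
    else if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
    else if (grepl("\\.nrrd$", path)) "nrrd"
    else "raw"
  }
  format <- match.arg(format, c("nifti", "nrrd", "dicom_dir", "raw"))
  if (format != "dicom_dir" && !file.exists(path))
    stop("cannot read ", format, " volume: file not found: ", path)
  switch(format,
         nifti = .load_nifti(path),
         nrrd = .load_nrrd(path),
         dicom_dir = .load_dicom_dir(path),
         raw = .load_raw_json(path))
}

.load_nifti <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file ", path,
                                           ": ", conditionMessage(e)))
  sp <- attr(img, "pixdim")[1:3]
  cbct_volume(array(as.numeric(img), dim(img)[1:3]), spacing = sp,
              meta = list(source = path, format = "nifti"))
}

# --- NRRD (raw-encoded, 3D) ------------------------------------------------

.load_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("unreadable NRRD file ", path,
                                   ": bad magic '", magic, "'")
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L || line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(kv[2])]] <- kv[3]
  }
  sizes <- as.integer(strsplit(fields$sizes, " +")[[1]])
  if (length(sizes) != 3L) stop("only 3D NRRD volumes are supported: ", path)
  if (!identical(tolower(fields$encoding), "raw"))
    stop("unsupported NRRD encoding '", fields$encoding, "' in ", path)
  type <- tolower(fields$type)
  spec <- switch(type,
                 "uchar" = , "uint8" = , "unsigned char" = list("integer", 1L, FALSE),
                 "short" = , "int16" = list("integer", 2L, TRUE),
                 "ushort" = , "uint16" = list("integer", 2L, FALSE),
                 "int" = , "int32" = list("integer", 4L, TRUE),
                 "float" = list("numeric", 4L, TRUE),
                 "double" = list("numeric", 8L, TRUE),
                 stop("unsupported NRRD type '", type, "' in ", path))
  endian <- if (!is.null(fields$endian)) fields$endian else "little"
  n <- prod(sizes)
  vals <- readBin(con, spec[[1]], n = n, size = spec[[2]],
                  signed = spec[[3]] || spec[[2]] > 2L, endian = endian)
  spacing <- c(1, 1, 1)
  if (!is.null(fields$spacings)) {
    spacing <- as.numeric(strsplit(trimws(fields$spacings), " +")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- t(vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3)))
    spacing <- sqrt(rowSums(m^2))
  }
  cbct_volume(array(as.numeric(vals), sizes), spacing = spacing,
              meta = list(source = path, format = "nrrd"))
}

#' Write a volume or mask to NRRD
#'
#' Raw-encoded NRRD with per-axis spacings; masks are written as uint8.
#'
#' @param x A `cbct_volume` or `tissue_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(x, path) {
  is_mask <- inherits(x, "tissue_mask")
  arr <- x$data
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("NRRD0004",
               "# produced by ccmark",
               sprintf("type: %s", if (is_mask) "uchar" else "double"),
               "dimension: 3",
               sprintf("sizes: %s", paste(dim(arr), collapse = " ")),
               sprintf("spacings: %s", paste(format(x$spacing), collapse = " ")),
               "encoding: raw",
               "endian: little",
               ""), con)
  if (is_mask) writeBin(as.integer(arr), con, size = 1L)
  else writeBin(as.numeric(arr), con, size = 8L, endian = "little")
  invisible(path)
}

#' Write a mask or volume to NIfTI
#'
#' @inheritParams write_nrrd
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  arr <- if (inherits(x, "tissue_mask")) array(as.integer(x$data), dim(x$data))
  else x$data
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

# --- raw + JSON sidecar ----------------------------------------------------

.raw_sidecar_path <- function(path) {
  cands <- c(paste0(path, ".json"), sub("\\.[^.]*$", ".json", path))
  hit <- cands[file.exists(cands)]
  if (length(hit) == 0L)
    stop("unreadable raw volume ", path, ": no JSON sidecar (looked for ",
         paste(unique(cands), collapse = ", "), ")")
  hit[1]
}

.load_raw_json <- function(path) {
  side <- jsonlite::fromJSON(.raw_sidecar_path(path))
  shape <- as.integer(side$shape)
  dtype <- tolower(side$dtype)
  spec <- switch(dtype,
                 "uint8" = list("integer", 1L, FALSE),
                 "int16" = list("integer", 2L, TRUE),
                 "uint16" = list("integer", 2L, FALSE),
                 "int32" = list("integer", 4L, TRUE),
                 "float32" = list("numeric", 4L, TRUE),
                 "float64" = list("numeric", 8L, TRUE),
                 stop("unsupported raw dtype '", dtype, "' for ", path))
  vals <- readBin(path, spec[[1]], n = prod(shape), size = spec[[2]],
                  signed = spec[[3]] || spec[[2]] > 2L, endian = "little")
  if (length(vals) < prod(shape))
    stop("unreadable raw volume ", path, ": too short for shape ",
         paste(shape, collapse = "x"))
  cbct_volume(array(as.numeric(vals), shape), spacing = side$spacing,
              meta = list(source = path, format = "raw"))
}

#' Write a volume as raw binary plus JSON sidecar
#'
#' @param volume A `cbct_volume`.
#' @param path Output `.raw` path; the sidecar is written at `<path>.json`.
#' @param dtype On-disk element type.
#' @return `path`, invisibly.
#' @export
write_raw_volume <- function(volume, path, dtype = "float64") {
  spec <- switch(dtype,
                 "uint8" = list(as.integer, 1L), "int16" = list(as.integer, 2L),
                 "int32" = list(as.integer, 4L), "float32" = list(as.numeric, 4L),
                 "float64" = list(as.numeric, 8L),
                 stop("unsupported raw dtype '", dtype, "'"))
  writeBin(spec[[1]](volume$data), path, size = spec[[2]], endian = "little")
  jsonlite::write_json(list(shape = dim(volume$data), dtype = dtype,
                            spacing = volume$spacing),
                       paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# --- DICOM series (uncompressed little-endian) -----------------------------

# Minimal single-frame DICOM parser: explicit or implicit VR little
# endian, no sequences.  Written in-package because no DICOM reader is
# among the package's dependencies; covers the tags a CBCT slice stack
# needs (geometry + pixel data).
.parse_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop("unreadable DICOM file ", path, ": missing DICM magic")
  u16 <- function(off) as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
  u32 <- function(off) u16(off) + 65536 * u16(off + 2L)
  tags <- list()
  pos <- 132L          # 0-based offset just past "DICM"
  explicit <- TRUE     # file meta group is always explicit VR
  n <- length(raw)
  while (pos + 8L <= n) {
    grp <- u16(pos); ele <- u16(pos + 2L)
    if (grp == 0x0002) {
      vr <- rawToChar(raw[pos + 5:6])
    } else if (explicit) {
      vr <- rawToChar(raw[pos + 5:6])
      if (!grepl("^[A-Z]{2}$", vr)) { explicit <- FALSE; vr <- "UN" }
    } else vr <- "UN"
    if (grp == 0x0002 || explicit) {
      if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
        len <- u32(pos + 8L); hdr <- 12L
      } else { len <- u16(pos + 6L); hdr <- 8L }
    } else { len <- u32(pos + 4L); hdr <- 8L }
    if (len == 4294967295) stop("undefined-length DICOM element in ", path,
                                " (sequences are not supported)")
    val_off <- pos + hdr
    key <- sprintf("%04x,%04x", grp, ele)
    tags[[key]] <- list(off = val_off, len = len, vr = vr)
    if (grp == 0x0002 && ele == 0x0010) {
      ts <- trimws(rawToChar(raw[val_off + seq_len(len)]))
      if (ts == "1.2.840.10008.1.2") explicit <- FALSE
      else if (!ts %in% c("1.2.840.10008.1.2.1"))
        stop("unsupported DICOM transfer syntax ", ts, " in ", path)
    }
    pos <- val_off + len
  }
  get_str <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) return(NULL)
    trimws(rawToChar(raw[t$off + seq_len(t$len)]))
  }
  get_num <- function(key) {
    s <- get_str(key)
    if (is.null(s)) NULL else as.numeric(strsplit(s, "\\\\")[[1]])
  }
  get_u16val <- function(key) {
    t <- tags[[key]]
    if (is.null(t)) NULL else u16(t$off)
  }
  rows <- get_u16val("0028,0010"); cols <- get_u16val("0028,0011")
  bits <- get_u16val("0028,0100")
  pixrep <- get_u16val("0028,0103")
  if (is.null(rows) || is.null(cols) || is.null(bits))
    stop("unreadable DICOM file ", path, ": missing image dimensions")
  pd <- tags[["7fe0,0010"]]
  if (is.null(pd)) stop("unreadable DICOM file ", path, ": no pixel data")
  npix <- rows * cols
  pix <- if (bits <= 8L) {
    as.integer(raw[pd$off + seq_len(npix)])
  } else {
    readBin(raw[pd$off + seq_len(2L * npix)], "integer", n = npix, size = 2L,
            signed = identical(pixrep, 1L), endian = "little")
  }
  list(rows = rows, cols = cols,
       pixel = matrix(pix, nrow = cols, ncol = rows),   # column-fastest
       pixel_spacing = get_num("0028,0030"),
       slice_thickness = get_num("0018,0050"),
       spacing_between = get_num("0018,0088"),
       position = get_num("0020,0032"),
       instance = get_num("0020,0013"))
}

.load_dicom_dir <- function(path) {
  if (!dir.exists(path)) stop("cannot read DICOM series: no such directory: ", path)
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  slices <- lapply(files, .parse_dicom_file)
  zpos <- vapply(slices, function(s) {
    if (!is.null(s$position)) s$position[3]
    else if (!is.null(s$instance)) s$instance[1]
    else stop("DICOM slice without position or instance number")
  }, 0)
  ord <- order(zpos)                 # by slice position, never by filename
  slices <- slices[ord]; zpos <- zpos[ord]
  dims <- vapply(slices, function(s) c(s$cols, s$rows), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("DICOM series with inconsistent slice dimensions in ", path)
  arr <- array(0, c(dims[1, 1], dims[2, 1], length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]$pixel
  ps <- slices[[1]]$pixel_spacing
  if (is.null(ps)) ps <- c(1, 1)
  dz <- if (length(slices) > 1L && !is.null(slices[[1]]$position))
    median(diff(zpos))
  else if (!is.null(slices[[1]]$spacing_between)) slices[[1]]$spacing_between
  else if (!is.null(slices[[1]]$slice_thickness)) slices[[1]]$slice_thickness
  else 1
  cbct_volume(arr, spacing = c(ps[2], ps[1], abs(dz)),
              meta = list(source = path, format = "dicom_dir",
                          n_slices = length(slices)))
}
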