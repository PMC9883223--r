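# Computer-calculated (CC) landmark points on the terraced mesh.
#
# A CC point is the centroid of the "tabletop" patch around a seeded
# starting point: mesh vertices within 50 pixels of the start, within a
# one-pixel band along the landmark's fixed anatomical normal, restricted
# to the edge-connected patch containing the start.  Pixels are voxel
# units (0.3 mm isotropic acquisition), so 50 px = 15 mm.

#' The six soft-tissue landmark definitions
#'
#' Fixed anatomical normal directions for the six convex facial
#' landmarks.  The raw vectors use the +/-0.5 component notation (axis
#' convention: +x subject-left, +y subject-backward, +z up), so anterior-
#' facing landmarks point along -y and the columella points 45 degrees
#' down-forward; only the direction is meaningful and `normal_unit` is
#' the normalized form used by all computations.
#'
#' @return A named list of six `landmark_definition` objects
#'   (`Pn`, `Co`, `ULP`, `LLP`, `Ch_r`, `Ch_l`), each with `name`,
#'   `abbreviation`, `normal_raw` and `normal_unit`.
#' @export
#' @examples
#' landmark_catalog()$Pn$normal_raw       # (0, -0.5, 0): anterior
#' landmark_catalog()$Co$normal_unit      # 45 degrees down-forward
landmark_catalog <- function() {
  defs <- list(
    Pn   = list(name = "Pronasale",
                def = "The most anterior point of the nasal tip",
                raw = c(0, -0.5, 0)),
    Co   = list(name = "Columella",
                def = "The most prominent point of the columella crest on the base view of the nose",
                raw = c(0, -0.5, -0.5)),
    ULP  = list(name = "Upper lip point",
                def = "The most anterior point of upper lip",
                raw = c(0, -0.5, 0)),
    LLP  = list(name = "Lower lip point",
                def = "The most anterior point of lower lip",
                raw = c(0, -0.5, 0)),
    Ch_r = list(name = "Cheek_right",
                def = "The most prominent point of the right cheek",
                raw = c(-0.5, -0.5, 0)),
    Ch_l = list(name = "Cheek_left",
                def = "The most prominent point of the left cheek",
                raw = c(0.5, -0.5, 0)))
  out <- lapply(names(defs), function(ab) {
    d <- defs[[ab]]
    structure(list(name = d$name, abbreviation = ab, definition = d$def,
                   normal_raw = d$raw,
                   normal_unit = d$raw / sqrt(sum(d$raw^2))),
              class = "landmark_definition")
  })
  names(out) <- names(defs)
  out
}

#' @export
print.landmark_definition <- function(x, ...) {
  cat(sprintf("%s (%s): normal (%s)\n", x$name, x$abbreviation,
              paste(format(x$normal_raw), collapse = ", ")))
  invisible(x)
}

# Resolve a landmark argument: abbreviation string or definition object.
.as_landmark <- function(landmark) {
  if (inherits(landmark, "landmark_definition")) return(landmark)
  cat_ <- landmark_catalog()
  if (is.character(landmark) && landmark %in% names(cat_))
    return(cat_[[landmark]])
  stop("unknown landmark: ", landmark)
}

#' Snap a point to the nearest mesh vertex
#'
#' Euclidean nearest vertex; ties are broken toward the lowest vertex
#' index, which makes the whole pipeline deterministic.
#'
#' @param point Length-3 numeric, voxel coordinates.
#' @param mesh A `triangle_mesh`.
#' @return The 1-based vertex index.
#' @export
snap_to_surface <- function(point, mesh) {
  stopifnot(nrow(mesh$vertices) > 0L)
  d2 <- (mesh$vertices[, 1] - point[1])^2 + (mesh$vertices[, 2] - point[2])^2 +
    (mesh$vertices[, 3] - point[3])^2
  which.min(d2)                      # first minimum = lowest index on ties
}

#' Find the tabletop patch containing a starting point
#'
#' Step 1 of the CC-point algorithm: from the (snapped) starting point,
#' keep mesh vertices within `radius_px` Euclidean distance, keep those
#' within `band_px` of the start along the landmark's unit normal (a slab
#' of thickness `2 * band_px` centred on the start), and restrict to the
#' edge-connected patch of the mesh containing the start — so two
#' same-height tabletops, as on a centrally grooved lower lip, are never
#' merged.
#'
#' @param mesh A `triangle_mesh`.
#' @param start Length-3 numeric starting point in voxel coordinates
#'   (snapped to the nearest vertex first).
#' @param landmark A `landmark_definition` or abbreviation string.
#' @param radius_px Neighbourhood radius in pixels (default 50).
#' @param band_px Normal-band half-thickness in pixels (default 1).
#' @return An object of class `tabletop_region` with the member vertex
#'   indices, the snapped start, and the filter parameters.
#' @export
find_tabletop <- function(mesh, start, landmark, radius_px = 50, band_px = 1) {
  landmark <- .as_landmark(landmark)
  n_hat <- landmark$normal_unit
  start_idx <- snap_to_surface(start, mesh)
  if (sum(mesh$normals[start_idx, ] * n_hat) <= 0)
    stop("starting point not on the landmark-facing surface (",
         landmark$abbreviation, ")")
  s <- mesh$vertices[start_idx, ]
  rel <- sweep(mesh$vertices, 2L, s)
  within_ball <- rowSums(rel^2) <= radius_px^2
  within_band <- abs(rel %*% n_hat) <= band_px
  cand <- which(within_ball & within_band)
  # edge-connected patch containing the start, within the candidate set
  f <- mesh$faces
  keep <- logical(nrow(mesh$vertices))
  keep[cand] <- TRUE
  fe <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  fe <- fe[keep[fe[, 1]] & keep[fe[, 2]], , drop = FALSE]
  members <- start_idx
  if (nrow(fe) > 0L) {
    adj <- split(c(fe[, 2], fe[, 1]), c(fe[, 1], fe[, 2]))
    visited <- logical(nrow(mesh$vertices))
    visited[start_idx] <- TRUE
    frontier <- start_idx
    while (length(frontier) > 0L) {
      nb <- unique(unlist(adj[as.character(frontier)], use.names = FALSE))
      nb <- nb[!visited[nb]]
      visited[nb] <- TRUE
      frontier <- nb
    }
    members <- which(visited)
  }
  structure(list(landmark = landmark, start_index = start_idx,
                 start_point = s, members = members,
                 radius_px = radius_px, band_px = band_px),
            class = "tabletop_region")
}

#' @export
print.tabletop_region <- function(x, ...) {
  cat(sprintf("tabletop_region (%s): %d member vertices around (%s)\n",
              x$landmark$abbreviation, length(x$members),
              paste(format(x$start_point), collapse = ", ")))
  invisible(x)
}

#' Coordinate conversion from voxel to reference millimetre space
#'
#' @param center Voxel-space origin subtracted before scaling; the
#'   reference convention is (266.5, 266.5, 266).
#' @param scale mm per voxel (0.3 for the emulated acquisition).
#' @return A `coordinate_conversion` object.
#' @export
coordinate_conversion <- function(center = c(266.5, 266.5, 266), scale = 0.3) {
  stopifnot(length(center) == 3L, scale > 0)
  structure(list(center = as.numeric(center), scale = as.numeric(scale)),
            class = "coordinate_conversion")
}

#' Convert voxel coordinates to reference millimetres
#'
#' `mm_i = (voxel_i - center_i) * scale`, an exact affine bijection;
#' [convert_mm_to_voxel()] is its inverse.
#'
#' @param point Length-3 numeric or an n x 3 matrix of voxel coordinates.
#' @param conversion A [coordinate_conversion()].
#' @return Coordinates in mm, same shape as `point`.
#' @export
#' @examples
#' convert_voxel_to_mm(c(266.5, 266.5, 266))   # the reference origin
#' convert_voxel_to_mm(c(276.5, 266.5, 266))   # 10 voxels = 3 mm along x
convert_voxel_to_mm <- function(point, conversion = coordinate_conversion()) {
  if (is.matrix(point)) sweep(point, 2L, conversion$center) * conversion$scale
  else (point - conversion$center) * conversion$scale
}

#' @rdname convert_voxel_to_mm
#' @export
convert_mm_to_voxel <- function(point, conversion = coordinate_conversion()) {
  if (is.matrix(point)) sweep(point / conversion$scale, 2L, -conversion$center)
  else point / conversion$scale + conversion$center
}

#' Euclidean distance of a point from the reference origin
#'
#' The landmark distance `d = sqrt(x^2 + y^2 + z^2)` recorded alongside
#' every digitized coordinate.
#'
#' @param point Length-3 numeric (mm) or an n x 3 matrix.
#' @return Scalar (or vector) Euclidean norm.
#' @export
euclidean_d <- function(point) {
  if (is.matrix(point)) sqrt(rowSums(point^2)) else sqrt(sum(point^2))
}

#' Compute the CC point of a tabletop region
#'
#' Step 2 of the algorithm: the unweighted arithmetic mean of the member
#' vertex positions, converted to reference millimetres, with the
#' Euclidean distance `d`.
#'
#' @param region A [find_tabletop()] result.
#' @param mesh The mesh the region indexes into.
#' @param conversion A [coordinate_conversion()].
#' @return An object of class `cc_point` with `voxel_coords`,
#'   `mm_coords`, `d` and `n_members`.
#' @export
compute_cc_point <- function(region, mesh,
                             conversion = coordinate_conversion()) {
  stopifnot(inherits(region, "tabletop_region"), length(region$members) > 0L)
  v <- mesh$vertices[region$members, , drop = FALSE]
  voxel <- colMeans(v)
  mm <- convert_voxel_to_mm(voxel, conversion)
  structure(list(landmark = region$landmark$abbreviation,
                 voxel_coords = voxel, mm_coords = mm,
                 d = euclidean_d(mm), n_members = length(region$members)),
            class = "cc_point")
}

#' @export
print.cc_point <- function(x, ...) {
  cat(sprintf("cc_point %s: voxel (%s), mm (%s), d = %.4f mm, %d members\n",
              x$landmark, paste(format(x$voxel_coords), collapse = ", "),
              paste(format(round(x$mm_coords, 4)), collapse = ", "),
              x$d, x$n_members))
  invisible(x)
}

#' In-plane perturbation directions for a landmark
#'
#' The screen-space "up, down, left, right" of the consistency
#' examination, realized in the tangent plane of the landmark's unit
#' normal: the projections of the global z axis (up/down) and of the
#' global x axis (left/right) onto the plane perpendicular to the normal,
#' normalized.  For anterior-facing landmarks (normal -y) this reduces to
#' +/-z and +/-x.
#'
#' @param landmark A `landmark_definition` or abbreviation.
#' @return A 4 x 3 matrix with rows `up`, `down`, `left`, `right`.
#' @export
perturbation_directions <- function(landmark) {
  n_hat <- .as_landmark(landmark)$normal_unit
  proj <- function(a) {
    p <- a - sum(a * n_hat) * n_hat
    if (sqrt(sum(p^2)) < 1e-8) {    # axis parallel to the normal: fall back
      a2 <- c(0, 1, 0)
      p <- a2 - sum(a2 * n_hat) * n_hat
    }
    p / sqrt(sum(p^2))
  }
  up <- proj(c(0, 0, 1)); left <- proj(c(1, 0, 0))
  out <- rbind(up = up, down = -up, left = left, right = -left)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Perturbation-consistency examination of a CC point
#'
#' Moves the CC point by each offset along each of the four in-plane
#' directions, snaps the moved point back to the surface, recomputes a
#' second CC point from it with the same filter parameters, and reports
#' the distance (in pixels) between the original and second CC point.
#' On a proper tabletop every moved point lands back on the same patch
#' and all distances are zero.  A moved point that snaps off the original
#' patch is reported with its nonzero distance, never suppressed.
#'
#' @param mesh A `triangle_mesh`.
#' @param region The original [find_tabletop()] region.
#' @param offsets_px Perturbation magnitudes in pixels.
#' @param directions Optional 4 x 3 matrix of unit directions; defaults
#'   to [perturbation_directions()] of the region's landmark.
#' @param conversion A [coordinate_conversion()] (used only to fill the
#'   second CC points' mm fields).
#' @return A data frame with columns `offset_px`, `direction`,
#'   `delta_d_px` (pixel distance between the original and second CC
#'   point) and `n_members_second`.
#' @export
consistency_check <- function(mesh, region,
                              offsets_px = seq(0.5, 4, by = 0.5),
                              directions = NULL,
                              conversion = coordinate_conversion()) {
  stopifnot(inherits(region, "tabletop_region"))
  if (is.null(directions)) directions <- perturbation_directions(region$landmark)
  if (is.null(rownames(directions)))
    rownames(directions) <- paste0("dir", seq_len(nrow(directions)))
  cc0 <- compute_cc_point(region, mesh, conversion)
  grid <- expand.grid(offset_px = offsets_px,
                      direction = rownames(directions),
                      stringsAsFactors = FALSE)
  res <- vapply(seq_len(nrow(grid)), function(r) {
    moved <- cc0$voxel_coords +
      grid$offset_px[r] * directions[grid$direction[r], ]
    reg2 <- find_tabletop(mesh, moved, region$landmark,
                          radius_px = region$radius_px,
                          band_px = region$band_px)
    cc2 <- compute_cc_point(reg2, mesh, conversion)
    c(sqrt(sum((cc2$voxel_coords - cc0$voxel_coords)^2)), cc2$n_members)
  }, numeric(2))
  grid$delta_d_px <- res[1, ]
  grid$n_members_second <- as.integer(res[2, ])
  grid
}
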