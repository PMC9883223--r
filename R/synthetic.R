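# Synthetic face phantoms with analytically known protrusion apices, and
# simulated rater series — every pipeline stage is testable without
# patient data.

# Run fn with a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  fn()
}

#' Specify a face-like phantom volume
#'
#' A two-intensity "head" (ellipsoid) with protruding bumps whose apices
#' are placed analytically along each landmark's anatomical normal.
#' Each bump is a sphere truncated by a plane perpendicular to the
#' landmark's Table-style normal: after binary marching cubes the facet
#' voxelizes into exactly the tabletop geometry the CC-point method
#' assumes — a flat plateau for anterior (axis-aligned) normals, and for
#' the 45-degree normals a zigzag staircase whose vertices all lie at
#' one constant level along the normal, which is the diagonal analogue
#' of a tabletop.  A small amount of subject-level geometric variation
#' (head position and size) is drawn deterministically from the seed, so
#' a set of seeds behaves like a cohort of subjects with non-constant
#' true landmark positions.
#'
#' @param shape Grid side length (cube); 160 keeps the full pipeline fast,
#'   533 mirrors the full 16 cm / 0.3 mm field of view.
#' @param spacing Voxel size in mm.
#' @param landmarks Character vector of bump landmarks (subset of the
#'   six catalog abbreviations).
#' @param bump_radius Sphere radius of each bump, in voxels.
#' @param facet_depth Truncation depth of the apex facet below the
#'   sphere's extreme point (voxels); the default 2.5 with radius 8 gives
#'   a facet of radius `sqrt(2 * 16 * 2 - 4)` (about 7.5 voxels), so the
#'   apex tabletop spans well over 5 vertices and comfortably contains
#'   every consistency-examination offset up to 4 px.
#' @param bump_height Protrusion of each apex above the head surface
#'   (voxels); a scalar or a per-landmark named vector.  The defaults
#'   differ between neighbouring midline landmarks (the nose protrudes
#'   more than the lips) so that every anterior facet lies well in front
#'   of the head's own anterior pole and each tabletop's normal-band
#'   slab is separated in depth from every other protrusion.
#' @param tissue,air Intensity levels of the two classes.
#' @param noise_sd Gaussian intensity noise SD added per voxel.
#' @param subject_variation SD-like scale of the deterministic
#'   subject-to-subject jitter of head centre (voxels) and axis scale.
#' @param seed Integer seed; fixes both the subject geometry and the
#'   noise, so generation is fully reproducible.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(shape = 160L, spacing = 0.3,
                         landmarks = c("Pn", "Co", "ULP", "LLP",
                                       "Ch_r", "Ch_l"),
                         bump_radius = 8, facet_depth = 2.5,
                         bump_height = c(Pn = 8, Co = 6, ULP = 6, LLP = 10,
                                         Ch_r = 6, Ch_l = 6),
                         tissue = 180, air = 5, noise_sd = 10,
                         subject_variation = 2, seed = 1L) {
  shape <- rep(as.integer(shape), length.out = 3L)
  stopifnot(all(shape >= 32L), bump_radius > 0, all(bump_height > 0),
            facet_depth > 0, facet_depth < bump_radius,
            noise_sd >= 0, tissue != air)
  cat_ <- landmark_catalog()
  stopifnot(all(landmarks %in% names(cat_)))
  if (is.null(names(bump_height)))
    bump_height <- stats::setNames(rep(bump_height, length.out = length(landmarks)),
                                   landmarks)
  stopifnot(all(landmarks %in% names(bump_height)))
  # anatomical anchor directions from the head centre (+x left, +y back,
  # +z up).  Each landmark is, by anatomical definition, the most
  # prominent surface point along its own normal, so the 45-degree
  # landmarks (columella, cheeks) are anchored at the ellipsoid tangent
  # points of their normal directions; the anterior landmarks are spread
  # along the facial midline.
  anchor_dirs <- list(
    Pn   = c(0, -1, 0.42),
    Co   = c(0, -0.60, -0.80),
    ULP  = c(0, -1, -0.28),
    LLP  = c(0, -1, -0.62),
    Ch_r = c(-0.641, -0.767, 0),
    Ch_l = c(0.641, -0.767, 0))
  geom <- .with_seed(seed, function() {
    list(center = shape * c(0.50, 0.62, 0.50) +
           stats::runif(3, -subject_variation, subject_variation),
         semiaxes = shape * c(0.33, 0.36, 0.42) *
           (1 + stats::runif(3, -0.015, 0.015) * subject_variation))
  })
  bumps <- lapply(landmarks, function(ab) {
    u <- anchor_dirs[[ab]]; u <- u / sqrt(sum(u^2))
    # ellipsoid surface point along u from the centre
    t_hit <- 1 / sqrt(sum((u / geom$semiaxes)^2))
    p0 <- geom$center + t_hit * u
    n_hat <- cat_[[ab]]$normal_unit
    apex <- p0 + bump_height[[ab]] * n_hat
    list(landmark = ab, apex = apex, radius = bump_radius,
         facet_depth = facet_depth, orientation = n_hat,
         center = apex - (bump_radius - facet_depth) * n_hat)
  })
  names(bumps) <- landmarks
  structure(list(shape = shape, spacing = spacing, bumps = bumps,
                 head = geom, tissue = tissue, air = air,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom volume with ground truth
#'
#' Voxelizes the union of the head ellipsoid and the spherical-cap bumps
#' into a two-level intensity volume, adds Gaussian intensity noise, and
#' returns the exact apex coordinates of every bump.  Bit-identical for a
#' fixed spec.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `volume` (a [cbct_volume()]) and `truth`, a data
#'   frame with the landmark abbreviations, continuous apex voxel
#'   coordinates, and the orientation vectors.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = 64, landmarks = "Pn",
#'                                     bump_radius = 8, bump_height = 4))
#' ph$truth
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  for (b in spec$bumps) {
    lo <- b$center - b$radius; hi <- b$center + b$radius
    if (any(lo < 1) || any(hi > d))
      stop("bump ", b$landmark, " extends outside the grid")
    rel <- (b$apex - spec$head$center) / spec$head$semiaxes
    if (sum(rel^2) <= 1)
      stop("bump ", b$landmark, " apex is not outside the base surface")
  }
  x <- seq_len(d[1]); y <- seq_len(d[2]); z <- seq_len(d[3])
  cx <- spec$head$center; ax <- spec$head$semiaxes
  ex <- ((x - cx[1]) / ax[1])^2
  ey <- ((y - cx[2]) / ax[2])^2
  ez <- ((z - cx[3]) / ax[3])^2
  inside <- outer(outer(ex, ey, `+`), ez, `+`) <= 1
  for (b in spec$bumps) {
    xr <- max(1, floor(b$center[1] - b$radius)):min(d[1], ceiling(b$center[1] + b$radius))
    yr <- max(1, floor(b$center[2] - b$radius)):min(d[2], ceiling(b$center[2] + b$radius))
    zr <- max(1, floor(b$center[3] - b$radius)):min(d[3], ceiling(b$center[3] + b$radius))
    bx <- (xr - b$center[1])^2
    by <- (yr - b$center[2])^2
    bz <- (zr - b$center[3])^2
    sph <- outer(outer(bx, by, `+`), bz, `+`) <= b$radius^2
    # truncate by the facet plane through the apex, perpendicular to the
    # landmark normal: (p - apex) . n <= 0
    n_hat <- b$orientation
    proj <- outer(outer(n_hat[1] * (xr - b$apex[1]),
                        n_hat[2] * (yr - b$apex[2]), `+`),
                  n_hat[3] * (zr - b$apex[3]), `+`)
    inside[xr, yr, zr] <- inside[xr, yr, zr] | (sph & proj <= 0)
  }
  vol <- array(ifelse(inside, spec$tissue, spec$air), d)
  if (spec$noise_sd > 0)
    vol <- vol + .with_seed(spec$seed + 1L, function()
      array(stats::rnorm(prod(d), 0, spec$noise_sd), d))
  truth <- do.call(rbind, lapply(spec$bumps, function(b)
    data.frame(landmark = b$landmark, x = b$apex[1], y = b$apex[2],
               z = b$apex[3], nx = b$orientation[1], ny = b$orientation[2],
               nz = b$orientation[3])))
  rownames(truth) <- NULL
  list(volume = cbct_volume(vol, spacing = spec$spacing,
                            meta = list(source = "phantom",
                                        seed = spec$seed)),
       truth = truth)
}

#' Specify simulated rater measurements
#'
#' Emulates a digitization study: each simulated click is the true
#' coordinate plus a constant per-rater bias plus isotropic Gaussian
#' per-click jitter.
#'
#' @param truth Data frame with columns `subject`, `landmark`, `x`, `y`,
#'   `z` in mm (e.g. converted phantom apices or CC points).
#' @param raters Rater identifiers.
#' @param sessions Session identifiers.
#' @param bias Per-rater constant offset: a raters x 3 matrix, a single
#'   length-3 vector applied to every rater, or 0.
#' @param jitter_sd Per-click isotropic jitter SD in mm (>= 0).
#' @param seed Integer seed.
#' @return A `rater_spec` object.
#' @export
rater_spec <- function(truth, raters = c("Ob1", "Ob2"), sessions = 1:2,
                       bias = 0, jitter_sd = 0.5, seed = 1L) {
  truth <- as.data.frame(truth)
  stopifnot(all(c("subject", "landmark", "x", "y", "z") %in% names(truth)),
            jitter_sd >= 0)
  if (!is.matrix(bias))
    bias <- matrix(rep(bias, length.out = 3L * length(raters)),
                   nrow = length(raters), byrow = TRUE)
  stopifnot(nrow(bias) == length(raters), ncol(bias) == 3L)
  rownames(bias) <- raters
  structure(list(truth = truth, raters = raters, sessions = sessions,
                 bias = bias, jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "rater_spec")
}

#' Simulate rater measurement series
#'
#' @param spec A [rater_spec()].
#' @return A long-format data frame `rater`, `session`, `subject`,
#'   `landmark`, `x`, `y`, `z` (mm), reproducible for a fixed spec.
#' @export
generate_rater_series <- function(spec) {
  stopifnot(inherits(spec, "rater_spec"))
  .with_seed(spec$seed, function() {
    out <- list()
    for (rt in spec$raters) for (ss in spec$sessions) {
      g <- spec$truth
      n <- nrow(g)
      jit <- if (spec$jitter_sd > 0)
        matrix(stats::rnorm(3L * n, 0, spec$jitter_sd), n, 3L)
      else matrix(0, n, 3L)
      out[[length(out) + 1L]] <- data.frame(
        rater = rt, session = ss, subject = g$subject, landmark = g$landmark,
        x = g$x + spec$bias[rt, 1] + jit[, 1],
        y = g$y + spec$bias[rt, 2] + jit[, 2],
        z = g$z + spec$bias[rt, 3] + jit[, 3])
    }
    do.call(rbind, out)
  })
}
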