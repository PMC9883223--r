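# End-to-end pipeline: simulate -> binarize -> reconstruct -> ccpoint ->
# consistency -> reliability, with a JSON config, a manifest, and CSV
# artifacts at every stage.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with defaults equal to the
#' reference parameter set: 50-pixel neighbourhood radius, 1-pixel
#' normal band, perturbation offsets 0.5..4.0 px in steps of 0.5,
#' conversion centre (266.5, 266.5, 266) and scale 0.3 mm/voxel.
#'
#' @param outdir Output directory for stage artifacts.
#' @param seed Integer seed driving phantom generation and rater
#'   simulation.
#' @param radius_px,band_px CC-point filter parameters (pixels).
#' @param offsets_px Consistency-examination offsets (pixels).
#' @param center,scale Voxel-to-mm conversion parameters.
#' @param phantom A [phantom_spec()] or `NULL` to use defaults seeded by
#'   `seed` (used by the `simulate` stage).
#' @param volume_path,volume_format Existing volume input for the
#'   `binarize` stage (alternative to simulation).
#' @param starts_path CSV/JSON of starting points `{landmark, x, y, z}`
#'   in voxel coordinates; when `NULL` and a phantom is simulated, the
#'   phantom's true apices serve as the seeded clicks.
#' @param invert Contrast-inversion flag for binarization.
#' @param bins Otsu histogram bins.
#' @param smooth_normals Normal-smoothing iterations after meshing.
#' @param jitter_sd,n_subjects Rater-simulation parameters for the
#'   `reliability` stage.
#' @return A `pipeline_config` object (validates on construction).
#' @export
pipeline_config <- function(outdir = tempfile("ccmark_run_"), seed = 1L,
                            radius_px = 50, band_px = 1,
                            offsets_px = seq(0.5, 4, by = 0.5),
                            center = c(266.5, 266.5, 266), scale = 0.3,
                            phantom = NULL, volume_path = NULL,
                            volume_format = NULL, starts_path = NULL,
                            invert = FALSE, bins = 256L,
                            smooth_normals = 0L,
                            jitter_sd = 0.5, n_subjects = 10L) {
  stopifnot(radius_px > 0, band_px > 0, all(offsets_px >= 0),
            length(center) == 3L, scale > 0, n_subjects >= 1L)
  structure(list(outdir = outdir, seed = as.integer(seed),
                 radius_px = radius_px, band_px = band_px,
                 offsets_px = offsets_px,
                 conversion = coordinate_conversion(center, scale),
                 phantom = phantom, volume_path = volume_path,
                 volume_format = volume_format, starts_path = starts_path,
                 invert = invert, bins = as.integer(bins),
                 smooth_normals = as.integer(smooth_normals),
                 jitter_sd = jitter_sd, n_subjects = as.integer(n_subjects)),
            class = "pipeline_config")
}

#' Read starting points
#'
#' @param path CSV or JSON file with fields `landmark`, `x`, `y`, `z`
#'   (voxel coordinates).
#' @return A data frame of starting points.
#' @export
read_starting_points <- function(path) {
  pts <- if (grepl("\\.json$", path)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("landmark", "x", "y", "z") %in% names(pts)))
  pts
}

#' Compute CC points for a table of starting points
#'
#' Runs [find_tabletop()] and [compute_cc_point()] for every row of a
#' starting-point table.
#'
#' @param mesh A `triangle_mesh`.
#' @param starts Data frame `landmark`, `x`, `y`, `z` (voxel coords).
#' @param radius_px,band_px Filter parameters.
#' @param conversion A [coordinate_conversion()].
#' @return A list with `cc_points` (list of `cc_point` objects, named by
#'   landmark with suffixes on repeats) and `table`: a data frame with
#'   columns `landmark`, `x_vox`, `y_vox`, `z_vox`, `x_mm`, `y_mm`,
#'   `z_mm`, `d_mm`, `n_members`.
#' @export
cc_points_from_mesh <- function(mesh, starts, radius_px = 50, band_px = 1,
                                conversion = coordinate_conversion()) {
  stopifnot(nrow(starts) >= 1L)
  ccs <- lapply(seq_len(nrow(starts)), function(r) {
    reg <- find_tabletop(mesh, c(starts$x[r], starts$y[r], starts$z[r]),
                         starts$landmark[r], radius_px, band_px)
    compute_cc_point(reg, mesh, conversion)
  })
  names(ccs) <- make.unique(starts$landmark)
  tab <- do.call(rbind, lapply(ccs, function(cc)
    data.frame(landmark = cc$landmark,
               x_vox = cc$voxel_coords[1], y_vox = cc$voxel_coords[2],
               z_vox = cc$voxel_coords[3],
               x_mm = cc$mm_coords[1], y_mm = cc$mm_coords[2],
               z_mm = cc$mm_coords[3], d_mm = cc$d,
               n_members = cc$n_members)))
  rownames(tab) <- NULL
  list(cc_points = ccs, table = tab)
}

# Fail with a stage-named error so pipeline aborts are attributable.
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes the stages in order — simulate (unless an input volume is
#' given), binarize, reconstruct, ccpoint, consistency, reliability —
#' writing each stage's artifact plus a manifest sufficient to re-run
#' the deterministic stages bit-identically.  Any stage failure aborts
#' with an error naming the stage.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`): artifact paths, parameter values, package
#'   version, and seed.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  truth <- NULL

  if (is.null(config$volume_path)) {
    ph <- .stage("simulate", {
      spec <- if (is.null(config$phantom)) phantom_spec(seed = config$seed)
      else config$phantom
      generate_phantom(spec)
    })
    volume <- ph$volume
    truth <- ph$truth
    paths$volume <- file.path(config$outdir, "phantom.nii.gz")
    paths$truth <- file.path(config$outdir, "truth.csv")
    .stage("simulate", {
      write_nifti_volume(volume, paths$volume)
      utils::write.csv(truth, paths$truth, row.names = FALSE)
    })
  } else {
    volume <- .stage("binarize",
                     load_volume(config$volume_path, config$volume_format))
    paths$volume <- config$volume_path
  }

  mask <- .stage("binarize",
                 binarize_soft_tissue(volume, invert = config$invert,
                                      bins = config$bins))
  paths$mask <- file.path(config$outdir, "mask.nrrd")
  .stage("binarize", write_nrrd(mask, paths$mask))

  mesh <- .stage("reconstruct", {
    m <- extract_isosurface(mask)
    if (config$smooth_normals > 0L)
      m <- smooth_preserving_plateaus(m, config$smooth_normals)
    m
  })
  paths$mesh <- file.path(config$outdir, "mesh.ply")
  .stage("reconstruct", write_ply(mesh, paths$mesh, format = "binary"))

  starts <- .stage("ccpoint", {
    if (!is.null(config$starts_path)) read_starting_points(config$starts_path)
    else if (!is.null(truth)) truth[, c("landmark", "x", "y", "z")]
    else stop("no starting points: provide starts_path or simulate a phantom")
  })
  cc <- .stage("ccpoint",
               cc_points_from_mesh(mesh, starts, config$radius_px,
                                   config$band_px, config$conversion))
  paths$cc <- file.path(config$outdir, "cc.csv")
  .stage("ccpoint", utils::write.csv(cc$table, paths$cc, row.names = FALSE))

  grids <- .stage("consistency", {
    do.call(rbind, lapply(names(cc$cc_points), function(nm) {
      ccp <- cc$cc_points[[nm]]
      reg <- find_tabletop(mesh, ccp$voxel_coords, ccp$landmark,
                           config$radius_px, config$band_px)
      g <- consistency_check(mesh, reg, config$offsets_px,
                             conversion = config$conversion)
      cbind(landmark = ccp$landmark, g)
    }))
  })
  paths$consistency <- file.path(config$outdir, "consistency.csv")
  .stage("consistency",
         utils::write.csv(grids, paths$consistency, row.names = FALSE))

  reliability <- .stage("reliability", {
    base <- if (!is.null(truth)) truth else cc$table
    mm <- if (!is.null(truth))
      convert_voxel_to_mm(as.matrix(truth[, c("x", "y", "z")]),
                          config$conversion)
    else as.matrix(cc$table[, c("x_mm", "y_mm", "z_mm")])
    # emulate a digitization study: a cohort of subjects scattered around
    # the measured landmark set (anatomical between-subject SD ~ 2 mm),
    # each digitized twice by two simulated raters
    n_lm <- nrow(base)
    truth_mm <- .with_seed(config$seed + 500L, function() {
      do.call(rbind, lapply(seq_len(config$n_subjects), function(s)
        data.frame(subject = s, landmark = base$landmark,
                   x = mm[, 1] + stats::rnorm(n_lm, 0, 2),
                   y = mm[, 2] + stats::rnorm(n_lm, 0, 2),
                   z = mm[, 3] + stats::rnorm(n_lm, 0, 2))))
    })
    series <- generate_rater_series(
      rater_spec(truth_mm, jitter_sd = config$jitter_sd,
                 seed = config$seed + 1000L))
    reliability_report(series)
  })
  paths$reliability <- file.path(config$outdir, "reliability_inter.csv")
  .stage("reliability", {
    utils::write.csv(reliability$inter, paths$reliability, row.names = FALSE)
    utils::write.csv(reliability$intra,
                     file.path(config$outdir, "reliability_intra.csv"),
                     row.names = FALSE)
  })

  manifest <- list(
    package = "ccmark",
    version = as.character(utils::packageVersion("ccmark")),
    seed = config$seed,
    parameters = list(radius_px = config$radius_px, band_px = config$band_px,
                      offsets_px = config$offsets_px,
                      center = config$conversion$center,
                      scale = config$conversion$scale,
                      invert = config$invert, bins = config$bins,
                      smooth_normals = config$smooth_normals,
                      jitter_sd = config$jitter_sd),
    artifacts = paths,
    consistency_max_delta_px = max(grids$delta_d_px))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
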