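# End-to-end analysis: read/generate -> binarize -> clean -> frame ->
# split plates -> partition regions -> per-plate/region porosity ->
# width/thickness profile -> pore map, with a machine-readable report.

#' Pipeline run configuration
#'
#' Exactly one of `input` (grayscale TIFF stack), `mask` (pre-binarized
#' TIFF stack), or `phantom` (a [phantom_config()]) must be supplied.
#'
#' @param input Path to a grayscale multi-page TIFF.
#' @param mask Path to a binarized multi-page TIFF.
#' @param phantom A `phantom_config` for synthetic mode.
#' @param voxel_size_um Voxel size (required for files without a JSON
#'   sidecar).
#' @param threshold Numeric threshold or `"auto"` (Otsu).
#' @param min_component_voxels Artifact-removal component cutoff.
#' @param closing_radius_um In-plane envelope closing radius; in
#'   phantom mode it defaults to 5 x the maximum phantom pore radius,
#'   otherwise it is required.
#' @param axial_closing_radius_um Axial semi-axis of the closing
#'   element (see [fill_envelope()]); phantom mode defaults to half the
#'   plate thickness, `NULL` keeps the spherical ball.
#' @param region_bounds_deg Basal/middle and middle/apex cut angles.
#' @param frame `"fit"` to fit the spiral frame from the mask, or a
#'   landmarks list as in [fit_spiral_frame()]. In phantom mode the
#'   construction frame is used.
#' @param pitch_um_per_turn Spiral pitch; estimated from the mask if
#'   `NULL` and not supplied by the frame.
#' @param profile_step_deg Angular step of the width/thickness profile.
#' @param delta_deg Angular slab width of profile samples.
#' @param n_bands Radial bands of the pore map.
#' @param min_radius_um Optional inner-radius clip (spiral-ganglion
#'   exclusion).
#' @param simplify_fraction Optional mesh decimation fraction.
#' @param envelope_method `"plate"` (height-field shrink-wrap, the
#'   right choice for the thin lamina plates) or `"ball"` (spherical
#'   closing); see [fill_envelope()].
#' @param output_dir Directory for CSV/JSON/TIFF/STL outputs (`NULL` =
#'   no files written).
#' @param write_meshes Write plate and envelope meshes as binary STL.
#' @param seed Seed for all stochastic steps.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(input = NULL, mask = NULL, phantom = NULL,
                       voxel_size_um = NULL, threshold = "auto",
                       min_component_voxels = 200,
                       closing_radius_um = NULL,
                       axial_closing_radius_um = NULL,
                       region_bounds_deg = c(360, 630),
                       frame = "fit", pitch_um_per_turn = NULL,
                       profile_step_deg = 45, delta_deg = 2,
                       n_bands = 3, min_radius_um = NULL,
                       simplify_fraction = NULL,
                       envelope_method = c("plate", "ball"),
                       output_dir = NULL, write_meshes = FALSE,
                       seed = 1L) {
  envelope_method <- match.arg(envelope_method)
  modes <- c(!is.null(input), !is.null(mask), !is.null(phantom))
  if (sum(modes) != 1)
    stop("exactly one of input, mask, or phantom must be supplied")
  if (!is.null(phantom) && !inherits(phantom, "phantom_config"))
    stop("phantom must be a phantom_config")
  if (is.null(closing_radius_um) && is.null(phantom))
    stop("closing_radius_um is required for image inputs (choose it from the observed pore sizes)")
  if (is.null(closing_radius_um)) {
    closing_radius_um <- 3 * max(phantom$pore_radius_um_range)
    if (is.null(axial_closing_radius_um))
      axial_closing_radius_um <- phantom$voxel_size_um / 2
  }
  structure(list(input = input, mask = mask, phantom = phantom,
                 voxel_size_um = voxel_size_um, threshold = threshold,
                 min_component_voxels = min_component_voxels,
                 closing_radius_um = closing_radius_um,
                 axial_closing_radius_um = axial_closing_radius_um,
                 region_bounds_deg = region_bounds_deg, frame = frame,
                 pitch_um_per_turn = pitch_um_per_turn,
                 profile_step_deg = profile_step_deg,
                 delta_deg = delta_deg, n_bands = n_bands,
                 min_radius_um = min_radius_um,
                 simplify_fraction = simplify_fraction,
                 envelope_method = envelope_method,
                 output_dir = output_dir, write_meshes = write_meshes,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Flat YAML keys matching the arguments of [run_config()]; the
#' `phantom` key may hold a nested map of [phantom_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$phantom)) y$phantom <- do.call(phantom_config, y$phantom)
  do.call(run_config, y)
}

#' Run the full OSL morphometry pipeline
#'
#' Executes segmentation, plate separation, region partitioning,
#' per-plate/region filled-envelope porosity, the width/thickness
#' profile, and the pore-distribution map; in phantom mode a
#' ground-truth comparison block is added. All tunable parameters in
#' force are recorded in the report. Deterministic for a fixed
#' configuration and seed.
#'
#' @param config A `run_config`.
#' @return An `osl_report` list; if `config$output_dir` is set, CSV,
#'   JSON, TIFF, and (optionally) STL outputs are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  warnings_log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    warnings_log <<- c(warnings_log, msg)
    message(msg)
  }

  truth <- NULL
  if (!is.null(config$phantom)) {
    ph <- generate_phantom(config$phantom)
    vol <- ph$volume
    truth <- ph$truth
  } else if (!is.null(config$input)) {
    vol <- read_volume_tiff(config$input, config$voxel_size_um)
  } else vol <- NULL

  if (!is.null(vol)) {
    mask <- binarize(vol, config$threshold)
    mask <- remove_artifacts(mask, config$min_component_voxels)
  } else {
    mask <- read_mask_tiff(config$mask, config$voxel_size_um)
    mask <- remove_artifacts(mask, config$min_component_voxels)
  }

  if (!is.null(truth)) {
    frame <- truth$frame
  } else if (identical(config$frame, "fit")) {
    frame <- fit_spiral_frame(mask)
  } else {
    frame <- fit_spiral_frame(mask, landmarks = config$frame)
  }
  if (!is.null(config$pitch_um_per_turn)) {
    frame$pitch_um_per_turn <- config$pitch_um_per_turn
    if (is.null(frame$base_offset_um)) {
      fr2 <- estimate_pitch(mask, frame)
      frame$base_offset_um <- fr2$base_offset_um
    }
  } else if (is.null(frame$pitch_um_per_turn)) {
    frame <- estimate_pitch(mask, frame)
  }

  plates <- split_plates(mask, frame)
  regions <- partition_regions(mask, frame, config$region_bounds_deg)

  # no exclusion mask here: inter-plate pillar stubs make the plates
  # touch at the gap mid-surface by construction, which would trip the
  # merge detector on legitimate geometry
  por <- rbind(
    plate_porosity(plates$vp, regions, config$closing_radius_um,
                   axial_radius_um = config$axial_closing_radius_um,
                   simplify_fraction = config$simplify_fraction,
                   plate = "vp", envelope_method = config$envelope_method,
                   frame = frame),
    plate_porosity(plates$tp, regions, config$closing_radius_um,
                   axial_radius_um = config$axial_closing_radius_um,
                   simplify_fraction = config$simplify_fraction,
                   plate = "tp", envelope_method = config$envelope_method,
                   frame = frame))

  prof <- spiral_profile(mask, frame, step_deg = config$profile_step_deg,
                         regions = regions, delta_deg = config$delta_deg,
                         min_radius_um = config$min_radius_um)

  pore_maps <- list()
  envs <- list()
  for (pl in c("vp", "tp")) {
    env <- if (config$envelope_method == "plate")
      sector_envelope(plates[[pl]], config$closing_radius_um, frame)
    else fill_envelope(plates[[pl]], config$closing_radius_um,
                       config$axial_closing_radius_um)
    ps <- pore_space(plates[[pl]], env)
    pm <- radial_pore_fraction(ps, env, frame, n_bands = config$n_bands,
                               regions = regions)
    pm$plate <- pl
    pore_maps[[pl]] <- pm
    envs[[pl]] <- env
  }
  pore_map <- do.call(rbind, pore_maps)
  rownames(pore_map) <- NULL

  comparison <- NULL
  if (!is.null(truth)) {
    oracle <- truth$true_porosity
    oracle <- oracle[oracle$n_envelope > 0, ]
    key <- paste(por$plate, por$region)
    okey <- paste(oracle$plate, oracle$region)
    oracle$pipeline_percent <- por$p_percent[match(okey, key)]
    oracle$error_pp <- oracle$pipeline_percent - oracle$porosity_percent
    # label agreement, excluding pillar voxels near the mid-surface
    agree <- label_agreement(truth, plates, regions)
    comparison <- list(porosity = oracle,
                       plate_label_agreement_percent = agree$plate,
                       region_label_agreement_percent = agree$region,
                       material_recall_percent = agree$recall,
                       width_base_true_um = truth$config$width_base_um,
                       width_apex_true_um = truth$config$width_apex_um,
                       assembly_thickness_true_um =
                         truth$assembly_thickness_um)
  }

  report <- structure(list(
    package = "oslmorph",
    version = as.character(packageVersion("oslmorph")),
    seed = config$seed,
    parameters = report_parameters(config, mask, frame),
    porosity = as.data.frame(por),
    profile = list(samples = prof$samples, summary = prof$summary),
    pore_map = as.data.frame(pore_map),
    truth_comparison = comparison,
    warnings = warnings_log), class = "osl_report")

  if (!is.null(config$output_dir))
    write_report_outputs(report, config, mask, plates, envs, prof)
  report
}

# Agreement of recovered plate/region labels with construction labels,
# over the voxels the segmentation retained: split/partition quality is
# reported separately from segmentation recall (the fraction of true
# material surviving thresholding and artifact removal). Pillar voxels
# carry no construction plate label and are excluded from the plate
# comparison.
label_agreement <- function(truth, plates, regions) {
  lab <- truth$label
  rec <- array(0L, dim(lab))
  rec[plates$vp$values] <- 1L
  rec[plates$tp$values] <- 2L
  plate_sel <- (lab == 1L | lab == 2L) & rec > 0L
  plate_ok <- 100 * sum(rec[plate_sel] == lab[plate_sel]) / sum(plate_sel)
  reg_sel <- lab > 0L & regions$labels > 0L
  reg_ok <- 100 * sum(regions$labels[reg_sel] == truth$region[reg_sel]) /
    sum(reg_sel)
  recall <- 100 * sum(rec > 0L & lab > 0L) / sum(lab > 0L)
  list(plate = plate_ok, region = reg_ok, recall = recall)
}

report_parameters <- function(config, mask, frame) {
  list(threshold = mask$provenance$threshold,
       threshold_method = mask$provenance$threshold_method,
       min_component_voxels = config$min_component_voxels,
       closing_radius_um = config$closing_radius_um,
       axial_closing_radius_um = config$axial_closing_radius_um,
       region_bounds_deg = config$region_bounds_deg,
       profile_step_deg = config$profile_step_deg,
       delta_deg = config$delta_deg,
       n_bands = config$n_bands,
       min_radius_um = config$min_radius_um,
       simplify_fraction = config$simplify_fraction,
       envelope_method = config$envelope_method,
       voxel_size_um = mask$voxel_size_um,
       frame = list(center_um = frame$center_um,
                    axis_unit = frame$axis_unit,
                    zero_angle_unit = frame$zero_angle_unit,
                    handedness = frame$handedness,
                    pitch_um_per_turn = frame$pitch_um_per_turn,
                    base_offset_um = frame$base_offset_um),
       phantom = if (is.null(config$phantom)) NULL else
         unclass(config$phantom))
}

write_report_outputs <- function(report, config, mask, plates, envs, prof) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  write_mask_tiff(mask, out("mask.tif"))
  write_mask_tiff(plates$vp, out("plate_vp.tif"))
  write_mask_tiff(plates$tp, out("plate_tp.tif"))
  write.csv(report$porosity, out("porosity.csv"), row.names = FALSE)
  write.csv(report$profile$samples, out("profile.csv"), row.names = FALSE)
  write.csv(report$pore_map, out("pore_map.csv"), row.names = FALSE)
  if (isTRUE(config$write_meshes)) {
    for (pl in c("vp", "tp")) {
      write_stl(extract_surface(plates[[pl]]),
                out(sprintf("plate_%s.stl", pl)))
      write_stl(extract_surface(envs[[pl]]),
                out(sprintf("envelope_%s.stl", pl)))
    }
  }
  jsonlite::write_json(unclass(report), out("report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(NULL)
}

#' @export
print.osl_report <- function(x, ...) {
  cat(sprintf("<osl_report> oslmorph %s, seed %d\n", x$version, x$seed))
  cat("Porosity (mesh-based, percent):\n")
  print(x$porosity[, c("plate", "region", "p_percent", "p_voxel_percent")],
        digits = 3, row.names = FALSE)
  cat("Profile summary:\n")
  print(x$profile$summary, digits = 4, row.names = FALSE)
  if (!is.null(x$truth_comparison)) {
    cat("Ground-truth comparison (porosity, percentage points):\n")
    print(x$truth_comparison$porosity[, c("plate", "region",
                                          "porosity_percent",
                                          "pipeline_percent", "error_pp")],
          digits = 3, row.names = FALSE)
    cat(sprintf("Plate label agreement: %.2f%%; region label agreement: %.2f%%\n",
                x$truth_comparison$plate_label_agreement_percent,
                x$truth_comparison$region_label_agreement_percent))
  }
  invisible(x)
}
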