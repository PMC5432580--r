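#' Pipeline configuration
#'
#' Collects the parameters of the full localization workflow. Values can
#' come from a YAML/JSON file ([read_config()]), with function arguments
#' overriding file values.
#'
#' @param model_path path to the textured model OBJ.
#' @param mri_path path to a NIfTI volume (alternative to `scalp_path`).
#' @param scalp_path path to a pre-extracted scalp mesh OBJ.
#' @param model_seg_path,mri_seg_path electrode-text files holding the
#'   facial-segment point clouds of model and MRI.
#' @param template_dir template directory for labeling (package defaults
#'   when NULL).
#' @param out_dir directory for intermediate artifacts.
#' @param truth_path optional ground-truth electrode file; when given the
#'   pipeline returns a deviation report.
#' @param n_views,pixel_pitch view count is fixed by the azimuth/elevation
#'   grid (10); `pixel_pitch` in mm/px.
#' @param r_min_mm,r_max_mm,sensitivity Hough parameters.
#' @param merge_radius candidate merge distance (mm).
#' @param icp_max_iter,icp_tol,icp_trim_frac ICP parameters.
#' @param seed master seed for any stochastic step.
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(model_path = NULL, mri_path = NULL,
                            scalp_path = NULL, model_seg_path = NULL,
                            mri_seg_path = NULL, template_dir = NULL,
                            out_dir = NULL, truth_path = NULL,
                            n_views = 10L, pixel_pitch = 0.6,
                            r_min_mm = 2, r_max_mm = 8, sensitivity = 0.3,
                            merge_radius = 10, icp_max_iter = 100L,
                            icp_tol = 1e-6, icp_trim_frac = 0,
                            seed = 1L, log_level = "info") {
  cfg <- list(model_path = model_path, mri_path = mri_path,
              scalp_path = scalp_path, model_seg_path = model_seg_path,
              mri_seg_path = mri_seg_path, template_dir = template_dir,
              out_dir = out_dir, truth_path = truth_path,
              n_views = as.integer(n_views), pixel_pitch = pixel_pitch,
              r_min_mm = r_min_mm, r_max_mm = r_max_mm,
              sensitivity = sensitivity, merge_radius = merge_radius,
              icp_max_iter = as.integer(icp_max_iter), icp_tol = icp_tol,
              icp_trim_frac = icp_trim_frac, seed = as.integer(seed),
              log_level = log_level)
  num <- c("n_views", "pixel_pitch", "r_min_mm", "r_max_mm", "sensitivity",
           "merge_radius", "icp_max_iter", "icp_tol")
  for (f in num)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop("config field '", f, "' must be a positive scalar")
  if (cfg$icp_trim_frac < 0 || cfg$icp_trim_frac >= 0.5)
    stop("config field 'icp_trim_frac' must be in [0, 0.5)")
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration (YAML or JSON)
#' @param path `.yaml`/`.yml`/`.json` file.
#' @param overrides named list of values overriding the file.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path, overrides = list()) {
  vals <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                           simplifyVector = TRUE)
          else yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param config a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  if (grepl("\\.json$", path))
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(vals, path)
  invisible(path)
}

pipe_log <- function(cfg, level, ...) {
  lv <- c(quiet = 0, info = 1, debug = 2)
  if (lv[[cfg$log_level %||% "info"]] >= lv[[level]])
    message("[headgeo] ", ...)
  invisible(NULL)
}

#' Run the full localization pipeline
#'
#' coregister (scaling + facial-segment ICP) -> detect (binarize, 10-view
#' Hough, back-project, merge) -> label (7-template majority vote) ->
#' project onto the MRI scalp -> report against ground truth when
#' supplied. Every stage's artifacts are written to `out_dir` and all
#' resolved parameters logged.
#'
#' @param config a [pipeline_config()].
#' @return A list with `electrodes` (labeled, scalp-projected
#'   [electrode_set()] in MRI space), `transform` (model-to-MRI), `scalp`,
#'   and `report` (a [deviation_report()], when ground truth was given).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("model_path", "model_seg_path", "mri_seg_path"))
    if (is.null(config[[f]]))
      stop("pipeline config is missing required field '", f, "'")
  if (is.null(config$mri_path) && is.null(config$scalp_path))
    stop("pipeline config needs either 'mri_path' or 'scalp_path'")
  for (f in c("model_path", "mri_path", "scalp_path", "model_seg_path",
              "mri_seg_path", "truth_path"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("pipeline input does not exist: ", config[[f]])
  out_dir <- config$out_dir
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  save_art <- function(writer, obj, name) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, name))
  }
  pipe_log(config, "info", "parameters: ",
           paste(names(unclass(config)), vapply(unclass(config), function(v)
             paste(format(v), collapse = ","), ""), sep = "=", collapse = " "))

  pipe_log(config, "info", "stage coregister: reading inputs")
  model <- read_textured_mesh(config$model_path, frame_id = "model")
  model_seg <- facial_segment(read_electrodes(config$model_seg_path)$points,
                              source_frame = "model")
  mri_seg <- facial_segment(read_electrodes(config$mri_seg_path)$points,
                            source_frame = "mri")
  scalp <- if (!is.null(config$scalp_path))
    read_textured_mesh(config$scalp_path, frame_id = "mri")
  else scalp_mesh_from_volume(read_volume(config$mri_path))
  xform <- withCallingHandlers(
    coregister_model_to_mri(model, model_seg, mri_seg,
                            icp_params = list(max_iter = config$icp_max_iter,
                                              tol = config$icp_tol,
                                              trim_frac = config$icp_trim_frac)),
    error = function(e) stop("stage coregister failed: ",
                             conditionMessage(e), call. = FALSE))
  pipe_log(config, "info", sprintf(
    "stage coregister: scale %.4f, ICP rms %.4f mm (%d iterations)",
    xform$scale, xform$rms, xform$iterations))
  model_mri <- apply_transform(xform, model)
  save_art(function(o, p) write_transform(o, p), xform, "model_to_mri.json")

  pipe_log(config, "info", "stage detect: 10-view Hough detection")
  detected <- tryCatch(
    detect_electrodes(model_mri,
                      views = default_views(model_mri,
                                            pixel_pitch = config$pixel_pitch),
                      r_min_mm = config$r_min_mm, r_max_mm = config$r_max_mm,
                      sensitivity = config$sensitivity,
                      merge_radius = config$merge_radius),
    error = function(e) stop("stage detect failed: ", conditionMessage(e),
                             call. = FALSE))
  pipe_log(config, "info", sprintf("stage detect: %d electrodes",
                                   nrow(detected$points)))
  save_art(write_electrodes, detected, "electrodes_raw.txt")

  pipe_log(config, "info", "stage label: majority vote")
  templates <- if (is.null(config$template_dir)) default_templates()
               else read_templates(config$template_dir)
  labeled <- tryCatch(label_majority_vote(detected, templates),
                      error = function(e) stop("stage label failed: ",
                                               conditionMessage(e),
                                               call. = FALSE))
  save_art(write_electrodes, labeled, "electrodes_labeled.txt")

  pipe_log(config, "info", "stage project: snapping to the scalp surface")
  final <- project_to_scalp(labeled, scalp)
  save_art(write_electrodes, final, "electrodes_final.txt")

  report <- NULL
  if (!is.null(config$truth_path)) {
    truth <- read_electrodes(config$truth_path)
    report <- electrode_deviation(final, truth,
                                  match_by = if (is.null(truth$labels))
                                    "order" else "labels")
    pipe_log(config, "info", sprintf(
      "stage report: mean deviation %.3f mm (n = %d)",
      report$summary$mean, report$summary$n))
    if (!is.null(out_dir))
      write_deviation_report(report, file.path(out_dir, "deviation"))
  }
  list(electrodes = final, transform = xform, scalp = scalp, report = report)
}
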