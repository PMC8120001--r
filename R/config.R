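# YAML configuration shared by the API and the command-line interface.
# Calibration is always taken from here, never from image metadata.

#' Read a YAML analysis / simulation configuration
#'
#' Recognised blocks: `calibration` (`pixel_size`, `frame_interval`,
#' `channel_roles`), `segmentation` (`neutrophil_threshold`,
#' `neutrophil_area_um2`, `macrophage_area_um2`, `prob_threshold`),
#' `tracking` (`max_link_distance_um`, `max_gap_frames`), `interaction`
#' (`thresholds`), `simulation` (passed to [sim_config()]), `seed`.
#'
#' @param path YAML file path.
#' @return Nested list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config Nested list from [read_config()].
#' @export
calibration_from_config <- function(config) {
  cc <- config$calibration
  if (is.null(cc)) stop("config has no 'calibration' block")
  calibration(cc$pixel_size, cc$frame_interval,
              unlist(cc$channel_roles))
}

#' @rdname read_config
#' @param classifier Optional trained classifier to attach.
#' @export
params_from_config <- function(config, classifier = NULL) {
  sg <- config$segmentation
  tk <- config$tracking
  ia <- config$interaction
  defaults <- analysis_params()
  thr <- defaults$thresholds
  if (!is.null(ia$thresholds)) {
    user <- unlist(ia$thresholds)
    thr[names(user)] <- user
  }
  analysis_params(
    neutrophil_threshold = sg$neutrophil_threshold %||%
      defaults$neutrophil_threshold,
    neutrophil_area_um2 = unlist(sg$neutrophil_area_um2) %||%
      defaults$neutrophil_area_um2,
    macrophage_area_um2 = unlist(sg$macrophage_area_um2) %||%
      defaults$macrophage_area_um2,
    classifier = classifier,
    prob_threshold = sg$prob_threshold %||% defaults$prob_threshold,
    max_link_distance_um = tk$max_link_distance_um %||%
      defaults$max_link_distance_um,
    max_gap_frames = tk$max_gap_frames %||% defaults$max_gap_frames,
    thresholds = thr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_config
#' @export
sim_config_from_config <- function(config) {
  sim <- config$simulation %||% list()
  args <- list(seed = config$seed %||% sim$seed)
  if (is.null(args$seed)) stop("config must provide a seed for simulation")
  for (nm in intersect(names(sim),
                       names(formals(sim_config)))) {
    if (nm == "seed") next
    val <- sim[[nm]]
    if (nm %in% c("image_size", "neutrophil_radius_um",
                  "macrophage_radius_um"))
      val <- unlist(val)
    if (nm == "lesion_polygon")
      val <- matrix(unlist(val), ncol = 2, byrow = TRUE,
                    dimnames = list(NULL, c("x", "y")))
    args[[nm]] <- val
  }
  do.call(sim_config, args)
}
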