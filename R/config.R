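#' Pipeline configuration
#'
#' All tunable parameters live in one nested list with units spelled out in
#' the field names. `pipeline_config()` returns the defaults, optionally
#' overridden; `read_config()` loads the same schema from a YAML document and
#' `write_config()` saves one.
#'
#' The single scale everything else derives from is
#' `nucleus_radius_um`: detection scales default to
#' `{0.5, 0.75, 1, 1.5} x` radius, the motion scale `sigma_motion_um` to one
#' radius, and the gating radius to three radii per unit frame gap.
#'
#' @param nucleus_radius_um nominal nucleus radius in micrometres.
#' @param ... named overrides for any nested field, e.g.
#'   `link = list(g_max = 3)` (merged shallowly per section).
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(nucleus_radius_um = 3, ...) {
  r <- nucleus_radius_um
  cfg <- list(
    nucleus_radius_um = r,
    seed = 1L,
    preprocess = list(
      deconvolve = list(enabled = FALSE, psf_path = NULL, iterations = 10L),
      register = list(enabled = FALSE),
      flow = list(enabled = FALSE, block_size_vox = 16L)
    ),
    detect = list(
      scales_um = c(0.5, 0.75, 1, 1.5) * r,
      z_threshold = 4,
      min_volume_um3 = (4 / 3) * pi * (0.5 * r)^3,
      max_volume_um3 = (4 / 3) * pi * (2.2 * r)^3,
      gradient_sigma = NULL  # NULL = estimated from the frame
    ),
    link = list(
      sigma_motion_um = r,
      gating_radius_um = 3 * r,
      strict_factor = 0.5,     # strict pass gate = strict_factor * gating radius
      g_max = 2L,
      c_skip = 2.0,
      c_border = 4.0,
      border_time_factor = 0.125,
      border_space_factor = 0.25,
      w_volume = 1.0,
      div_discount = 0.25,
      div_merge_knn = 3L,
      div_volume_frac = c(0.2, 0.8)
    ),
    correct = list(
      max_iterations = 5L,
      redetect_relax = 0.5,
      volume_tolerance = 0.30,
      underseg_gamma = 1.6,
      window_frames = 3L,
      merge_pair_dist_um = 2.4 * r
    ),
    lineage = list(
      tracklet_gap_max = 3L,
      relax_factor = 2.0,
      division_min_parent_len = 5L,
      division_child_volume_frac = c(0.3, 0.7),
      batch_size = 0L,          # 0 = whole scene
      batch_overlap = 5L
    )
  )
  cfg <- merge_config(cfg, list(...))
  validate_config(cfg)
}

merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

validate_config <- function(cfg) {
  if (cfg$correct$max_iterations < 1) abort("correct.max_iterations must be >= 1")
  if (cfg$link$g_max < 1) abort("link.g_max must be >= 1")
  if (any(cfg$detect$scales_um <= 0)) abort("detect.scales_um must be positive")
  if (cfg$nucleus_radius_um <= 0) abort("nucleus_radius_um must be positive")
  if (cfg$link$gating_radius_um <= 0 || cfg$link$sigma_motion_um <= 0)
    abort("link radii/scales must be positive")
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- pipeline_config(nucleus_radius_um = raw$nucleus_radius_um %||% 3)
  validate_config(merge_config(unclass(base), raw))
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
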