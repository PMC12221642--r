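#' Gaze-cone specification
#'
#' Describes one visual-field cone in the head-local coordinate system.
#' Azimuth is measured from the forward (+Y) axis toward the bird's right
#' (+X); elevation from the horizontal (XY) plane toward head-up (+Z).
#' The lateral foveae project at +/-75 deg azimuth and 0 deg elevation;
#' the binocular field is a forward cone at 0/0. Negative azimuth is the
#' left fovea. The half angle is the angular error margin around the
#' center line (10 deg by default, accommodating eye movement and noise;
#' for the forward cone this matches the ~20 deg binocular field width).
#'
#' @param label one of `"left_fovea"`, `"right_fovea"`, `"binocular"`.
#' @param azimuth_deg center-line azimuth in degrees.
#' @param elevation_deg center-line elevation in degrees.
#' @param half_angle_deg cone half angle in degrees, in (0, 90).
#' @return an object of class `gaze_cone_spec`.
#' @export
gaze_cone_spec <- function(label, azimuth_deg, elevation_deg = 0,
                           half_angle_deg = 10) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.finite(half_angle_deg) || half_angle_deg <= 0 || half_angle_deg >= 90)
    stop("half_angle_deg must lie in (0, 90)")
  structure(
    list(label = label, azimuth_deg = azimuth_deg,
         elevation_deg = elevation_deg, half_angle_deg = half_angle_deg),
    class = "gaze_cone_spec")
}

#' Default cone set: two lateral foveae and the binocular field
#'
#' @param half_angle_deg cone half angle applied to all three cones.
#' @return list of [gaze_cone_spec()] objects.
#' @export
default_cone_specs <- function(half_angle_deg = 10) {
  list(
    gaze_cone_spec("left_fovea",  -75, 0, half_angle_deg),
    gaze_cone_spec("right_fovea",  75, 0, half_angle_deg),
    gaze_cone_spec("binocular",     0, 0, half_angle_deg)
  )
}

#' Spherical region of interest around a stimulus window
#'
#' The default radius of 0.25 m (a 50 cm diameter sphere) encompasses a
#' 30 cm wide window with a 10 cm margin on each side.
#'
#' @param label location label, e.g. `"top_A"`.
#' @param center numeric length-3 world-frame center (m).
#' @param radius_m sphere radius in meters (> 0).
#' @return an object of class `roi_sphere`.
#' @export
roi_sphere <- function(label, center, radius_m = 0.25) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3L, all(is.finite(center)))
  if (!is.finite(radius_m) || radius_m <= 0) stop("radius_m must be > 0")
  structure(list(label = label, center = center, radius_m = radius_m),
            class = "roi_sphere")
}

#' Axis-aligned table region
#'
#' @param label side label (`"A"` or `"B"`).
#' @param xlim,ylim,zlim numeric length-2 extents in meters.
#' @return an object of class `table_region`.
#' @export
table_region <- function(label, xlim, ylim, zlim = c(0, 2)) {
  stopifnot(length(xlim) == 2L, length(ylim) == 2L, length(zlim) == 2L,
            xlim[1] < xlim[2], ylim[1] < ylim[2], zlim[1] < zlim[2])
  structure(list(label = label, xlim = as.numeric(xlim),
                 ylim = as.numeric(ylim), zlim = as.numeric(zlim)),
            class = "table_region")
}

regions_overlap <- function(a, b) {
  all(a$xlim[1] < b$xlim[2], b$xlim[1] < a$xlim[2],
      a$ylim[1] < b$ylim[2], b$ylim[1] < a$ylim[2],
      a$zlim[1] < b$zlim[2], b$zlim[1] < a$zlim[2])
}

point_in_region <- function(p, region) {
  p[1] >= region$xlim[1] & p[1] <= region$xlim[2] &
    p[2] >= region$ylim[1] & p[2] <= region$ylim[2] &
    p[3] >= region$zlim[1] & p[3] <= region$zlim[2]
}

#' Scene configuration
#'
#' Bundles every tunable constant of the pipeline: capture frame rate,
#' region-of-interest spheres, the two table regions holding the birds,
#' the gaze-cone set, and the filtering thresholds. No threshold is
#' hard-coded elsewhere; everything that defines "a look" lives here.
#'
#' @param frame_rate capture rate in Hz (> 0). The capture rate is rig
#'   dependent and therefore required configuration; the default of 100 Hz
#'   matches common marker-based rigs.
#' @param rois named list of [roi_sphere()] objects (names = location
#'   labels such as `"top_A"`, `"bottom_B"`).
#' @param table_regions list of exactly two disjoint [table_region()]s
#'   labeled `"A"` and `"B"`.
#' @param cone_specs list of [gaze_cone_spec()]s.
#' @param saccade_threshold_deg_s angular-speed threshold (deg/s) above
#'   which a frame counts as a head saccade.
#' @param fixation_min_ms minimum fixation duration (ms) for a bout.
#' @param smoothing list with `max_gap_frames` (gaps up to this many
#'   frames are interpolated) and `window_frames` (odd length of the
#'   zero-phase moving-average smoother; 1 disables smoothing). The
#'   default 3-frame window suppresses marker jitter while smearing a
#'   head saccade across at most one frame on each side.
#' @param grooming list with `pitch_threshold_deg` (head pitch below this
#'   counts as head-down), `dist_threshold_m` (eye-midpoint-to-backpack
#'   distance) and `min_ms` (minimum sustained duration).
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(frame_rate = 100,
                         rois = NULL,
                         table_regions = NULL,
                         cone_specs = default_cone_specs(),
                         saccade_threshold_deg_s = 300,
                         fixation_min_ms = 300,
                         smoothing = list(max_gap_frames = 10L,
                                          window_frames = 3L),
                         grooming = list(pitch_threshold_deg = -45,
                                         dist_threshold_m = 0.15,
                                         min_ms = 400)) {
  if (!is.numeric(frame_rate) || frame_rate <= 0)
    stop("frame_rate must be > 0")
  if (is.null(rois)) rois <- default_rois()
  if (is.null(table_regions)) table_regions <- default_table_regions()
  if (length(table_regions) != 2L)
    stop("exactly two table regions are required")
  if (regions_overlap(table_regions[[1]], table_regions[[2]]))
    stop("table regions must be disjoint")
  if (fixation_min_ms <= 0) stop("fixation_min_ms must be > 0")
  if (saccade_threshold_deg_s <= 0) stop("saccade_threshold_deg_s must be > 0")
  for (r in rois) stopifnot(inherits(r, "roi_sphere"))
  for (cs in cone_specs) stopifnot(inherits(cs, "gaze_cone_spec"))
  names(rois) <- vapply(rois, `[[`, character(1), "label")
  names(table_regions) <- vapply(table_regions, `[[`, character(1), "label")
  structure(
    list(frame_rate = frame_rate, rois = rois,
         table_regions = table_regions, cone_specs = cone_specs,
         saccade_threshold_deg_s = saccade_threshold_deg_s,
         fixation_min_ms = fixation_min_ms,
         smoothing = smoothing, grooming = grooming),
    class = "scene_config")
}

# Default scene: an upright stimulus structure at y = 0 between two
# tables parallel to it, with a top and a bottom tube location. One
# sphere per location: the sphere radius (0.25 m) exceeds the offset
# between a tube's two side windows, so side-specific spheres would
# coincide almost entirely; which side can see the object is carried by
# the schedule's demonstrator side, not by the geometry.
default_rois <- function(radius_m = 0.25) {
  list(
    roi_sphere("top",    c(0, 0, 1.60), radius_m),
    roi_sphere("bottom", c(0, 0, 0.80), radius_m)
  )
}

default_table_regions <- function() {
  list(
    table_region("A", xlim = c(-1.05, 1.05), ylim = c(0.6, 1.1),
                 zlim = c(0.5, 1.1)),
    table_region("B", xlim = c(-1.05, 1.05), ylim = c(-1.1, -0.6),
                 zlim = c(0.5, 1.1))
  )
}

#' @export
print.scene_config <- function(x, ...) {
  cat("Scene configuration\n")
  cat("  frame rate:      ", x$frame_rate, "Hz\n")
  cat("  ROIs:            ", paste(names(x$rois), collapse = ", "), "\n")
  cat("  cones:           ",
      paste(vapply(x$cone_specs, `[[`, character(1), "label"),
            collapse = ", "), "\n")
  cat("  saccade thresh:  ", x$saccade_threshold_deg_s, "deg/s\n")
  cat("  min fixation:    ", x$fixation_min_ms, "ms\n")
  invisible(x)
}

#' Read / write a scene configuration as YAML
#'
#' All thresholds of the pipeline are serialized so an analysis is fully
#' described by its config file.
#'
#' @param path file path.
#' @return [read_scene_config()] returns a `scene_config`;
#'   [write_scene_config()] returns `path` invisibly.
#' @export
read_scene_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  rois <- lapply(y$rois, function(r)
    roi_sphere(r$label, as.numeric(r$center), r$radius_m))
  regions <- lapply(y$table_regions, function(r)
    table_region(r$label, as.numeric(r$xlim), as.numeric(r$ylim),
                 as.numeric(r$zlim)))
  cones <- lapply(y$cone_specs, function(cs)
    gaze_cone_spec(cs$label, cs$azimuth_deg, cs$elevation_deg,
                   cs$half_angle_deg))
  scene_config(frame_rate = y$frame_rate, rois = rois,
               table_regions = regions, cone_specs = cones,
               saccade_threshold_deg_s = y$saccade_threshold_deg_s,
               fixation_min_ms = y$fixation_min_ms,
               smoothing = y$smoothing, grooming = y$grooming)
}

#' @rdname read_scene_config
#' @param config a `scene_config`.
#' @export
write_scene_config <- function(config, path) {
  stopifnot(inherits(config, "scene_config"))
  y <- list(
    frame_rate = config$frame_rate,
    rois = lapply(unname(config$rois), unclass),
    table_regions = lapply(unname(config$table_regions), unclass),
    cone_specs = lapply(config$cone_specs, unclass),
    saccade_threshold_deg_s = config$saccade_threshold_deg_s,
    fixation_min_ms = config$fixation_min_ms,
    smoothing = config$smoothing,
    grooming = config$grooming)
  yaml::write_yaml(y, path)
  invisible(path)
}
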