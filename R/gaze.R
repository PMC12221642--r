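#' World-frame center line of a gaze cone
#'
#' Maps a cone's head-frame direction into the world through the head
#' rotation. Azimuth is measured from the forward (+Y) axis toward the
#' bird's right (+X), elevation from the XY plane toward head-up (+Z):
#' the direction is `(sin az cos el, cos az cos el, sin el)` in head
#' coordinates.
#'
#' @param R 3 x 3 world-from-head rotation.
#' @param spec a [gaze_cone_spec()].
#' @return unit length-3 world direction.
#' @export
cone_axis_world <- function(R, spec) {
  az <- deg2rad(spec$azimuth_deg)
  el <- deg2rad(spec$elevation_deg)
  d <- c(sin(az) * cos(el), cos(az) * cos(el), sin(el))
  as.numeric(R %*% d)
}

#' Does a gaze cone cross an ROI sphere?
#'
#' True when the apex lies inside the sphere, or when the angle between
#' the cone axis and the apex-to-center direction does not exceed the
#' cone half angle plus the sphere's angular radius
#' `asin(min(1, r / d))` seen from the apex.
#'
#' @param apex length-3 cone apex (world, m).
#' @param axis length-3 cone axis (need not be unit length).
#' @param half_angle_deg cone half angle, degrees, in (0, 90).
#' @param roi a [roi_sphere()].
#' @return logical.
#' @export
cone_hits_sphere <- function(apex, axis, half_angle_deg, roi) {
  stopifnot(half_angle_deg > 0, half_angle_deg < 90)
  v <- roi$center - apex
  d <- vnorm(v)
  if (d <= roi$radius_m) return(TRUE)
  offset <- vec_angle(axis, v)
  offset <= deg2rad(half_angle_deg) + asin(min(1, roi$radius_m / d))
}

# World axes of one cone for every frame at once: 3 x n matrix
# axis_i = R_i d = d1 R[,1,i] + d2 R[,2,i] + d3 R[,3,i].
cone_axes_all <- function(Rarr, spec) {
  az <- deg2rad(spec$azimuth_deg)
  el <- deg2rad(spec$elevation_deg)
  d <- c(sin(az) * cos(el), cos(az) * cos(el), sin(el))
  d[1] * Rarr[, 1, ] + d[2] * Rarr[, 2, ] + d[3] * Rarr[, 3, ]
}

# Frame-wise cone-hit matrix for one bird: n_frames x n_cones logical
# per ROI; invalid-pose frames are FALSE. Vectorized over frames.
cone_hit_frames <- function(pose_bird, cone_specs, roi) {
  n <- length(pose_bird$valid)
  H <- matrix(FALSE, n, length(cone_specs))
  v <- t(sweep(pose_bird$origin, 2, roi$center, "-")) * -1  # 3 x n
  d <- sqrt(colSums(v^2))
  inside <- is.finite(d) & d <= roi$radius_m
  cap <- asin(pmin(1, roi$radius_m / pmax(d, roi$radius_m)))
  for (j in seq_along(cone_specs)) {
    ax <- cone_axes_all(pose_bird$R, cone_specs[[j]])  # unit by constr.
    ca <- colSums(ax * v) / pmax(d, .Machine$double.eps)
    offset <- acos(pmax(-1, pmin(1, ca)))
    hit <- offset <= deg2rad(cone_specs[[j]]$half_angle_deg) + cap
    hit[!is.finite(offset)] <- FALSE
    H[, j] <- (hit | inside) & pose_bird$valid
  }
  H
}

empty_bout_table <- function() {
  data.frame(bird = character(), roi = character(), cone = character(),
             start_frame = integer(), end_frame = integer(),
             duration_ms = numeric(), stringsAsFactors = FALSE)
}

#' Segment filtered looking bouts
#'
#' For every bird and ROI sphere, a frame is a hit when at least one
#' gaze cone crosses the sphere, the pose is valid, and the frame is
#' neither saccade- nor grooming-flagged. Maximal runs of hit frames
#' lasting at least `fixation_min_ms` become bouts. Flagged frames break
#' runs (no gap bridging). Each bout is labeled with the cone that holds
#' the majority of its hit frames; simultaneous hits by several cones
#' are a single look (cones are OR-ed before segmentation, so one
#' orienting event is never double-counted), and ties are resolved in
#' favor of a fovea. When presentation windows are supplied the hit
#' series is clipped to each window before segmentation.
#'
#' @param poses a [head_pose_series()].
#' @param masks list with elements `saccade` and `grooming`, each a
#'   named list of logical per-frame vectors as returned by
#'   [detect_saccades()] / [detect_grooming()].
#' @param config a [scene_config()].
#' @param cone_specs,rois defaults taken from `config`.
#' @param windows optional data.frame with `start_frame`, `end_frame`
#'   (frame indices, same basis as `poses$frames`) and optionally
#'   `trial_id` / `presentation_index` carried onto the bouts.
#' @return data.frame with columns bird, roi, cone, start_frame,
#'   end_frame, duration_ms (plus window ids when given). Frames are
#'   indices into the capture (0-based, inclusive ends).
#' @export
detect_looks <- function(poses, masks, config,
                         cone_specs = config$cone_specs,
                         rois = config$rois, windows = NULL) {
  fr <- poses$frame_rate
  min_frames <- ceiling(config$fixation_min_ms / 1000 * fr)
  cone_labels <- vapply(cone_specs, `[[`, character(1), "label")
  foveal <- grepl("fovea", cone_labels)
  out <- list()
  for (b in names(poses$birds)) {
    pb <- poses$birds[[b]]
    sac <- masks$saccade[[b]]
    grm <- masks$grooming[[b]]
    ok <- pb$valid & !ifelse(is.na(sac), FALSE, sac) &
      !ifelse(is.na(grm), FALSE, grm)
    for (roi in rois) {
      H <- cone_hit_frames(pb, cone_specs, roi)
      hit <- rowSums(H) > 0 & ok
      segs <- if (is.null(windows)) {
        data.frame(start_frame = poses$frames[1],
                   end_frame = poses$frames[length(poses$frames)])
      } else windows
      for (s in seq_len(nrow(segs))) {
        sel <- poses$frames >= segs$start_frame[s] &
          poses$frames <= segs$end_frame[s]
        idx <- which(sel)
        if (!length(idx)) next
        runs <- true_runs(hit[idx])
        if (!nrow(runs)) next
        runs <- runs[runs$end - runs$start + 1L >= min_frames, ,
                     drop = FALSE]
        for (k in seq_len(nrow(runs))) {
          gi <- idx[runs$start[k]:runs$end[k]]
          votes <- colSums(H[gi, , drop = FALSE])
          best <- which(votes == max(votes))
          if (length(best) > 1L && any(foveal[best]))
            best <- best[foveal[best]]
          row <- data.frame(
            bird = b, roi = roi$label, cone = cone_labels[best[1]],
            start_frame = poses$frames[gi[1]],
            end_frame = poses$frames[gi[length(gi)]],
            duration_ms = length(gi) / fr * 1000,
            stringsAsFactors = FALSE)
          if (!is.null(windows)) {
            for (cn in intersect(c("trial_id", "presentation_index",
                                   "condition"), names(windows)))
              row[[cn]] <- windows[[cn]][s]
          }
          out[[length(out) + 1L]] <- row
        }
      }
    }
  }
  if (!length(out)) {
    tb <- empty_bout_table()
    if (!is.null(windows)) {
      for (cn in intersect(c("trial_id", "presentation_index", "condition"),
                           names(windows)))
        tb[[cn]] <- tb$bird[0]
    }
    return(tb)
  }
  do.call(rbind, out)
}

#' Proportion of looks made with foveal versus binocular fields
#'
#' @param bouts a bout table from [detect_looks()].
#' @return named numeric `c(foveal = , binocular = )` summing to 1, or
#'   `NULL` when there are no bouts.
#' @export
classify_field_usage <- function(bouts) {
  if (is.null(bouts) || nrow(bouts) == 0L) return(NULL)
  fov <- grepl("fovea", bouts$cone)
  c(foveal = mean(fov), binocular = mean(!fov))
}

#' Write / read a bout table
#' @param bouts bout table.
#' @param path file path.
#' @export
write_bout_csv <- function(bouts, path) {
  utils::write.csv(bouts, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bout_csv
#' @export
read_bout_csv <- function(path) {
  if (!file.exists(path)) stop("bout file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
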