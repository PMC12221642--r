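# End-to-end wrapper: markers -> poses -> masks -> bouts -> observer
# table -> exclusions. Each stage is also callable on its own.

# Backpack centroid positions (n x 3) per bird over given frame rows.
backpack_positions <- function(markers, rows) {
  out <- list()
  for (b in bird_ids(markers)) {
    bp <- markers$birds[[b]]$backpack
    if (dim(bp)[2] == 0L) {
      # fall back to the head centroid when no backpack is present
      bp <- markers$birds[[b]]$head
    }
    ctr <- apply(bp[rows, , , drop = FALSE], c(1, 3), mean, na.rm = TRUE)
    ctr[!is.finite(ctr)] <- NA_real_
    out[[b]] <- ctr
  }
  out
}

#' Assign table sides for every presentation of a schedule
#'
#' Runs [assign_sides()] on the backpack centroid positions of every
#' bird within each presentation window.
#'
#' @param markers a [marker_series()].
#' @param schedule a `presentation_schedule`.
#' @param config a [scene_config()].
#' @return data.frame(trial_id, presentation_index, bird, side,
#'   flew_off, switched, untracked).
#' @export
assign_sides_schedule <- function(markers, schedule, config) {
  out <- list()
  for (p in seq_len(nrow(schedule))) {
    sc <- schedule[p, ]
    rows <- which(markers$frames >= sc$start_frame &
                    markers$frames <= sc$end_frame)
    pos <- backpack_positions(markers, rows)
    sides <- assign_sides(pos, config$table_regions)
    sides$trial_id <- sc$trial_id
    sides$presentation_index <- sc$presentation_index
    out[[p]] <- sides
  }
  do.call(rbind, out)
}

#' Run the full gaze-following pipeline
#'
#' Reconstructs and smooths head poses, computes saccade and grooming
#' masks, segments looking bouts within the presentation windows,
#' assigns table sides, builds the per-observer presentation table and
#' applies the exclusion rules.
#'
#' @param markers a [marker_series()].
#' @param calibs named list of [head_calibration()]s (or a single one
#'   applied to all birds).
#' @param config a [scene_config()].
#' @param schedule a `presentation_schedule`.
#' @param grooming_external optional externally supplied grooming masks
#'   (named list of logical vectors), passed through verbatim.
#' @param verbose emit progress messages to stderr.
#' @return list with `poses`, `masks`, `sides`, `bouts`, `table`
#'   (pre-exclusion), `analysis` (post-exclusion table) and
#'   `exclusion_report`.
#' @export
run_gaze_pipeline <- function(markers, calibs, config, schedule,
                              grooming_external = NULL,
                              verbose = FALSE) {
  say <- function(...) if (verbose) message("[gazeflock] ", ...)
  if (inherits(calibs, "head_calibration"))
    calibs <- stats::setNames(rep(list(calibs), length(bird_ids(markers))),
                              bird_ids(markers))
  say("reconstructing head poses for ", length(bird_ids(markers)),
      " birds, ", n_frames(markers), " frames")
  poses <- reconstruct_head_poses(markers, calibs, config)
  poses <- smooth_poses(poses, config)
  say("computing saccade and grooming masks")
  masks <- list(
    saccade = detect_saccades(poses, config$saccade_threshold_deg_s),
    grooming = detect_grooming(poses, markers, config,
                               external = grooming_external))
  say("segmenting looking bouts")
  bouts <- detect_looks(poses, masks, config, windows = schedule)
  say("found ", nrow(bouts), " bouts")
  sides <- assign_sides_schedule(markers, schedule, config)
  tab <- build_presentation_table(bouts, schedule, sides,
                                  masks$grooming, poses$frames, config)
  excl <- apply_exclusions(tab)
  say("presentation table: ", nrow(tab), " rows, ",
      excl$n_excluded, " excluded")
  list(poses = poses, masks = masks, sides = sides, bouts = bouts,
       table = tab, analysis = excl$table,
       exclusion_report = excl$report)
}

#' Write / read a head-pose + mask table
#'
#' Long CSV with one row per bird and frame: origin, the nine rotation
#' entries (column-major), validity, alignment rmsd and the two
#' behavior flags.
#'
#' @param poses a [head_pose_series()].
#' @param masks mask list as in [run_gaze_pipeline()] (optional).
#' @param path file path.
#' @export
write_pose_csv <- function(poses, path, masks = NULL) {
  rows <- list()
  for (b in names(poses$birds)) {
    pb <- poses$birds[[b]]
    n <- length(pb$valid)
    Rflat <- matrix(pb$R, 9L, n)
    df <- data.frame(bird = b, frame = poses$frames, valid = pb$valid,
                     ox = pb$origin[, 1], oy = pb$origin[, 2],
                     oz = pb$origin[, 3], t(Rflat), rmsd = pb$rmsd)
    names(df)[7:15] <- paste0("r", rep(1:3, 3), rep(1:3, each = 3))
    df$saccade <- if (!is.null(masks)) masks$saccade[[b]] else NA
    df$grooming <- if (!is.null(masks)) masks$grooming[[b]] else NA
    rows[[b]] <- df
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_pose_csv
#' @param frame_rate capture rate of the stored poses.
#' @return `read_pose_csv` returns a list with `poses` and `masks`.
#' @export
read_pose_csv <- function(path, frame_rate) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  birds <- list(); sacc <- list(); groom <- list()
  frames <- sort(unique(df$frame))
  for (b in unique(df$bird)) {
    d <- df[df$bird == b, ]
    d <- d[order(d$frame), ]
    n <- nrow(d)
    Rarr <- array(t(as.matrix(d[paste0("r", rep(1:3, 3),
                                       rep(1:3, each = 3))])),
                  c(3L, 3L, n))
    birds[[b]] <- list(origin = as.matrix(d[c("ox", "oy", "oz")]),
                       R = Rarr, valid = as.logical(d$valid),
                       rmsd = d$rmsd)
    sacc[[b]] <- as.logical(d$saccade)
    groom[[b]] <- as.logical(d$grooming)
  }
  list(poses = head_pose_series(frame_rate, frames, birds),
       masks = list(saccade = sacc, grooming = groom))
}
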