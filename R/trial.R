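# From bouts + schedule + table-side assignments to the per-observer,
# per-presentation analysis table, with the data-exclusion rules and
# demonstrator counts.

#' Assign each bird to a table side for one presentation window
#'
#' The side is the table region containing the bird's median position
#' over the window. Flags are raised when the bird's position leaves
#' both regions (`flew_off`), changes region within the window
#' (`switched`; transit frames between the tables count as part of the
#' switch, not as a fly-off), or is untracked for the entire window
#' (`untracked`).
#'
#' @param positions named list of `n x 3` position matrices (one per
#'   bird, rows = frames of the window; e.g. backpack centroids).
#' @param table_regions list of two [table_region()]s.
#' @return data.frame(bird, side, flew_off, switched, untracked).
#' @export
assign_sides <- function(positions, table_regions) {
  labs <- vapply(table_regions, `[[`, character(1), "label")
  rows <- lapply(names(positions), function(b) {
    P <- positions[[b]]
    ok <- stats::complete.cases(P)
    if (!any(ok))
      return(data.frame(bird = b, side = NA_character_, flew_off = FALSE,
                        switched = FALSE, untracked = TRUE))
    P <- P[ok, , drop = FALSE]
    memb <- apply(P, 1L, function(p) {
      inA <- point_in_region(p, table_regions[[1]])
      inB <- point_in_region(p, table_regions[[2]])
      if (inA) labs[1] else if (inB) labs[2] else NA_character_
    })
    seen <- unique(memb[!is.na(memb)])
    med <- apply(P, 2L, stats::median)
    side <- if (point_in_region(med, table_regions[[1]])) labs[1]
      else if (point_in_region(med, table_regions[[2]])) labs[2]
      else if (length(seen) == 1L) seen else NA_character_
    switched <- length(seen) > 1L
    flew_off <- !switched && anyNA(memb)
    data.frame(bird = b, side = side, flew_off = flew_off,
               switched = switched, untracked = FALSE)
  })
  do.call(rbind, rows)
}

# Window-long grooming mask (1-based over the window frames) for one
# bird; NA mask frames count as not grooming.
window_mask <- function(mask, frames, start_frame, end_frame) {
  idx <- which(frames >= start_frame & frames <= end_frame)
  m <- mask[idx]
  m[is.na(m)] <- FALSE
  list(frames = frames[idx], mask = m)
}

#' Count demonstrators that provided a gaze cue to one observer
#'
#' A demonstrator-side bird counts when it has at least one bout at the
#' target ROI within the window that overlaps at least one frame in
#' which the observer was not grooming; demonstrator looks falling
#' entirely inside the observer's grooming are excluded, since the
#' observer could not have seen them.
#'
#' @param bouts bout table ([detect_looks()]).
#' @param demonstrators character vector of demonstrator-side bird ids.
#' @param target_roi ROI label of the target on the demonstrator side.
#' @param start_frame,end_frame presentation window (inclusive).
#' @param observer_grooming logical per-frame vector for the observer
#'   (same frame basis as `frames`), or `NULL` for a never-grooming
#'   observer.
#' @param frames frame indices the grooming mask is defined on.
#' @return integer count.
#' @export
count_actual_demonstrators <- function(bouts, demonstrators, target_roi,
                                       start_frame, end_frame,
                                       observer_grooming = NULL,
                                       frames = NULL) {
  if (!length(demonstrators)) return(0L)
  db <- bouts[bouts$bird %in% demonstrators & bouts$roi == target_roi &
                bouts$end_frame >= start_frame &
                bouts$start_frame <= end_frame, , drop = FALSE]
  if (!nrow(db)) return(0L)
  if (is.null(observer_grooming)) return(length(unique(db$bird)))
  counted <- vapply(seq_len(nrow(db)), function(k) {
    f0 <- max(db$start_frame[k], start_frame)
    f1 <- min(db$end_frame[k], end_frame)
    sel <- frames >= f0 & frames <= f1
    g <- observer_grooming[sel]
    g[is.na(g)] <- FALSE
    any(!g)  # overlaps at least one non-grooming observer frame
  }, logical(1))
  length(unique(db$bird[counted]))
}

# target/distractor ROI label for a bird standing on `side`. One ROI
# sphere covers both side windows of a tube location (the sphere radius
# exceeds their offset), so the label is just the location.
roi_for <- function(location, side) location
other_location <- function(location) ifelse(location == "top", "bottom", "top")

#' Build the per-observer, per-presentation analysis table
#'
#' One row per observer-side bird per presentation: binary and count
#' looking responses at the target and distractor locations visible
#' from the observer side, the first-looked location, the number of
#' demonstrator-side birds, the observer-specific "actual number of
#' demonstrators" (demonstrator-side birds that looked at the target at
#' least once, excluding looks fully inside the observer's grooming),
#' and the side-assignment flags used later by [apply_exclusions()].
#' The presentation-level count of demonstrators that looked,
#' unfiltered by any observer's grooming, is carried along for the
#' test-presentation exclusion rule. The mean number of demonstrators
#' looking at any instant of the window is emitted as an optional extra
#' covariate.
#'
#' @param bouts bout table over the full capture ([detect_looks()]).
#' @param schedule a `presentation_schedule`.
#' @param sides data.frame as from [assign_sides()] per presentation,
#'   with columns trial_id, presentation_index, bird, side, flew_off,
#'   switched, untracked.
#' @param grooming named list of per-frame logical grooming masks.
#' @param frames frame indices the masks are defined on.
#' @param config a [scene_config()].
#' @return data.frame of class `presentation_table`.
#' @export
build_presentation_table <- function(bouts, schedule, sides, grooming,
                                     frames, config) {
  schedule <- validate_schedule(as.data.frame(schedule))
  if (max(schedule$end_frame) > max(frames) ||
      min(schedule$start_frame) < min(frames)) {
    bad <- schedule[schedule$end_frame > max(frames) |
                      schedule$start_frame < min(frames), ]
    stop("presentation window outside tracked frames: trial ",
         bad$trial_id[1], " presentation ", bad$presentation_index[1])
  }
  out <- list()
  for (p in seq_len(nrow(schedule))) {
    sc <- schedule[p, ]
    srows <- sides[sides$trial_id == sc$trial_id &
                     sides$presentation_index == sc$presentation_index, ,
                   drop = FALSE]
    if (!nrow(srows)) next
    dem_side <- sc$demonstrator_side
    obs_side <- setdiff(c("A", "B"), dem_side)
    dem_birds <- srows$bird[!is.na(srows$side) & srows$side == dem_side]
    obs_rows <- srows[is.na(srows$side) | srows$side == obs_side, ,
                      drop = FALSE]
    dem_target <- roi_for(sc$presentation_location, dem_side)
    obs_target <- roi_for(sc$presentation_location, obs_side)
    obs_distr <- roi_for(other_location(sc$presentation_location),
                         obs_side)
    # presentation-level demonstrator looking, no grooming filter
    n_dem_any <- count_actual_demonstrators(
      bouts, dem_birds, dem_target, sc$start_frame, sc$end_frame)
    # mean number of demonstrators looking at any given frame
    wsel <- frames >= sc$start_frame & frames <= sc$end_frame
    nw <- sum(wsel)
    dem_db <- bouts[bouts$bird %in% dem_birds & bouts$roi == dem_target &
                      bouts$end_frame >= sc$start_frame &
                      bouts$start_frame <= sc$end_frame, , drop = FALSE]
    looking_n <- numeric(nw)
    if (nrow(dem_db) && nw) {
      wf <- frames[wsel]
      for (k in seq_len(nrow(dem_db)))
        looking_n <- looking_n +
          as.numeric(wf >= dem_db$start_frame[k] &
                       wf <= dem_db$end_frame[k])
    }
    mean_dem_looking <- if (nw) mean(looking_n) else 0

    for (r in seq_len(nrow(obs_rows))) {
      b <- obs_rows$bird[r]
      ob <- bouts[bouts$bird == b &
                    bouts$end_frame >= sc$start_frame &
                    bouts$start_frame <= sc$end_frame, , drop = FALSE]
      tb <- ob[ob$roi == obs_target, , drop = FALSE]
      db <- ob[ob$roi == obs_distr, , drop = FALSE]
      first_t <- if (nrow(tb)) min(tb$start_frame) else NA_integer_
      first_d <- if (nrow(db)) min(db$start_frame) else NA_integer_
      first_look <- if (is.na(first_t) && is.na(first_d)) "none"
        else if (is.na(first_d) || (!is.na(first_t) && first_t < first_d))
          "target"
        else if (is.na(first_t) || first_d < first_t) "distractor"
        else "none"  # identical onset frame at both ROIs
      n_act <- count_actual_demonstrators(
        bouts, dem_birds, dem_target, sc$start_frame, sc$end_frame,
        observer_grooming = grooming[[b]], frames = frames)
      out[[length(out) + 1L]] <- data.frame(
        experiment_id = sc$experiment_id, trial_id = sc$trial_id,
        presentation_index = sc$presentation_index,
        condition = sc$condition,
        presentation_location = sc$presentation_location,
        observer_id = b,
        looked_target = as.integer(nrow(tb) > 0),
        n_looks_target = nrow(tb),
        looked_distractor = as.integer(nrow(db) > 0),
        n_looks_distractor = nrow(db),
        first_look = first_look,
        n_demonstrators = length(dem_birds),
        n_actual_demonstrators = n_act,
        n_dem_looked_unfiltered = n_dem_any,
        mean_demonstrators_looking = mean_dem_looking,
        flew_off = obs_rows$flew_off[r], switched = obs_rows$switched[r],
        untracked = obs_rows$untracked[r],
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, out)
  class(tab) <- c("presentation_table", "data.frame")
  tab
}

#' Apply the data-exclusion rules
#'
#' Drops (a) observer rows whose bird flew off, switched tables, or was
#' untracked during the presentation, and (b) every row of test
#' presentations in which no demonstrator looked at the target
#' (evaluated on demonstrator bouts before any observer-grooming
#' filtering: it is a property of the presentation). Control
#' presentations are never excluded for lack of demonstrator looks.
#'
#' @param table a `presentation_table`.
#' @return list with `table` (retained rows, with `excluded` columns
#'   dropped) and `report` (data.frame of reason / count, one row per
#'   excluded observer-row by first matching reason).
#' @export
apply_exclusions <- function(table) {
  reason <- rep(NA_character_, nrow(table))
  reason[table$untracked] <- "untracked"
  reason[is.na(reason) & table$switched] <- "switched"
  reason[is.na(reason) & table$flew_off] <- "flew_off"
  no_dem <- table$condition == "test" & table$n_dem_looked_unfiltered == 0
  reason[is.na(reason) & no_dem] <- "no_demonstrator_looked"
  keep <- is.na(reason)
  tb <- table(reason[!keep])
  report <- data.frame(reason = names(tb), n = as.integer(tb),
                       stringsAsFactors = FALSE)
  kept <- table[keep, , drop = FALSE]
  kept$flew_off <- kept$switched <- kept$untracked <- NULL
  rownames(kept) <- NULL
  list(table = kept, report = report,
       n_excluded = sum(!keep), n_total = nrow(table))
}
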