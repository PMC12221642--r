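# Convenience builder for complete randomized flock scenarios with an
# injected gaze-following effect: demonstrator looks are scheduled at
# the target, and each observer's looking probability increases with the
# number of demonstrators that look. Used by the CLI `simulate` stage
# and by the end-to-end recovery harness.

# Pick a random sub-interval of `len` frames inside [w0, w1] that does
# not overlap any interval in `busy` (data.frame start/end). Returns
# c(start, end) or NULL.
free_slot <- function(w0, w1, len, busy, tries = 30L) {
  for (i in seq_len(tries)) {
    s <- if (w1 - len <= w0) w0 else
      sample(w0:(w1 - len), 1L)
    e <- s + len - 1L
    if (e > w1) next
    if (!nrow(busy) ||
        all(e < busy$start - 10L | s > busy$end + 10L))
      return(c(s, e))
  }
  NULL
}

#' Build a randomized flock scenario with known gaze-following structure
#'
#' Creates a presentation schedule from a counterbalanced condition
#' pattern, shuffles the birds across the two tables between
#' presentations, schedules demonstrator looks at the target during
#' test presentations (fovea or binocular cone, 92:8 by default), and
#' schedules observer looks whose probability rises with the number of
#' looking demonstrators, plus base-rate looks in both conditions and
#' occasional grooming bouts.
#'
#' @param config a [scene_config()].
#' @param n_birds flock size (released on the two tables).
#' @param n_trials number of trials; each repeats `pattern`.
#' @param pattern condition pattern per trial, e.g.
#'   `"TC-CT-TC-TC-CT-TC-CT-CT"`.
#' @param presentation_s,gap_s presentation / gap durations (s).
#' @param p_dem_look probability that a demonstrator looks at the
#'   target during a test presentation.
#' @param obs_base_logit baseline log-odds of an observer target look.
#' @param obs_dem_effect increase in those log-odds per looking
#'   demonstrator (the injected collective effect).
#' @param p_distractor probability of an observer distractor look.
#' @param p_groom probability a bird grooms during a presentation.
#' @param p_binocular probability a scheduled look uses the binocular
#'   cone rather than a fovea.
#' @param noise_sd,dropout marker noise model (see [flock_scenario()]).
#' @param experiment_id experiment identifier for the schedule.
#' @param seed integer seed.
#' @return a [flock_scenario()].
#' @export
random_flock_scenario <- function(config, n_birds = 10, n_trials = 2,
                                  pattern = "TC-CT-TC-TC-CT-TC-CT-CT",
                                  presentation_s = 8, gap_s = 3,
                                  p_dem_look = 0.7,
                                  obs_base_logit = -1.6,
                                  obs_dem_effect = 0.35,
                                  p_distractor = 0.12, p_groom = 0.12,
                                  p_binocular = 0.08,
                                  noise_sd = 3e-04, dropout = 0.02,
                                  experiment_id = 1L, seed = 1L) {
  set.seed(as.integer(seed))
  fr <- config$frame_rate
  birds <- sprintf("bird%02d", seq_len(n_birds))
  min_frames <- ceiling(config$fixation_min_ms / 1000 * fr)

  sched <- list()
  start <- 0L
  for (tr in seq_len(n_trials)) {
    s <- schedule_from_pattern(pattern, config, trial_id = tr,
                               experiment_id = experiment_id,
                               presentation_s = presentation_s,
                               gap_s = gap_s, start_frame = start,
                               locations = sample(c("top", "bottom"),
                                                  50, replace = TRUE),
                               demonstrator_side = sample(c("A", "B"),
                                                          50,
                                                          replace = TRUE))
    sched[[tr]] <- s
    start <- max(s$end_frame) + as.integer(round(gap_s * fr))
  }
  sched <- do.call(rbind, sched)

  sides <- list(); events <- list(); grooms <- list()
  busy_by_bird <- stats::setNames(
    rep(list(data.frame(start = integer(), end = integer())), n_birds),
    birds)
  pick_cone <- function() {
    if (stats::runif(1) < p_binocular) return("binocular")
    sample(c("left_fovea", "right_fovea"), 1L)
  }
  for (p in seq_len(nrow(sched))) {
    sc <- sched[p, ]
    n_dem <- sample(2:(n_birds - 2L), 1L)
    dem <- sample(birds, n_dem)
    side <- ifelse(birds %in% dem, sc$demonstrator_side,
                   setdiff(c("A", "B"), sc$demonstrator_side))
    sides[[p]] <- data.frame(trial_id = sc$trial_id,
                             presentation_index = sc$presentation_index,
                             bird = birds, side = side,
                             behavior = "stay",
                             stringsAsFactors = FALSE)
    dem_target <- roi_for(sc$presentation_location, sc$demonstrator_side)
    obs_side <- setdiff(c("A", "B"), sc$demonstrator_side)
    obs_target <- roi_for(sc$presentation_location, obs_side)
    obs_distr <- roi_for(other_location(sc$presentation_location),
                         obs_side)

    schedule_look <- function(b, roi) {
      len <- as.integer(round(stats::runif(1, 1.4, 2.6) * min_frames))
      slot <- free_slot(sc$start_frame, sc$end_frame, len,
                        busy_by_bird[[b]])
      if (is.null(slot)) return(NULL)
      busy_by_bird[[b]] <<- rbind(busy_by_bird[[b]],
                                  data.frame(start = slot[1],
                                             end = slot[2]))
      data.frame(bird = b, trial_id = sc$trial_id,
                 presentation_index = sc$presentation_index,
                 roi = roi, cone = pick_cone(), start_frame = slot[1],
                 end_frame = slot[2], stringsAsFactors = FALSE)
    }

    n_looking <- 0L
    if (sc$condition == "test") {
      for (b in dem) {
        if (stats::runif(1) < p_dem_look) {
          e <- schedule_look(b, dem_target)
          if (!is.null(e)) {
            events[[length(events) + 1L]] <- e
            n_looking <- n_looking + 1L
          }
        }
      }
    }
    for (b in setdiff(birds, dem)) {
      p_look <- stats::plogis(obs_base_logit +
                                obs_dem_effect * n_looking)
      if (stats::runif(1) < p_look)
        events[[length(events) + 1L]] <- schedule_look(b, obs_target)
      if (stats::runif(1) < p_distractor)
        events[[length(events) + 1L]] <- schedule_look(b, obs_distr)
    }
    for (b in birds) {
      if (stats::runif(1) < p_groom) {
        len <- as.integer(round(stats::runif(1, 0.8, 1.5) * fr))
        slot <- free_slot(sc$start_frame, sc$end_frame, len,
                          busy_by_bird[[b]])
        if (!is.null(slot)) {
          busy_by_bird[[b]] <- rbind(busy_by_bird[[b]],
                                     data.frame(start = slot[1],
                                                end = slot[2]))
          grooms[[length(grooms) + 1L]] <-
            data.frame(bird = b, start_frame = slot[1],
                       end_frame = slot[2], stringsAsFactors = FALSE)
        }
      }
    }
  }
  events <- do.call(rbind, Filter(Negate(is.null), events))
  if (is.null(events))
    events <- data.frame(bird = character(), trial_id = integer(),
                         presentation_index = integer(),
                         roi = character(), cone = character(),
                         start_frame = integer(), end_frame = integer())
  grooms <- if (length(grooms)) do.call(rbind, grooms) else NULL
  flock_scenario(sched, do.call(rbind, sides), events, grooms,
                 noise_sd = noise_sd, dropout = dropout, seed = seed)
}
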