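# Shared fixtures, all generated in code.

quick_config <- function(...) scene_config(...)

# Small randomized scenario for end-to-end tests.
quick_scenario <- function(seed = 3, n_birds = 6, pattern = "TC-CT",
                           presentation_s = 6, gap_s = 2, ...) {
  random_flock_scenario(quick_config(), n_birds = n_birds,
                        n_trials = 1, pattern = pattern,
                        presentation_s = presentation_s, gap_s = gap_s,
                        seed = seed, ...)
}

# A deterministic scripted scenario: explicit schedule, sides and
# events. `events_per_bird` supra-threshold events per bird, plus
# `sub_ms` sub-threshold events if requested.
scripted_scenario <- function(config, n_birds = 4, n_presentations = 4,
                              events_per_bird = 1, sub_events = 0,
                              presentation_s = 8, gap_s = 2,
                              behaviors = NULL, grooming = NULL,
                              noise_sd = 0, dropout = 0, seed = 1) {
  fr <- config$frame_rate
  birds <- sprintf("bird%02d", seq_len(n_birds))
  pattern <- paste(rep(c("T", "C"), length.out = n_presentations),
                   collapse = "")
  sched <- schedule_from_pattern(pattern, config,
                                 presentation_s = presentation_s,
                                 gap_s = gap_s,
                                 locations = c("top", "bottom"),
                                 demonstrator_side = "A")
  half <- ceiling(n_birds / 2)
  sides <- do.call(rbind, lapply(seq_len(n_presentations), function(p)
    data.frame(trial_id = 1L, presentation_index = p, bird = birds,
               side = rep(c("A", "B"), c(half, n_birds - half)),
               behavior = "stay", stringsAsFactors = FALSE)))
  if (!is.null(behaviors)) {
    for (i in seq_len(nrow(behaviors))) {
      sel <- sides$bird == behaviors$bird[i] &
        sides$presentation_index == behaviors$presentation_index[i]
      sides$behavior[sel] <- behaviors$behavior[i]
    }
  }
  min_frames <- ceiling(config$fixation_min_ms / 1000 * fr)
  ev <- list()
  cones <- c("left_fovea", "right_fovea", "binocular")
  for (p in seq_len(n_presentations)) {
    w0 <- sched$start_frame[p]
    for (bi in seq_len(n_birds)) {
      for (k in seq_len(events_per_bird)) {
        len <- 2L * min_frames + 10L * k
        s <- w0 + 20L + (bi - 1L) * 5L + (k - 1L) * (len + fr)
        ev[[length(ev) + 1L]] <- data.frame(
          bird = birds[bi], trial_id = 1L, presentation_index = p,
          roi = sched$presentation_location[p],
          cone = cones[(bi + k) %% 3 + 1],
          start_frame = s, end_frame = s + len - 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (sub_events > 0) {
    sub_len <- max(2L, min_frames - ceiling(0.1 * fr) - 2L)
    for (k in seq_len(sub_events)) {
      p <- (k - 1L) %% n_presentations + 1L
      s <- sched$end_frame[p] - 2L * fr + k * 30L
      ev[[length(ev) + 1L]] <- data.frame(
        bird = birds[(k - 1L) %% n_birds + 1L], trial_id = 1L,
        presentation_index = p,
        roi = other_loc(sched$presentation_location[p]),
        cone = "left_fovea", start_frame = s,
        end_frame = s + sub_len - 1L, stringsAsFactors = FALSE)
    }
  }
  flock_scenario(sched, sides, do.call(rbind, ev), grooming,
                 noise_sd = noise_sd, dropout = dropout, seed = seed)
}

other_loc <- function(x) ifelse(x == "top", "bottom", "top")

# Match ground-truth events to recovered bouts; returns a data.frame
# with one row per event: matched (exactly one overlapping bout at the
# same bird/roi) and the absolute onset error in frames.
match_events_to_bouts <- function(events, bouts) {
  res <- data.frame(matched = logical(nrow(events)),
                    onset_err = NA_integer_)
  for (i in seq_len(nrow(events))) {
    hit <- bouts$bird == events$bird[i] & bouts$roi == events$roi[i] &
      bouts$start_frame <= events$end_frame[i] &
      bouts$end_frame >= events$start_frame[i]
    res$matched[i] <- sum(hit) == 1L
    if (res$matched[i])
      res$onset_err[i] <- abs(bouts$start_frame[hit] -
                                events$start_frame[i])
  }
  res
}

# Build a head_pose_series directly from a per-frame rotation schedule
# (list of R matrices or a single R recycled) and a fixed origin.
poses_from_rotations <- function(R_list, origin = c(0, 0, 1),
                                 frame_rate = 100, bird = "bird01",
                                 valid = NULL) {
  n <- length(R_list)
  Rarr <- array(NA_real_, c(3, 3, n))
  for (i in seq_len(n)) Rarr[, , i] <- R_list[[i]]
  if (is.null(valid)) valid <- rep(TRUE, n)
  birds <- list(list(origin = matrix(origin, n, 3, byrow = TRUE),
                     R = Rarr, valid = valid, rmsd = rep(0, n)))
  names(birds) <- bird
  head_pose_series(frame_rate, 0:(n - 1), birds)
}

no_masks <- function(poses) {
  list(saccade = lapply(poses$birds, function(b)
         ifelse(b$valid, FALSE, NA)),
       grooming = lapply(poses$birds, function(b)
         ifelse(b$valid, FALSE, NA)))
}

# Uniform random rotation matrix.
random_rotation <- function() {
  v <- stats::rnorm(3)
  gazeflock:::vec_to_rot(v / sqrt(sum(v^2)) * stats::runif(1, 0, pi))
}

# Independent ray-sampling oracle for cone/sphere crossing.
ray_oracle <- function(apex, axis, half_deg, roi, n_rays = 10000) {
  axis <- axis / sqrt(sum(axis^2))
  if (sqrt(sum((roi$center - apex)^2)) <= roi$radius_m) return(TRUE)
  a <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * axis) * axis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  cosph <- stats::runif(n_rays, cos(half_deg * pi / 180), 1)
  ph <- acos(cosph)
  th <- stats::runif(n_rays, 0, 2 * pi)
  U <- outer(cos(ph), axis) + outer(sin(ph) * cos(th), e1) +
    outer(sin(ph) * sin(th), e2)
  oc <- roi$center - apex
  tproj <- U %*% oc
  d2 <- sum(oc * oc) - tproj^2
  any(tproj > 0 & d2 <= roi$radius_m^2)
}
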