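# Synthetic flock generator. Emits marker-level trajectories with known
# ground truth (look events, saccade jumps, grooming bouts, table-side
# scripts) so the whole reconstruction pipeline can be validated against
# construction, plus presentation-level response tables with known
# effect sizes for the model-fitting stage.

#' Default synthetic head calibration
#'
#' A stylized pigeon head in the marker-template frame: eyes 2 cm apart
#' on the X axis, beak tip 2 cm ahead and 30 deg below the eye line (so
#' the constructed forward axis is horizontal for an upright template),
#' four non-coplanar markers on the crown.
#'
#' @return a [head_calibration()].
#' @export
synthetic_head_calibration <- function() {
  b <- 0.02 * c(0, cos(deg2rad(30)), -sin(deg2rad(30)))
  template <- rbind(c( 0.012,  0.004, 0.012),
                    c(-0.012,  0.004, 0.012),
                    c( 0.000, -0.014, 0.016),
                    c( 0.000,  0.016, 0.020))
  head_calibration(left_eye = c(-0.01, 0, 0), right_eye = c(0.01, 0, 0),
                   beak_tip = b, template = template)
}

#' Synthetic flock scenario
#'
#' Scripts everything the generator needs: the presentation schedule,
#' which table each bird stands on per presentation (with optional
#' scripted switches/fly-offs), ground-truth look events, grooming
#' bouts, and the marker noise model.
#'
#' @param schedule a `presentation_schedule` (see [read_schedule()]).
#' @param sides data.frame(trial_id, presentation_index, bird, side,
#'   behavior) with side in A/B and behavior in
#'   `stay`/`switch`/`flyoff`/`untracked`.
#' @param look_events data.frame(bird, trial_id, presentation_index,
#'   roi, cone, start_frame, end_frame); events must lie inside their
#'   presentation window.
#' @param grooming data.frame(bird, start_frame, end_frame), possibly
#'   empty.
#' @param noise_sd isotropic marker noise sd in meters (>= 0).
#' @param dropout per-marker per-frame dropout probability in `[0, 1]`.
#' @param seed integer seed; all randomness in the generator flows from
#'   it (per-bird substreams are derived deterministically).
#' @return object of class `flock_scenario`.
#' @export
flock_scenario <- function(schedule, sides, look_events,
                           grooming = NULL, noise_sd = 3e-04,
                           dropout = 0.02, seed = 1L) {
  schedule <- validate_schedule(as.data.frame(schedule))
  stopifnot(noise_sd >= 0, dropout >= 0, dropout <= 1)
  if (is.null(grooming))
    grooming <- data.frame(bird = character(), start_frame = integer(),
                           end_frame = integer())
  if (nrow(look_events)) {
    key <- paste(look_events$trial_id, look_events$presentation_index)
    skey <- paste(schedule$trial_id, schedule$presentation_index)
    m <- match(key, skey)
    if (anyNA(m)) stop("look event refers to an unknown presentation")
    inside <- look_events$start_frame >= schedule$start_frame[m] &
      look_events$end_frame <= schedule$end_frame[m]
    if (!all(inside)) stop("look events must lie inside their window")
    if (any(look_events$start_frame > look_events$end_frame))
      stop("look events need start_frame <= end_frame")
  }
  structure(list(schedule = schedule, sides = sides,
                 look_events = look_events, grooming = grooming,
                 noise_sd = noise_sd, dropout = dropout,
                 seed = as.integer(seed),
                 birds = sort(unique(sides$bird))),
            class = "flock_scenario")
}

#' @export
print.flock_scenario <- function(x, ...) {
  cat("Synthetic flock scenario:", length(x$birds), "birds,",
      nrow(x$schedule), "presentations,",
      nrow(x$look_events), "look events\n")
  cat("  marker noise sd:", x$noise_sd, "m; dropout:", x$dropout,
      "; seed:", x$seed, "\n")
  invisible(x)
}

# Standing spots along each table (world frame).
table_spot <- function(region, slot, n_slots) {
  x <- seq(region$xlim[1] + 0.15, region$xlim[2] - 0.15,
           length.out = max(n_slots, 2L))[slot]
  c(x, mean(region$ylim), mean(region$zlim))
}

# Pose aiming a cone (elevation 0) exactly at a world target point,
# keeping head-up as close to world-up as possible.
aim_pose <- function(origin, target, azimuth_deg) {
  u <- normalize3(target - origin)
  zw <- c(0, 0, 1)
  Z <- zw - sum(zw * u) * u
  if (vnorm(Z) < 1e-9) stop("cannot aim straight up/down")
  Z <- normalize3(Z)
  W2 <- cross3(Z, u)
  phi <- deg2rad(azimuth_deg - 90)
  X <- cos(phi) * u + sin(phi) * W2
  Y <- -sin(phi) * u + cos(phi) * W2
  cbind(X, Y, Z, deparse.level = 0)
}

# Pose with forward axis at a given yaw/pitch (rad), head-up near
# world-up.
yaw_pitch_pose <- function(yaw, pitch) {
  Y <- c(sin(yaw) * cos(pitch), cos(yaw) * cos(pitch), sin(pitch))
  zw <- c(0, 0, 1)
  Z <- zw - sum(zw * Y) * Y
  Z <- normalize3(Z)
  X <- cross3(Y, Z)
  cbind(X, Y, Z, deparse.level = 0)
}

# Would any cone from this pose hit any ROI, with an angular margin?
pose_hits_any_roi <- function(origin, R, cone_specs, rois, margin_deg) {
  for (roi in rois) {
    v <- roi$center - origin
    d <- vnorm(v)
    cap <- asin(min(1, roi$radius_m / max(d, roi$radius_m)))
    for (cs in cone_specs) {
      ax <- cone_axis_world(R, cs)
      if (vec_angle(ax, v) <=
          deg2rad(cs$half_angle_deg + margin_deg) + cap)
        return(TRUE)
    }
  }
  FALSE
}

# Random wandering pose at least `margin_deg` clear of every cone/ROI
# combination.
wander_pose <- function(origin, cone_specs, rois, margin_deg = 5) {
  for (try in 1:200) {
    R <- yaw_pitch_pose(stats::runif(1, -pi, pi),
                        stats::runif(1, deg2rad(-20), deg2rad(40)))
    if (!pose_hits_any_roi(origin, R, cone_specs, rois, margin_deg))
      return(R)
  }
  stop("could not sample a clear wandering pose")
}

#' Generate marker trajectories for a scripted flock scenario
#'
#' Head motion is piecewise constant: fixations separated by
#' instantaneous orientation jumps (head saccades). During each scripted
#' look event the designated cone's center line points exactly at the
#' ROI center; outside events the head wanders with every cone at least
#' 5 deg clear of every ROI sphere. Grooming bouts pitch the head 60 deg
#' down next to the backpack. The scripted poses are converted to the
#' four head markers through the calibration template, then corrupted
#' with isotropic Gaussian noise and random per-marker dropout.
#'
#' Events shorter than the fixation threshold at the configured frame
#' rate are kept but marked `sub_threshold` in the returned ground
#' truth (with a warning): by construction the pipeline must not
#' recover them as bouts.
#'
#' @param scenario a [flock_scenario()].
#' @param calib a single [head_calibration()] applied to every bird, or
#'   a named list per bird.
#' @param config a [scene_config()].
#' @return list with `markers` (a [marker_series()]), `truth` (list of
#'   `events` with a `sub_threshold` flag, `grooming`, `saccade_frames`
#'   per bird, `sides`, and per-frame `poses` as a
#'   [head_pose_series()]), and `calibs` (named list actually used).
#' @export
generate_flock_trajectories <- function(scenario, calib, config) {
  stopifnot(inherits(scenario, "flock_scenario"),
            inherits(config, "scene_config"))
  fr <- config$frame_rate
  birds <- scenario$birds
  calibs <- if (inherits(calib, "head_calibration"))
    stats::setNames(rep(list(calib), length(birds)), birds)
  else calib
  n_total <- max(scenario$schedule$end_frame) + round(2 * fr) + 1L
  frames <- 0:(n_total - 1L)
  min_frames <- ceiling(config$fixation_min_ms / 1000 * fr)

  ev <- scenario$look_events
  if (nrow(ev)) {
    ev$sub_threshold <- (ev$end_frame - ev$start_frame + 1L) < min_frames
    if (any(ev$sub_threshold))
      warning(sum(ev$sub_threshold),
              " look event(s) are shorter than the fixation threshold",
              " and marked sub_threshold")
  } else ev$sub_threshold <- logical(0)

  cone_az <- stats::setNames(
    vapply(config$cone_specs, `[[`, numeric(1), "azimuth_deg"),
    vapply(config$cone_specs, `[[`, character(1), "label"))

  sched <- scenario$schedule
  skey <- paste(sched$trial_id, sched$presentation_index)
  region_of <- function(side) config$table_regions[[side]]

  birds_out <- list()
  pose_birds <- list()
  sac_truth <- list()
  for (bi in seq_along(birds)) {
    b <- birds[bi]
    # deterministic per-bird substream, kept within the 32-bit seed range
    set.seed((scenario$seed %% 2000000L) * 1000L + bi)
    cal <- calibs[[b]]
    calfr <- build_head_frame(cal$left_eye, cal$right_eye, cal$beak_tip,
                              cal$head_up)
    # head <- template transform pieces: p_w = Rwt (p_t - o_t) + o_h
    Rt <- calfr$R; ot <- calfr$origin

    # --- body position timeline -------------------------------------
    srows <- scenario$sides[scenario$sides$bird == b, , drop = FALSE]
    pos <- matrix(NA_real_, n_total, 3L)
    head_z <- 0.15  # head height above table surface
    cur <- NULL
    for (si in seq_len(nrow(srows))) {
      pr <- sched[skey == paste(srows$trial_id[si],
                                srows$presentation_index[si]), ]
      if (nrow(pr) != 1L) stop("side row without matching presentation")
      w0 <- pr$start_frame + 1L  # to 1-based row index (frames are 0-based)
      w1 <- pr$end_frame + 1L
      beh <- if ("behavior" %in% names(srows)) srows$behavior[si] else "stay"
      reg <- region_of(srows$side[si])
      spot <- table_spot(reg, 1L + (bi - 1L) %% 5L, 5L)
      spot[3] <- mean(reg$zlim) + head_z / 2
      if (beh == "untracked") {
        # leave NA for the whole window
      } else if (beh == "switch") {
        other <- setdiff(names(config$table_regions), srows$side[si])
        reg2 <- region_of(other)
        spot2 <- table_spot(reg2, 1L + (bi - 1L) %% 5L, 5L)
        spot2[3] <- mean(reg2$zlim) + head_z / 2
        mid <- (w0 + w1) %/% 2L
        hop <- min(w1, mid + as.integer(fr %/% 2))
        pos[w0:mid, ] <- matrix(spot, mid - w0 + 1L, 3L, byrow = TRUE)
        # fly over the stimulus structure, clear of the ROI spheres
        apexp <- c((spot[1] + spot2[1]) / 2, 0, 1.25)
        h1 <- (mid + hop) %/% 2L
        tt <- seq(0, 1, length.out = h1 - mid + 1L)
        pos[mid:h1, ] <- outer(1 - tt, spot) + outer(tt, apexp)
        tt <- seq(0, 1, length.out = hop - h1 + 1L)
        pos[h1:hop, ] <- outer(1 - tt, apexp) + outer(tt, spot2)
        if (hop < w1)
          pos[(hop + 1L):w1, ] <- matrix(spot2, w1 - hop, 3L, byrow = TRUE)
      } else if (beh == "flyoff") {
        mid <- (w0 + w1) %/% 2L
        away <- c(spot[1], sign(spot[2]) * 2.5, 1.6)  # off the tables
        pos[w0:mid, ] <- matrix(spot, mid - w0 + 1L, 3L, byrow = TRUE)
        pos[(mid + 1L):w1, ] <- matrix(away, w1 - mid, 3L, byrow = TRUE)
      } else {
        pos[w0:w1, ] <- matrix(spot, w1 - w0 + 1L, 3L, byrow = TRUE)
      }
      # hold position through the gap after the window
      if (is.null(cur) && w0 > 1L)
        pos[seq_len(w0 - 1L), ] <- matrix(pos[w0, ], w0 - 1L, 3L,
                                          byrow = TRUE)
      cur <- pos[w1, ]
      nxt <- if (si < nrow(srows)) {
        pr2 <- sched[skey == paste(srows$trial_id[si + 1L],
                                   srows$presentation_index[si + 1L]), ]
        pr2$start_frame + 1L
      } else n_total
      if (w1 < nxt && !anyNA(cur))
        pos[(w1 + 1L):nxt, ] <- matrix(cur, nxt - w1, 3L, byrow = TRUE)
    }
    # any frames still NA outside untracked windows: hold last known
    if (anyNA(pos[1, ])) {
      first_ok <- which(stats::complete.cases(pos))[1]
      if (!is.na(first_ok) && first_ok > 1L)
        pos[seq_len(first_ok - 1L), ] <-
          matrix(pos[first_ok, ], first_ok - 1L, 3L, byrow = TRUE)
    }

    # --- orientation timeline ---------------------------------------
    Rseq <- array(NA_real_, c(3L, 3L, n_total))
    track_ok <- stats::complete.cases(pos)
    bev <- ev[ev$bird == b, , drop = FALSE]
    bgr <- scenario$grooming[scenario$grooming$bird == b, , drop = FALSE]
    occupied <- rep(FALSE, n_total)
    groom_flag <- rep(FALSE, n_total)
    for (k in seq_len(nrow(bev))) {
      i0 <- bev$start_frame[k] + 1L; i1 <- bev$end_frame[k] + 1L
      roi <- config$rois[[bev$roi[k]]]
      if (is.null(roi)) stop("unknown ROI in look event: ", bev$roi[k])
      az <- cone_az[[bev$cone[k]]]
      if (is.null(az)) stop("unknown cone in look event: ", bev$cone[k])
      for (i in i0:i1) {
        if (!track_ok[i]) next
        Rseq[, , i] <- aim_pose(pos[i, ], roi$center, az)
        occupied[i] <- TRUE
      }
    }
    for (k in seq_len(nrow(bgr))) {
      i0 <- bgr$start_frame[k] + 1L; i1 <- bgr$end_frame[k] + 1L
      Rg <- yaw_pitch_pose(stats::runif(1, -pi, pi), deg2rad(-60))
      for (i in i0:i1) {
        if (!track_ok[i] || occupied[i]) next
        Rseq[, , i] <- Rg
        occupied[i] <- TRUE
        groom_flag[i] <- TRUE
      }
    }
    # fill remaining frames with wandering fixations
    i <- 1L
    while (i <= n_total) {
      if (occupied[i] || !track_ok[i]) { i <- i + 1L; next }
      len <- round(stats::runif(1, 0.35, 1.2) * fr)
      j <- i
      # a fixation ends at scheduled behavior, tracking loss, or a
      # change of standing position (the pose was sampled for pos[i, ])
      while (j <= n_total && j - i + 1L <= len &&
             !occupied[j] && track_ok[j] &&
             isTRUE(all(pos[j, ] == pos[i, ]))) j <- j + 1L
      Rw <- wander_pose(pos[i, ], config$cone_specs, config$rois)
      for (t in i:(j - 1L)) Rseq[, , t] <- Rw
      i <- j
    }

    # grooming pulls the head down toward the backpack
    # behind/below the head spot, clear of the grooming distance gate
    backpack_offset <- c(0, -0.08, -0.16)
    bp_center <- pos + matrix(backpack_offset, n_total, 3L, byrow = TRUE)
    origin_seq <- pos
    groom_origin_shift <- c(0, -0.045, -0.10)
    if (any(groom_flag))
      origin_seq[groom_flag, ] <- pos[groom_flag, , drop = FALSE] +
        matrix(groom_origin_shift, sum(groom_flag), 3L, byrow = TRUE)

    # ground-truth saccade frames: orientation jumps between
    # consecutive tracked frames
    pose_ok <- track_ok & is.finite(Rseq[1, 1, ])
    tr <- colSums(matrix(Rseq[, , 1:(n_total - 1L)] *
                           Rseq[, , 2:n_total], 9L))
    sp <- rad2deg(acos(pmax(-1, pmin(1, (tr - 1) / 2)))) * fr
    ji <- which(pose_ok[-1L] & pose_ok[-n_total] &
                  sp > config$saccade_threshold_deg_s) + 1L
    jumps <- frames[ji]

    # --- emit markers ------------------------------------------------
    head_arr <- array(NA_real_, c(n_total, 4L, 3L))
    bp_arr <- array(NA_real_, c(n_total, 4L, 3L))
    bp_template <- rbind(c(0.03, 0.03, 0), c(-0.03, 0.03, 0),
                         c(0.03, -0.03, 0), c(-0.03, -0.03, 0))
    emit <- which(pose_ok)
    for (m in 1:4) {
      # marker position = Rseq_i (Rt' (template_m - ot)) + origin_i
      q <- as.numeric(t(Rt) %*% (cal$template[m, ] - ot))
      pw <- q[1] * Rseq[, 1, ] + q[2] * Rseq[, 2, ] + q[3] * Rseq[, 3, ]
      head_arr[emit, m, ] <- t(pw)[emit, , drop = FALSE] +
        origin_seq[emit, , drop = FALSE]
      bp_arr[emit, m, ] <- bp_center[emit, , drop = FALSE] +
        matrix(bp_template[m, ], length(emit), 3L, byrow = TRUE)
    }
    if (scenario$noise_sd > 0) {
      nz <- array(stats::rnorm(length(head_arr), 0, scenario$noise_sd),
                  dim = dim(head_arr))
      head_arr <- head_arr + nz
    }
    if (scenario$dropout > 0) {
      drop <- matrix(stats::runif(n_total * 4L) < scenario$dropout,
                     n_total, 4L)
      for (m in 1:4) head_arr[drop[, m], m, ] <- NA_real_
    }

    birds_out[[b]] <- list(head = head_arr, backpack = bp_arr)
    ok_pose <- track_ok & is.finite(Rseq[1, 1, ])
    pose_birds[[b]] <- list(origin = origin_seq, R = Rseq,
                            valid = ok_pose,
                            rmsd = rep(0, n_total))
    sac_truth[[b]] <- jumps
  }

  truth <- list(events = ev, grooming = scenario$grooming,
                saccade_frames = sac_truth, sides = scenario$sides,
                poses = head_pose_series(fr, frames, pose_birds))
  list(markers = marker_series(fr, frames, birds_out), truth = truth,
       calibs = calibs)
}

#' Effect specification for synthetic response tables
#'
#' Defines the generating GLMM for a statistical twin of the
#' per-presentation observer table: a baseline (log-odds for the binary
#' response, log-rate for the count response), a condition effect, a
#' demonstrator-count effect on the z-scored count (optionally with a
#' quadratic term), and per-individual Gaussian random intercepts and
#' slopes.
#'
#' Defaults mirror the fitted effect sizes at the combined-data scale: a
#' demonstrator-count effect of 0.324 (z scale) and a condition effect
#' of 0.425, with modest random-effect spread.
#'
#' @param baseline intercept (log-odds and log-rate scale).
#' @param beta_cond condition (test vs control) effect.
#' @param beta_dem demonstrator-count effect, z-scored scale.
#' @param beta_dem2 quadratic demonstrator-count effect (on z squared).
#' @param sd_intercept,sd_slope_cond,sd_slope_dem random-effect sds
#'   (>= 0).
#' @param n_individuals number of observer individuals (>= 2).
#' @param n_presentations presentations (rows) per individual.
#' @param max_demonstrators largest possible demonstrator count (one
#'   less than the flock size).
#' @return object of class `effect_spec`.
#' @export
effect_spec <- function(baseline = 0, beta_cond = 0.425,
                        beta_dem = 0.324, beta_dem2 = 0,
                        sd_intercept = 0.5, sd_slope_cond = 0.2,
                        sd_slope_dem = 0.2, n_individuals = 70,
                        n_presentations = 21, max_demonstrators = 9) {
  stopifnot(sd_intercept >= 0, sd_slope_cond >= 0, sd_slope_dem >= 0,
            n_individuals >= 2, n_presentations >= 1,
            max_demonstrators >= 1)
  structure(as.list(environment()), class = "effect_spec")
}

#' Generate a per-presentation response table with known effects
#'
#' Draws a table shaped like the observer analysis table: one row per
#' observer per presentation, with condition, demonstrator count,
#' trial/presentation control covariates, and both a binary response
#' (`looked`, Bernoulli through a logit link) and a count response
#' (`n_looks`, Poisson through a log link) generated from the linear
#' predictor
#' `eta = baseline + beta_cond * cond + beta_dem * z + beta_dem2 * z^2
#'  + b0_i + bc_i * cond + bd_i * z`,
#' where `z` is the within-table z-scored demonstrator count and the
#' `b`s are independent per-individual Gaussian effects. The generating
#' parameters and the per-individual effects are returned alongside.
#'
#' @param spec an [effect_spec()].
#' @param seed integer seed.
#' @return list with `table` (data.frame) and `truth` (spec plus the
#'   drawn random effects).
#' @export
generate_response_table <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "effect_spec"))
  set.seed(as.integer(seed))
  ni <- spec$n_individuals; np <- spec$n_presentations
  ids <- sprintf("bird%03d", seq_len(ni))
  b0 <- stats::rnorm(ni, 0, spec$sd_intercept)
  bc <- stats::rnorm(ni, 0, spec$sd_slope_cond)
  bd <- stats::rnorm(ni, 0, spec$sd_slope_dem)
  tab <- expand.grid(presentation_index = seq_len(np),
                     observer_id = ids, stringsAsFactors = FALSE)
  n <- nrow(tab)
  tab$trial_id <- (tab$presentation_index - 1L) %/% 8L + 1L
  tab$condition <- ifelse(stats::runif(n) < 0.5, "test", "control")
  tab$presentation_location <- sample(c("top", "bottom"), n,
                                      replace = TRUE)
  tab$n_actual_demonstrators <- sample.int(spec$max_demonstrators, n,
                                           replace = TRUE)
  i <- match(tab$observer_id, ids)
  z <- as.numeric(scale(tab$n_actual_demonstrators))
  cond <- as.numeric(tab$condition == "test")
  eta <- spec$baseline + spec$beta_cond * cond + spec$beta_dem * z +
    spec$beta_dem2 * z^2 + b0[i] + bc[i] * cond + bd[i] * z
  tab$looked <- stats::rbinom(n, 1L, stats::plogis(eta))
  tab$n_looks <- stats::rpois(n, exp(eta))
  list(table = tab,
       truth = list(spec = spec,
                    random_effects = data.frame(
                      observer_id = ids, intercept = b0,
                      slope_cond = bc, slope_dem = bd)))
}
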