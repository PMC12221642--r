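# Rigid alignment, head-frame construction, smoothing and masks.

test_that("rigid_align recovers exact rigid motions and stays proper", {
  set.seed(11)
  tpl <- synthetic_head_calibration()$template
  for (rep in 1:20) {
    R0 <- random_rotation()
    t0 <- rnorm(3)
    obs <- sweep(tpl %*% t(R0), 2, t0, "+")
    al <- rigid_align(obs, tpl)
    expect_lt(max(abs(al$R - R0)), 1e-10)
    expect_lt(max(abs(al$t - t0)), 1e-10)
    expect_lt(al$rmsd, 1e-10)
  }
})

test_that("rigid_align rmsd tracks the noise level and det stays +1", {
  set.seed(12)
  tpl <- synthetic_head_calibration()$template
  rmsds <- replicate(200, {
    R0 <- random_rotation()
    obs <- tpl %*% t(R0) + matrix(rnorm(12, 0, 1e-3), 4, 3)
    al <- rigid_align(obs, tpl)
    expect_equal(det(al$R), 1, tolerance = 1e-9)
    al$rmsd
  })
  # per-point rmsd after fitting ~ sd * sqrt(2 * (n - 2) / n) scale
  expect_gt(mean(rmsds), 0.3e-3)
  expect_lt(mean(rmsds), 2e-3)
})

test_that("rigid_align needs three valid markers", {
  tpl <- synthetic_head_calibration()$template
  obs <- tpl
  obs[1, 1] <- NA
  expect_false(is.null(rigid_align(obs, tpl)))
  obs[2, 2] <- NA
  expect_null(rigid_align(obs, tpl))
})

test_that("head frame puts the beak at -30 deg elevation, azimuth 0", {
  fr <- build_head_frame(c(-0.01, 0, 0), c(0.01, 0, 0),
                         c(0, 0.0173, -0.01))
  expect_equal(fr$origin, c(0, 0, 0))
  expect_equal(fr$R[, 2], c(0, 1, 0), tolerance = 1e-3)
  bh <- c(0, 0.0173, -0.01); bh <- bh / sqrt(sum(bh^2))
  hb <- as.numeric(t(fr$R) %*% bh)
  expect_equal(atan2(hb[1], hb[2]) * 180 / pi, 0, tolerance = 1e-6)
  expect_equal(asin(hb[3]) * 180 / pi, -30, tolerance = 0.1)

  # exact -30: beak constructed exactly 30 deg below horizontal
  beak <- 0.02 * c(0, cos(pi / 6), -sin(pi / 6))
  fr2 <- build_head_frame(c(-0.01, 0, 0), c(0.01, 0, 0), beak)
  hb2 <- as.numeric(t(fr2$R) %*% (beak / sqrt(sum(beak^2))))
  expect_equal(asin(hb2[3]) * 180 / pi, -30, tolerance = 1e-6)
  # eyes at elevation 0, azimuth signs by side
  re <- as.numeric(t(fr2$R) %*% c(0.01, 0, 0)) # right eye - origin
  expect_equal(re[3], 0, tolerance = 1e-9)
  expect_gt(re[1], 0)
})

test_that("head frame is orthonormal, right-handed, and invertible", {
  set.seed(13)
  cal <- synthetic_head_calibration()
  for (rep in 1:20) {
    R0 <- random_rotation()
    t0 <- rnorm(3)
    w <- function(p) as.numeric(R0 %*% p + t0)
    base <- build_head_frame(cal$left_eye, cal$right_eye, cal$beak_tip,
                             cal$head_up)
    fr <- build_head_frame(w(cal$left_eye), w(cal$right_eye),
                           w(cal$beak_tip),
                           head_up = as.numeric(R0 %*% cal$head_up))
    expect_lt(max(abs(crossprod(fr$R) - diag(3))), 1e-12)
    expect_equal(det(fr$R), 1, tolerance = 1e-12)
    # transforming the inputs transforms the frame: R_world = R0 R_base
    expect_lt(max(abs(fr$R - R0 %*% base$R)), 1e-10)
  }
  expect_error(build_head_frame(c(-0.01, 0, 0), c(0.01, 0, 0),
                                c(0.05, 0, 0)), "collinear")
})

test_that("pose reconstruction is equivariant under global rigid moves", {
  cfg <- quick_config()
  sc <- scripted_scenario(cfg, n_birds = 2, n_presentations = 1,
                          presentation_s = 3)
  gen <- generate_flock_trajectories(sc, synthetic_head_calibration(),
                                     cfg)
  poses <- reconstruct_head_poses(gen$markers, gen$calibs, cfg)
  set.seed(14)
  Rg <- random_rotation(); tg <- rnorm(3)
  moved <- gen$markers
  for (b in bird_ids(moved)) {
    for (part in c("head", "backpack")) {
      a <- moved$birds[[b]][[part]]
      for (m in seq_len(dim(a)[2]))
        a[, m, ] <- sweep(a[, m, , drop = TRUE] %*% t(Rg), 2, tg, "+")
      moved$birds[[b]][[part]] <- a
    }
  }
  poses2 <- reconstruct_head_poses(moved, gen$calibs, cfg)
  b <- bird_ids(moved)[1]
  i <- which(poses$birds[[b]]$valid)[5]
  expect_equal(poses2$birds[[b]]$origin[i, ],
               as.numeric(Rg %*% poses$birds[[b]]$origin[i, ] + tg),
               tolerance = 1e-8)
  expect_equal(poses2$birds[[b]]$R[, , i],
               Rg %*% poses$birds[[b]]$R[, , i], tolerance = 1e-8)
})

test_that("smoothing fills short gaps, keeps long gaps, reduces jitter", {
  cfg <- quick_config()
  R0 <- diag(3)
  n <- 80
  # constant pose with a 3-frame gap
  valid <- rep(TRUE, n); valid[40:42] <- FALSE
  poses <- poses_from_rotations(rep(list(R0), n), valid = valid)
  sm <- smooth_poses(poses, cfg)
  expect_true(all(sm$birds$bird01$valid))
  expect_equal(sm$birds$bird01$R[, , 41], R0, tolerance = 1e-12)
  expect_equal(sm$birds$bird01$origin[41, ], c(0, 0, 1))

  # 50-frame gap stays invalid
  valid2 <- rep(TRUE, 120); valid2[30:79] <- FALSE
  poses2 <- poses_from_rotations(rep(list(R0), 120), valid = valid2)
  sm2 <- smooth_poses(poses2, cfg)
  expect_false(any(sm2$birds$bird01$valid[30:79]))

  # white orientation noise: output angular jitter < input jitter
  set.seed(15)
  noisy <- lapply(1:200, function(i)
    gazeflock:::vec_to_rot(rnorm(3, 0, 0.02)))
  poses3 <- poses_from_rotations(noisy)
  sm3 <- smooth_poses(poses3, cfg)
  jitter <- function(p) mean(sapply(2:200, function(i)
    gazeflock:::rot_angle(p$birds$bird01$R[, , i - 1],
                          p$birds$bird01$R[, , i])))
  expect_lt(jitter(sm3), jitter(poses3))
})

test_that("saccade mask flags exactly the fast rotation frames", {
  cfg <- quick_config()
  R0 <- diag(3)
  R1 <- gazeflock:::rot_about(c(0, 0, 1), 20 * pi / 180)
  poses <- poses_from_rotations(c(rep(list(R0), 50), rep(list(R1), 50)))
  m <- detect_saccades(poses, 300)[[1]]
  expect_identical(which(m), 51L)  # 20 deg in one frame at 100 Hz
  # static head: nothing flagged
  m0 <- detect_saccades(poses_from_rotations(rep(list(R0), 50)), 300)[[1]]
  expect_false(any(m0))
  # first frame of each valid run is never flagged
  valid <- rep(TRUE, 100); valid[49:50] <- FALSE
  poses2 <- poses_from_rotations(c(rep(list(R0), 50), rep(list(R1), 50)),
                                 valid = valid)
  m2 <- detect_saccades(poses2, 300)[[1]]
  expect_true(is.na(m2[50]))
  expect_false(isTRUE(m2[51]))  # run restart, no predecessor
})

test_that("grooming heuristic flags head-down near-backpack postures", {
  cfg <- quick_config()
  sc <- scripted_scenario(cfg, n_birds = 2, n_presentations = 1,
                          presentation_s = 6,
                          grooming = data.frame(
                            bird = "bird01", start_frame = 100L,
                            end_frame = 220L))
  gen <- generate_flock_trajectories(sc, synthetic_head_calibration(),
                                     cfg)
  poses <- smooth_poses(
    reconstruct_head_poses(gen$markers, gen$calibs, cfg), cfg)
  g <- detect_grooming(poses, gen$markers, cfg)
  flagged <- which(g$bird01)
  expect_gt(length(flagged), 80)
  expect_true(all(flagged >= 99 & flagged <= 224))
  # the second, upright bird is never flagged
  expect_false(any(g$bird02, na.rm = TRUE))
  # an external mask passes through verbatim
  ext <- list(bird01 = rep(c(TRUE, FALSE), 5))
  expect_identical(detect_grooming(poses, gen$markers, cfg,
                                   external = ext), ext)
})

test_that("masks are defined exactly on valid-pose frames", {
  cfg <- quick_config()
  sc <- quick_scenario(seed = 21, n_birds = 3, pattern = "T",
                       presentation_s = 4, gap_s = 1, dropout = 0.25)
  gen <- generate_flock_trajectories(sc, synthetic_head_calibration(),
                                     cfg)
  poses <- reconstruct_head_poses(gen$markers, gen$calibs, cfg)
  sac <- detect_saccades(poses, cfg$saccade_threshold_deg_s)
  grm <- detect_grooming(poses, gen$markers, cfg)
  for (b in names(poses$birds)) {
    v <- poses$birds[[b]]$valid
    expect_true(all(is.na(sac[[b]][!v])))
    expect_true(all(!is.na(sac[[b]][v])))
    expect_true(all(is.na(grm[[b]][!v])))
  }
})
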