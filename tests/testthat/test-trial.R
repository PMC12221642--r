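# Side assignment, demonstrator counting, the observer table and the
# exclusion rules.

regions <- default_table_regions()

test_that("side assignment flags switches, fly-offs and untracked birds", {
  onA <- matrix(c(0, 0.85, 0.8), 60, 3, byrow = TRUE)
  onB <- matrix(c(0, -0.85, 0.8), 60, 3, byrow = TRUE)
  off <- matrix(c(3, 0, 1.6), 30, 3, byrow = TRUE)
  s <- assign_sides(list(stay = onA,
                         switch = rbind(onA[1:30, ], onB[1:30, ]),
                         flyoff = rbind(onA[1:30, ], off),
                         untracked = matrix(NA_real_, 60, 3)),
                    regions)
  expect_equal(s$side[s$bird == "stay"], "A")
  expect_false(any(unlist(s[s$bird == "stay",
                            c("flew_off", "switched", "untracked")])))
  expect_true(s$switched[s$bird == "switch"])
  expect_true(s$flew_off[s$bird == "flyoff"])
  expect_false(s$switched[s$bird == "flyoff"])
  expect_true(s$untracked[s$bird == "untracked"])
})

test_that("actual-demonstrator counting follows the overlap rule", {
  bouts <- data.frame(
    bird = c("d1", "d2", "d3", "o1"),
    roi = c("top", "top", "bottom", "top"),
    cone = "left_fovea",
    start_frame = c(100L, 200L, 150L, 300L),
    end_frame = c(160L, 260L, 210L, 360L))
  dem <- c("d1", "d2", "d3", "d4", "d5")
  # 3 demonstrators, only 2 with *target* (top) bouts; observer never
  # grooms
  expect_equal(count_actual_demonstrators(bouts, dem, "top", 0L, 500L),
               2L)
  frames <- 0:500
  never <- rep(FALSE, 501)
  expect_equal(count_actual_demonstrators(bouts, dem, "top", 0L, 500L,
                                          never, frames), 2L)
  # observer grooming for the whole window: all looks excluded
  always <- rep(TRUE, 501)
  expect_equal(count_actual_demonstrators(bouts, dem, "top", 0L, 500L,
                                          always, frames), 0L)
  # one demonstrator bout fully inside grooming, the other outside
  g <- rep(FALSE, 501); g[101:161] <- TRUE  # covers d1 bout entirely
  expect_equal(count_actual_demonstrators(bouts, dem, "top", 0L, 500L,
                                          g, frames), 1L)
  # a single overlapping non-grooming frame is enough
  g2 <- rep(TRUE, 501); g2[161] <- FALSE    # d1 bout ends at frame 160
  expect_equal(count_actual_demonstrators(bouts, dem, "top", 0L, 500L,
                                          g2, frames), 1L)
  expect_equal(count_actual_demonstrators(bouts, character(0), "top",
                                          0L, 500L), 0L)
})

test_that("removing observer grooming never lowers the count", {
  set.seed(51)
  frames <- 0:400
  for (rep in 1:20) {
    n <- 6
    bouts <- data.frame(
      bird = paste0("d", sample(1:4, n, replace = TRUE)),
      roi = "top", cone = "left_fovea",
      start_frame = sample(0:300, n))
    bouts$end_frame <- bouts$start_frame + sample(30:80, n)
    g <- runif(401) < 0.4
    with_g <- count_actual_demonstrators(bouts, paste0("d", 1:4), "top",
                                         0L, 400L, g, frames)
    without <- count_actual_demonstrators(bouts, paste0("d", 1:4), "top",
                                          0L, 400L, rep(FALSE, 401),
                                          frames)
    expect_lte(with_g, without)
  }
})

make_fixture_table <- function() {
  cfg <- quick_config()
  sched <- validate_schedule(data.frame(
    trial_id = 1L, presentation_index = 1:2,
    condition = c("test", "control"),
    presentation_location = c("top", "bottom"),
    demonstrator_side = "A",
    start_frame = c(0L, 1000L), end_frame = c(800L, 1800L),
    experiment_id = 1L))
  sides <- do.call(rbind, lapply(1:2, function(p) data.frame(
    trial_id = 1L, presentation_index = p,
    bird = c("d1", "d2", "o1", "o2"),
    side = c("A", "A", "B", "B"),
    flew_off = FALSE, switched = FALSE, untracked = FALSE)))
  # o1: target bouts at 3.2 s and 7.0 s, distractor bout at 5.1 s
  bouts <- data.frame(
    bird = c("d1", "o1", "o1", "o1"),
    roi = c("top", "top", "bottom", "top"),
    cone = "left_fovea",
    start_frame = c(100L, 320L, 510L, 700L),
    end_frame = c(160L, 360L, 550L, 740L),
    duration_ms = c(610, 410, 410, 410))
  grooming <- list(d1 = rep(FALSE, 1801), d2 = rep(FALSE, 1801),
                   o1 = rep(FALSE, 1801), o2 = rep(FALSE, 1801))
  list(cfg = cfg, sched = sched, sides = sides, bouts = bouts,
       grooming = grooming, frames = 0:1800)
}

test_that("the observer table matches the hand-computed fixture", {
  fx <- make_fixture_table()
  tab <- build_presentation_table(fx$bouts, fx$sched, fx$sides,
                                  fx$grooming, fx$frames, fx$cfg)
  # presentation 1: two observer rows (o1, o2)
  p1 <- tab[tab$presentation_index == 1, ]
  expect_equal(sort(p1$observer_id), c("o1", "o2"))
  o1 <- p1[p1$observer_id == "o1", ]
  expect_equal(o1$n_looks_target, 2L)
  expect_equal(o1$looked_target, 1L)
  expect_equal(o1$n_looks_distractor, 1L)
  expect_equal(o1$first_look, "target")
  expect_equal(o1$n_demonstrators, 2L)
  expect_equal(o1$n_actual_demonstrators, 1L)  # only d1 looked
  o2 <- p1[p1$observer_id == "o2", ]
  expect_equal(o2$n_looks_target, 0L)
  expect_equal(o2$looked_target, 0L)
  expect_equal(o2$first_look, "none")
  # looked_* is exactly (n_looks_* > 0) on every row
  expect_identical(tab$looked_target,
                   as.integer(tab$n_looks_target > 0))
  expect_identical(tab$looked_distractor,
                   as.integer(tab$n_looks_distractor > 0))
  # presentation 2 is control at bottom; o1's bottom bout is outside
  # its window, so all responses are zero
  p2 <- tab[tab$presentation_index == 2, ]
  expect_true(all(p2$n_looks_target == 0))
  expect_equal(nrow(tab), 4L)  # 2 observers x 2 presentations

  # schedule outside the tracked frames names the presentation
  bad <- fx$sched; bad$end_frame[2] <- 99999L
  expect_error(build_presentation_table(fx$bouts, bad, fx$sides,
                                        fx$grooming, fx$frames, fx$cfg),
               "presentation 2")
})

test_that("first-look ties at identical onset are recorded as none", {
  fx <- make_fixture_table()
  bouts <- data.frame(
    bird = c("d1", "o1", "o1"), roi = c("top", "top", "bottom"),
    cone = c("left_fovea", "left_fovea", "right_fovea"),
    start_frame = c(100L, 320L, 320L),
    end_frame = c(160L, 360L, 355L), duration_ms = 400)
  tab <- build_presentation_table(bouts, fx$sched, fx$sides,
                                  fx$grooming, fx$frames, fx$cfg)
  expect_equal(tab$first_look[tab$observer_id == "o1" &
                                tab$presentation_index == 1], "none")
})

test_that("exclusion rules drop the scripted rows and report reasons", {
  fx <- make_fixture_table()
  sides <- fx$sides
  sides$switched[sides$bird == "o2" & sides$presentation_index == 1] <- TRUE
  sides$flew_off[sides$bird == "o1" & sides$presentation_index == 2] <- TRUE
  tab <- build_presentation_table(fx$bouts, fx$sched, sides,
                                  fx$grooming, fx$frames, fx$cfg)
  excl <- apply_exclusions(tab)
  expect_equal(excl$report$n[excl$report$reason == "switched"], 1L)
  expect_equal(excl$report$n[excl$report$reason == "flew_off"], 1L)
  expect_equal(excl$n_excluded, 2L)
  expect_equal(nrow(excl$table), 2L)
  expect_false("switched" %in% names(excl$table))
})

test_that("test presentations without any demonstrator look are dropped,
           control presentations are kept", {
  fx <- make_fixture_table()
  # remove the demonstrator bout: no demonstrator looked in pres 1 (test)
  bouts <- fx$bouts[fx$bouts$bird != "d1", ]
  tab <- build_presentation_table(bouts, fx$sched, fx$sides,
                                  fx$grooming, fx$frames, fx$cfg)
  excl <- apply_exclusions(tab)
  expect_equal(excl$report$n[excl$report$reason ==
                               "no_demonstrator_looked"], 2L)
  # the control presentation (no looks anywhere either) is retained
  expect_equal(unique(excl$table$condition), "control")
  expect_equal(nrow(excl$table), 2L)
})

test_that("scripted switch and fly-off scenarios produce the scripted
           exclusion counts end to end", {
  cfg <- quick_config()
  behaviors <- data.frame(
    bird = c("bird03", "bird04"), presentation_index = c(1L, 2L),
    behavior = c("switch", "flyoff"))
  sc <- scripted_scenario(cfg, n_birds = 4, n_presentations = 2,
                          presentation_s = 6, behaviors = behaviors,
                          seed = 8)
  gen <- generate_flock_trajectories(sc, synthetic_head_calibration(),
                                     cfg)
  res <- run_gaze_pipeline(gen$markers, gen$calibs, cfg, sc$schedule)
  rep <- res$exclusion_report
  expect_equal(rep$n[rep$reason == "switched"], 1L)
  expect_equal(rep$n[rep$reason == "flew_off"], 1L)
})
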