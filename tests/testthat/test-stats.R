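# z-scoring, GLMM fitting, model comparison, simulated CIs and
# diagnostics.

test_that("z-scoring uses the n-1 sd convention and round-trips", {
  tab <- data.frame(x = c(1, 2, 3), y = c(10, 20, 40))
  z <- zscore_predictors(tab, c("x", "y"))
  expect_equal(z$x, c(-1, 0, 1))
  sc <- attr(z, "zscore_scaling")
  expect_equal(sc$sd[sc$column == "x"], 1)
  expect_equal(zscore_backtransform(z$y, sc, "y"), tab$y)
  expect_error(zscore_predictors(data.frame(k = rep(2, 5)), "k"),
               "zero-variance column 'k'")
  expect_error(zscore_predictors(data.frame(k = letters[1:3]), "k"),
               "not numeric")
})

test_that("the fitted model recovers a known condition effect", {
  spec <- effect_spec(baseline = -0.3, beta_cond = 0.6, beta_dem = 0,
                      sd_intercept = 0.4, sd_slope_cond = 0.15,
                      sd_slope_dem = 0, n_individuals = 60,
                      n_presentations = 20)
  g <- generate_response_table(spec, seed = 61)
  res <- fit_glmm(glmm_spec("binomial", "looked", "condition",
                            random = "uncorrelated"), g$table)
  expect_true(res$converged)
  i <- grep("^condition", res$coefficients$term)
  est <- res$coefficients$estimate[i]
  se <- res$coefficients$se[i]
  expect_gt(0.6, est - 1.96 * se)
  expect_lt(0.6, est + 1.96 * se)
  expect_gt(res$tests$chisq, 0)
  expect_lt(res$tests$p, 0.05)
  # condition is coded control = 0, test = 1: positive beta = stronger
  # response in test
  expect_gt(est, 0)
})

test_that("LRT statistics are non-negative with p in (0, 1]", {
  spec <- effect_spec(beta_cond = 0, beta_dem = 0, sd_slope_cond = 0,
                      sd_slope_dem = 0, n_individuals = 20,
                      n_presentations = 8)
  for (seed in 62:64) {
    g <- generate_response_table(spec, seed = seed)
    res <- fit_glmm(glmm_spec("poisson", "n_looks",
                              "n_actual_demonstrators",
                              random = "intercept"), g$table)
    expect_gte(res$tests$chisq, 0)
    expect_gt(res$tests$p, 0)
    expect_lte(res$tests$p, 1)
  }
})

test_that("reported statistics do not depend on row order", {
  spec <- effect_spec(n_individuals = 25, n_presentations = 10)
  g <- generate_response_table(spec, seed = 65)
  s <- glmm_spec("poisson", "n_looks", "n_actual_demonstrators",
                 random = "intercept")
  r1 <- fit_glmm(s, g$table)
  set.seed(66)
  r2 <- fit_glmm(s, g$table[sample(nrow(g$table)), ])
  expect_equal(r1$coefficients$estimate, r2$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(r1$tests$chisq, r2$tests$chisq, tolerance = 1e-6)
  expect_equal(r1$aic, r2$aic, tolerance = 1e-6)
})

test_that("quadratic specs test the quadratic term and AIC comparison
           prefers the true linear model", {
  spec <- effect_spec(beta_dem = 0.4, beta_dem2 = 0,
                      sd_slope_cond = 0, sd_slope_dem = 0,
                      n_individuals = 40, n_presentations = 12)
  g <- generate_response_table(spec, seed = 67)
  lin <- fit_glmm(glmm_spec("poisson", "n_looks",
                            "n_actual_demonstrators",
                            random = "intercept"), g$table)
  quad <- fit_glmm(glmm_spec("poisson", "n_looks",
                             "n_actual_demonstrators", quadratic = TRUE,
                             random = "intercept"), g$table)
  expect_true(any(grepl("\\^2", quad$tests$term)))
  cmp <- compare_models(lin, quad)
  expect_equal(cmp$delta_aic, lin$aic - quad$aic)
  self <- compare_models(lin, lin)
  expect_equal(self$delta_aic, 0)
  expect_equal(self$preferred, "tie")
  expect_error(glmm_spec("poisson", "n_looks", "condition",
                         quadratic = TRUE), "count predictor")
})

test_that("control predictors enter the fixed-effects design", {
  spec <- effect_spec(n_individuals = 30, n_presentations = 12)
  g <- generate_response_table(spec, seed = 68)
  res <- fit_glmm(glmm_spec("poisson", "n_looks",
                            "n_actual_demonstrators",
                            controls = c("trial_id",
                                         "presentation_index",
                                         "presentation_location"),
                            random = "intercept"), g$table)
  terms <- res$coefficients$term
  expect_true("trial_id" %in% terms)
  expect_true("presentation_index" %in% terms)
  expect_true(any(grepl("presentation_location", terms)))
  # z-scaling recorded for the numeric ones
  expect_setequal(res$scaling$column,
                  c("n_actual_demonstrators", "trial_id",
                    "presentation_index"))
})

test_that("simulated CIs bracket the point prediction and tighten with n", {
  spec <- effect_spec(beta_dem = 0.3, sd_slope_cond = 0,
                      sd_slope_dem = 0, n_individuals = 30,
                      n_presentations = 8)
  g1 <- generate_response_table(spec, seed = 69)
  s <- glmm_spec("poisson", "n_looks", "n_actual_demonstrators",
                 random = "intercept")
  r1 <- fit_glmm(s, g1$table)
  nd <- data.frame(n_actual_demonstrators = c(-1, 0, 1))
  ci1 <- simulate_ci(r1, nd, n_draws = 4000)
  expect_true(all(ci1$lwr <= ci1$fit & ci1$fit <= ci1$upr))
  expect_true(all(ci1$upr - ci1$lwr > 0))
  # four times the data: narrower bands at the same grid
  spec4 <- effect_spec(beta_dem = 0.3, sd_slope_cond = 0,
                       sd_slope_dem = 0, n_individuals = 30,
                       n_presentations = 32)
  g4 <- generate_response_table(spec4, seed = 69)
  r4 <- fit_glmm(s, g4$table)
  ci4 <- simulate_ci(r4, nd, n_draws = 4000)
  expect_lt(mean(ci4$upr - ci4$lwr), mean(ci1$upr - ci1$lwr))
  # refuses a non-converged fit
  broken <- r1; broken$converged <- FALSE
  expect_error(simulate_ci(broken, nd), "non-converged")
})

test_that("diagnostics report dispersion near 1, unit VIFs and the
           planted influential individual", {
  spec <- effect_spec(beta_cond = 0.3, beta_dem = 0.3,
                      sd_intercept = 0.3, sd_slope_cond = 0,
                      sd_slope_dem = 0, n_individuals = 24,
                      n_presentations = 12)
  g <- generate_response_table(spec, seed = 70)
  tab <- g$table
  res <- fit_glmm(glmm_spec("poisson", "n_looks",
                            "n_actual_demonstrators",
                            controls = "condition",
                            random = "intercept"), tab)
  d <- glmm_diagnostics(res, cooks = FALSE)
  # Poisson data fitted with the generating structure: dispersion ~ 1
  expect_gt(d$overdispersion, 0.7)
  expect_lt(d$overdispersion, 1.3)
  # independently sampled predictors: VIFs ~ 1
  expect_true(all(d$vif < 1.2))

  # inflate one individual's counts and find it by Cook's distance
  tab2 <- tab
  victim <- "bird001"
  sel <- tab2$observer_id == victim
  tab2$n_looks[sel] <- tab2$n_looks[sel] + 8L
  res2 <- fit_glmm(glmm_spec("poisson", "n_looks",
                             "n_actual_demonstrators",
                             random = "intercept"), tab2)
  d2 <- glmm_diagnostics(res2, cooks = TRUE)
  expect_equal(names(which.max(d2$cooks)), victim)
})

test_that("a constant response is flagged as degenerate, not an error", {
  spec <- effect_spec(n_individuals = 10, n_presentations = 5)
  g <- generate_response_table(spec, seed = 71)
  g$table$looked <- 0L
  res <- fit_glmm(glmm_spec("binomial", "looked", "condition",
                            random = "intercept"), g$table)
  expect_s3_class(res, "glmm_result")
  expect_false(res$converged)
  expect_error(fit_glmm(glmm_spec("binomial", "looked", "condition"),
                        g$table[g$table$observer_id == "bird001", ]),
               "2 individuals")
})

test_that("Wald chi-squares broadly agree with the LRT on strong effects", {
  spec <- effect_spec(beta_dem = 0.5, sd_slope_cond = 0,
                      sd_slope_dem = 0, n_individuals = 40,
                      n_presentations = 15)
  g <- generate_response_table(spec, seed = 72)
  res <- fit_glmm(glmm_spec("poisson", "n_looks",
                            "n_actual_demonstrators",
                            random = "intercept"), g$table)
  w <- wald_tests(res)
  expect_equal(nrow(w), 1L)
  expect_lt(abs(w$chisq - res$tests$chisq) /
              max(w$chisq, res$tests$chisq), 0.2)
})
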