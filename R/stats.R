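# Mixed-model stage: binomial / Poisson GLMMs of the looking responses
# with z-scored predictors, per-individual random intercepts and slopes,
# likelihood-ratio chi-square tests, AIC comparison, simulation-based
# confidence bands and the standard diagnostics.

#' Z-score predictor columns
#'
#' Replaces each named column by `(x - mean) / sd` (sample sd, n - 1),
#' computed on the modeled rows, and stores the scaling in the
#' `"zscore_scaling"` attribute so values can be mapped back to the
#' original scale. Numerical predictors are normalized per modeled
#' dataset to control for scale effects, so combined and per-experiment
#' analyses scale independently.
#'
#' @param table data.frame.
#' @param columns character vector of numeric column names.
#' @return the table with scaled columns and a scaling attribute.
#' @export
zscore_predictors <- function(table, columns) {
  sc <- data.frame(column = columns, mean = NA_real_, sd = NA_real_,
                   stringsAsFactors = FALSE)
  for (k in seq_along(columns)) {
    cn <- columns[k]
    x <- table[[cn]]
    if (!is.numeric(x)) stop("column '", cn, "' is not numeric")
    m <- mean(x); s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("cannot z-score zero-variance column '", cn, "'")
    table[[cn]] <- (x - m) / s
    sc$mean[k] <- m; sc$sd[k] <- s
  }
  attr(table, "zscore_scaling") <- sc
  table
}

#' @rdname zscore_predictors
#' @param x z-scored values to map back.
#' @param scaling a scaling record (the `"zscore_scaling"` attribute).
#' @param column which column's scaling to use.
#' @export
zscore_backtransform <- function(x, scaling, column) {
  k <- match(column, scaling$column)
  if (is.na(k)) stop("no scaling recorded for column '", column, "'")
  x * scaling$sd[k] + scaling$mean[k]
}

#' Specification of one looking-response mixed model
#'
#' @param family `"binomial"` (likelihood of looking / first look) or
#'   `"poisson"` (number of looks).
#' @param response response column (`"looked_target"`,
#'   `"n_looks_target"`, `"first_look_target"`, or any column of the
#'   table matching the family).
#' @param predictor main predictor: `"condition"`,
#'   `"n_actual_demonstrators"` or `"n_demonstrators"`.
#' @param quadratic add a quadratic term of the (z-scored) count
#'   predictor; only meaningful with a count predictor.
#' @param controls control fixed effects; any of `"trial_id"`,
#'   `"presentation_index"`, `"presentation_location"`,
#'   `"experiment_id"` (the latter for combined analyses only).
#' @param random random-effect structure for the individual grouping
#'   factor: `"full"` (intercept + slopes for all fixed effects, with
#'   correlations), `"uncorrelated"`, or `"intercept"`.
#' @param group grouping column, default `"observer_id"`.
#' @param nAGQ passed to [lme4::glmer()] (1 = Laplace).
#' @return object of class `glmm_spec`.
#' @export
glmm_spec <- function(family = c("binomial", "poisson"),
                      response = "looked_target",
                      predictor = "condition",
                      quadratic = FALSE,
                      controls = character(0),
                      random = c("full", "uncorrelated", "intercept"),
                      group = "observer_id", nAGQ = 1L) {
  family <- match.arg(family)
  random <- match.arg(random)
  if (quadratic && predictor == "condition")
    stop("a quadratic term requires a count predictor")
  structure(list(family = family, response = response,
                 predictor = predictor, quadratic = quadratic,
                 controls = controls, random = random, group = group,
                 nAGQ = nAGQ),
            class = "glmm_spec")
}

# Build the model formula for a spec. `drop` removes the focal term
# (for LRT reduced models): "main" or "quadratic".
glmm_formula <- function(spec, drop = NULL, random = spec$random) {
  main <- spec$predictor
  fixed <- c(main, if (spec$quadratic) paste0("I(", main, "^2)"),
             spec$controls)
  if (!is.null(drop)) {
    fixed <- switch(drop,
      main = setdiff(fixed, main),
      quadratic = setdiff(fixed, paste0("I(", main, "^2)")),
      stop("unknown term to drop"))
  }
  if (!length(fixed)) fixed <- "1"
  slopes <- c(main, if (spec$quadratic) paste0("I(", main, "^2)"),
              spec$controls)
  re <- switch(random,
    full = paste0("(1 + ", paste(slopes, collapse = " + "), " | ",
                  spec$group, ")"),
    uncorrelated = paste0("(1 + ", paste(slopes, collapse = " + "),
                          " || ", spec$group, ")"),
    intercept = paste0("(1 | ", spec$group, ")"))
  stats::as.formula(paste(spec$response, "~",
                          paste(fixed, collapse = " + "), "+", re))
}

# Numeric columns among candidates that should be z-scored.
zscore_columns <- function(spec, table) {
  cand <- unique(c(
    if (spec$predictor != "condition") spec$predictor,
    intersect(spec$controls, c("trial_id", "presentation_index"))))
  cand[vapply(cand, function(cn) is.numeric(table[[cn]]), logical(1))]
}

fit_converged <- function(fit) {
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  code_ok <- is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0
  msg_bad <- any(grepl("failed to converge", msgs, ignore.case = TRUE))
  code_ok && !msg_bad
}

quiet_glmer <- function(...) {
  withCallingHandlers(
    lme4::glmer(...),
    warning = function(w) invokeRestart("muffleWarning"),
    message = function(m) invokeRestart("muffleMessage"))
}

#' Fit a looking-response GLMM
#'
#' Maximum-likelihood fit (Laplace approximation of the random effects)
#' of the binomial or Poisson mixed model described by the spec.
#' Condition is coded control = 0, test = 1, so a positive coefficient
#' means a stronger response in the test condition. Numeric predictors
#' are z-scored on the modeled rows before fitting. Each tested
#' predictor (the main predictor, and the quadratic term when present)
#' gets a chi-square(1) likelihood-ratio test against the model dropping
#' that fixed effect, with the random structure held fixed.
#'
#' If the requested random structure fails to converge the model is
#' refitted down a documented ladder (correlated slopes, uncorrelated
#' slopes, random intercept only); the structure actually used and the
#' path taken are recorded in the result.
#'
#' @param spec a [glmm_spec()].
#' @param table the analysis table (e.g. from [apply_exclusions()] or
#'   [generate_response_table()]).
#' @return object of class `glmm_result`: coefficients, tests, AIC,
#'   log-likelihood, convergence flag, random structure used, the lme4
#'   fit, and the z-scaling record.
#' @export
fit_glmm <- function(spec, table) {
  stopifnot(inherits(spec, "glmm_spec"))
  table <- as.data.frame(table)
  if (length(unique(table[[spec$group]])) < 2L)
    stop("need at least 2 individuals")
  if (spec$response %in% names(table) &&
      spec$family == "binomial" &&
      !all(table[[spec$response]] %in% c(0, 1, NA))) {
    # derive 0/1 from a labeled column such as first_look
    stop("binomial response must be 0/1; recode '", spec$response, "'")
  }
  if ("condition" %in% c(spec$predictor, spec$controls) ||
      "condition" %in% names(table)) {
    if (is.character(table$condition))
      table$condition <- factor(table$condition,
                                levels = c("control", "test"))
  }
  if ("presentation_location" %in% names(table) &&
      is.character(table$presentation_location))
    table$presentation_location <- factor(table$presentation_location)
  if ("experiment_id" %in% spec$controls)
    table$experiment_id <- factor(table$experiment_id)
  zs <- zscore_columns(spec, table)
  if (length(zs)) table <- zscore_predictors(table, zs)
  scaling <- attr(table, "zscore_scaling")

  ladder <- switch(spec$random,
                   full = c("full", "uncorrelated", "intercept"),
                   uncorrelated = c("uncorrelated", "intercept"),
                   intercept = "intercept")
  fam <- if (spec$family == "binomial") stats::binomial()
         else stats::poisson()
  fit <- NULL; used <- NULL; path <- character(0)
  for (rs in ladder) {
    f <- glmm_formula(spec, random = rs)
    cand <- try(quiet_glmer(f, data = table, family = fam,
                            nAGQ = spec$nAGQ,
                            control = lme4::glmerControl(
                              calc.derivs = FALSE)), silent = TRUE)
    path <- c(path, rs)
    if (!inherits(cand, "try-error")) {
      fit <- cand; used <- rs
      if (fit_converged(cand)) break
    }
  }
  if (is.null(fit)) {
    # degenerate data (e.g. a constant response): flag, do not crash
    return(structure(list(
      spec = spec, fit = NULL,
      coefficients = data.frame(term = character(),
                                estimate = numeric(), se = numeric(),
                                z = numeric(), p = numeric()),
      tests = data.frame(term = character(), chisq = numeric(),
                         df = numeric(), p = numeric()),
      aic = NA_real_, logLik = NA_real_, converged = FALSE,
      random_structure = NA_character_, fallback_path = path,
      scaling = scaling, n_obs = nrow(table),
      n_groups = length(unique(table[[spec$group]])),
      data = table,
      note = paste("no ladder step produced a fit:",
                   conditionMessage(attr(cand, "condition")))),
      class = "glmm_result"))
  }
  converged <- fit_converged(fit)

  # likelihood-ratio tests for the tested terms
  tests <- list()
  focal <- c(main = "main", if (spec$quadratic) c(quadratic = "quadratic"))
  for (term in focal) {
    f0 <- glmm_formula(spec, drop = term, random = used)
    red <- try(quiet_glmer(f0, data = table, family = fam,
                           nAGQ = spec$nAGQ,
                           control = lme4::glmerControl(
                             calc.derivs = FALSE)), silent = TRUE)
    if (inherits(red, "try-error")) next
    chisq <- max(0, 2 * (as.numeric(stats::logLik(fit)) -
                           as.numeric(stats::logLik(red))))
    term_label <- if (term == "main") spec$predictor
                  else paste0("I(", spec$predictor, "^2)")
    tests[[term]] <- data.frame(
      term = term_label, chisq = chisq, df = 1,
      p = stats::pchisq(chisq, 1, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(term = character(), chisq = numeric(), df = numeric(),
               p = numeric())
  rownames(tests) <- NULL

  co <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(co), estimate = co[, 1],
                      se = co[, 2], z = co[, 3], p = co[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)

  structure(list(spec = spec, fit = fit, coefficients = coefs,
                 tests = tests, aic = stats::AIC(fit),
                 logLik = as.numeric(stats::logLik(fit)),
                 converged = converged, random_structure = used,
                 fallback_path = path, scaling = scaling,
                 n_obs = nrow(table),
                 n_groups = length(unique(table[[spec$group]])),
                 data = table),
            class = "glmm_result")
}

#' @export
print.glmm_result <- function(x, ...) {
  cat(sprintf("GLMM (%s) %s ~ %s%s | %d obs, %d individuals\n",
              x$spec$family, x$spec$response, x$spec$predictor,
              if (x$spec$quadratic) " (+ quadratic)" else "",
              x$n_obs, x$n_groups))
  cat(sprintf("  AIC %.1f, logLik %.1f, random: %s%s\n", x$aic, x$logLik,
              x$random_structure,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  for (i in seq_len(nrow(x$tests)))
    cat(sprintf("  %s: chisq(1) = %.3f, beta = %.3f, p = %.3f\n",
                x$tests$term[i], x$tests$chisq[i],
                x$coefficients$estimate[match(x$tests$term[i],
                                              x$coefficients$term)],
                x$tests$p[i]))
  invisible(x)
}

#' Wald chi-square tests (optional alternative to the LRT)
#'
#' @param result a `glmm_result`.
#' @return data.frame(term, chisq, df, p) for the tested terms.
#' @export
wald_tests <- function(result) {
  co <- result$coefficients
  # a factor condition appears in the coefficients as "conditiontest"
  terms <- result$tests$term
  rows <- lapply(terms, function(tm) {
    i <- which(co$term == tm | co$term == paste0(tm, "test"))
    if (!length(i)) return(NULL)
    chisq <- (co$estimate[i] / co$se[i])^2
    data.frame(term = tm, chisq = chisq, df = 1,
               p = stats::pchisq(chisq, 1, lower.tail = FALSE))
  })
  do.call(rbind, rows)
}

#' Compare two fitted models by AIC
#'
#' @param a,b `glmm_result`s fitted to the same response rows.
#' @return list with `delta_aic` (`AIC(a) - AIC(b)`) and `preferred`
#'   (`"a"`, `"b"`, or `"tie"`).
#' @export
compare_models <- function(a, b) {
  stopifnot(inherits(a, "glmm_result"), inherits(b, "glmm_result"))
  if (a$n_obs != b$n_obs)
    warning("comparing models fitted to different numbers of rows")
  d <- a$aic - b$aic
  list(delta_aic = d,
       preferred = if (d < 0) "a" else if (d > 0) "b" else "tie",
       aic_a = a$aic, aic_b = b$aic)
}

# Fixed-effects model matrix for new data under a result's formula.
fixed_model_matrix <- function(result, newdata) {
  f <- lme4::nobars(stats::formula(result$fit))
  tt <- stats::delete.response(stats::terms(f))
  xlev <- lapply(result$fit@frame, function(c)
    if (is.factor(c)) levels(c))
  xlev <- Filter(Negate(is.null), xlev)
  xlev <- xlev[intersect(names(xlev), all.vars(tt))]
  mf <- stats::model.frame(tt, newdata, xlev = xlev)
  stats::model.matrix(tt, mf)
}

#' Simulation-based confidence band for model predictions
#'
#' Draws fixed-effect vectors from their asymptotic multivariate normal
#' distribution (10,000 draws by default), pushes each draw through the
#' inverse link at the requested predictor values with all other
#' variables held at their means (zero on the z-scored scale, reference
#' level handling via the model matrix), and returns the 2.5th and
#' 97.5th percentiles of the simulated predictions around the
#' point prediction.
#'
#' @param result a converged `glmm_result`.
#' @param newdata data.frame of predictor values to predict at; missing
#'   model variables are filled with zeros (their z-scored mean) or the
#'   reference factor level.
#' @param n_draws number of parameter draws.
#' @param level coverage of the band.
#' @return `newdata` with columns `fit`, `lwr`, `upr` (response scale).
#' @export
simulate_ci <- function(result, newdata, n_draws = 10000,
                        level = 0.95) {
  stopifnot(inherits(result, "glmm_result"))
  if (!result$converged)
    stop("refusing to simulate from a non-converged fit")
  beta <- lme4::fixef(result$fit)
  V <- as.matrix(stats::vcov(result$fit))
  # fill unmentioned model variables at their means / reference levels
  frame <- result$data
  vars <- all.vars(lme4::nobars(stats::formula(result$fit)))[-1]
  for (v in setdiff(vars, names(newdata))) {
    col <- frame[[v]]
    newdata[[v]] <- if (is.factor(col)) factor(levels(col)[1],
                                               levels = levels(col))
      else if (is.character(col)) sort(unique(col))[1]
      else mean(col)
  }
  for (v in intersect(vars, names(newdata))) {
    col <- frame[[v]]
    if (is.factor(col) && !is.factor(newdata[[v]]))
      newdata[[v]] <- factor(newdata[[v]], levels = levels(col))
  }
  X <- fixed_model_matrix(result, newdata)
  linkinv <- if (result$spec$family == "binomial") stats::plogis else exp
  draws <- MASS::mvrnorm(n_draws, beta, V)
  eta <- draws %*% t(X)
  pred <- linkinv(eta)
  a <- (1 - level) / 2
  newdata$fit <- linkinv(as.numeric(X %*% beta))
  newdata$lwr <- apply(pred, 2, stats::quantile, probs = a)
  newdata$upr <- apply(pred, 2, stats::quantile, probs = 1 - a)
  newdata
}

#' Model diagnostics: overdispersion, collinearity, influence
#'
#' Overdispersion is the Pearson chi-square divided by the residual
#' degrees of freedom (reported for Poisson models; values near 1 are
#' consistent with the Poisson assumption). Variance-inflation factors
#' are computed from the correlation matrix of the fixed-effects model
#' matrix (intercept excluded). Influence of individuals is assessed by
#' a leave-one-individual-out Cook's distance
#' `(beta - beta_(-i))' V^-1 (beta - beta_(-i)) / p` on the fixed
#' effects.
#'
#' @param result a `glmm_result`.
#' @param cooks whether to run the (refit-heavy) leave-one-out loop.
#' @return list with `overdispersion`, `vif` (named vector), and
#'   `cooks` (named vector per individual, or `NULL`).
#' @export
glmm_diagnostics <- function(result, cooks = TRUE) {
  fit <- result$fit
  rdf <- stats::df.residual(fit)
  pearson <- stats::residuals(fit, type = "pearson")
  disp <- sum(pearson^2) / rdf

  X <- stats::model.matrix(fit)
  Xp <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  vif <- if (ncol(Xp) >= 2L) {
    Rm <- stats::cor(Xp)
    stats::setNames(diag(solve(Rm)), colnames(Xp))
  } else if (ncol(Xp) == 1L) stats::setNames(1, colnames(Xp)) else NULL

  cooksd <- NULL
  if (cooks) {
    beta <- lme4::fixef(fit)
    Vinv <- solve(as.matrix(stats::vcov(fit)))
    p <- length(beta)
    grp <- result$spec$group
    ids <- unique(result$data[[grp]])
    cooksd <- stats::setNames(numeric(length(ids)), ids)
    for (k in seq_along(ids)) {
      sub <- result$data[result$data[[grp]] != ids[k], , drop = FALSE]
      refit <- try(quiet_glmer(
        glmm_formula(result$spec, random = result$random_structure),
        data = sub,
        family = if (result$spec$family == "binomial") stats::binomial()
                 else stats::poisson(),
        nAGQ = result$spec$nAGQ,
        control = lme4::glmerControl(calc.derivs = FALSE)),
        silent = TRUE)
      if (inherits(refit, "try-error")) { cooksd[k] <- NA; next }
      d <- beta - lme4::fixef(refit)
      cooksd[k] <- as.numeric(t(d) %*% Vinv %*% d) / p
    }
  }
  list(overdispersion = disp, vif = vif, cooks = cooksd)
}
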