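# Behavioral-assay statistics: no-choice oviposition counts, choice-cage
# preference, olfactometer outcomes, and the PD/PS predictor regressions.
#
# Input tables (all plain data frames, read from CSV by the drivers):
#   no-choice:    treatment, week, cage, count  ("control" is the reserved
#                 water-treated label; every week block must contain controls)
#   choice:       treatment, cage, treated_count, control_count
#   olfactometer: treatment, replicate, outcome in
#                 {chose_treated, chose_control, no_choice, stress}

CONTROL_LABEL <- "control"

OLF_OUTCOMES <- c("chose_treated", "chose_control", "no_choice", "stress")

check_nochoice <- function(trials) {
  need <- c("treatment", "week", "cage", "count")
  if (!all(need %in% names(trials)))
    stop(sprintf("no-choice table needs columns %s", paste(need, collapse = ", ")))
  if (any(trials$count < 0) || any(trials$count != floor(trials$count)))
    stop("larval counts must be non-negative integers")
  invisible(trials)
}

#' Quality-control filter on week blocks
#'
#' Drops entire week blocks whose control plants averaged fewer than
#' `min_control_mean` larvae: low control oviposition indicates a failed run,
#' so all trials from that week are discarded (and in the live study, re-run).
#'
#' @param trials No-choice data frame (`treatment`, `week`, `cage`, `count`).
#' @param min_control_mean Minimum mean control count to retain a block.
#' @return List with `trials` (retained rows) and `report` (one row per week:
#'   `week`, `control_mean`, `dropped`).
#' @export
qc_filter_weeks <- function(trials, min_control_mean = 5) {
  check_nochoice(trials)
  weeks <- unique(trials$week)
  report <- do.call(rbind, lapply(weeks, function(w) {
    blk <- trials[trials$week == w, ]
    ctrl <- blk$count[blk$treatment == CONTROL_LABEL]
    if (length(ctrl) == 0L)
      stop(sprintf("week block '%s' has no control trials", w))
    data.frame(week = w, control_mean = mean(ctrl),
               dropped = mean(ctrl) < min_control_mean,
               stringsAsFactors = FALSE)
  }))
  keep <- report$week[!report$dropped]
  list(trials = trials[trials$week %in% keep, , drop = FALSE], report = report)
}

#' Percent change in oviposition relative to control
#'
#' `100 * (mean_control - mean_treated) / mean_control` per treatment; 96
#' means a 96% reduction in larvae on treated plants, negative values mean
#' treated plants received more larvae than controls.
#'
#' @param trials Post-QC no-choice data frame.
#' @return Data frame `treatment`, `mean_treated`, `mean_control`,
#'   `percent_change`.
#' @export
percent_change_from_control <- function(trials) {
  check_nochoice(trials)
  ctrl <- trials$count[trials$treatment == CONTROL_LABEL]
  if (length(ctrl) == 0L) stop("no control trials present")
  mc <- mean(ctrl)
  if (mc == 0) stop("control mean is zero; percent change undefined")
  trts <- setdiff(unique(trials$treatment), CONTROL_LABEL)
  if (length(trts) == 0L) stop("no treated trials present")
  mt <- vapply(trts, function(tr) mean(trials$count[trials$treatment == tr]), 0)
  data.frame(treatment = trts, mean_treated = unname(mt), mean_control = mc,
             percent_change = 100 * (mc - mt) / mc,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Count regression of larval density on treatment
#'
#' Log-link count regression of no-choice larval counts on treatment
#' indicators (control as reference), negative binomial by default with
#' maximum-likelihood dispersion. If the ML fit fails to converge the
#' dispersion falls back to a method-of-moments estimate (flagged in the
#' result). Treatment levels with all-zero counts are complete separations on
#' the log scale: their coefficients are reported as `-Inf` with a warning
#' and the `separation` flag lists them.
#'
#' @param trials Post-QC no-choice data frame.
#' @param family `"negbin"` (default) or `"poisson"`.
#' @return List of class `count_model`: `family`, `coefficients` (data frame
#'   `term`, `estimate`, `se`, `z`, `p`), `theta` (negbin dispersion k, NA for
#'   Poisson), `separation` (character vector of all-zero levels),
#'   `dispersion_method`, and the fitted `model`.
#' @export
fit_treatment_count_model <- function(trials, family = c("negbin", "poisson")) {
  family <- match.arg(family)
  check_nochoice(trials)
  trials$treatment <- stats::relevel(factor(trials$treatment), ref = CONTROL_LABEL)
  if (nlevels(trials$treatment) < 2L)
    stop("need >= 2 treatment levels (control plus at least one treatment)")
  zero_lvls <- levels(trials$treatment)[tapply(trials$count, trials$treatment, sum) == 0]
  zero_lvls <- setdiff(zero_lvls, CONTROL_LABEL)
  if (length(zero_lvls) > 0L)
    warning(sprintf("all-zero treatment level(s) %s: log-scale coefficient unbounded below",
                    paste(sQuote(zero_lvls), collapse = ", ")))
  dispersion_method <- NA_character_
  if (family == "negbin") {
    fit <- tryCatch(
      suppressWarnings(MASS::glm.nb(count ~ treatment, data = trials)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      # method-of-moments dispersion: var = mu + mu^2/k per treatment level
      mu <- tapply(trials$count, trials$treatment, mean)
      v <- tapply(trials$count, trials$treatment, stats::var)
      excess <- stats::weighted.mean(pmax(v - mu, 1e-8) / mu^2,
                                     w = tapply(trials$count, trials$treatment, length))
      k <- 1 / max(excess, 1e-8)
      fit <- stats::glm(count ~ treatment, data = trials,
                        family = MASS::negative.binomial(theta = k))
      dispersion_method <- "moments"
    } else {
      dispersion_method <- "ml"
    }
    theta <- if (!is.null(fit$theta)) fit$theta else environment(fit$family$variance)$.Theta
  } else {
    fit <- stats::glm(count ~ treatment, data = trials, family = stats::poisson())
    theta <- NA_real_
  }
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1L], se = sm[, 2L],
                      z = sm[, 3L], p = sm[, 4L],
                      row.names = NULL, stringsAsFactors = FALSE)
  for (lvl in zero_lvls) {
    i <- coefs$term == paste0("treatment", lvl)
    coefs$estimate[i] <- -Inf
    coefs$se[i] <- Inf
  }
  structure(list(family = family, coefficients = coefs, theta = theta,
                 separation = zero_lvls, dispersion_method = dispersion_method,
                 model = fit),
            class = "count_model")
}

#' @export
print.count_model <- function(x, ...) {
  cat(sprintf("<count model> family %s%s\n", x$family,
              if (x$family == "negbin") sprintf(", dispersion k = %.3g (%s)",
                                                x$theta, x$dispersion_method) else ""))
  print(x$coefficients, digits = 4)
  if (length(x$separation) > 0L)
    cat("complete separation in:", paste(x$separation, collapse = ", "), "\n")
  invisible(x)
}

#' Expected proportion of larvae on treated plants under no preference
#'
#' Weights the choice-test null by no-choice acceptability: if larvae end up
#' on treated plants merely in proportion to how acceptable those plants are
#' without alternatives, the expected treated fraction is
#' `p0 = mean_treated / (mean_treated + mean_control)`.
#'
#' @param mean_treated,mean_control No-choice mean larval counts.
#' @return `p0` in `[0, 1]`.
#' @export
expected_choice_proportion <- function(mean_treated, mean_control) {
  stopifnot(mean_treated >= 0, mean_control >= 0)
  if (mean_treated + mean_control == 0)
    stop("both no-choice means are zero; expected proportion undefined")
  p0 <- mean_treated / (mean_treated + mean_control)
  if (p0 == 0)
    warning("treated no-choice mean is 0; the choice test degenerates at p0 = 0")
  p0
}

#' Weighted one-sample Hotelling T-squared choice test
#'
#' Tests whether the per-cage fraction of larvae on treated plants differs
#' from the no-choice-weighted expectation `p0`. On the univariate fraction
#' the statistic is `T2 = n * (xbar - p0)^2 / s^2` and equals the squared
#' one-sample t statistic; `F = T2 * (n - p) / (p * (n - 1))` with `p = 1`
#' follows `F(1, n - 1)`.
#'
#' @param cages Data frame with `treated_count`, `control_count`, one row per
#'   cage (a single treatment). Cages with zero total larvae are excluded
#'   with a warning.
#' @param p0 Expected treated fraction under no preference.
#' @return List of class `hotelling_test`: `T2`, `F`, `df1`, `df2`, `p_value`,
#'   `p0`, `n`, `mean_fraction`, `degenerate`.
#' @export
hotelling_choice_test <- function(cages, p0) {
  stopifnot(p0 >= 0, p0 <= 1,
            all(c("treated_count", "control_count") %in% names(cages)))
  total <- cages$treated_count + cages$control_count
  if (any(total == 0)) {
    warning(sprintf("excluding %d cage(s) with zero larvae", sum(total == 0)))
    cages <- cages[total > 0, , drop = FALSE]
    total <- total[total > 0]
  }
  n <- nrow(cages)
  if (n < 2L) stop("need >= 2 cages with larvae")
  x <- cages$treated_count / total
  xbar <- mean(x)
  s2 <- stats::var(x)
  if (s2 == 0) {
    if (isTRUE(all.equal(xbar, p0))) {
      return(structure(list(T2 = 0, F = 0, df1 = 1L, df2 = n - 1L, p_value = 1,
                            p0 = p0, n = n, mean_fraction = xbar,
                            degenerate = TRUE),
                       class = "hotelling_test"))
    }
    return(structure(list(T2 = Inf, F = Inf, df1 = 1L, df2 = n - 1L, p_value = 0,
                          p0 = p0, n = n, mean_fraction = xbar,
                          degenerate = TRUE),
                     class = "hotelling_test"))
  }
  T2 <- n * (xbar - p0)^2 / s2
  Fstat <- T2 * (n - 1L) / (1 * (n - 1L))  # p = 1
  p_value <- stats::pf(Fstat, 1L, n - 1L, lower.tail = FALSE)
  structure(list(T2 = T2, F = Fstat, df1 = 1L, df2 = n - 1L, p_value = p_value,
                 p0 = p0, n = n, mean_fraction = xbar, degenerate = FALSE),
            class = "hotelling_test")
}

#' @export
print.hotelling_test <- function(x, ...) {
  cat(sprintf("<Hotelling T2> T2 = %.4g, F(%d, %d) = %.4g, p = %.4g (p0 = %.3f, n = %d)\n",
              x$T2, x$df1, x$df2, x$F, x$p_value, x$p0, x$n))
  invisible(x)
}

#' Odds ratio of choosing treated plants
#'
#' Intercept-only per-larva logistic model: each larva chooses the treated
#' (1) or untreated (0) side, so the ML odds ratio is simply
#' `total_treated / total_control` with Wald CI
#' `exp(log(OR) +/- 1.96 * sqrt(1/t + 1/c))`. A zero margin is complete
#' separation: the point estimate and one CI bound are reported as 0 or
#' infinite and the `separation` flag is set. Cage-level heterogeneity
#' (overdispersion relative to the pooled binomial) is flagged via a
#' chi-squared test when >= 2 cages are available.
#'
#' @param cages Data frame with `treated_count`, `control_count`.
#' @param conf_level Wald confidence level.
#' @return List of class `choice_or`: `odds_ratio`, `lower`, `upper`,
#'   `p_value` (Wald test of log OR = 0), `total_treated`, `total_control`,
#'   `separation`, `heterogeneity_p`.
#' @export
choice_odds_ratio <- function(cages, conf_level = 0.95) {
  stopifnot(all(c("treated_count", "control_count") %in% names(cages)))
  t_tot <- sum(cages$treated_count)
  c_tot <- sum(cages$control_count)
  if (t_tot + c_tot == 0) stop("no larvae in any cage")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  separation <- (t_tot == 0 || c_tot == 0)
  if (separation) {
    or <- if (t_tot == 0) 0 else Inf
    lower <- if (t_tot == 0) 0 else NA_real_
    upper <- if (t_tot == 0) NA_real_ else Inf
    p_value <- NA_real_
  } else {
    or <- t_tot / c_tot
    se <- sqrt(1 / t_tot + 1 / c_tot)
    lower <- exp(log(or) - z * se)
    upper <- exp(log(or) + z * se)
    p_value <- 2 * stats::pnorm(-abs(log(or) / se))
  }
  het_p <- NA_real_
  tot <- cages$treated_count + cages$control_count
  use <- tot > 0
  if (sum(use) >= 2L && !separation) {
    het <- suppressWarnings(
      stats::chisq.test(cbind(cages$treated_count[use], cages$control_count[use])))
    het_p <- het$p.value
  }
  structure(list(odds_ratio = or, lower = lower, upper = upper,
                 p_value = p_value, total_treated = t_tot,
                 total_control = c_tot, separation = separation,
                 heterogeneity_p = het_p),
            class = "choice_or")
}

#' @export
print.choice_or <- function(x, ...) {
  cat(sprintf("<choice OR> %.4g [%.4g, %.4g], totals %d treated / %d control%s\n",
              x$odds_ratio, x$lower, x$upper, x$total_treated, x$total_control,
              if (x$separation) " (complete separation)" else ""))
  invisible(x)
}

#' Exact binomial olfactometer test
#'
#' Classifies replicate outcomes into the four categories and tests whether
#' arm choices depart from the null split (50% treated : 50% control by
#' default) with a two-sided exact binomial test (minimum-likelihood
#' two-sided rule, as in [stats::binom.test()]). Stress and no-choice
#' replicates are excluded from `n` but tallied.
#'
#' @param trials Data frame with `outcome` (one treatment's replicates), each
#'   outcome one of `chose_treated`, `chose_control`, `no_choice`, `stress`.
#' @param p0 Null probability of choosing the treated arm.
#' @return List of class `olf_test`: `k` (chose treated), `n`
#'   (choices made), `p_value` (NA with a note if `n` is 0), and `tally`.
#' @export
olfactometer_exact_test <- function(trials, p0 = 0.5) {
  stopifnot("outcome" %in% names(trials))
  bad <- setdiff(unique(trials$outcome), OLF_OUTCOMES)
  if (length(bad) > 0L)
    stop(sprintf("unknown olfactometer outcome(s): %s", paste(bad, collapse = ", ")))
  tally <- vapply(OLF_OUTCOMES, function(o) sum(trials$outcome == o), 0L)
  k <- tally[["chose_treated"]]
  n <- k + tally[["chose_control"]]
  if (n == 0L) {
    return(structure(list(k = 0L, n = 0L, p_value = NA_real_, p0 = p0,
                          tally = tally,
                          note = "no choices made after exclusions; test skipped"),
                     class = "olf_test"))
  }
  p_value <- stats::binom.test(k, n, p = p0)$p.value
  structure(list(k = k, n = n, p_value = p_value, p0 = p0, tally = tally,
                 note = NA_character_),
            class = "olf_test")
}

#' @export
print.olf_test <- function(x, ...) {
  cat(sprintf("<olfactometer exact test> k = %d / n = %d vs p0 = %.2f: p = %.4g\n",
              x$k, x$n, x$p0, x$p_value))
  cat("  tally:", paste(sprintf("%s=%d", names(x$tally), x$tally), collapse = ", "), "\n")
  invisible(x)
}

#' Regress a behavioral response on a PD or PS score
#'
#' The cross-treatment predictor models: negative-binomial or Poisson
#' log-linear regression for count responses, logistic regression for binary
#' (arm-choice) responses, and ordinary least squares (reporting R-squared)
#' for linear summaries.
#'
#' @param data Data frame holding the response and score columns.
#' @param response Response column name. For `family = "logistic"` it may be a
#'   0/1 column, or `c(successes, trials)` column names for aggregated
#'   binomial data.
#' @param score Score column name (PD or PS); needs >= 3 distinct values.
#' @param family One of `"negbin"`, `"poisson"`, `"logistic"`, `"linear"`.
#' @return List of class `predictor_fit`: `family`, `coefficients` (term,
#'   estimate, se, statistic, p), `slope`, `r_squared` (linear only), `theta`
#'   (negbin only), and the fitted `model`.
#' @export
predictor_regression <- function(data, response, score,
                                 family = c("negbin", "poisson", "logistic", "linear")) {
  family <- match.arg(family)
  stopifnot(score %in% names(data))
  if (length(unique(data[[score]])) < 3L)
    stop("need >= 3 distinct score values")
  theta <- NA_real_
  r2 <- NA_real_
  if (family == "logistic" && length(response) == 2L) {
    stopifnot(all(response %in% names(data)))
    succ <- data[[response[1L]]]
    fail <- data[[response[2L]]] - succ
    fml <- stats::as.formula(sprintf("cbind(succ, fail) ~ %s", score))
    fit <- stats::glm(fml, data = cbind(data, succ = succ, fail = fail),
                      family = stats::binomial())
  } else {
    stopifnot(response %in% names(data))
    fml <- stats::as.formula(sprintf("%s ~ %s", response, score))
    fit <- switch(family,
      negbin = suppressWarnings(MASS::glm.nb(fml, data = data)),
      poisson = stats::glm(fml, data = data, family = stats::poisson()),
      logistic = stats::glm(fml, data = data, family = stats::binomial()),
      linear = stats::lm(fml, data = data))
  }
  if (family == "negbin") theta <- fit$theta
  if (family == "linear") r2 <- summary(fit)$r.squared
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1L], se = sm[, 2L],
                      statistic = sm[, 3L], p = sm[, 4L],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(family = family, coefficients = coefs,
                 slope = coefs$estimate[coefs$term == score],
                 r_squared = r2, theta = theta, model = fit),
            class = "predictor_fit")
}

#' @export
print.predictor_fit <- function(x, ...) {
  cat(sprintf("<predictor regression> family %s, slope = %.4g%s\n", x$family,
              x$slope,
              if (!is.na(x$r_squared)) sprintf(", R2 = %.3f", x$r_squared) else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}
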