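test_that("the week-block QC filter drops low-control blocks whole and is idempotent", {
  blk <- function(week, ctrl, trt) rbind(
    nochoice_table("control", ctrl, week), nochoice_table("oilA", trt, week))
  d <- rbind(blk("w1", c(6, 7, 8, 2, 3), c(1, 2, 0)),     # mean 5.2 -> kept
             blk("w2", c(1, 2, 3, 4, 5), c(0, 0, 1)))     # mean 3.0 -> dropped
  out <- qc_filter_weeks(d)
  expect_equal(sort(unique(out$trials$week)), "w1")
  expect_equal(out$report$dropped, c(FALSE, TRUE))
  expect_equal(out$report$control_mean, c(5.2, 3.0))
  again <- qc_filter_weeks(out$trials)
  expect_equal(again$trials, out$trials)                   # idempotent
  expect_error(qc_filter_weeks(nochoice_table("oilA", c(1, 2), "w1")),
               "no control trials")
})

test_that("percent change from control follows the closed form", {
  d <- rbind(nochoice_table("control", rep(10, 4)),
             nochoice_table("oilA", c(0, 1, 0, 1)),       # mean 0.5 -> 95%
             nochoice_table("oilB", rep(10, 4)),          # equal -> 0%
             nochoice_table("oilC", rep(12, 4)))          # -20%
  pc <- percent_change_from_control(d)
  expect_equal(pc$percent_change[match(c("oilA", "oilB", "oilC"), pc$treatment)],
               c(95, 0, -20))
  zero <- rbind(nochoice_table("control", rep(0, 3)), nochoice_table("oilA", 1:3))
  expect_error(percent_change_from_control(zero), "control mean is zero")
})

test_that("Poisson treatment model recovers the closed-form rate ratio", {
  d <- rbind(nochoice_table("control", c(8, 12, 10, 10)),
             nochoice_table("oilA", c(2, 2, 1, 3)))
  fit <- fit_treatment_count_model(d, family = "poisson")
  # single-factor Poisson ML: coefficient = log(mean_t / mean_c)
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "treatmentoilA"],
               log(2 / 10), tolerance = 1e-8)
  expect_true(is.na(fit$theta))
})

test_that("negbin treatment model estimates dispersion and flags separation", {
  set.seed(31)
  d <- rbind(nochoice_table("control", rnbinom(40, mu = 10, size = 2)),
             nochoice_table("oilA", rnbinom(40, mu = 2, size = 2)))
  fit <- fit_treatment_count_model(d)
  expect_equal(fit$family, "negbin")
  expect_gt(fit$theta, 0.8); expect_lt(fit$theta, 5)
  est <- fit$coefficients$estimate[fit$coefficients$term == "treatmentoilA"]
  expect_lt(abs(est - log(0.2)), 0.8)
  expect_length(fit$separation, 0)

  dz <- rbind(nochoice_table("control", c(9, 11, 10, 10)),
              nochoice_table("oilZ", rep(0, 4)))
  expect_warning(fz <- fit_treatment_count_model(dz), "all-zero")
  expect_equal(fz$separation, "oilZ")
  expect_equal(fz$coefficients$estimate[fz$coefficients$term == "treatmentoilZ"], -Inf)
})

test_that("expected choice proportion is the acceptability-weighted null", {
  expect_equal(expected_choice_proportion(1, 9), 0.1)
  expect_equal(expected_choice_proportion(5, 5), 0.5)
  expect_warning(p0 <- expected_choice_proportion(0, 7), "degenerates")
  expect_equal(p0, 0)
  expect_error(expected_choice_proportion(0, 0), "undefined")
})

test_that("univariate Hotelling T2 equals the squared one-sample t", {
  cages <- data.frame(treated_count = c(1, 4, 3, 1), control_count = c(9, 16, 17, 19))
  x <- cages$treated_count / (cages$treated_count + cages$control_count)
  ht <- hotelling_choice_test(cages, p0 = 0.5)
  tt <- t.test(x, mu = 0.5)
  expect_equal(ht$T2, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(ht$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(ht$df1, 1L); expect_equal(ht$df2, 3L)

  set.seed(32)
  for (i in 1:200) {
    n <- sample(3:15, 1)
    tot <- rpois(n, 40) + 1L
    tr <- rbinom(n, tot, runif(1, 0.1, 0.9))
    cg <- data.frame(treated_count = tr, control_count = tot - tr)
    x <- tr / tot
    if (var(x) == 0) next
    p0 <- runif(1)
    ht <- hotelling_choice_test(cg, p0)
    expect_lt(abs(ht$T2 - unname(t.test(x, mu = p0)$statistic)^2), 1e-9)
  }
})

test_that("degenerate Hotelling inputs are handled as specified", {
  allsame <- data.frame(treated_count = rep(3, 4), control_count = rep(9, 4))
  at_null <- hotelling_choice_test(allsame, p0 = 0.25)
  expect_equal(at_null$T2, 0); expect_equal(at_null$p_value, 1)
  off_null <- hotelling_choice_test(allsame, p0 = 0.5)
  expect_equal(off_null$p_value, 0)
  expect_true(off_null$degenerate)
  with_empty <- data.frame(treated_count = c(3, 1, 0), control_count = c(9, 7, 0))
  expect_warning(hotelling_choice_test(with_empty, 0.3), "zero larvae")
})

test_that("choice odds ratio equals the count ratio and matches the logit model", {
  cg <- data.frame(treated_count = c(4, 6), control_count = c(11, 9))
  or <- choice_odds_ratio(cg)
  expect_equal(or$odds_ratio, 0.5)
  glm_fit <- glm(cbind(10, 20) ~ 1, family = binomial())
  expect_equal(log(or$odds_ratio), unname(coef(glm_fit)), tolerance = 1e-8)
  eq <- choice_odds_ratio(data.frame(treated_count = 15, control_count = 15))
  expect_equal(eq$odds_ratio, 1)
  expect_true(eq$lower < 1 && eq$upper > 1)
  sep <- choice_odds_ratio(data.frame(treated_count = 0, control_count = 15))
  expect_true(sep$separation)
  expect_equal(sep$odds_ratio, 0)
  expect_error(choice_odds_ratio(data.frame(treated_count = 0, control_count = 0)),
               "no larvae")
})

test_that("olfactometer exact test matches closed forms and excludes stress/no-choice", {
  mk <- function(k, n, extra = character(0)) data.frame(
    treatment = "oilA", replicate = seq_len(n + length(extra)),
    outcome = c(rep("chose_treated", k), rep("chose_control", n - k), extra),
    stringsAsFactors = FALSE)
  expect_equal(olfactometer_exact_test(mk(15, 30))$p_value, 1)
  r30 <- olfactometer_exact_test(mk(30, 30))
  expect_equal(r30$p_value, 2 * 0.5^30, tolerance = 1e-12)
  r25 <- olfactometer_exact_test(mk(25, 30, c("stress", "stress", "no_choice")))
  expect_equal(r25$n, 30L)                               # exclusions don't enter n
  expect_equal(r25$tally[["stress"]], 2L)
  expect_equal(r25$p_value, exact_binom_oracle(25, 30, 0.5), tolerance = 1e-12)
  skipped <- olfactometer_exact_test(data.frame(outcome = rep("stress", 5)))
  expect_true(is.na(skipped$p_value))
  expect_match(skipped$note, "skipped")
  expect_error(olfactometer_exact_test(data.frame(outcome = "flew_away")),
               "unknown olfactometer outcome")
})

test_that("predictor regressions fit each family and report R2 for linear", {
  set.seed(33)
  d <- data.frame(score = rep(seq(0, 1, length.out = 10), each = 5))
  d$count <- rpois(nrow(d), exp(3 - 2 * d$score))
  nb <- predictor_regression(d, "count", "score", "negbin")
  expect_lt(abs(nb$slope + 2), 1)
  po <- predictor_regression(d, "count", "score", "poisson")
  expect_equal(po$family, "poisson")
  d$y <- 5 - 3 * d$score
  # a perfect fit triggers lm's "essentially perfect fit" warning
  lin <- suppressWarnings(predictor_regression(d, "y", "score", "linear"))
  expect_equal(lin$r_squared, 1)
  expect_equal(lin$slope, -3, tolerance = 1e-10)
  d$hit <- as.integer(runif(nrow(d)) < plogis(1 - 2 * d$score))
  lg <- predictor_regression(d, "hit", "score", "logistic")
  expect_equal(lg$family, "logistic")
  dd <- data.frame(score = rep(0.5, 6), count = rpois(6, 5))
  expect_error(predictor_regression(dd, "count", "score", "poisson"),
               "3 distinct score values")
})
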