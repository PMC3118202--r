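test_that("partial-likelihood score has the textbook value in a two-subject risk set", {
  # one exposed subject with an event at t=1, both subjects at risk:
  # U(0) = 1 - 1/2; with max_iter = 0 the returned score residuals are
  # evaluated at beta = 0 and sum to the score.
  rows <- data.frame(id = c("a", "b"), stratum = 1L, start = 0,
                     stop = c(1, 2), status = c(1L, 0L), x = c(1, 0))
  fit <- fit_cox(rows, "x", max_iter = 0L)
  expect_equal(sum(fit$score_residuals), 0.5)
  expect_false(fit$converged)
})

test_that("a perfectly separated covariate raises the monotone-likelihood flag", {
  rows <- data.frame(id = letters[1:4], stratum = 1L, start = 0,
                     stop = c(1, 2, 3, 4), status = c(1L, 1L, 0L, 0L),
                     x = c(1, 1, 0, 0))
  fit <- suppressWarnings(fit_cox(rows, "x", max_iter = 200L))
  expect_true(fit$monotone_likelihood)
  expect_false(fit$converged)
})

test_that("data without events are rejected", {
  rows <- data.frame(id = "a", stratum = 1L, start = 0, stop = 1,
                     status = 0L, x = 0)
  expect_error(fit_cox(rows, "x"), class = "msrecur_no_events")
})

test_that("the fitted maximum dominates a brute-force likelihood grid", {
  # five subjects with up to two events; oracle = explicit risk-set loop
  subjects <- list(subject_with(c(30, 200), 400, arm = 1L, id = 1),
                   subject_with(120, 500, arm = 0L, id = 2),
                   subject_with(numeric(0), 350, arm = 1L, id = 3),
                   subject_with(c(80, 310), 330, arm = 0L, id = 4),
                   subject_with(60, 600, arm = 1L, id = 5))
  rows <- build_layout(small_trial(subjects), "ag")
  fit <- fit_cox(rows, "treatment")
  ll_hat <- brute_force_logpl(rows, "treatment", coef(fit))
  expect_equal(ll_hat, fit$log_partial_likelihood, tolerance = 1e-10)
  grid <- seq(-3, 3, by = 0.001)
  ll_grid <- vapply(grid, function(b)
    brute_force_logpl(rows, "treatment", b), numeric(1))
  expect_true(all(ll_hat >= ll_grid - 1e-10))

  # concavity along the line through the maximum
  expect_true(all(diff(ll_grid[grid <= coef(fit)]) > 0))
  expect_true(all(diff(ll_grid[grid >= coef(fit)]) < 0))
})

test_that("estimates agree with the reference survival implementation on every layout", {
  skip_if_not_installed("survival")
  library(survival)
  trial <- emulate_covariate_trial(60, design = trial_design(n_per_arm = 60),
                                   seed = 31)
  k <- max_event_count(trial)
  terms <- c("treatment", "prior_relapses", "age")
  for (m in c("first_event", "ag", "pwp_t", "pwp_g", "wlw", "lwa")) {
    lay <- build_layout(trial, m, k)
    fit <- suppressWarnings(fit_cox(lay, terms))
    strata_part <- if (m %in% c("pwp_t", "pwp_g", "wlw"))
      "+ strata(stratum)" else ""
    ref <- coxph(as.formula(paste(
      "Surv(start, stop, status) ~ treatment + prior_relapses + age",
      "+ cluster(id)", strata_part)), data = lay)
    expect_equal(coef(fit), coef(ref), tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(sqrt(diag(fit$naive_covariance)),
                 sqrt(diag(ref$naive.var)), tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(sqrt(diag(fit$robust_covariance)),
                 sqrt(diag(ref$var)), tolerance = 1e-6,
                 ignore_attr = TRUE)
    mr <- martingale_residuals(fit)
    rr <- tapply(residuals(ref, type = "martingale"), lay$id, sum)
    expect_equal(mr[names(rr)], rr, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("coefficients are invariant to covariate location and equivariant to scale", {
  trial <- simulate_trial(trial_design(n_per_arm = 50), scenario1(),
                          seed = 32)
  lay <- build_layout(trial, "ag")
  fit0 <- fit_cox(lay, "treatment")
  lay$treatment <- lay$treatment + 5
  expect_equal(coef(fit_cox(lay, "treatment")), coef(fit0),
               tolerance = 1e-7)
  lay$treatment <- (lay$treatment - 5) * 4
  expect_equal(coef(fit_cox(lay, "treatment")), coef(fit0) / 4,
               tolerance = 1e-7)
})

test_that("robust and naive variances agree broadly on independent null data", {
  # one row per subject, cluster size 1, no treatment effect
  set.seed(33)
  n <- 500
  rows <- data.frame(id = as.character(1:n), stratum = 1L, start = 0,
                     stop = rexp(n), status = rbinom(n, 1L, 0.7),
                     x = rnorm(n))
  fit <- fit_cox(rows, "x")
  expect_lt(abs(fit$robust_covariance[1, 1] / fit$naive_covariance[1, 1]
                - 1), 0.2)
})

test_that("martingale residuals behave under the null model", {
  trial <- simulate_trial(trial_design(n_per_arm = 40), scenario1(),
                          seed = 34)
  lay <- build_layout(trial, "ag")
  null_fit <- fit_cox(lay, "treatment", max_iter = 0L)  # beta held at 0
  mr <- martingale_residuals(null_fit)
  expect_equal(sum(mr), 0, tolerance = 1e-8)
  nev <- vapply(trial$subjects, function(s) length(s$event_times_days),
                integer(1))
  names(nev) <- vapply(trial$subjects, function(s) as.character(s$id),
                       character(1))
  expect_true(all(mr <= nev[names(mr)] + 1e-12))
})

test_that("hazard-ratio summaries follow the exp(beta +/- 1.96 se) arithmetic", {
  fake_fit <- function(b, se) {
    structure(list(coefficients = c(treatment = b),
                   robust_covariance = matrix(se^2, 1, 1,
                                              dimnames = list("treatment",
                                                              "treatment"))),
              class = "cox_fit")
  }
  # published reference pairs; upper bounds computed from the rounded
  # inputs can differ by one unit in the third decimal
  s <- hazard_ratio_summary(fake_fit(-0.263, 0.194))
  expect_equal(round(s$hazard_ratio, 3), 0.769)
  expect_equal(round(s$ci_low, 3), 0.526)
  expect_lt(abs(s$ci_high - 1.123), 0.0015)

  s <- hazard_ratio_summary(fake_fit(-0.489, 0.231))
  expect_equal(round(s$hazard_ratio, 3), 0.613)
  expect_equal(round(s$ci_low, 3), 0.390)
  expect_lt(abs(s$ci_high - 0.965), 0.0015)

  s <- hazard_ratio_summary(fake_fit(0, 0.5))
  expect_equal(s$hazard_ratio, 1)
  expect_equal(s$ci_low * s$ci_high, 1, tolerance = 1e-12)

  expect_error(hazard_ratio_summary(fake_fit(0, 1), "nope"), "available")
})
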