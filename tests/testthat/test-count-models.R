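test_that("Poisson closed forms hold for intercept-only and two-group data", {
  rows <- data.frame(id = as.character(1:6), interval_index = 1L,
                     event_count = c(2L, 0L, 1L, 4L, 3L, 2L),
                     exposure_days = c(300, 400, 365.25, 200, 500, 450),
                     g = c(0, 0, 0, 1, 1, 1))
  fit <- fit_poisson(rows, character(0))
  expect_equal(unname(coef(fit)),
               log(sum(rows$event_count) /
                     sum(rows$exposure_days / 365.25)),
               tolerance = 1e-10)

  fit2 <- fit_poisson(rows, "g")
  r0 <- sum(rows$event_count[rows$g == 0]) /
    sum(rows$exposure_days[rows$g == 0] / 365.25)
  r1 <- sum(rows$event_count[rows$g == 1]) /
    sum(rows$exposure_days[rows$g == 1] / 365.25)
  expect_equal(unname(coef(fit2)["g"]), log(r1 / r0), tolerance = 1e-10)

  rows$event_count <- 0L
  expect_error(fit_poisson(rows, "g"), class = "msrecur_all_zero_counts")
})

test_that("Poisson estimates match the reference GLM and sandwich variances", {
  skip_if_not_installed("survival")  # only to keep suite deps aligned
  trial <- emulate_covariate_trial(80, design = trial_design(n_per_arm = 80),
                                   seed = 41)
  cnt <- build_counts(trial, "subject")
  terms <- c("treatment", "prior_relapses", "age")
  fit <- fit_poisson(cnt, terms)
  ref <- glm(event_count ~ treatment + prior_relapses + age +
               offset(log(exposure_days / 365.25)),
             family = poisson, data = cnt)
  expect_equal(coef(fit), coef(ref), tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sqrt(diag(fit$naive_covariance)),
               sqrt(diag(vcov(ref))), tolerance = 1e-7, ignore_attr = TRUE)
  skip_if_not_installed("sandwich")
  vc <- sandwich::vcovCL(ref, cluster = cnt$id, type = "HC0",
                         cadjust = FALSE)
  expect_equal(fit$robust_covariance, vc, tolerance = 1e-7,
               ignore_attr = TRUE)

  # score equations at the optimum
  mu <- exp(log(cnt$exposure_days / 365.25) +
              as.matrix(cbind(1, cnt[terms])) %*% coef(fit))
  score <- crossprod(as.matrix(cbind(1, cnt[terms])),
                     cnt$event_count - mu)
  expect_lt(max(abs(score)), 1e-6)
})

test_that("exposure rescaling shifts only the intercept", {
  trial <- simulate_trial(trial_design(n_per_arm = 60), scenario1(),
                          seed = 42)
  cnt <- build_counts(trial, "subject")
  fit1 <- fit_poisson(cnt, "treatment")
  cnt2 <- cnt
  cnt2$exposure_days <- cnt2$exposure_days * 10
  fit2 <- fit_poisson(cnt2, "treatment")
  expect_equal(unname(coef(fit2)["treatment"]),
               unname(coef(fit1)["treatment"]), tolerance = 1e-10)
  expect_equal(unname(coef(fit2)["(Intercept)"]),
               unname(coef(fit1)["(Intercept)"]) - log(10),
               tolerance = 1e-10)
})

test_that("GEE degenerates to Poisson for trivial clusterings", {
  trial <- simulate_trial(trial_design(n_per_arm = 60), scenario2(),
                          seed = 43)
  # one row per subject: independence and exchangeable both collapse
  cnt <- build_counts(trial, "subject")
  pois <- fit_poisson(cnt, "treatment")
  ind <- fit_gee_poisson(cnt, "treatment", working = "independence")
  exch <- fit_gee_poisson(cnt, "treatment", working = "exchangeable")
  expect_equal(coef(ind), coef(pois), tolerance = 1e-12)
  expect_equal(coef(exch), coef(pois), tolerance = 1e-12)

  # interval rows: independence GEE equals Poisson on the same rows
  iv <- build_counts(trial, "interval")
  ind2 <- fit_gee_poisson(iv, "treatment", working = "independence")
  pois2 <- fit_poisson(iv, "treatment")
  expect_equal(coef(ind2), coef(pois2), tolerance = 1e-10)
})

test_that("exchangeable GEE matches the frozen statsmodels reference fits", {
  for (ref in gee_reference_fits()) {
    trial <- simulate_trial(trial_design(), scenario1(), seed = ref$seed)
    fit <- fit_gee_poisson(build_counts(trial, "interval"), "treatment")
    expect_equal(unname(coef(fit)["treatment"]), ref$coef,
                 tolerance = 1e-6)
    expect_equal(sqrt(fit$robust_covariance["treatment", "treatment"]),
                 ref$robust_se, tolerance = 1e-6)
    expect_equal(fit$correlation_estimate, ref$alpha, tolerance = 1e-6)
  }

  # multi-covariate reference on the emulated trial (same provenance)
  trial <- emulate_covariate_trial(100, design = trial_design(n_per_arm = 100),
                                   seed = 7)
  fit <- fit_gee_poisson(build_counts(trial, "interval"),
                         c("treatment", "prior_relapses", "age"))
  expect_equal(unname(coef(fit)),
               c(-0.33262461408383, -0.36639026685047, 0.39546976346977,
                 -0.00298508359426), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(fit$robust_covariance))),
               c(0.23784444695266, 0.0936033465843, 0.07000809316039,
                 0.00563022463303), tolerance = 1e-6)
})

test_that("large samples recover a known Poisson rate ratio", {
  # homogeneous Poisson counts with rate ratio 0.7 over one year
  set.seed(44)
  n <- 2000
  rows <- data.frame(id = as.character(1:(2 * n)), interval_index = 1L,
                     event_count = c(rpois(n, 1.2), rpois(n, 1.2 * 0.7)),
                     exposure_days = 365.25,
                     treatment = rep(c(0, 1), each = n))
  fit <- fit_poisson(rows, "treatment")
  mc_se <- sqrt(1 / sum(rows$event_count[rows$treatment == 0]) +
                  1 / sum(rows$event_count[rows$treatment == 1]))
  expect_lt(abs(unname(coef(fit)["treatment"]) - log(0.7)), 2 * mc_se)
})

test_that("person-time rates reproduce the printed rate-ratio arithmetic", {
  expect_equal(round(0.763 / 1.069, 3), 0.714)
  expect_equal(round(53 / 69.5, 3), 0.763)

  # equal arms give ratio 1
  subs <- list(subject_with(100, 365.25, arm = 0L, id = 1),
               subject_with(100, 365.25, arm = 1L, id = 2))
  r <- person_time_rates(small_trial(subs))
  expect_equal(r$rate_ratio, 1)

  # rates are events over person-years
  subs <- list(subject_with(c(100, 200), 730.5, arm = 0L, id = 1),
               subject_with(300, 365.25, arm = 1L, id = 2))
  r <- person_time_rates(small_trial(subs))
  expect_equal(r$rate_control$rate, 1)
  expect_equal(r$rate_active$rate, 1)

  # an arm without events flags the ratio as degenerate
  subs <- list(subject_with(100, 365.25, arm = 0L, id = 1),
               subject_with(numeric(0), 365.25, arm = 1L, id = 2))
  r <- person_time_rates(small_trial(subs))
  expect_true(r$zero_events)
  expect_true(is.na(r$ci_low))
})
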