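#' Weibull parameters on the survival-function scale
#'
#' Parameterises a Weibull law through its survival function
#' \eqn{S(t) = \exp(-\lambda t^\gamma)} with `shape` \eqn{= \gamma}
#' (dimensionless) and `scale` \eqn{= \lambda} (units day^-shape).  The
#' hazard is \eqn{h(t) = \lambda\gamma t^{\gamma-1}}, so multiplying `scale`
#' by a constant multiplies the hazard by that constant at every time:
#' proportional hazards holds exactly within a fixed shape.
#'
#' @param shape positive shape \eqn{\gamma}.
#' @param scale positive scale \eqn{\lambda} in day^(-shape).
#' @return An object of class `weibull_params`.
#' @examples
#' weibull_params(1.1452, 0.00141)
#' @export
weibull_params <- function(shape, scale) {
  check_scalar_pos(shape, "shape")
  check_scalar_pos(scale, "scale")
  structure(list(shape = shape, scale = scale), class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("Weibull S(t) = exp(-%g t^%g)\n", x$scale, x$shape))
  invisible(x)
}

#' Draw Weibull event times by inverse-CDF sampling
#'
#' Returns `t = (-log(U) / scale)^(1/shape)` for `U ~ Uniform(0,1)`, so that
#' the draws satisfy \eqn{S(t) = \exp(-\lambda t^\gamma)} exactly.
#'
#' @param n number of draws.
#' @param params a [weibull_params()] object.
#' @param u optional vector of uniforms (length `n`) for deterministic use;
#'   by default fresh uniforms are drawn from the current RNG stream.
#' @return Numeric vector of times in days.
#' @export
sample_weibull <- function(n, params, u = NULL) {
  stopifnot(inherits(params, "weibull_params"))
  if (is.null(u)) u <- stats::runif(n)
  (-log(u) / params$scale)^(1 / params$shape)
}

#' Scale Weibull parameters by a hazard ratio
#'
#' Multiplies the scale parameter by `hazard_ratio`, which under
#' \eqn{S(t)=\exp(-\lambda t^\gamma)} multiplies the hazard by exactly
#' `hazard_ratio` at all times (exact proportional hazards).
#'
#' @param params a [weibull_params()] object.
#' @param hazard_ratio positive multiplicative effect on the hazard.
#' @return A new `weibull_params` object.
#' @export
treated_params <- function(params, hazard_ratio) {
  check_scalar_pos(hazard_ratio, "hazard_ratio")
  weibull_params(params$shape, params$scale * hazard_ratio)
}

#' Mixture scenario for the lesion-activation law
#'
#' A scenario is a finite mixture of Weibull components over patients: each
#' patient draws one component (once, at entry) and all of that patient's
#' lesion gap times follow the component law.
#'
#' @param name scenario label.
#' @param components list of `list(proportion =, params = weibull_params)`.
#' @return An object of class `scenario_spec`.
#' @seealso [scenario1()], [scenario2()] for the packaged presets.
#' @export
scenario_spec <- function(name, components) {
  stopifnot(is.character(name), length(components) >= 1L)
  props <- vapply(components, function(co) co$proportion, numeric(1))
  if (any(props <= 0) || any(props > 1))
    stop("component proportions must lie in (0, 1]", call. = FALSE)
  if (abs(sum(props) - 1) > 1e-12)
    stop("component proportions must sum to 1", call. = FALSE)
  for (co in components) stopifnot(inherits(co$params, "weibull_params"))
  structure(list(name = name, components = components),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%d component%s)\n", x$name,
              length(x$components),
              if (length(x$components) > 1) "s" else ""))
  for (co in x$components)
    cat(sprintf("  %4.1f%%  shape %g, scale %g\n", 100 * co$proportion,
                co$params$shape, co$params$scale))
  invisible(x)
}

#' Homogeneous single-Weibull relapse scenario
#'
#' All patients share one Weibull gap-time law (shape 1.1452, scale 0.00141
#' per day^shape), giving roughly 1.2 relapses per person-year in the
#' placebo arm -- a natural-history-like relapse rate.
#'
#' @return A `scenario_spec` with one component.
#' @export
scenario1 <- function() {
  scenario_spec("scenario1", list(
    list(proportion = 1, params = weibull_params(1.1452, 0.00141))))
}

#' Heterogeneous three-component relapse scenario
#'
#' A mixture over patients: 46% with shape 1.2442 / scale 0.000604, 45% with
#' shape 1.1550 / scale 0.001578, and 9% with shape 1.9694 / scale
#' 0.0000661.  The three components correspond to roughly 1, 1.4 and 3
#' relapses per person-year, echoing a 1 / 2 / 3-or-more split of relapse
#' counts in the year before entry.
#'
#' @return A `scenario_spec` with three components.
#' @export
scenario2 <- function() {
  scenario_spec("scenario2", list(
    list(proportion = 0.46, params = weibull_params(1.2442, 0.000604)),
    list(proportion = 0.45, params = weibull_params(1.1550, 0.001578)),
    list(proportion = 0.09, params = weibull_params(1.9694, 0.0000661))))
}

#' Design of the simulated two-arm relapse trial
#'
#' @param n_per_arm subjects per arm (default 100).
#' @param n_lesions latent lesions per patient (default 10); each lesion can
#'   produce at most one relapse, so the per-subject event count is capped.
#' @param followup_days administrative follow-up (default 3 years = 1095).
#' @param censoring dropout-time Weibull (default shape 2.1399, scale
#'   5.76e-7 per day^shape; median dropout just under 2 years).  Draws above
#'   `followup_days` are truncated to administrative censoring.
#' @param hazard_ratio multiplicative treatment effect on the lesion hazard
#'   (default 1/1.3; the true log hazard ratio is `log(1/1.3)` = -0.26236).
#' @param lesion_process `"sequential"` (default): lesions activate one
#'   after another, i.i.d. Weibull gap times between consecutive relapses.
#'   `"simultaneous"`: all lesion clocks start at entry and activation times
#'   are i.i.d. from entry.
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(n_per_arm = 100L,
                         n_lesions = 10L,
                         followup_days = 1095,
                         censoring = weibull_params(2.1399, 5.76e-7),
                         hazard_ratio = 1 / 1.3,
                         lesion_process = c("sequential", "simultaneous")) {
  stopifnot(n_per_arm >= 1, n_lesions >= 0)
  check_scalar_pos(followup_days, "followup_days")
  check_scalar_pos(hazard_ratio, "hazard_ratio")
  stopifnot(inherits(censoring, "weibull_params"))
  structure(list(n_per_arm = as.integer(n_per_arm),
                 n_lesions = as.integer(n_lesions),
                 followup_days = followup_days,
                 censoring = censoring,
                 hazard_ratio = hazard_ratio,
                 lesion_process = match.arg(lesion_process)),
            class = "trial_design")
}

subject_history <- function(id, arm, component_index, covariates,
                            event_times_days, censor_time_days) {
  stopifnot(arm %in% c(0L, 1L))
  if (length(event_times_days) > 1 && any(diff(event_times_days) <= 0))
    stop("event times must be strictly increasing", call. = FALSE)
  if (length(event_times_days) && any(event_times_days >= censor_time_days))
    stop("all event times must fall strictly before the censoring time",
         call. = FALSE)
  structure(list(id = id, arm = as.integer(arm),
                 component_index = as.integer(component_index),
                 covariates = covariates,
                 event_times_days = as.numeric(event_times_days),
                 censor_time_days = as.numeric(censor_time_days)),
            class = "subject_history")
}

#' @export
print.subject_history <- function(x, ...) {
  cat(sprintf("Subject %s (arm %d): %d event(s), censored at day %.1f\n",
              as.character(x$id), x$arm, length(x$event_times_days),
              x$censor_time_days))
  invisible(x)
}

## Draw one subject's lesion activation times given a component law.
## `log_hr_extra` shifts the hazard multiplicatively on top of the arm effect
## (used by the covariate emulator).
simulate_subject_impl <- function(design, scenario, arm, id,
                                  log_hr_extra = 0,
                                  covariates = numeric(0)) {
  props <- vapply(scenario$components, function(co) co$proportion, numeric(1))
  ci <- if (length(props) == 1L) 1L
        else sample.int(length(props), 1L, prob = props)
  pars <- scenario$components[[ci]]$params
  mult <- exp(log_hr_extra) * if (arm == 1L) design$hazard_ratio else 1
  pars <- treated_params(pars, mult)
  cens <- min(sample_weibull(1L, design$censoring), design$followup_days)
  if (design$n_lesions > 0L) {
    draws <- sample_weibull(design$n_lesions, pars)
    times <- switch(design$lesion_process,
                    sequential   = cumsum(draws),
                    simultaneous = sort(draws))
    ev <- times[times < cens]
  } else times <- ev <- numeric(0)
  out <- subject_history(id, arm, ci, covariates, ev, cens)
  ## latent (uncensored) activation times, kept for diagnostics such as
  ## checking the independence of censoring from the event process
  attr(out, "latent_times") <- times
  out
}

#' Simulate one subject of the lesion-based relapse process
#'
#' Draws the subject's mixture component, then the lesion activation times
#' (treatment-scaled in the active arm), then an independent censoring time
#' `min(Weibull dropout, followup)`.  Events are the activation times that
#' fall strictly before the censoring time; at most `n_lesions` events can
#' occur.
#'
#' @param design a [trial_design()].
#' @param scenario a [scenario_spec()].
#' @param arm 0 = placebo/low-dose, 1 = active/high-dose.
#' @param id subject identifier.
#' @return A `subject_history` object with fields `id`, `arm`,
#'   `component_index`, `covariates`, `event_times_days`,
#'   `censor_time_days`.
#' @export
simulate_subject <- function(design, scenario, arm, id = 1L) {
  stopifnot(inherits(design, "trial_design"),
            inherits(scenario, "scenario_spec"))
  simulate_subject_impl(design, scenario, as.integer(arm), id)
}

#' Simulate a full two-arm recurrent-event trial
#'
#' @param design a [trial_design()].
#' @param scenario a [scenario_spec()].
#' @param seed optional integer; when given, the dataset is a deterministic
#'   function of `(design, scenario, seed)` and the caller's RNG stream is
#'   left untouched.
#' @return A `trial_dataset`: list with `design`, `scenario`, and `subjects`
#'   (placebo arm first, then active).
#' @examples
#' trial <- simulate_trial(trial_design(n_per_arm = 20), scenario1(), seed = 1)
#' length(trial$subjects)
#' @export
simulate_trial <- function(design, scenario, seed = NULL) {
  stopifnot(inherits(design, "trial_design"),
            inherits(scenario, "scenario_spec"))
  with_seed(seed, {
    n <- design$n_per_arm
    subjects <- vector("list", 2L * n)
    k <- 0L
    for (arm in c(0L, 1L)) for (i in seq_len(n)) {
      k <- k + 1L
      subjects[[k]] <- simulate_subject_impl(design, scenario, arm, k)
    }
    structure(list(design = design, scenario = scenario, subjects = subjects),
              class = "trial_dataset")
  })
}

#' @export
print.trial_dataset <- function(x, ...) {
  nev <- vapply(x$subjects, function(s) length(s$event_times_days), integer(1))
  arm <- vapply(x$subjects, function(s) s$arm, integer(1))
  cat(sprintf("trial_dataset: %d subjects (%d placebo / %d active), %d events\n",
              length(x$subjects), sum(arm == 0L), sum(arm == 1L), sum(nev)))
  cat(sprintf("  mean events/subject: %.2f (placebo %.2f, active %.2f)\n",
              mean(nev), mean(nev[arm == 0L]), mean(nev[arm == 1L])))
  invisible(x)
}

#' Default covariate configuration for the trial emulator
#'
#' Marginal samplers and log-hazard coefficients for the baseline covariates
#' carried by [emulate_covariate_trial()]: `sex` (1 = male, drawn with the
#' 55:133 male:female ratio), `age` (Normal(35, 8) truncated to 18--60),
#' `edss` (discrete uniform 0--6), `mri_area` (log-normal, median 10),
#' `prior_relapses` (1, 2 or 3 with probabilities 0.46 / 0.45 / 0.09, the
#' "3" bucket standing for three-or-more).  By default only
#' `prior_relapses` affects the hazard, with coefficient `log(1.27)` per
#' prior relapse; all samplers and coefficients can be overridden.
#'
#' @param coefficients named numeric vector of log-hazard coefficients.
#' @param samplers named list of functions `n -> numeric(n)`.
#' @return A list with elements `coefficients` and `samplers`.
#' @export
covariate_config <- function(coefficients = NULL, samplers = NULL) {
  def_coef <- c(sex = 0, age = 0, edss = 0, mri_area = 0,
                prior_relapses = log(1.27))
  def_samp <- list(
    sex = function(n) stats::rbinom(n, 1L, 55 / 188),
    age = function(n) pmin(pmax(stats::rnorm(n, 35, 8), 18), 60),
    edss = function(n) sample(0:6, n, replace = TRUE),
    mri_area = function(n) stats::rlnorm(n, log(10), 0.5),
    prior_relapses = function(n)
      sample(1:3, n, replace = TRUE, prob = c(0.46, 0.45, 0.09)))
  if (!is.null(coefficients)) {
    if (any(!is.finite(coefficients)))
      stop("covariate coefficients must be finite", call. = FALSE)
    def_coef[names(coefficients)] <- coefficients
  }
  if (!is.null(samplers)) def_samp[names(samplers)] <- samplers
  if (!all(names(def_coef) %in% names(def_samp)))
    stop("every coefficient needs a matching sampler", call. = FALSE)
  list(coefficients = def_coef, samplers = def_samp)
}

#' Emulate a covariate-rich relapse trial
#'
#' Generates a two-arm trial like [simulate_trial()] but attaches baseline
#' covariates to every subject and scales each subject's lesion hazard by
#' `exp(sum(coefficients * (x - mean(x))))`; covariates are centred at their
#' realised means so that the marginal event rate stays comparable to the
#' covariate-free simulator.  Stands in for a real 188-patient dose
#' comparison whose data are not available.
#'
#' @param n_per_arm subjects per arm.
#' @param config a [covariate_config()].
#' @param design a [trial_design()]; its `hazard_ratio` is the treatment
#'   effect.
#' @param scenario gap-time law (default [scenario1()]).
#' @param seed optional integer seed.
#' @return A `trial_dataset` whose subjects carry named covariate vectors.
#' @export
emulate_covariate_trial <- function(n_per_arm = 94L,
                                    config = covariate_config(),
                                    design = trial_design(n_per_arm = n_per_arm),
                                    scenario = scenario1(),
                                    seed = NULL) {
  stopifnot(inherits(design, "trial_design"),
            inherits(scenario, "scenario_spec"))
  design$n_per_arm <- as.integer(n_per_arm)
  coefs <- config$coefficients
  with_seed(seed, {
    n <- design$n_per_arm
    ntot <- 2L * n
    covmat <- vapply(names(coefs),
                     function(nm) config$samplers[[nm]](ntot),
                     numeric(ntot))
    centred <- sweep(covmat, 2L, colMeans(covmat))
    lp <- drop(centred %*% coefs)
    subjects <- vector("list", ntot)
    k <- 0L
    for (arm in c(0L, 1L)) for (i in seq_len(n)) {
      k <- k + 1L
      subjects[[k]] <- simulate_subject_impl(
        design, scenario, arm, k,
        log_hr_extra = lp[k], covariates = covmat[k, ])
    }
    structure(list(design = design, scenario = scenario, subjects = subjects),
              class = "trial_dataset")
  })
}

#' Long-format view of a trial dataset
#'
#' One row per event (`status = 1`) plus one terminal censoring row per
#' subject (`status = 0`), with columns `id`, `arm`, `time_days`, `status`
#' and any subject covariates.
#'
#' @param x a `trial_dataset`.
#' @param row.names,optional,... ignored (base generic signature).
#' @return A `data.frame`.
#' @export
as.data.frame.trial_dataset <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  subs <- x$subjects
  nev <- vapply(subs, function(s) length(s$event_times_days), integer(1))
  nrow_i <- nev + 1L
  id <- rep(vapply(subs, function(s) as.character(s$id), character(1)), nrow_i)
  arm <- rep(vapply(subs, function(s) s$arm, integer(1)), nrow_i)
  time <- unlist(lapply(subs, function(s)
    c(s$event_times_days, s$censor_time_days)), use.names = FALSE)
  status <- unlist(lapply(nev, function(k) c(rep(1L, k), 0L)),
                   use.names = FALSE)
  out <- data.frame(id = id, arm = arm, time_days = time, status = status,
                    stringsAsFactors = FALSE)
  covnames <- names(subs[[1]]$covariates)
  for (nm in covnames)
    out[[nm]] <- rep(vapply(subs, function(s) s$covariates[[nm]], numeric(1)),
                     nrow_i)
  out
}

#' Write a trial dataset as a long-format CSV
#'
#' @param dataset a `trial_dataset`.
#' @param path output file; times are written with 6 decimal places.
#' @return `path`, invisibly.
#' @seealso [read_trial_csv()] for the inverse.
#' @export
write_trial_csv <- function(dataset, path) {
  df <- as.data.frame(dataset)
  df$time_days <- sprintf("%.6f", df$time_days)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a scenario/design configuration file
#'
#' Flat JSON with optional blocks `design` (fields of [trial_design()];
#' `censoring` given as `{shape, scale}`) and `scenario` (`name` plus
#' `components`, each `{proportion, shape, scale}`).  The packaged presets
#' `scenario1.json` and `scenario2.json` under `extdata` are examples.
#'
#' @param path JSON file.
#' @return List with elements `design` and `scenario`.
#' @export
read_scenario_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  design <- trial_design()
  if (!is.null(cfg$design)) {
    d <- cfg$design
    design <- trial_design(
      n_per_arm = d$n_per_arm %||% 100L,
      n_lesions = d$n_lesions %||% 10L,
      followup_days = d$followup_days %||% 1095,
      censoring = if (!is.null(d$censoring))
        weibull_params(d$censoring$shape, d$censoring$scale)
      else weibull_params(2.1399, 5.76e-7),
      hazard_ratio = d$hazard_ratio %||% (1 / 1.3),
      lesion_process = d$lesion_process %||% "sequential")
  }
  comp <- cfg$scenario$components
  scenario <- if (is.null(comp)) scenario1() else
    scenario_spec(cfg$scenario$name %||% "custom",
                  lapply(seq_len(nrow(comp)), function(i)
                    list(proportion = comp$proportion[i],
                         params = weibull_params(comp$shape[i],
                                                 comp$scale[i]))))
  list(design = design, scenario = scenario)
}
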