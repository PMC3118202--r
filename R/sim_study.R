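# Monte-Carlo comparison of the eight models: replicate trials, fit every
# requested model, and summarise the treatment log-hazard-ratio estimates
# as bias and MSE against the design's true log hazard ratio.

MODEL_KEYS <- c("first_event", "ag", "pwp_t", "pwp_g", "wlw", "lwa",
                "poisson", "gee_poisson")

MODEL_LABELS <- c(
  first_event = "1: Time-to-first-event Cox regression",
  ag          = "2: AG model",
  pwp_t       = "3-1: PWP-T model",
  pwp_g       = "3-2: PWP-G model",
  wlw         = "4: WLW model",
  lwa         = "5: LWA model",
  poisson     = "6: Poisson regression model",
  gee_poisson = "7: GEE-Poisson model")

#' Configuration of a Monte-Carlo model-comparison study
#'
#' @param scenario a [scenario_spec()].
#' @param design a [trial_design()].
#' @param models subset of `"first_event"`, `"ag"`, `"pwp_t"`, `"pwp_g"`,
#'   `"wlw"`, `"lwa"`, `"poisson"`, `"gee_poisson"` (default all eight).
#' @param replicates number of simulated trials (default 1000).
#' @param base_seed integer; replicate r uses seed `base_seed + r`, so the
#'   simulated data stream does not depend on which models are requested.
#' @return An object of class `study_config`.
#' @export
study_config <- function(scenario = scenario1(), design = trial_design(),
                         models = MODEL_KEYS, replicates = 1000L,
                         base_seed = 20260101L) {
  stopifnot(inherits(scenario, "scenario_spec"),
            inherits(design, "trial_design"),
            replicates >= 1L, length(models) >= 1L)
  models <- match.arg(models, MODEL_KEYS, several.ok = TRUE)
  structure(list(scenario = scenario, design = design, models = models,
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed)),
            class = "study_config")
}

fit_model_on_trial <- function(trial, model, max_stratum = NULL) {
  switch(model,
         first_event = fit_cox(build_layout(trial, "first_event"),
                               "treatment"),
         ag    = fit_cox(build_layout(trial, "ag"), "treatment"),
         pwp_t = fit_cox(build_layout(trial, "pwp_t", max_stratum),
                         "treatment"),
         pwp_g = fit_cox(build_layout(trial, "pwp_g", max_stratum),
                         "treatment"),
         wlw   = fit_cox(build_layout(trial, "wlw", max_stratum),
                         "treatment"),
         lwa   = fit_cox(build_layout(trial, "lwa", max_stratum),
                         "treatment"),
         poisson = fit_poisson(build_counts(trial, "subject"), "treatment"),
         gee_poisson = fit_gee_poisson(build_counts(trial, "interval"),
                                       "treatment"))
}

#' Simulate and fit one study replicate
#'
#' Simulates one trial with seed `base_seed + rep_index` and fits every
#' requested model with treatment as the sole covariate.  Per-model
#' failures are recorded, never fatal.
#'
#' @param config a [study_config()].
#' @param rep_index replicate number (1-based).
#' @return List with `estimate`, `robust_se` and `converged`, each a named
#'   vector over `config$models`.
#' @export
run_replicate <- function(config, rep_index) {
  seed <- (config$base_seed + as.integer(rep_index)) %% .Machine$integer.max
  trial <- simulate_trial(config$design, config$scenario, seed = seed)
  k <- max_event_count(trial)
  est <- se <- stats::setNames(rep(NA_real_, length(config$models)),
                               config$models)
  ok <- stats::setNames(rep(FALSE, length(config$models)), config$models)
  for (m in config$models) {
    fit <- tryCatch(suppressWarnings(fit_model_on_trial(trial, m, k)),
                    error = function(e) NULL)
    if (!is.null(fit) && isTRUE(fit$converged)) {
      est[m] <- unname(fit$coefficients["treatment"])
      se[m] <- sqrt(fit$robust_covariance["treatment", "treatment"])
      ok[m] <- TRUE
    }
  }
  list(estimate = est, robust_se = se, converged = ok)
}

#' Run the full Monte-Carlo study
#'
#' Bias is `mean(beta_hat) - log(hazard_ratio)` and MSE is
#' `mean((beta_hat - log(hazard_ratio))^2)`, both over converged
#' replicates; the true log hazard ratio is taken from the design for every
#' model, including the time-to-first-event and marginal models.
#'
#' @param config a [study_config()].
#' @param progress print a dot every 100 replicates.
#' @return A `data.frame` of class `simulation_result` with one row per
#'   model: `model`, `label`, `replicates_used`, `failures`, `bias`,
#'   `mse`, `mean_robust_se`, `mc_se_of_bias`.
#' @examples
#' cfg <- study_config(replicates = 5, models = c("first_event", "ag"))
#' run_study(cfg)
#' @export
run_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  R <- config$replicates
  nm <- length(config$models)
  est <- se <- matrix(NA_real_, R, nm,
                      dimnames = list(NULL, config$models))
  for (r in seq_len(R)) {
    rep_r <- run_replicate(config, r)
    est[r, ] <- rep_r$estimate
    se[r, ] <- rep_r$robust_se
    if (progress && r %% 100L == 0L) cat(".")
  }
  if (progress) cat("\n")
  beta_true <- log(config$design$hazard_ratio)
  rows <- lapply(config$models, function(m) {
    ok <- is.finite(est[, m])
    used <- sum(ok)
    if (used < 0.9 * R)
      stop(sprintf("model '%s': %d of %d replicates failed (>10%%)",
                   m, R - used, R), call. = FALSE)
    dev <- est[ok, m] - beta_true
    data.frame(model = m, label = unname(MODEL_LABELS[m]),
               replicates_used = used, failures = R - used,
               bias = mean(dev), mse = mean(dev^2),
               mean_robust_se = mean(se[ok, m]),
               mc_se_of_bias = stats::sd(dev) / sqrt(used),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "beta_true") <- beta_true
  attr(out, "scenario") <- config$scenario$name
  class(out) <- c("simulation_result", "data.frame")
  out
}

#' Write a bias/MSE study report
#'
#' Emits a CSV and a Markdown table with columns `Model | Bias | MSE` per
#' scenario, models in the fixed report order.
#'
#' @param results a `simulation_result`, or a named list of them (one per
#'   scenario) to be laid out side by side.
#' @param path output stem; `<path>.csv` and `<path>.md` are written.
#' @return Invisible character vector of the files written.
#' @export
write_study_report <- function(results, path) {
  if (inherits(results, "simulation_result"))
    results <- stats::setNames(list(results),
                               attr(results, "scenario") %||% "study")
  stopifnot(length(results) >= 1L)
  models <- results[[1]]$model
  tab <- data.frame(Model = unname(MODEL_LABELS[models]),
                    stringsAsFactors = FALSE)
  for (nm in names(results)) {
    r <- results[[nm]]
    stopifnot(identical(r$model, models))
    tab[[paste0("Bias (", nm, ")")]] <- round(r$bias, 3)
    tab[[paste0("MSE (", nm, ")")]] <- round(r$mse, 3)
  }
  csv <- paste0(path, ".csv"); md <- paste0(path, ".md")
  utils::write.csv(tab, csv, row.names = FALSE)
  fmt_row <- function(cells) paste0("| ", paste(cells, collapse = " | "),
                                    " |")
  lines <- c(fmt_row(names(tab)),
             fmt_row(rep("---", ncol(tab))),
             vapply(seq_len(nrow(tab)), function(i)
               fmt_row(unlist(lapply(tab[i, ], format))), character(1)))
  writeLines(lines, md)
  invisible(c(csv, md))
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Simulation study (%s): true log HR %.5f\n",
              attr(x, "scenario") %||% "?", attr(x, "beta_true")))
  df <- as.data.frame(x)
  df$bias <- round(df$bias, 4); df$mse <- round(df$mse, 4)
  df$mean_robust_se <- round(df$mean_robust_se, 4)
  df$mc_se_of_bias <- round(df$mc_se_of_bias, 4)
  print(df[, c("label", "replicates_used", "failures", "bias", "mse",
               "mean_robust_se", "mc_se_of_bias")], row.names = FALSE)
  invisible(x)
}
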