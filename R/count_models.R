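# Person-time count models: Poisson regression with a log-exposure offset,
# GEE-Poisson on 6-month interval counts with an exchangeable working
# correlation, and person-time rate utilities.
#
# Exposure offsets are in YEARS (days / 365.25) so intercepts are annual
# log-rates, directly comparable with annual relapse rates.

DAYS_PER_YEAR <- 365.25

count_design <- function(rows, covariates) {
  if (!all(covariates %in% names(rows)))
    stop("missing covariate columns: ",
         paste(setdiff(covariates, names(rows)), collapse = ", "),
         call. = FALSE)
  if (any(rows$exposure_days <= 0))
    stop("all exposures must be positive", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, as.matrix(rows[covariates]))
  if (any(!is.finite(X))) stop("non-finite covariates", call. = FALSE)
  list(X = X, y = as.numeric(rows$event_count),
       off = log(rows$exposure_days / DAYS_PER_YEAR),
       id = as.character(rows$id))
}

count_fit_obj <- function(beta, naive, robust, working, alpha, scale,
                          iter, converged, names_, extra = list()) {
  names(beta) <- names_
  dimnames(naive) <- dimnames(robust) <- list(names_, names_)
  structure(c(list(coefficients = beta, naive_covariance = naive,
                   robust_covariance = robust,
                   working_correlation = working,
                   correlation_estimate = alpha, scale = scale,
                   iterations = iter, converged = converged), extra),
            class = "count_fit")
}

#' @export
print.count_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s working correlation), %s in %d iteration(s)\n",
              if (x$working_correlation == "none") "Poisson" else
                "GEE-Poisson",
              x$working_correlation,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  if (x$working_correlation == "exchangeable")
    cat(sprintf("  estimated intra-subject correlation: %.4f\n",
                x$correlation_estimate))
  print(data.frame(coef = x$coefficients,
                   `se(naive)` = sqrt(diag(x$naive_covariance)),
                   `se(robust)` = sqrt(diag(x$robust_covariance)),
                   check.names = FALSE))
  invisible(x)
}

#' @export
coef.count_fit <- function(object, ...) object$coefficients

#' @export
vcov.count_fit <- function(object, type = c("robust", "naive"), ...) {
  switch(match.arg(type), robust = object$robust_covariance,
         naive = object$naive_covariance)
}

#' Poisson regression with person-time offset
#'
#' Maximum-likelihood Poisson fit of `event_count` on an intercept plus
#' `covariates` with offset `log(exposure_days / 365.25)`, by iteratively
#' reweighted least squares.  Returns the naive information-based
#' covariance (no overdispersion scaling) and a cluster-robust sandwich
#' covariance grouped by subject `id`.
#'
#' @param rows count rows from [build_counts()] (columns `id`,
#'   `event_count`, `exposure_days`, covariates).
#' @param covariates character vector of covariate column names.
#' @param tol gradient max-norm tolerance.
#' @param max_iter IRLS iteration cap.
#' @return A `count_fit`.
#' @export
fit_poisson <- function(rows, covariates, tol = 1e-10, max_iter = 50L) {
  d <- count_design(rows, covariates)
  if (sum(d$y) == 0)
    stop_msrecur("no events in the dataset", "msrecur_all_zero_counts")
  p <- ncol(d$X)
  beta <- c(log(sum(d$y) / sum(exp(d$off))), numeric(p - 1L))
  converged <- FALSE
  iter <- 0L
  repeat {
    mu <- exp(d$off + drop(d$X %*% beta))
    U <- drop(crossprod(d$X, d$y - mu))
    if (max(abs(U)) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    I <- crossprod(d$X * mu, d$X)
    beta <- beta + solve(I, U)
    iter <- iter + 1L
  }
  if (!converged)
    stop_msrecur("Poisson IRLS failed to converge", "msrecur_nonconvergence")
  I <- crossprod(d$X * mu, d$X)
  naive <- solve(I)
  G <- rowsum(d$X * (d$y - mu), d$id, reorder = TRUE)
  robust <- naive %*% crossprod(G) %*% naive
  count_fit_obj(beta, naive, robust, "none", NA_real_, NA_real_, iter,
                converged, colnames(d$X))
}

## Closed-form pieces of the exchangeable working-covariance inverse:
## R^-1 = (1/(1-a)) [I - (a / (1 + (n-1)a)) J].
gee_cluster_stats <- function(Z, e, id, alpha) {
  ## Z = diag(sqrt(mu)) X, e = (y - mu)/sqrt(mu); returns per-cluster
  ## contributions to M = D'V^-1 D and s_c = D'V^-1 (y - mu) (phi omitted:
  ## it cancels in the estimating equation and the sandwich).
  c1 <- 1 / (1 - alpha)
  Zs <- rowsum(Z, id, reorder = TRUE)            # cluster sums of rows of Z
  es <- rowsum(e, id, reorder = TRUE)[, 1L]
  nc <- as.vector(table(id)[rownames(Zs)])
  c2 <- alpha / (1 + (nc - 1) * alpha)
  M <- c1 * (crossprod(Z) - crossprod(Zs, Zs * c2))
  S <- c1 * (rowsum(Z * e, id, reorder = TRUE) - Zs * (c2 * es))
  list(M = M, S = S)
}

#' GEE-Poisson regression on interval counts
#'
#' Solves the generalized estimating equations for a log-link Poisson mean
#' with offset `log(exposure_days / 365.25)`, clustering the 6-month
#' interval counts by subject.  With the exchangeable working structure the
#' common intra-subject correlation is re-estimated from standardized
#' (Pearson) residuals at every iteration using moment estimators with
#' denominators `N - p` for the dispersion and `N_pairs - p` for the
#' correlation; the robust covariance is the subject-clustered sandwich.
#' If the correlation estimate leaves the feasible interval
#' `(-1/(max cluster size - 1), 1)` the fit falls back to the independence
#' structure with `working_fallback = TRUE`.
#'
#' @param rows interval count rows from
#'   `build_counts(dataset, "interval")`.
#' @param covariates character vector of covariate column names.
#' @param working `"exchangeable"` (default) or `"independence"`.
#' @param tol tolerance on the coefficient max-change.
#' @param max_iter scoring iteration cap.
#' @return A `count_fit` with `working_correlation`,
#'   `correlation_estimate` and `working_fallback`.
#' @export
fit_gee_poisson <- function(rows, covariates,
                            working = c("exchangeable", "independence"),
                            tol = 1e-10, max_iter = 100L) {
  working <- match.arg(working)
  d <- count_design(rows, covariates)
  if (length(unique(d$id)) < 2L)
    stop("GEE needs at least 2 subjects", call. = FALSE)
  if (sum(d$y) == 0)
    stop_msrecur("no events in the dataset", "msrecur_all_zero_counts")
  p <- ncol(d$X)
  N <- length(d$y)
  csize <- table(d$id)
  n_pairs <- sum(csize * (csize - 1) / 2)
  alpha_max <- if (max(csize) > 1) 1 else Inf
  alpha_min <- if (max(csize) > 1) -1 / (max(csize) - 1) else -Inf

  beta <- coef(fit_poisson(rows, covariates))
  alpha <- 0
  fallback <- FALSE
  converged <- FALSE
  iter <- 0L
  repeat {
    mu <- exp(d$off + drop(d$X %*% beta))
    rmu <- sqrt(mu)
    e <- (d$y - mu) / rmu
    phi <- sum(e^2) / (N - p)
    if (working == "exchangeable" && !fallback && n_pairs > p) {
      es <- rowsum(e, d$id, reorder = TRUE)[, 1L]
      ess <- rowsum(e^2, d$id, reorder = TRUE)[, 1L]
      alpha <- sum(es^2 - ess) / 2 / phi / (n_pairs - p)
      if (!is.finite(alpha) || alpha <= alpha_min || alpha >= alpha_max) {
        fallback <- TRUE
        alpha <- 0
      }
    }
    st <- gee_cluster_stats(d$X * rmu, e, d$id, alpha)
    score <- colSums(st$S)
    delta <- solve(st$M, score)
    beta <- beta + delta
    iter <- iter + 1L
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (!converged)
    stop_msrecur("GEE-Poisson failed to converge", "msrecur_nonconvergence")
  mu <- exp(d$off + drop(d$X %*% beta))
  rmu <- sqrt(mu)
  e <- (d$y - mu) / rmu
  phi <- sum(e^2) / (N - p)
  st <- gee_cluster_stats(d$X * rmu, e, d$id, alpha)
  Minv <- solve(st$M)
  naive <- Minv * phi
  robust <- Minv %*% crossprod(st$S) %*% Minv
  count_fit_obj(beta, naive, robust,
                if (fallback) "independence" else working,
                if (working == "exchangeable" && !fallback) alpha
                else NA_real_,
                phi, iter, converged, colnames(d$X),
                extra = list(working_fallback = fallback))
}

#' Annual relapse rates by the person-time method
#'
#' Per-arm rate = total events / total person-years (days / 365.25); the
#' rate ratio is active over control with a log-scale normal 95% CI using
#' `SE = sqrt(1/e1 + 1/e0)` and a two-sided Wald p-value.
#'
#' @param dataset a `trial_dataset`.
#' @return List with per-arm `rate_control` / `rate_active` summaries
#'   (`events`, `person_years`, `rate`), `rate_ratio`, `ci_low`,
#'   `ci_high`, `p_value`, and `zero_events` flag (CI undefined when an
#'   arm has no events).
#' @export
person_time_rates <- function(dataset) {
  arm <- vapply(dataset$subjects, function(s) s$arm, integer(1))
  nev <- vapply(dataset$subjects, function(s) length(s$event_times_days),
                integer(1))
  py <- vapply(dataset$subjects, function(s) s$censor_time_days,
               numeric(1)) / DAYS_PER_YEAR
  summ <- function(a) {
    e <- sum(nev[arm == a]); y <- sum(py[arm == a])
    list(events = e, person_years = y, rate = e / y)
  }
  s0 <- summ(0L); s1 <- summ(1L)
  if (s0$person_years <= 0 || s1$person_years <= 0)
    stop("both arms need positive person-time", call. = FALSE)
  ratio <- s1$rate / s0$rate
  zero <- s0$events == 0L || s1$events == 0L
  if (zero) {
    ci <- c(NA_real_, NA_real_); pv <- NA_real_
  } else {
    se <- sqrt(1 / s1$events + 1 / s0$events)
    ci <- exp(log(ratio) + c(-1.96, 1.96) * se)
    pv <- 2 * stats::pnorm(-abs(log(ratio) / se))
  }
  list(rate_control = s0, rate_active = s1, rate_ratio = ratio,
       ci_low = ci[1], ci_high = ci[2], p_value = pv, zero_events = zero)
}
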