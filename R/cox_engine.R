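# Stratified Cox partial-likelihood fitter on counting-process rows.
#
# The partial likelihood uses the Breslow tie approximation and is summed
# over strata; risk sets never cross strata, so the six recurrent-event
# formulations (AG, PWP-T, PWP-G, WLW, LWA, first-event) arise purely from
# the layout handed in.  Cluster-robust variance is the Lin-Wei sandwich
# I^-1 (sum_c g_c g_c') I^-1 with g_c the score residuals summed over a
# cluster (subject).

## Per-stratum static structure: event times, death counts, death covariate
## sums, and each row's (a, b] window of covered event indices.
cox_prepare_stratum <- function(start, stop, status, X) {
  dead <- status == 1L
  et <- sort(unique(stop[dead]))
  m <- length(et)
  if (m == 0L) return(NULL)
  dk <- as.vector(rowsum(rep(1, sum(dead)),
                         match(stop[dead], et), reorder = TRUE))
  sx <- rowsum(X[dead, , drop = FALSE], match(stop[dead], et),
               reorder = TRUE)
  ## row i is at risk at event k iff start_i < et_k <= stop_i
  a <- findInterval(start, et)            # number of event times <= start
  b <- findInterval(stop, et)             # number of event times <= stop
  list(et = et, m = m, dk = dk, sx = sx, a = a, b = b,
       death_b = b[dead], dead = dead)
}

## Accumulate `vals` (vector or matrix) at positions `pos` into length-m rows.
accum_at <- function(vals, pos, m) {
  out <- rowsum(vals, pos, reorder = TRUE)
  idx <- as.integer(rownames(out))
  full <- matrix(0, m, ncol(out))
  keep <- idx >= 1L & idx <= m
  full[idx[keep], ] <- out[keep, , drop = FALSE]
  full
}

## Risk-set sums S(k) = sum over rows covering event k of `vals`, for all k,
## via a difference-array + cumulative sum (O(n + m)).
riskset_sums <- function(vals, a, b, m) {
  vals <- as.matrix(vals)
  inc <- accum_at(rbind(vals, -vals), c(a + 1L, b + 1L), m + 1L)
  apply(inc, 2L, cumsum)[seq_len(m), , drop = FALSE]
}

cox_stratum_derivs <- function(st, w, wx, wxx, beta_x_dead) {
  m <- st$m
  S0 <- riskset_sums(w, st$a, st$b, m)[, 1L]
  S1 <- riskset_sums(wx, st$a, st$b, m)
  S2u <- riskset_sums(wxx, st$a, st$b, m)   # upper-triangle columns
  xbar <- S1 / S0
  loglik <- sum(beta_x_dead) - sum(st$dk * log(S0))
  U <- colSums(st$sx) - colSums(st$dk * xbar)
  p <- ncol(S1)
  H <- matrix(0, p, p)
  col <- 0L
  for (j in seq_len(p)) for (l in j:p) {
    col <- col + 1L
    hjl <- sum(st$dk * (S2u[, col] / S0 - xbar[, j] * xbar[, l]))
    H[j, l] <- H[l, j] <- hjl
  }
  list(loglik = loglik, U = U, H = H, S0 = S0, xbar = xbar)
}

upper_tri_products <- function(X) {
  p <- ncol(X)
  out <- matrix(0, nrow(X), p * (p + 1L) / 2L)
  col <- 0L
  for (j in seq_len(p)) for (l in j:p) {
    col <- col + 1L
    out[, col] <- X[, j] * X[, l]
  }
  out
}

#' Fit a (stratified) Cox model on counting-process rows
#'
#' Maximises the Breslow partial likelihood by Newton-Raphson from
#' `beta = 0` with step-halving, and returns both the naive covariance
#' (inverse observed information) and the cluster-robust sandwich
#' covariance grouped by subject.
#'
#' @param rows layout `data.frame` with columns `start`, `stop`, `status`,
#'   `id`, optionally `stratum`, and the covariate columns.
#' @param covariates character vector of covariate column names.
#' @param stratified if `FALSE`, the `stratum` column is ignored and a
#'   single baseline is used.
#' @param cluster_by_subject compute the robust sandwich variance with
#'   subjects (`id`) as clusters (default `TRUE`).
#' @param tol convergence tolerance on the gradient max-norm.
#' @param max_iter Newton-Raphson iteration cap.
#' @return An object of class `cox_fit` with elements `coefficients`,
#'   `naive_covariance`, `robust_covariance`, `log_partial_likelihood`,
#'   `iterations`, `converged`, `monotone_likelihood`, `n_events`,
#'   `strata_count`, `martingale_residuals` (per subject) and
#'   `score_residuals` (per cluster).
#' @examples
#' trial <- simulate_trial(trial_design(n_per_arm = 50), scenario1(), seed = 1)
#' fit <- fit_cox(build_layout(trial, "ag"), "treatment")
#' hazard_ratio_summary(fit, "treatment")
#' @export
fit_cox <- function(rows, covariates, stratified = TRUE,
                    cluster_by_subject = TRUE, tol = 1e-8, max_iter = 25L) {
  if (!all(covariates %in% names(rows)))
    stop("missing covariate columns: ",
         paste(setdiff(covariates, names(rows)), collapse = ", "),
         call. = FALSE)
  if (any(rows$stop <= rows$start))
    stop("zero-length or inverted (start, stop] intervals", call. = FALSE)
  X <- as.matrix(rows[covariates])
  if (any(!is.finite(X))) stop("non-finite covariates", call. = FALSE)
  status <- as.integer(rows$status)
  n_events <- sum(status == 1L)
  if (n_events == 0L)
    stop_msrecur("no events in the data; cannot fit a Cox model",
                 "msrecur_no_events")
  strat <- if (stratified && !is.null(rows$stratum)) rows$stratum
           else rep(1L, nrow(rows))
  p <- length(covariates)

  idx_by_stratum <- split(seq_len(nrow(rows)), strat)
  strata <- lapply(idx_by_stratum, function(ii)
    c(cox_prepare_stratum(rows$start[ii], rows$stop[ii], status[ii],
                          X[ii, , drop = FALSE]), list(rows = ii)))
  empty <- vapply(strata, function(s) is.null(s$et), logical(1))
  if (any(empty)) {
    warning(sum(empty), " stratum/strata without events dropped from the ",
            "partial likelihood", call. = FALSE)
    strata <- strata[!empty]
  }

  beta <- numeric(p)
  loglik_prev <- -Inf
  converged <- FALSE
  monotone <- FALSE
  iter <- 0L
  deriv <- NULL

  eval_derivs <- function(beta) {
    eta <- drop(X %*% beta)
    w <- exp(eta)
    total <- list(loglik = 0, U = numeric(p), H = matrix(0, p, p),
                  per_stratum = vector("list", length(strata)))
    for (si in seq_along(strata)) {
      st <- strata[[si]]
      ii <- st$rows
      Xi <- X[ii, , drop = FALSE]
      d <- cox_stratum_derivs(st, w[ii], w[ii] * Xi,
                              w[ii] * upper_tri_products(Xi),
                              eta[ii][st$dead])
      total$loglik <- total$loglik + d$loglik
      total$U <- total$U + d$U
      total$H <- total$H + d$H
      total$per_stratum[[si]] <- d
    }
    total$w <- w
    total
  }

  repeat {
    deriv <- eval_derivs(beta)
    if (iter == 0L || deriv$loglik >= loglik_prev - 1e-12)
      loglik_prev <- deriv$loglik
    if (max(abs(deriv$U)) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    if (max(abs(beta)) > 15) { monotone <- TRUE; break }
    step <- tryCatch(solve(deriv$H, deriv$U), error = function(e) NULL)
    if (is.null(step)) { monotone <- TRUE; break }
    ## step-halving on likelihood decrease (slack scaled to the loglik
    ## magnitude so float noise near the optimum is not treated as one)
    slack <- 1e-10 * (abs(deriv$loglik) + 1)
    half <- 0L
    repeat {
      cand <- beta + step
      ll_cand <- eval_derivs(cand)$loglik
      if (ll_cand >= deriv$loglik - slack || half >= 20L) break
      step <- step / 2
      half <- half + 1L
    }
    beta <- beta + step
    iter <- iter + 1L
  }

  naive <- tryCatch(solve(deriv$H), error = function(e)
    matrix(NA_real_, p, p))

  ## residuals at beta-hat
  w <- deriv$w
  score_rows <- matrix(0, nrow(rows), p)
  mart_rows <- numeric(nrow(rows))
  for (si in seq_along(strata)) {
    st <- strata[[si]]
    d <- deriv$per_stratum[[si]]
    ii <- st$rows
    A <- st$dk / d$S0                       # baseline hazard increments
    cumA <- c(0, cumsum(A))
    cumB <- rbind(0, apply(A * d$xbar, 2L, cumsum))
    Xi <- X[ii, , drop = FALSE]
    wi <- w[ii]
    expected <- wi * (cumA[st$b + 1L] - cumA[st$a + 1L])
    mart_rows[ii] <- status[ii] - expected
    drift <- wi * (Xi * (cumA[st$b + 1L] - cumA[st$a + 1L]) -
                     (cumB[st$b + 1L, , drop = FALSE] -
                        cumB[st$a + 1L, , drop = FALSE]))
    obs <- matrix(0, length(ii), p)
    obs[st$dead, ] <- Xi[st$dead, , drop = FALSE] -
      d$xbar[st$death_b, , drop = FALSE]
    score_rows[ii, ] <- obs - drift
  }
  cl <- if (cluster_by_subject) as.character(rows$id)
        else as.character(seq_len(nrow(rows)))
  G <- rowsum(score_rows, cl, reorder = TRUE)
  robust <- naive %*% crossprod(G) %*% naive
  mart <- rowsum(mart_rows, as.character(rows$id), reorder = TRUE)

  names(beta) <- covariates
  dimnames(naive) <- dimnames(robust) <- list(covariates, covariates)
  structure(list(coefficients = beta,
                 naive_covariance = naive,
                 robust_covariance = robust,
                 log_partial_likelihood = deriv$loglik,
                 iterations = iter,
                 converged = converged && !monotone,
                 monotone_likelihood = monotone,
                 n_events = n_events,
                 strata_count = length(strata),
                 martingale_residuals = stats::setNames(mart[, 1L],
                                                        rownames(mart)),
                 score_residuals = G),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit: %d events, %d strat%s, %s in %d iteration(s)\n",
              x$n_events, x$strata_count,
              if (x$strata_count > 1) "a" else "um",
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  se_n <- sqrt(diag(x$naive_covariance))
  se_r <- sqrt(diag(x$robust_covariance))
  print(data.frame(coef = x$coefficients, `se(naive)` = se_n,
                   `se(robust)` = se_r, check.names = FALSE))
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) object$coefficients

#' @export
vcov.cox_fit <- function(object, type = c("robust", "naive"), ...) {
  switch(match.arg(type), robust = object$robust_covariance,
         naive = object$naive_covariance)
}

#' Hazard ratio with 95% confidence interval and Wald p-value
#'
#' `HR = exp(beta)`, `CI = exp(beta +/- 1.96 * SE)` with the normal
#' quantile fixed at 1.96, and a two-sided Wald p-value.  The robust SE is
#' used when available.
#'
#' @param fit a `cox_fit` or `count_fit`.
#' @param name coefficient name (default `"treatment"`).
#' @return Named list with `estimate`, `se`, `hazard_ratio`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
hazard_ratio_summary <- function(fit, name = "treatment") {
  if (!name %in% names(fit$coefficients))
    stop(sprintf("no coefficient '%s'; available: %s", name,
                 paste(names(fit$coefficients), collapse = ", ")),
         call. = FALSE)
  b <- unname(fit$coefficients[name])
  V <- fit$robust_covariance
  if (is.null(V) || any(!is.finite(diag(V)))) V <- fit$naive_covariance
  se <- sqrt(V[name, name])
  list(estimate = b, se = se,
       hazard_ratio = exp(b),
       ci_low = exp(b - 1.96 * se),
       ci_high = exp(b + 1.96 * se),
       p_value = 2 * stats::pnorm(-abs(b / se)))
}

#' Per-subject martingale residuals
#'
#' `N_i - sum over the subject's rows of exp(x'beta) *
#' (Lambda0(stop) - Lambda0(start))` with the Breslow baseline cumulative
#' hazard estimated within each stratum.  Under the null model the
#' residuals sum to zero; each residual is bounded above by the subject's
#' event count.
#'
#' @param fit a converged `cox_fit`.
#' @return Named numeric vector, one residual per subject.
#' @export
martingale_residuals <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  fit$martingale_residuals
}
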