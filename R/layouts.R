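# Model-specific risk-set layouts.
#
# Every time-to-event layout is a data.frame of counting-process rows
# (id, stratum, start, stop, status, covariates) on half-open intervals
# (start, stop]: the event sits at `stop`, and a subject is at risk at time
# t in a stratum iff it has a row there with start < t <= stop.  The six
# Cox-type models differ ONLY in their layout; the fitter is shared.

subject_covariate_row <- function(subject) {
  c(treatment = as.numeric(subject$arm), subject$covariates)
}

layout_frame <- function(subject, stratum, start, stop, status) {
  n <- length(start)
  cov <- subject_covariate_row(subject)
  out <- data.frame(id = rep(as.character(subject$id), n),
                    stratum = as.integer(stratum),
                    start = as.numeric(start), stop = as.numeric(stop),
                    status = as.integer(status), stringsAsFactors = FALSE)
  for (nm in names(cov)) out[[nm]] <- rep(cov[[nm]], n)
  out
}

#' Time-to-first-event layout
#'
#' One row per subject: `(0, T1, 1)` if the subject has at least one event,
#' otherwise `(0, C, 0)`.  All information past the first event is
#' discarded.
#'
#' @param subject a `subject_history`.
#' @return A one-row layout `data.frame`.
#' @export
build_first_event <- function(subject) {
  ev <- subject$event_times_days
  if (length(ev))
    layout_frame(subject, 1L, 0, ev[1], 1L)
  else
    layout_frame(subject, 1L, 0, subject$censor_time_days, 0L)
}

#' Andersen-Gill counting-process layout
#'
#' Consecutive at-risk intervals `(0,T1], (T1,T2], ..., (Tk, C]`, all in a
#' single stratum; the rows partition the whole follow-up `(0, C]`, and a
#' subject re-enters the common risk set immediately after each event.
#'
#' @param subject a `subject_history`.
#' @return A layout `data.frame` with `events + 1` rows.
#' @export
build_ag <- function(subject) {
  ev <- subject$event_times_days
  brk <- c(0, ev, subject$censor_time_days)
  n <- length(brk) - 1L
  layout_frame(subject, 1L, brk[-length(brk)], brk[-1L],
               c(rep(1L, length(ev)), 0L))
}

#' PWP total-time (conditional) layout
#'
#' Same intervals as [build_ag()] but row j carries stratum j: a subject is
#' only at risk for the j-th event after experiencing the (j-1)-th, and the
#' clock keeps measuring from entry.  Rows beyond `max_stratum` are dropped.
#'
#' @param subject a `subject_history`.
#' @param max_stratum highest event number retained.
#' @return A layout `data.frame`.
#' @export
build_pwp_total <- function(subject, max_stratum = Inf) {
  stopifnot(max_stratum >= 1)
  out <- build_ag(subject)
  out$stratum <- seq_len(nrow(out))
  out[out$stratum <= max_stratum, , drop = FALSE]
}

#' PWP gap-time (conditional) layout
#'
#' Conditional risk sets as in [build_pwp_total()], but the clock resets at
#' every recurrence: row j is `(0, Tj - T(j-1), status)` in stratum j, with
#' a final censored gap `C - Tk`.
#'
#' @param subject a `subject_history`.
#' @param max_stratum highest event number retained.
#' @return A layout `data.frame`.
#' @export
build_pwp_gap <- function(subject, max_stratum = Inf) {
  stopifnot(max_stratum >= 1)
  ev <- subject$event_times_days
  gaps <- diff(c(0, ev, subject$censor_time_days))
  if (any(gaps == 0))
    stop("tied event times give a zero gap; gap-time layout undefined",
         call. = FALSE)
  n <- length(gaps)
  out <- layout_frame(subject, seq_len(n), rep(0, n), gaps,
                      c(rep(1L, length(ev)), 0L))
  out[out$stratum <= max_stratum, , drop = FALSE]
}

#' WLW marginal layout
#'
#' For every event number j up to `max_stratum`, the subject contributes a
#' row `(0, min(Tj, C), 1{Tj observed})` in stratum j; subjects with fewer
#' than j events contribute a censored row `(0, C, 0)`.  Every subject
#' appears in every stratum, so the j-th stratum models the marginal
#' distribution of the time to the j-th event.
#'
#' @param subject a `subject_history`.
#' @param max_stratum number of marginal strata.
#' @return A layout `data.frame` with exactly `max_stratum` rows.
#' @export
build_wlw <- function(subject, max_stratum) {
  stopifnot(is.finite(max_stratum), max_stratum >= 1)
  max_stratum <- as.integer(max_stratum)
  ev <- subject$event_times_days
  tj <- c(ev, rep(Inf, max_stratum))[seq_len(max_stratum)]
  layout_frame(subject, seq_len(max_stratum),
               rep(0, max_stratum),
               pmin(tj, subject$censor_time_days),
               as.integer(tj <= subject$censor_time_days))
}

#' LWA common-baseline marginal layout
#'
#' The same rows as [build_wlw()] but pooled into a single stratum: all
#' event numbers share one baseline hazard, and a subject sits in several
#' risk sets simultaneously.
#'
#' @param subject a `subject_history`.
#' @param max_stratum number of marginal copies per subject.
#' @return A layout `data.frame` with all rows in stratum 1.
#' @export
build_lwa <- function(subject, max_stratum) {
  out <- build_wlw(subject, max_stratum)
  out$stratum <- 1L
  out
}

#' Per-subject event count with person-time exposure
#'
#' @param subject a `subject_history`.
#' @return A one-row `data.frame` with `id`, `interval_index`,
#'   `event_count`, `exposure_days` and covariates.
#' @export
build_poisson <- function(subject) {
  cov <- subject_covariate_row(subject)
  out <- data.frame(id = as.character(subject$id), interval_index = 1L,
                    event_count = length(subject$event_times_days),
                    exposure_days = subject$censor_time_days,
                    stringsAsFactors = FALSE)
  for (nm in names(cov)) out[[nm]] <- cov[[nm]]
  out
}

#' Event counts binned into fixed calendar intervals
#'
#' Splits `(0, C]` into consecutive bins of `interval_days` (6 months =
#' 182.5 days by default), counts the events falling in each bin, and
#' records the overlap of the bin with follow-up as exposure.  Bins with
#' zero exposure are omitted; exposures always sum to `C`.
#'
#' @param subject a `subject_history`.
#' @param interval_days bin width in days.
#' @return A `data.frame` with one row per non-empty bin.
#' @export
build_gee_intervals <- function(subject, interval_days = 182.5) {
  check_scalar_pos(interval_days, "interval_days")
  C <- subject$censor_time_days
  nbin <- ceiling(C / interval_days)
  upper <- pmin(seq_len(nbin) * interval_days, C)
  lower <- (seq_len(nbin) - 1L) * interval_days
  expo <- upper - lower
  keep <- expo > 0
  ev <- subject$event_times_days
  ## events at a bin's upper edge belong to that bin: intervals are (lo, hi]
  counts <- if (length(ev))
    tabulate(findInterval(ev, lower, left.open = TRUE), nbins = nbin)
  else rep(0L, nbin)
  cov <- subject_covariate_row(subject)
  out <- data.frame(id = rep(as.character(subject$id), sum(keep)),
                    interval_index = which(keep),
                    event_count = as.integer(counts[keep]),
                    exposure_days = expo[keep], stringsAsFactors = FALSE)
  for (nm in names(cov)) out[[nm]] <- rep(cov[[nm]], nrow(out))
  out
}

layout_builders <- list(
  first_event = function(s, k) build_first_event(s),
  ag          = function(s, k) build_ag(s),
  pwp_t       = function(s, k) build_pwp_total(s, k),
  pwp_g       = function(s, k) build_pwp_gap(s, k),
  wlw         = function(s, k) build_wlw(s, k),
  lwa         = function(s, k) build_lwa(s, k))

## Column-wise snapshot of a dataset, used by the vectorized dataset-level
## builders (one data.frame per layout instead of one per subject).
dataset_core <- function(dataset) {
  subs <- dataset$subjects
  ev <- lapply(subs, function(s) s$event_times_days)
  covnames <- names(subs[[1]]$covariates)
  cov <- if (length(covnames))
    do.call(rbind, lapply(subs, function(s) s$covariates[covnames]))
  else NULL
  list(id = vapply(subs, function(s) as.character(s$id), character(1)),
       arm = vapply(subs, function(s) s$arm, integer(1)),
       ev = ev, nev = lengths(ev),
       C = vapply(subs, function(s) s$censor_time_days, numeric(1)),
       cov = cov, covnames = covnames)
}

assemble_layout <- function(core, rep_idx, stratum, start, stop, status) {
  out <- data.frame(id = core$id[rep_idx], stratum = as.integer(stratum),
                    start = as.numeric(start), stop = as.numeric(stop),
                    status = as.integer(status), stringsAsFactors = FALSE)
  out$treatment <- as.numeric(core$arm[rep_idx])
  for (nm in core$covnames) out[[nm]] <- core$cov[rep_idx, nm]
  out
}

build_layout_fast <- function(core, model, k) {
  n <- length(core$id)
  if (model == "first_event") {
    has <- core$nev > 0L
    stop <- ifelse(has, vapply(core$ev, function(e) e[1] %||% NA_real_,
                               numeric(1)), core$C)
    return(assemble_layout(core, seq_len(n), 1L, 0, stop, as.integer(has)))
  }
  if (model %in% c("ag", "pwp_t", "pwp_g")) {
    ni <- core$nev + 1L
    rep_idx <- rep.int(seq_len(n), ni)
    status <- rep.int(1L, sum(ni))
    status[cumsum(ni)] <- 0L
    stratum <- if (model == "ag") 1L else sequence(ni)
    if (model == "pwp_g") {
      stop <- unlist(Map(function(e, cc) diff(c(0, e, cc)), core$ev,
                         core$C), use.names = FALSE)
      start <- 0
    } else {
      start <- unlist(Map(function(e, cc) c(0, e), core$ev, core$C),
                      use.names = FALSE)
      stop <- unlist(Map(c, core$ev, core$C), use.names = FALSE)
    }
    out <- assemble_layout(core, rep_idx, stratum, start, stop, status)
    if (model != "ag") out <- out[out$stratum <= k, , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  ## wlw / lwa: k rows per subject, column i of tjm = subject i
  tjm <- vapply(core$ev, function(e)
    c(e, rep.int(Inf, k))[seq_len(k)], numeric(k))
  tj <- as.vector(tjm)
  rep_idx <- rep(seq_len(n), each = k)
  cc <- core$C[rep_idx]
  assemble_layout(core, rep_idx,
                  if (model == "lwa") 1L else rep.int(seq_len(k), n),
                  0, pmin(tj, cc), as.integer(tj <= cc))
}

#' Maximum observed event count in a dataset
#'
#' The default strata cap for the conditional and marginal layouts.
#'
#' @param dataset a `trial_dataset`.
#' @return Integer (at least 1).
#' @export
max_event_count <- function(dataset) {
  max(1L, max(vapply(dataset$subjects,
                     function(s) length(s$event_times_days), integer(1))))
}

#' Build a model layout for a whole dataset
#'
#' @param dataset a `trial_dataset`.
#' @param model one of `"first_event"`, `"ag"`, `"pwp_t"`, `"pwp_g"`,
#'   `"wlw"`, `"lwa"`.
#' @param max_stratum strata cap for the stratified/marginal layouts;
#'   defaults to the maximum observed event count.
#' @return A layout `data.frame` with columns `id`, `stratum`, `start`,
#'   `stop`, `status`, `treatment` and any subject covariates.
#' @export
build_layout <- function(dataset, model = c("first_event", "ag", "pwp_t",
                                            "pwp_g", "wlw", "lwa"),
                         max_stratum = NULL) {
  model <- match.arg(model)
  if (is.null(max_stratum)) max_stratum <- max_event_count(dataset)
  build_layout_fast(dataset_core(dataset), model, max_stratum)
}

#' Build count-model rows for a whole dataset
#'
#' @param dataset a `trial_dataset`.
#' @param type `"subject"` for one row per subject (Poisson regression) or
#'   `"interval"` for 6-month bins (GEE-Poisson).
#' @param interval_days bin width for `type = "interval"`.
#' @return A `data.frame` of count rows.
#' @export
build_counts <- function(dataset, type = c("subject", "interval"),
                         interval_days = 182.5) {
  type <- match.arg(type)
  core <- dataset_core(dataset)
  n <- length(core$id)
  if (type == "subject") {
    out <- data.frame(id = core$id, interval_index = 1L,
                      event_count = core$nev,
                      exposure_days = core$C, stringsAsFactors = FALSE)
    rep_idx <- seq_len(n)
  } else {
    check_scalar_pos(interval_days, "interval_days")
    nbin <- as.integer(ceiling(core$C / interval_days))
    rep_idx <- rep.int(seq_len(n), nbin)
    bin <- sequence(nbin)
    upper <- pmin(bin * interval_days, core$C[rep_idx])
    lower <- (bin - 1) * interval_days
    ## global bin index of each event: events sit in (lo, hi] bins
    offset <- cumsum(c(0L, nbin))
    evsub <- rep.int(seq_len(n), core$nev)
    gbin <- offset[evsub] + ceiling(unlist(core$ev, use.names = FALSE) /
                                      interval_days)
    out <- data.frame(id = core$id[rep_idx], interval_index = bin,
                      event_count = tabulate(gbin, nbins = sum(nbin)),
                      exposure_days = upper - lower,
                      stringsAsFactors = FALSE)
  }
  out$treatment <- as.numeric(core$arm[rep_idx])
  for (nm in core$covnames) out[[nm]] <- core$cov[rep_idx, nm]
  out
}

#' Write a layout to CSV
#'
#' @param layout a layout `data.frame` from [build_layout()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_layout_csv <- function(layout, path) {
  utils::write.csv(layout, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
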