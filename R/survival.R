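# Kaplan-Meier estimation and log-rank comparison of stratified groups.

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator via [survival::survfit()] with
#' log-transformed Greenwood confidence intervals, whose inversion gives
#' the Brookmeyer-Crowley 95% CI for the median.  The median is the
#' smallest time at which the survival function drops to 0.5 or below.
#'
#' @param times Positive survival/censoring times (months).
#' @param events Logical event indicator (`TRUE` = death observed,
#'   `FALSE` = censored).
#' @return An object of class `km_fit`: `curve` (tibble `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`, `lower`, `upper`),
#'   `median`, `median_lower`, `median_upper`, `n`, `n_events`.
#' @export
kaplan_meier <- function(times, events) {
  if (length(times) == 0L) ms1_abort("no survival times supplied")
  if (any(!is.finite(times)) || any(times <= 0)) {
    ms1_abort("survival times must be positive")
  }
  if (length(events) != length(times)) {
    ms1_abort("`events` must match `times` in length")
  }
  events <- as.logical(events)
  fit <- survival::survfit(
    survival::Surv(times, events) ~ 1,
    conf.type = "log", conf.int = 0.95
  )
  tab <- summary(fit)$table
  structure(
    list(
      curve = tibble::tibble(
        time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
        n_censor = fit$n.censor, survival = fit$surv,
        lower = fit$lower, upper = fit$upper
      ),
      median = unname(tab["median"]),
      median_lower = unname(tab["0.95LCL"]),
      median_upper = unname(tab["0.95UCL"]),
      n = length(times), n_events = sum(events)
    ),
    class = "km_fit"
  )
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf(
    "<km_fit> n = %d (%d events); median %.1f months (95%% CI %.1f-%.1f)\n",
    x$n, x$n_events, x$median, x$median_lower, x$median_upper
  ))
  invisible(x)
}

#' @export
tidy.km_fit <- function(x, ...) x$curve

#' @export
glance.km_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events, median = x$median,
    median_lower = x$median_lower, median_upper = x$median_upper
  )
}

#' Log-rank comparison of two survival groups
#'
#' Standard one-degree-of-freedom log-rank test via
#' [survival::survdiff()]: chi-square from observed-minus-expected event
#' counts over the shared risk sets.
#'
#' @param times_a,events_a Times and event indicators for group A.
#' @param times_b,events_b Times and event indicators for group B.
#' @return A list with `chi2` and `p` (from the chi-square distribution
#'   with 1 df).
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (length(times_a) == 0L || length(times_b) == 0L) {
    ms1_abort("both groups must be nonempty")
  }
  events_a <- as.logical(events_a); events_b <- as.logical(events_b)
  if (sum(events_a) + sum(events_b) == 0L) {
    ms1_abort("log-rank test undefined with no observed events")
  }
  times <- c(times_a, times_b)
  if (any(!is.finite(times)) || any(times <= 0)) {
    ms1_abort("survival times must be positive")
  }
  grp <- c(rep("A", length(times_a)), rep("B", length(times_b)))
  sd_fit <- survival::survdiff(
    survival::Surv(times, c(events_a, events_b)) ~ grp
  )
  chi2 <- unname(sd_fit$chisq)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Compare survival between biomarker strata
#'
#' Kaplan-Meier curves per stratum plus the log-rank test between them.
#'
#' @param data Tibble with one row per patient: survival time, event
#'   flag and stratum label.
#' @param time_col,event_col,group_col Column names.
#' @return A list of class `survival_comparison`: `fits` (named list of
#'   `km_fit` per stratum), `medians` (tibble per stratum),
#'   `logrank_chi2`, `logrank_p`.
#' @export
compare_survival <- function(data, time_col = "survival_months",
                             event_col = "event_observed",
                             group_col = "biomarker_status") {
  check_data_frame(data, "data", c(time_col, event_col, group_col))
  groups <- sort(unique(as.character(data[[group_col]])))
  if (length(groups) != 2L) {
    ms1_abort(sprintf("`%s` must define exactly 2 strata, found %d",
                      group_col, length(groups)))
  }
  fits <- lapply(groups, function(g) {
    rows <- data[[group_col]] == g
    kaplan_meier(data[[time_col]][rows], data[[event_col]][rows])
  })
  names(fits) <- groups
  lr <- logrank_test(
    data[[time_col]][data[[group_col]] == groups[1]],
    data[[event_col]][data[[group_col]] == groups[1]],
    data[[time_col]][data[[group_col]] == groups[2]],
    data[[event_col]][data[[group_col]] == groups[2]]
  )
  medians <- dplyr::bind_rows(
    lapply(groups, function(g) {
      dplyr::mutate(glance(fits[[g]]), group = g, .before = 1)
    })
  )
  structure(
    list(fits = fits, medians = medians,
         logrank_chi2 = lr$chi2, logrank_p = lr$p),
    class = "survival_comparison"
  )
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat("<survival_comparison>\n")
  for (i in seq_len(nrow(x$medians))) {
    m <- x$medians[i, ]
    cat(sprintf("  %s: n = %d, median %.1f (95%% CI %.1f-%.1f)\n",
                m$group, m$n, m$median, m$median_lower, m$median_upper))
  }
  cat(sprintf("  log-rank chi2 = %.2f, p = %.4g\n", x$logrank_chi2, x$logrank_p))
  invisible(x)
}

#' @export
tidy.survival_comparison <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$fits), function(g) {
    dplyr::mutate(tidy(x$fits[[g]]), group = g, .before = 1)
  }))
}

#' @export
glance.survival_comparison <- function(x, ...) {
  tibble::tibble(logrank_chi2 = x$logrank_chi2, logrank_p = x$logrank_p)
}
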