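# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

# Brute-force XIC: enumerate every (scan, peak) combination.  The apex
# scan is the one holding the globally best monoisotopic match (max
# intensity, then min |ppm|, then earliest rt); isotopes are re-matched
# exhaustively at that scan.
brute_force_xic <- function(peaks, theoretical_mz, charge, consensus_rt,
                            rt_window_minutes = 5, ppm_tolerance = 3) {
  half <- rt_window_minutes / 2
  inwin <- peaks[abs(peaks$rt_minutes - consensus_rt) <= half, , drop = FALSE]
  if (nrow(inwin) == 0L) return(list(intensity = 0, observed_ppm = NA_real_))
  ppm0 <- (inwin$mz - theoretical_mz) / theoretical_mz * 1e6
  cand <- which(abs(ppm0) <= ppm_tolerance)
  if (length(cand) == 0L) return(list(intensity = 0, observed_ppm = NA_real_))
  best <- cand[order(-inwin$intensity[cand], abs(ppm0[cand]),
                     inwin$rt_minutes[cand])][1]
  apex_rt <- inwin$rt_minutes[best]
  total <- inwin$intensity[best]
  scan <- inwin[inwin$rt_minutes == apex_rt, , drop = FALSE]
  for (k in 1:2) {
    target <- theoretical_mz + k * 1.00335 / charge
    ppmk <- (scan$mz - target) / target * 1e6
    hits <- which(abs(ppmk) <= ppm_tolerance)
    if (length(hits) > 0L) {
      bk <- hits[order(-scan$intensity[hits], abs(ppmk[hits]))][1]
      total <- total + scan$intensity[bk]
    }
  }
  list(intensity = total, observed_ppm = ppm0[best])
}

# Trapezoidal area under the step ROC curve, from the stored points.
trapezoid_auc <- function(curve) {
  ord <- order(1 - curve$specificity, curve$sensitivity)
  x <- (1 - curve$specificity)[ord]
  y <- curve$sensitivity[ord]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# Mean of a normal truncated to [lower, upper], by numeric integration.
truncnorm_mean_numint <- function(mean, sd, lower = -Inf, upper = Inf) {
  mass <- pnorm(upper, mean, sd) - pnorm(lower, mean, sd)
  integrate(function(x) x * dnorm(x, mean, sd),
            lower = max(lower, mean - 12 * sd),
            upper = min(upper, mean + 12 * sd),
            rel.tol = 1e-10)$value / mass
}

# Hand-rolled two-group log-rank chi-square from the risk-set table
# (no ties assumed between groups beyond what table() handles).
logrank_chi2_manual <- function(times_a, times_b) {
  times <- sort(unique(c(times_a, times_b)))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    n_a <- sum(times_a >= t); n_b <- sum(times_b >= t)
    d_a <- sum(times_a == t); d_b <- sum(times_b == t)
    n <- n_a + n_b; d <- d_a + d_b
    if (n == 0 || d == 0) next
    e_a <- d * n_a / n
    o_minus_e <- o_minus_e + (d_a - e_a)
    if (n > 1) v <- v + d * (n_a / n) * (n_b / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}

# Small synthetic cohort used by several files; cached per session.
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_ms_cohort(
        n_good = 3, n_limited = 3, seed = 42,
        truth_args = list(n_proteins = 25, n_bd = 4, n_tid = 3,
                          n_glyco = 3, n_deamidated_nonsequon = 2,
                          n_variant = 2),
        run_args = list(background_peaks_per_run = 100)
      )
    }
    cache
  }
})

# Random peak table resembling one centroided run.
random_peak_table <- function(n_peaks, rt_range = c(0, 60),
                              mz_range = c(400, 1200)) {
  tibble::tibble(
    rt_minutes = runif(n_peaks, rt_range[1], rt_range[2]),
    mz = runif(n_peaks, mz_range[1], mz_range[2]),
    intensity = rlnorm(n_peaks, log(1000), 1)
  )
}
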