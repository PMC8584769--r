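#' Split spike trains into early and late response windows
#'
#' Auditory responses in the deep superior colliculus have an early
#' (< 20 ms) and a late (> 20 ms) component relative to auditory stimulus
#' onset; visual responses only occupy the late window. Spike times are
#' binned into `[0, 20)` ms (early) and `[20, 100]` ms (late) — a spike at
#' exactly 20 ms counts as late — and converted to rates in Hz.
#'
#' @param spikes A data frame of per-trial spike times with columns
#'   `trial` and `time_ms` (ms relative to auditory onset; pass
#'   `onset_ms` to shift).
#' @param n_trials Total number of trials (trials without spikes are
#'   counted as zero-rate trials).
#' @param onset_ms Auditory onset time in the clock of `time_ms`.
#' @param early,late Window bounds in ms (early is half-open on the
#'   right, late is closed).
#' @param trial_end_ms End of the usable trial epoch; windows must fit.
#' @param per_trial Return per-trial rates instead of the summary?
#' @return A tibble with one row per window: `window`, `rate_mean` (Hz),
#'   `rate_sem`, `n_trials`; or per-trial rates when `per_trial = TRUE`.
#' @export
split_windows <- function(spikes, n_trials, onset_ms = 0,
                          early = c(0, 20), late = c(20, 100),
                          trial_end_ms = Inf, per_trial = FALSE) {
  stopifnot(all(c("trial", "time_ms") %in% names(spikes)), n_trials >= 1)
  if (late[2] + onset_ms > trial_end_ms) {
    abort("the late window extends past the end of the trial.",
          class = "scmsi_window_error")
  }
  t <- spikes$time_ms - onset_ms
  count_window <- function(lo, hi, closed_right) {
    sel <- if (closed_right) t >= lo & t <= hi else t >= lo & t < hi
    counts <- table(factor(spikes$trial[sel], levels = seq_len(n_trials)))
    as.numeric(counts)
  }
  widths <- c((early[2] - early[1]) / 1000, (late[2] - late[1]) / 1000)
  rates <- tibble::tibble(
    trial = rep(seq_len(n_trials), 2),
    window = rep(c("early", "late"), each = n_trials),
    rate = c(count_window(early[1], early[2], FALSE) / widths[1],
             count_window(late[1], late[2], TRUE) / widths[2])
  )
  if (per_trial) return(rates)
  rates |>
    dplyr::group_by(.data$window) |>
    dplyr::summarise(rate_mean = mean(.data$rate),
                     rate_sem = sd(.data$rate) / sqrt(dplyr::n()),
                     n_trials = dplyr::n(), .groups = "drop")
}

#' Quasi-Poisson responsiveness test
#'
#' Tests whether a window's evoked spike count exceeds the baseline
#' expectation under an overdispersed Poisson null with variance
#' `theta * mean`. The null is realized as a Poisson distribution when
#' `theta <= 1` and as a moment-matched negative binomial when
#' `theta > 1`; the p-value is the upper-tail probability of the total
#' count over trials.
#'
#' @param total_count Total evoked spike count summed over trials.
#' @param n_trials Number of trials.
#' @param window_s Window length in seconds.
#' @param baseline_rate Baseline firing rate (Hz) measured from
#'   inter-stimulus intervals.
#' @param theta Dispersion factor of the null.
#' @param p_threshold Significance level (default 0.001).
#' @return A one-row tibble: `p_value`, `significant`.
#' @export
responsiveness_test <- function(total_count, n_trials, window_s,
                                baseline_rate, theta = 1,
                                p_threshold = 0.001) {
  stopifnot(total_count >= 0, n_trials >= 1, window_s > 0,
            baseline_rate >= 0, theta > 0)
  mu <- baseline_rate * window_s * n_trials
  p <- if (mu == 0) {
    if (total_count == 0) 1 else 0
  } else if (theta <= 1) {
    ppois(total_count - 1, mu, lower.tail = FALSE)
  } else {
    pnbinom(total_count - 1, size = mu / (theta - 1), mu = mu,
            lower.tail = FALSE)
  }
  tibble::tibble(p_value = p, significant = p < p_threshold)
}

#' Classify intensity tuning as monotonic or non-monotonic
#'
#' A late auditory response is called non-monotonic when some
#' non-maximum-intensity stimulus drives a significantly higher rate than
#' the maximum-intensity stimulus. The test is an omnibus one-way ANOVA
#' across intensity levels followed by one-sided two-sample contrasts of
#' each non-max level against the max level; the neuron is non-monotonic
#' iff any contrast is below `p_threshold` (uncorrected, applied per
#' neuron).
#'
#' @param trials A data frame of per-trial rates with columns `intensity`
#'   and `rate`; at least 3 intensity levels with >= 2 trials each.
#' @param p_threshold Contrast significance level (default 0.001).
#' @return A one-row tibble: `class` (`"monotonic"`/`"non_monotonic"`),
#'   `p_omnibus`, `p_min_contrast`.
#' @export
classify_monotonicity <- function(trials, p_threshold = 0.001) {
  stopifnot(all(c("intensity", "rate") %in% names(trials)))
  lv <- sort(unique(trials$intensity))
  if (length(lv) < 3) abort("need at least 3 intensity levels.")
  n_per <- table(trials$intensity)
  if (any(n_per < 2)) abort("need at least 2 trials per intensity level.")
  fit <- aov(rate ~ factor(intensity), data = trials)
  p_omni <- summary(fit)[[1]][["Pr(>F)"]][1]
  x_max <- trials$rate[trials$intensity == max(lv)]
  p_contrasts <- vapply(lv[-length(lv)], function(l) {
    x <- trials$rate[trials$intensity == l]
    # one-sided pooled-variance t contrast: H1 is rate(l) > rate(max)
    n1 <- length(x); n2 <- length(x_max)
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(x_max)) /
      (n1 + n2 - 2)
    if (sp2 == 0) return(if (mean(x) > mean(x_max)) 0 else 1)
    tstat <- (mean(x) - mean(x_max)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    pt(tstat, df = n1 + n2 - 2, lower.tail = FALSE)
  }, numeric(1))
  tibble::tibble(
    class = if (any(p_contrasts < p_threshold)) "non_monotonic" else "monotonic",
    p_omnibus = p_omni,
    p_min_contrast = min(p_contrasts)
  )
}
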