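# Synthetic fixtures: analytic twitches, calibration ranges, cohorts.

#' Synthetic two-exponential twitch trace
#'
#' Generates an analytic twitch
#' `x(t) = baseline + amp * (exp(-t/tau_decay) - exp(-t/tau_rise)) / c`
#' with the normaliser `c` chosen so the peak equals `amp` above baseline,
#' plus optional Gaussian noise. The two-exponential form has closed-form
#' peak time `t* = log(tau_decay/tau_rise) * tau_rise * tau_decay /
#' (tau_decay - tau_rise)`, recorded in the attributes as ground truth for
#' biomarker tests. The same waveform is written to both the tension and
#' calcium channels (units kPa and uM respectively) so either channel can
#' be tested.
#'
#' @param amp Peak amplitude above baseline (> 0).
#' @param tau_rise,tau_decay Rise and decay time constants, ms
#'   (`tau_rise < tau_decay`).
#' @param baseline Baseline value.
#' @param cycle Trace duration, ms.
#' @param dt Sample spacing, ms.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Optional seed for reproducible noise.
#' @return An `hcm_trace` tibble with attributes `t_peak` (analytic peak
#'   time) and the generator arguments.
#' @examples
#' tr <- synth_twitch(10, 30, 150)
#' attr(tr, "t_peak")
#' @export
synth_twitch <- function(amp, tau_rise, tau_decay, baseline = 0,
                         cycle = 1000, dt = 1, noise_sd = 0, seed = NULL) {
  if (tau_rise >= tau_decay) {
    stop("tau_rise must be smaller than tau_decay", call. = FALSE)
  }
  if (amp <= 0) stop("amp must be > 0", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  t <- seq(0, cycle, by = dt)
  t_peak <- log(tau_decay / tau_rise) * tau_rise * tau_decay /
    (tau_decay - tau_rise)
  shape <- exp(-t / tau_decay) - exp(-t / tau_rise)
  norm <- exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise)
  x <- baseline + amp * shape / norm
  if (noise_sd > 0) x <- x + rnorm(length(t), sd = noise_sd)
  tb <- tibble::tibble(time_ms = t, cai_uM = x, tension_kPa = x)
  structure(tb, class = c("hcm_trace", class(tb)),
            t_peak = t_peak, amp = amp, baseline = baseline,
            tau_rise = tau_rise, tau_decay = tau_decay)
}

#' Calibration ranges from a control population
#'
#' Derives per-biomarker acceptance ranges as percentiles of a simulated
#' control population, standing in for experimental human calibration data.
#' The ranges are synthetic: they bound plausibility relative to the model's
#' own control variability, not measured human physiology.
#'
#' @param control_population A population tibble containing biomarker
#'   columns (see [calibrate_population()]).
#' @param lo_pct,hi_pct Percentile bounds (0-100), `lo_pct < hi_pct` unless
#'   both equal.
#' @param biomarkers Character vector of biomarker columns to bound.
#' @return A `calibration_ranges` tibble with columns `biomarker`, `lo`,
#'   `hi`.
#' @export
synth_calibration_ranges <- function(control_population,
                                     lo_pct = 2.5, hi_pct = 97.5,
                                     biomarkers = c("tension_amp",
                                                    "tension_rt90", "ca_amp",
                                                    "ca_td50", "ca_td95")) {
  if (lo_pct > hi_pct) {
    stop("lo_pct must not exceed hi_pct", call. = FALSE)
  }
  missing_cols <- setdiff(biomarkers, names(control_population))
  if (length(missing_cols)) {
    stop("population lacks biomarker column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(control_population) == 0) {
    stop("empty control population", call. = FALSE)
  }
  rows <- lapply(biomarkers, function(b) {
    v <- control_population[[b]]
    v <- v[is.finite(v)]
    tibble::tibble(biomarker = b,
                   lo = unname(quantile(v, lo_pct / 100)),
                   hi = unname(quantile(v, hi_pct / 100)))
  })
  structure(dplyr::bind_rows(rows),
            class = c("calibration_ranges", class(tibble::tibble())))
}

#' Synthetic grouped biomarker cohorts
#'
#' Gaussian groups with specified mean shifts (in units of `noise_sd`),
#' used to exercise and calibrate the nonparametric statistics layer.
#'
#' @param n_per_group Observations per group (>= 2).
#' @param effect_sizes Numeric vector of group mean shifts in SD units;
#'   one group per element (the first is conventionally 0 = control).
#' @param noise_sd Within-group standard deviation.
#' @param seed Optional seed.
#' @return A tibble with columns `group` (factor) and `value`.
#' @export
synth_cohort <- function(n_per_group, effect_sizes = c(0, 1),
                         noise_sd = 1, seed = NULL) {
  stopifnot(n_per_group >= 2)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  groups <- paste0("g", seq_along(effect_sizes))
  dplyr::bind_rows(lapply(seq_along(effect_sizes), function(i) {
    tibble::tibble(
      group = groups[i],
      value = rnorm(n_per_group, mean = effect_sizes[i] * noise_sd,
                    sd = noise_sd))
  })) %>% mutate(group = factor(.data$group, levels = groups))
}
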