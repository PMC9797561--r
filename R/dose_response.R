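# Mavacamten dose -> myosin availability mapping and its calibration.

#' Dose-response parameters for Mavacamten
#'
#' Mavacamten stabilises the myosin super-relaxed state, shrinking the pool
#' of heads available for crossbridge formation. Its effect is modelled as
#' a Hill inhibition of the DRX:SRX parameter:
#' `R(conc) = R_base * (1 - E_max * conc^h / (conc^h + IC50^h))`.
#'
#' The shipped defaults are calibration products of
#' [calibrate_dose_response()] on this package's control/MYH7 cells (chosen
#' so 0.5 uM approximately restores the MYH7 R403Q availability excess to
#' control), not measured constants.
#'
#' @param E_max Maximal fractional reduction of R, in `[0, 1]`.
#' @param IC50 Half-effect concentration, uM (> 0).
#' @param hill_h Hill coefficient (> 0).
#' @return A `dose_response` object.
#' @export
dose_response_params <- function(E_max = 0.6, IC50 = 0.65, hill_h = 1.8) {
  if (E_max < 0 || E_max > 1) stop("E_max must lie in [0, 1]", call. = FALSE)
  if (IC50 <= 0) stop("IC50 must be > 0", call. = FALSE)
  if (hill_h <= 0) stop("hill_h must be > 0", call. = FALSE)
  structure(list(E_max = E_max, IC50 = IC50, hill_h = hill_h),
            class = "dose_response")
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("<dose_response> E_max = %.3f, IC50 = %.3f uM, h = %.2f\n",
              x$E_max, x$IC50, x$hill_h))
  invisible(x)
}

#' Myosin availability at a Mavacamten concentration
#'
#' @param conc_uM Free drug concentration, uM (>= 0); vectorised.
#' @param dr A `dose_response` object.
#' @param R_base Untreated DRX:SRX parameter (the genotype's R).
#' @return `R` after drug: strictly decreasing in concentration, equal to
#'   `R_base` at 0 and approaching `R_base * (1 - E_max)` at high dose.
#' @examples
#' mavacamten_R(c(0, 0.5, 1), dose_response_params(), R_base = 1.3)
#' @export
mavacamten_R <- function(conc_uM, dr, R_base = 1) {
  if (any(conc_uM < 0)) stop("concentration must be >= 0", call. = FALSE)
  ch <- conc_uM^dr$hill_h
  R_base * (1 - dr$E_max * ch / (ch + dr$IC50^dr$hill_h))
}

#' Mavacamten scaling spec
#'
#' Wraps [mavacamten_R()] as a multiplicative scaling on `R`, so it
#' composes with variant specs (drug applied after genotype remodelling).
#'
#' @inheritParams mavacamten_R
#' @return A `scaling_spec` scaling `R` by `mavacamten_R(conc, dr, 1)`.
#' @export
mavacamten_spec <- function(conc_uM, dr = dose_response_params()) {
  scaling_spec(sprintf("mavacamten:%guM", conc_uM),
               scale = c(R = mavacamten_R(conc_uM, dr, 1)))
}

#' Convert a plasma concentration in ng/ml to uM
#'
#' `conc_uM = conc_ngml / molar_mass * free_fraction` (ng/ml divided by
#' g/mol gives uM). The molar mass and plasma free fraction must be
#' supplied from a compound database; no default is assumed.
#'
#' @param conc_ngml Plasma concentration, ng/ml (>= 0).
#' @param molar_mass Compound molar mass, g/mol (> 0).
#' @param free_fraction Unbound fraction in plasma, in `(0, 1]`.
#' @return Free concentration in uM.
#' @examples
#' ng_per_ml_to_uM(1000, molar_mass = 1000, free_fraction = 1) # 1 uM
#' @export
ng_per_ml_to_uM <- function(conc_ngml, molar_mass, free_fraction) {
  if (missing(molar_mass) || is.null(molar_mass) || !is.numeric(molar_mass) ||
      molar_mass <= 0) {
    stop("molar_mass (g/mol) must be supplied and > 0", call. = FALSE)
  }
  if (any(conc_ngml < 0)) stop("concentration must be >= 0", call. = FALSE)
  if (free_fraction <= 0 || free_fraction > 1) {
    stop("free_fraction must lie in (0, 1]", call. = FALSE)
  }
  conc_ngml / molar_mass * free_fraction
}

# Default simulation-based response: steady-twitch tension amplitude of
# `spec` + drug at `conc`, relative to the untreated scenario.
.sim_amp_ratio <- function(params_base, spec, tol, max_beats) {
  base_ss <- run_to_steady_state(apply_spec(params_base, spec),
                                 tol = tol, max_beats = max_beats)
  base_amp <- extract_biomarkers(base_ss$trace)$tension_amp
  function(conc, dr) {
    p <- apply_spec(params_base, combine_specs(spec, mavacamten_spec(conc, dr)))
    ss <- run_to_steady_state(p, tol = tol, max_beats = max_beats,
                              y0 = base_ss$state)
    extract_biomarkers(ss$trace)$tension_amp / base_amp
  }
}

#' Calibrate the Mavacamten dose-response
#'
#' Least-squares fit of `(E_max, IC50)` (Hill coefficient fixed) so that
#' the predicted steady-twitch tension-amplitude ratios match the supplied
#' target points. The response is simulated by default; a `response_fn`
#' hook (`function(conc, dr) -> amplitude ratio`) allows closed-form
#' responses in tests and fast surrogate calibrations.
#'
#' The optimiser is Nelder-Mead on `(logit E_max, log IC50)` from a fixed
#' start, so the fit is deterministic.
#'
#' @param target_points Data frame with columns `conc_uM` and `amp_ratio`
#'   (>= 2 rows).
#' @param params_base Base `cell_params` (used by the simulated response).
#' @param spec Scenario `scaling_spec` the drug is applied on top of.
#' @param hill_h Fixed Hill coefficient.
#' @param response_fn Optional response hook; defaults to simulation.
#' @param start Starting values for `E_max` and `IC50`.
#' @param tol,max_beats Steady-state settings for the simulated response.
#' @return A `dose_response_fit`: the fitted `dose_response` plus
#'   residuals, convergence flag and the targets. See [tidy.dose_response_fit()].
#' @export
calibrate_dose_response <- function(target_points, params_base = cell_params(),
                                    spec = variant_spec("control"),
                                    hill_h = 1.8, response_fn = NULL,
                                    start = c(E_max = 0.5, IC50 = 0.5),
                                    tol = 1e-6, max_beats = 500) {
  if (!is.data.frame(target_points) || nrow(target_points) < 2) {
    stop("at least 2 target points are required (fit is under-determined)",
         call. = FALSE)
  }
  stopifnot(all(c("conc_uM", "amp_ratio") %in% names(target_points)))
  if (is.null(response_fn)) {
    response_fn <- .sim_amp_ratio(params_base, spec, tol, max_beats)
  }
  obj <- function(theta) {
    dr <- dose_response_params(E_max = stats::plogis(theta[1]),
                               IC50 = exp(theta[2]), hill_h = hill_h)
    pred <- vapply(target_points$conc_uM, response_fn, numeric(1), dr = dr)
    sum((pred - target_points$amp_ratio)^2)
  }
  theta0 <- c(stats::qlogis(start[["E_max"]]), log(start[["IC50"]]))
  fit <- optim(theta0, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-10, maxit = 300))
  dr <- dose_response_params(E_max = stats::plogis(fit$par[1]),
                             IC50 = exp(fit$par[2]), hill_h = hill_h)
  pred <- vapply(target_points$conc_uM, response_fn, numeric(1), dr = dr)
  res <- target_points$amp_ratio - pred
  if (fit$convergence != 0) {
    stop("dose-response calibration did not converge; residuals: ",
         paste(signif(res, 3), collapse = ", "), call. = FALSE)
  }
  structure(list(dr = dr, residuals = res, targets = target_points,
                 value = fit$value, converged = TRUE),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  print(x$dr)
  cat(sprintf("  fit SSE %.3g over %d target points\n",
              x$value, nrow(x$targets)))
  invisible(x)
}

#' Tidy a dose-response fit
#'
#' @param x A `dose_response_fit` from [calibrate_dose_response()].
#' @param ... Unused.
#' @return A tibble with one row per fitted parameter (`term`, `estimate`).
#' @export
tidy.dose_response_fit <- function(x, ...) {
  tibble::tibble(term = c("E_max", "IC50", "hill_h"),
                 estimate = c(x$dr$E_max, x$dr$IC50, x$dr$hill_h),
                 fixed = c(FALSE, FALSE, TRUE))
}

#' Glance at a dose-response fit
#'
#' @inheritParams tidy.dose_response_fit
#' @return A one-row tibble with fit summary statistics.
#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble::tibble(sse = x$value, n_targets = nrow(x$targets),
                 max_abs_residual = max(abs(x$residuals)),
                 converged = x$converged)
}
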