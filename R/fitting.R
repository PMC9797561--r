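# Recovering remodelling scalings from observed traces.

#' Refit parameter scalings from a twitch/calcium trace
#'
#' Least-squares recovery of multiplicative remodelling factors (by default
#' the thin-filament knobs `Ca50` and `k_off_trpn`) from a steady-state
#' twitch: the candidate scalings are applied to the base parameters, the
#' cell is paced to steady state, and the summed squared deviation of the
#' simulated tension and calcium traces from the observed ones (each
#' channel normalised by its observed amplitude) is minimised with
#' Nelder-Mead on the log-scalings. Deterministic for a fixed start.
#'
#' This inversion is what links an observed mutant phenotype back to its
#' underlying sarcomere remodelling, so recovery accuracy on synthetic
#' traces with known scalings is the natural self-check.
#'
#' @param trace Observed `hcm_trace` (one steady-state beat starting at the
#'   stimulus, e.g. from [run_to_steady_state()]).
#' @param params_base Control `cell_params`.
#' @param fit_params Parameter names to recover.
#' @param start Initial scaling guess (default all 1).
#' @param tol,max_beats Steady-state settings per objective evaluation.
#' @param maxit Optimiser iteration cap.
#' @return An `hcm_trace_fit`: `scalings` (named vector), `sse`, `n_eval`,
#'   `converged`.
#' @export
fit_trace_scalings <- function(trace, params_base = cell_params(),
                               fit_params = c("Ca50", "k_off_trpn"),
                               start = NULL, tol = 1e-6, max_beats = 500,
                               maxit = 200) {
  stopifnot(length(fit_params) >= 1)
  if (is.null(start)) start <- setNames(rep(1, length(fit_params)), fit_params)
  t_obs <- trace$time_ms
  amp_t <- diff(range(trace$tension_kPa))
  amp_c <- diff(range(trace$cai_uM))
  if (amp_t <= 0 || amp_c <= 0) {
    stop("trace must contain a non-flat beat on both channels",
         call. = FALSE)
  }
  n_eval <- 0L
  obj <- function(theta) {
    n_eval <<- n_eval + 1L
    sc <- setNames(exp(theta), fit_params)
    p <- scale_params(params_base, sc)
    ss <- tryCatch(
      run_to_steady_state(p, tol = tol, max_beats = max_beats,
                          dt_out = diff(t_obs[1:2])),
      error = function(e) NULL)
    if (is.null(ss)) return(1e6)
    sim <- ss$trace
    ten <- approx(sim$time_ms, sim$tension_kPa, t_obs, rule = 2)$y
    cai <- approx(sim$time_ms, sim$cai_uM, t_obs, rule = 2)$y
    sum(((ten - trace$tension_kPa) / amp_t)^2) +
      sum(((cai - trace$cai_uM) / amp_c)^2)
  }
  fit <- optim(log(start), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-8, maxit = maxit))
  structure(list(scalings = setNames(exp(fit$par), fit_params),
                 sse = fit$value, n_eval = n_eval,
                 converged = fit$convergence == 0),
            class = "hcm_trace_fit")
}

#' @export
print.hcm_trace_fit <- function(x, ...) {
  cat("<hcm_trace_fit>",
      paste(sprintf("%s x%.3f", names(x$scalings), x$scalings),
            collapse = ", "),
      sprintf(" (sse %.3g, %d evaluations)\n", x$sse, x$n_eval))
  invisible(x)
}

#' Tidy a trace-scaling fit
#'
#' @param x An `hcm_trace_fit` from [fit_trace_scalings()].
#' @param ... Unused.
#' @return Tibble with `term` and `estimate` (the recovered scaling).
#' @export
tidy.hcm_trace_fit <- function(x, ...) {
  tibble::tibble(term = names(x$scalings), estimate = unname(x$scalings))
}

#' Glance at a trace-scaling fit
#'
#' @inheritParams tidy.hcm_trace_fit
#' @return One-row tibble with `sse`, `n_eval`, `converged`.
#' @export
glance.hcm_trace_fit <- function(x, ...) {
  tibble::tibble(sse = x$sse, n_eval = x$n_eval, converged = x$converged)
}
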