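# Absolute biomarker-to-parameter sensitivities.

# Default simulation hook: biomarkers of the steady twitch at `params`.
.default_bm_fn <- function(tol = 1e-6, max_beats = 500) {
  function(params) {
    ss <- run_to_steady_state(params, tol = tol, max_beats = max_beats)
    suppressWarnings(extract_biomarkers(ss$trace))
  }
}

#' Absolute sensitivity of one biomarker to one parameter
#'
#' Normalised central difference: the model is evaluated with the parameter
#' scaled by `(1 - delta)` and `(1 + delta)` and the sensitivity is the
#' relative biomarker change per relative parameter change,
#' `S = ((B(1+delta) - B(1-delta)) / B(1)) / (2 delta)`; the absolute value
#' is returned. Unit-free, so sensitivities are comparable across
#' biomarkers. One-sided variants are available for biomarkers undefined on
#' one side.
#'
#' @param params Baseline `cell_params`.
#' @param param_name Parameter to perturb.
#' @param delta Perturbation fraction in (0, 1); conventionally 0.3 for
#'   `Ca50`/`k_ub` and 0.5 for `k_off_trpn`.
#' @param biomarker_name Biomarker column name (see [extract_biomarkers()]).
#' @param bm_fn Hook `function(params) -> one-row biomarker tibble`;
#'   defaults to the steady-twitch simulation. Tests use closed-form stubs.
#' @param side `"central"` (default), `"lower"` or `"upper"`.
#' @return `|S|`, or `NA` (with a warning) if the biomarker is undefined at
#'   an evaluation point.
#' @export
absolute_sensitivity <- function(params, param_name, delta, biomarker_name,
                                 bm_fn = NULL,
                                 side = c("central", "lower", "upper")) {
  stopifnot(delta > 0, delta < 1)
  side <- match.arg(side)
  if (is.null(bm_fn)) bm_fn <- .default_bm_fn()
  ev <- function(f) {
    bm <- bm_fn(scale_params(params, setNames(f, param_name)))
    bm[[biomarker_name]]
  }
  b0 <- ev(1)
  b_lo <- if (side != "upper") ev(1 - delta) else NULL
  b_hi <- if (side != "lower") ev(1 + delta) else NULL
  vals <- c(b0, b_lo, b_hi)
  if (any(!is.finite(vals))) {
    warning("biomarker '", biomarker_name,
            "' undefined at a perturbed point; sensitivity is NA",
            call. = FALSE)
    return(NA_real_)
  }
  S <- switch(side,
    central = (b_hi - b_lo) / b0 / (2 * delta),
    lower = (b0 - b_lo) / b0 / delta,
    upper = (b_hi - b0) / b0 / delta)
  abs(S)
}

#' Sensitivity matrix over parameters and biomarkers
#'
#' Computes [absolute_sensitivity()] for every (parameter, biomarker) pair,
#' either on a single baseline model or across a population of models
#' (each model's own scalings applied to the base parameters), summarised
#' by the median.
#'
#' @param params_base Control `cell_params`.
#' @param param_names Parameters to perturb.
#' @param deltas Single fraction or named vector of per-parameter fractions
#'   (e.g. `c(Ca50 = 0.3, k_off_trpn = 0.5)`).
#' @param biomarker_names Biomarkers to analyse.
#' @param population Optional population tibble (rows = models, scaling
#'   columns as in [lhs_sample()]); `NULL` analyses the baseline model.
#' @param bm_fn Optional biomarker hook passed through.
#' @param tol,max_beats Steady-state settings for the default hook.
#' @return An `hcm_sensitivity` object; see [tidy.hcm_sensitivity()] for
#'   the tidy `(parameter, biomarker, median_abs_S, n_defined)` form.
#' @export
sensitivity_matrix <- function(params_base, param_names, deltas,
                               biomarker_names, population = NULL,
                               bm_fn = NULL, tol = 1e-6, max_beats = 500) {
  stopifnot(length(param_names) >= 1, length(biomarker_names) >= 1)
  if (length(deltas) == 1 && is.null(names(deltas))) {
    deltas <- setNames(rep(deltas, length(param_names)), param_names)
  }
  missing_d <- setdiff(param_names, names(deltas))
  if (length(missing_d)) {
    stop("no delta given for: ", paste(missing_d, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(bm_fn)) bm_fn <- .default_bm_fn(tol, max_beats)
  model_params <- if (is.null(population)) {
    list(params_base)
  } else {
    if (nrow(population) == 0) stop("empty population", call. = FALSE)
    axes <- intersect(names(population), names(params_base))
    lapply(seq_len(nrow(population)), function(i) {
      scale_params(params_base, .row_scalings(population[i, ], axes))
    })
  }
  cells <- purrr::map_dfr(seq_along(model_params), function(m) {
    purrr::map_dfr(param_names, function(pn) {
      purrr::map_dfr(biomarker_names, function(bn) {
        s <- suppressWarnings(absolute_sensitivity(
          model_params[[m]], pn, deltas[[pn]], bn, bm_fn = bm_fn))
        tibble::tibble(model = m, parameter = pn, biomarker = bn, abs_S = s)
      })
    })
  })
  summary <- cells %>%
    group_by(.data$parameter, .data$biomarker) %>%
    summarise(median_abs_S = median(.data$abs_S, na.rm = TRUE),
              n_defined = sum(is.finite(.data$abs_S)), .groups = "drop")
  structure(list(cells = cells, summary = summary, deltas = deltas),
            class = "hcm_sensitivity")
}

#' @export
print.hcm_sensitivity <- function(x, ...) {
  cat("<hcm_sensitivity> median |S| over",
      max(x$cells$model), "model(s)\n")
  print(x$summary)
  invisible(x)
}

#' Tidy a sensitivity result
#'
#' @param x An `hcm_sensitivity` from [sensitivity_matrix()].
#' @param ... Unused.
#' @return Tibble `(parameter, biomarker, median_abs_S, n_defined)`.
#' @export
tidy.hcm_sensitivity <- function(x, ...) x$summary

#' Glance at a sensitivity result
#'
#' @inheritParams tidy.hcm_sensitivity
#' @return One-row tibble with analysis dimensions.
#' @export
glance.hcm_sensitivity <- function(x, ...) {
  tibble::tibble(n_models = max(x$cells$model),
                 n_parameters = length(unique(x$cells$parameter)),
                 n_biomarkers = length(unique(x$cells$biomarker)),
                 n_missing = sum(!is.finite(x$cells$abs_S)))
}
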