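# Cell parameter container and multiplicative scaling.

# Canonical parameter order shared with the compiled derivative code
# (src/cellmodel.c). Do not reorder without updating the enum there.
.hcm_par_names <- c(
  "Ca50", "n_trpn", "k_on_trpn", "k_off_trpn", "n_tm", "k_bu", "k_ub",
  "trpn_cap", "k_uw", "k_wu", "k_ws", "k_su", "T_ref", "rho0", "R",
  "gamma_fb", "fb_mode_code", "fb_lo", "fb_hi", "ctrl_ws_peak", "r_on_tref",
  "g_amp", "tau_rel", "k_rel", "V_serca", "K_serca", "h_serca",
  "k_ncx", "Ca_dia", "A_in", "d_in", "vr", "B_cmdn", "K_cmdn", "TRPN_tot",
  "lcc_scale", "serca_scale", "ncx_scale", "inal_block", "alpha_nal", "cl"
)

.fb_modes <- c(off = 0, static = 1, dynamic = 2)

#' Default cardiomyocyte model parameters
#'
#' Builds the full parameter set for the coupled myofilament /
#' calcium-handling twitch model: troponin calcium binding, tropomyosin
#' blocked-unblocked switching, a four-state crossbridge cycle scaled by
#' myosin DRX availability, and a reduced intracellular calcium subsystem
#' (SR release, SERCA reuptake, extrusion, trigger influx, fast buffering).
#'
#' Defaults are calibration values chosen so that the control cell, paced at
#' 1 Hz, produces a physiological human twitch: diastolic calcium near
#' 0.1 uM, calcium-transient amplitude in the 0.3-0.7 uM range, and tension
#' relaxation on the few-hundred-millisecond scale.
#'
#' @param ... Named overrides of any default, e.g. `cell_params(R = 1.3)`.
#'   `fb_mode` takes one of `"off"`, `"static"`, `"dynamic"`.
#'
#' @return An object of class `cell_params`: a named list with fields
#'   documented below.
#'
#' @section Myofilament fields:
#' \describe{
#'   \item{Ca50}{calcium concentration at half-maximal thin-filament
#'     activation, uM. Lower = more sensitive.}
#'   \item{n_trpn}{Hill coefficient of troponin calcium binding.}
#'   \item{k_on_trpn, k_off_trpn}{troponin binding/dissociation rate
#'     constants, 1/ms. `k_off_trpn` is the "k_off" remodelling knob.}
#'   \item{n_tm}{tropomyosin cooperativity exponent.}
#'   \item{k_bu, k_ub}{blocked->unblocked and unblocked->blocked base rates,
#'     1/ms. Scaling `k_ub` rescales the blocked/unblocked equilibrium (the
#'     "K_B" knob).}
#'   \item{trpn_cap}{upper cap on the CaTRPN^(-n_tm/2) factor.}
#'   \item{k_uw, k_wu, k_ws, k_su}{crossbridge cycling rates, 1/ms.}
#'   \item{T_ref}{reference maximal tension, kPa.}
#'   \item{rho0}{control DRX:SRX odds (DRX fraction / SRX fraction).}
#'   \item{R}{DRX:SRX odds relative to control; R > 1 = more available
#'     myosin heads.}
#'   \item{gamma_fb, fb_mode, fb_lo, fb_hi}{myosin-to-thin-filament feedback
#'     gain, form (`off`/`static`/`dynamic`) and clip bounds on the Ca50
#'     scaling factor.}
#'   \item{ctrl_ws_peak}{control reference crossbridge occupancy for the
#'     dynamic feedback form.}
#'   \item{r_on_tref}{if `TRUE`, availability scales `T_ref` instead of the
#'     attachment rate `k_uw`.}
#' }
#'
#' @section Calcium-handling fields:
#' \describe{
#'   \item{g_amp, tau_rel, k_rel}{release-gate increment per stimulus, gate
#'     decay time constant (ms) and release rate constant (1/ms).}
#'   \item{V_serca, K_serca, h_serca}{SERCA maximal rate (uM/ms),
#'     half-saturation (uM) and Hill coefficient.}
#'   \item{k_ncx, Ca_dia}{extrusion rate constant (1/ms) towards the target
#'     diastolic calcium (uM).}
#'   \item{A_in, d_in}{trigger influx amplitude (uM/ms) and duration (ms).}
#'   \item{vr}{cytosol-to-SR volume ratio.}
#'   \item{B_cmdn, K_cmdn}{fast-buffer capacity and affinity, uM.}
#'   \item{TRPN_tot}{troponin buffer capacity, uM.}
#'   \item{lcc_scale, serca_scale, ncx_scale}{multiplicative intervention
#'     scalings on trigger influx, SERCA and extrusion.}
#'   \item{inal_block, alpha_nal}{late-sodium block fraction in [0,1] and
#'     the coupling gain mapping it to enhanced extrusion.}
#' }
#'
#' @section Protocol fields:
#' \describe{
#'   \item{cl}{pacing cycle length, ms (default 1000 = 1 Hz).}
#'   \item{rtol, atol, max_step}{solver tolerances and maximal step (ms).}
#' }
#'
#' @examples
#' p <- cell_params(R = 1.3, fb_mode = "static")
#' p$R
#' @export
cell_params <- function(...) {
  p <- list(
    # myofilament
    Ca50 = 0.8, n_trpn = 2, k_on_trpn = 0.1, k_off_trpn = 0.1,
    n_tm = 2.2, k_bu = 0.18, k_ub = 0.02, trpn_cap = 100,
    k_uw = 0.15, k_wu = 0.2, k_ws = 0.015, k_su = 0.012,
    T_ref = 120, rho0 = 1, R = 1,
    gamma_fb = 0.5, fb_mode = "off", fb_lo = 0.5, fb_hi = 1.5,
    ctrl_ws_peak = 0.2, r_on_tref = FALSE,
    # calcium handling
    g_amp = 1, tau_rel = 25, k_rel = 0.008,
    V_serca = 0.4, K_serca = 0.5, h_serca = 3,
    k_ncx = 0.04, Ca_dia = 0.1, A_in = 0.04, d_in = 100,
    vr = 15, B_cmdn = 50, K_cmdn = 2.38, TRPN_tot = 70,
    lcc_scale = 1, serca_scale = 1, ncx_scale = 1,
    inal_block = 0, alpha_nal = 0.3,
    # protocol / solver
    cl = 1000, rtol = 1e-8, atol = 1e-10, max_step = 10
  )
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("all arguments to cell_params() must be named", call. = FALSE)
    }
    unknown <- setdiff(names(dots), names(p))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  p <- structure(p, class = "cell_params")
  validate_params(p)
  p
}

#' Validate a cell parameter set
#'
#' Checks positivity, range and mode invariants. Called by [cell_params()]
#' and after every scaling application.
#'
#' @param p A `cell_params` object.
#' @return `p`, invisibly, if valid; otherwise an error.
#' @export
validate_params <- function(p) {
  pos <- c("Ca50", "k_on_trpn", "k_off_trpn", "k_bu", "k_ub",
           "k_uw", "k_wu", "k_ws", "k_su", "T_ref", "rho0", "R",
           "tau_rel", "cl", "rtol", "atol", "max_step")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] <= 0) {
      stop(nm, " must be a strictly positive scalar", call. = FALSE)
    }
  }
  nonneg <- c("n_tm", "g_amp", "k_rel", "V_serca", "K_serca", "h_serca",
              "k_ncx", "Ca_dia", "A_in", "d_in", "vr", "B_cmdn", "K_cmdn",
              "TRPN_tot", "gamma_fb", "ctrl_ws_peak")
  for (nm in nonneg) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] < 0) {
      stop(nm, " must be a non-negative scalar", call. = FALSE)
    }
  }
  for (nm in c("lcc_scale", "serca_scale", "ncx_scale")) {
    if (p[[nm]] <= 0) stop(nm, " must be > 0", call. = FALSE)
  }
  if (p$n_trpn < 1) stop("n_trpn must be >= 1", call. = FALSE)
  if (p$trpn_cap < 1) stop("trpn_cap must be >= 1", call. = FALSE)
  if (p$inal_block < 0 || p$inal_block > 1) {
    stop("inal_block must lie in [0, 1]", call. = FALSE)
  }
  if (!p$fb_mode %in% names(.fb_modes)) {
    stop("fb_mode must be one of ", paste(names(.fb_modes), collapse = ", "),
         call. = FALSE)
  }
  if (p$fb_lo < 0.1 || p$fb_hi > 10 || p$fb_lo > p$fb_hi) {
    stop("fb bounds must satisfy 0.1 <= fb_lo <= fb_hi <= 10", call. = FALSE)
  }
  invisible(p)
}

# Flatten to the numeric vector consumed by the compiled derivatives.
param_vector <- function(p) {
  v <- vapply(.hcm_par_names, function(nm) {
    switch(nm,
      fb_mode_code = unname(.fb_modes[p$fb_mode]),
      r_on_tref = as.numeric(isTRUE(p$r_on_tref)),
      as.numeric(p[[nm]])
    )
  }, numeric(1))
  names(v) <- .hcm_par_names
  v
}

#' Apply multiplicative parameter scalings
#'
#' Multiplies named parameters of a `cell_params` object by the given
#' factors. Scalings compose: applying `a` then `b` equals applying the
#' elementwise product `a * b`.
#'
#' @param params A `cell_params` object.
#' @param scalings Named numeric vector of strictly positive multiplicative
#'   factors; names must be parameter fields.
#' @return The scaled, re-validated `cell_params` object.
#' @examples
#' p <- cell_params() |> scale_params(c(Ca50 = 0.7, k_ub = 0.8))
#' p$Ca50
#' @export
scale_params <- function(params, scalings) {
  if (length(scalings) == 0) return(params)
  if (is.null(names(scalings)) || any(names(scalings) == "")) {
    stop("scalings must be a named numeric vector", call. = FALSE)
  }
  unknown <- setdiff(names(scalings), names(params))
  if (length(unknown)) {
    stop("unknown parameter(s) in scalings: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(scalings <= 0)) stop("scaling factors must be > 0", call. = FALSE)
  for (nm in names(scalings)) {
    params[[nm]] <- params[[nm]] * scalings[[nm]]
  }
  validate_params(params)
  params
}

#' @export
print.cell_params <- function(x, ...) {
  cat("<cell_params>\n")
  cat("  R (DRX:SRX vs control):", x$R,
      " feedback:", x$fb_mode, "\n")
  cat("  Ca50:", x$Ca50, "uM  k_off_trpn:", x$k_off_trpn,
      "/ms  k_ub:", x$k_ub, "/ms\n")
  cat("  pacing:", x$cl, "ms cycle length\n")
  invisible(x)
}

#' Convert a parameter set to a one-row tibble
#'
#' @param x A `cell_params` object.
#' @param ... Unused.
#' @return A one-row tibble with one column per parameter.
#' @export
as_tibble.cell_params <- function(x, ...) {
  tibble::as_tibble(lapply(unclass(x), identity))
}
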