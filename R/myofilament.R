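# Myofilament operations: DRX availability, feedback, derivatives, tension.

#' Fraction of myosin heads in the DRX state
#'
#' Myosin heads partition between the super-relaxed state (SRX, unavailable
#' for actin binding) and the disordered relaxed state (DRX, available to
#' form crossbridges). `R` rescales the control DRX:SRX odds `rho0`, so the
#' DRX fraction is `R * rho0 / (1 + R * rho0)`.
#'
#' @param R DRX:SRX odds relative to control (> 0); R > 1 means SRX
#'   destabilisation (more available heads).
#' @param rho0 Control DRX:SRX odds (> 0).
#' @return DRX head fraction in (0, 1), strictly increasing in `R`.
#' @examples
#' drx_fraction(1, 1)    # 0.5 at control 1:1 odds
#' drx_fraction(1.3, 1)  # the MYH7 R403Q value
#' @export
drx_fraction <- function(R, rho0) {
  if (any(!is.finite(R)) || any(R <= 0)) stop("R must be > 0", call. = FALSE)
  if (any(!is.finite(rho0)) || any(rho0 <= 0)) {
    stop("rho0 must be > 0", call. = FALSE)
  }
  R * rho0 / (1 + R * rho0)
}

#' Crossbridge availability multiplier
#'
#' The DRX fraction normalised to its control value; multiplies the
#' crossbridge attachment rate `k_uw` in the model derivatives (or `T_ref`
#' when `r_on_tref` is set). Equals 1 at `R = 1`.
#'
#' @inheritParams drx_fraction
#' @return Dimensionless multiplier, strictly increasing in `R`.
#' @export
availability_scale <- function(R, rho0) {
  drx_fraction(R, rho0) / drx_fraction(1, rho0)
}

#' Effective thin-filament calcium sensitivity
#'
#' Applies the myosin-to-thin-filament feedback to `Ca50`. With
#' `fb_mode = "off"` the stored `Ca50` is returned unchanged. With
#' `fb_mode = "static"` the scaling factor is `1 - gamma_fb * (R - 1)`,
#' clipped to `[fb_lo, fb_hi]`: excess available myosin (R > 1) sensitises
#' the thin filament (smaller effective Ca50). The `"dynamic"` form drives
#' the factor with instantaneous crossbridge occupancy `(W + S)` relative to
#' the configured control reference `ctrl_ws_peak`.
#'
#' @param params A `cell_params` object.
#' @param state Optional named state vector (needs `W` and `S` for the
#'   dynamic form).
#' @return Effective Ca50 in uM. Smaller = more calcium sensitive.
#' @export
ca50_effective <- function(params, state = NULL) {
  fb <- switch(params$fb_mode,
    off = 1,
    static = 1 - params$gamma_fb * (params$R - 1),
    dynamic = {
      if (is.null(state)) {
        stop("dynamic feedback requires a state with W and S", call. = FALSE)
      }
      1 - params$gamma_fb * (state[["W"]] + state[["S"]]) / params$ctrl_ws_peak
    }
  )
  params$Ca50 * min(max(fb, params$fb_lo), params$fb_hi)
}

#' Myofilament state derivatives
#'
#' Reference implementation of the four-state activation model: Hill-type
#' troponin calcium binding, tropomyosin blocked/unblocked switching with
#' cooperativity driven by troponin occupancy, and weak/strong crossbridge
#' cycling with DRX-availability-scaled attachment. The compiled solver core
#' evaluates the same equations; this function is the documented form used
#' for closed-form checks.
#'
#' @param state Named numeric vector with `CaTRPN`, `B`, `W`, `S`
#'   (the unblocked, non-crossbridge fraction `U = 1 - B - W - S` is
#'   implicit).
#' @param Cai Free cytosolic calcium, uM (>= 0).
#' @param params A `cell_params` object.
#' @return Named numeric vector of time derivatives (1/ms) for
#'   `CaTRPN`, `B`, `W`, `S`.
#' @export
myofilament_derivatives <- function(state, Cai, params) {
  if (!is.finite(Cai) || Cai < 0) stop("Cai must be >= 0", call. = FALSE)
  CaTRPN <- min(max(state[["CaTRPN"]], 1e-12), 1)
  B <- state[["B"]]; W <- state[["W"]]; S <- state[["S"]]
  U <- 1 - B - W - S

  ca50 <- ca50_effective(params, state)
  x <- (Cai / ca50)^params$n_trpn
  dCaTRPN <- params$k_on_trpn * x * (1 - CaTRPN) - params$k_off_trpn * CaTRPN

  half <- params$n_tm / 2
  gain <- min(CaTRPN^(-half), params$trpn_cap)
  dB <- params$k_ub * gain * U - params$k_bu * CaTRPN^half * B

  k_uw_eff <- params$k_uw *
    if (isTRUE(params$r_on_tref)) 1 else availability_scale(params$R, params$rho0)
  dW <- k_uw_eff * U - (params$k_wu + params$k_ws) * W
  dS <- params$k_ws * W - params$k_su * S

  c(CaTRPN = dCaTRPN, B = dB, W = dW, S = dS)
}

#' Active tension from state
#'
#' Isometric output map at fixed extension ratio: `T_a = T_ref * S`
#' (scaled additionally by the availability multiplier when `r_on_tref`
#' routes DRX availability through `T_ref`).
#'
#' @param state Named state vector with `S`.
#' @param params A `cell_params` object.
#' @return Active tension, kPa (>= 0).
#' @export
active_tension <- function(state, params) {
  tsc <- if (isTRUE(params$r_on_tref)) {
    availability_scale(params$R, params$rho0)
  } else 1
  params$T_ref * tsc * max(state[["S"]], 0)
}

#' Troponin calcium buffering flux
#'
#' Net flux of calcium onto troponin, `J_trpn = TRPN_tot * dCaTRPN/dt`
#' (uM/ms, positive = calcium leaving the free cytosolic pool). This
#' bidirectional coupling is what lets `k_off_trpn` remodelling reshape the
#' calcium transient.
#'
#' @inheritParams myofilament_derivatives
#' @return Flux in uM/ms.
#' @export
troponin_flux <- function(state, Cai, params) {
  d <- myofilament_derivatives(state, Cai, params)
  params$TRPN_tot * d[["CaTRPN"]]
}
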