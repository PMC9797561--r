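# Reduced intracellular calcium-handling subsystem.

#' Instantaneous fast-buffer factor
#'
#' Rapid-buffering approximation for calmodulin-like fast buffers:
#' `beta(Cai) = 1 / (1 + B_cmdn * K_cmdn / (K_cmdn + Cai)^2)`. Multiplies
#' every free-calcium flux; approaches 1 as the buffer empties
#' (`B_cmdn -> 0`) or saturates (`Cai -> Inf`).
#'
#' @param Cai Free cytosolic calcium, uM (>= 0).
#' @param params A `cell_params` object (uses `B_cmdn`, `K_cmdn`).
#' @return Factor in (0, 1], strictly increasing in `Cai`.
#' @export
fast_buffer_factor <- function(Cai, params) {
  if (any(Cai < 0)) stop("Cai must be >= 0", call. = FALSE)
  1 / (1 + params$B_cmdn * params$K_cmdn / (params$K_cmdn + Cai)^2)
}

#' Calcium subsystem fluxes
#'
#' Evaluates the four calcium fluxes at a given state: SR release
#' (`J_rel = k_rel * g * Ca_sr`), SERCA reuptake (Hill kinetics scaled by
#' `serca_scale`), extrusion towards diastolic calcium (scaled by
#' `ncx_scale` and enhanced by late-sodium block), and the square-pulse
#' trigger influx active for `d_in` ms after each stimulus (scaled by
#' `lcc_scale`).
#'
#' @param state Named vector with `Cai`, `Ca_sr`, `g`.
#' @param t_since_stim Time since the last stimulus, ms (>= 0).
#' @param params A `cell_params` object.
#' @return Named numeric vector `J_rel`, `J_serca`, `J_ncx`, `J_in`
#'   (uM/ms).
#' @export
calcium_fluxes <- function(state, t_since_stim, params) {
  Cai <- max(state[["Cai"]], 0)
  cah <- Cai^params$h_serca
  c(
    J_rel = params$k_rel * state[["g"]] * max(state[["Ca_sr"]], 0),
    J_serca = params$serca_scale * params$V_serca * cah /
      (cah + params$K_serca^params$h_serca),
    J_ncx = params$ncx_scale * (1 + params$alpha_nal * params$inal_block) *
      params$k_ncx * (Cai - params$Ca_dia),
    J_in = if (t_since_stim < params$d_in) params$lcc_scale * params$A_in else 0
  )
}

#' Calcium state derivatives
#'
#' Reference implementation of the reduced calcium subsystem:
#' `dCai/dt = beta(Cai) * (J_in + J_rel - J_serca - J_ncx - J_trpn)`,
#' `dCa_sr/dt = vr * (J_serca - J_rel)` and first-order release-gate decay
#' `dg/dt = -g / tau_rel`. The gate is incremented by `g_amp` at each
#' stimulus instant by the simulator, not here.
#'
#' @param state Named vector with `Cai`, `Ca_sr`, `g`.
#' @param J_trpn Troponin buffering flux, uM/ms (positive = calcium leaving
#'   the free pool); see [troponin_flux()].
#' @param t_since_stim Time since the last stimulus, ms (>= 0).
#' @param params A `cell_params` object.
#' @return Named numeric vector of derivatives for `Cai` (uM/ms),
#'   `Ca_sr` (uM/ms) and `g` (1/ms).
#' @export
calcium_derivatives <- function(state, J_trpn, t_since_stim, params) {
  if (t_since_stim < 0) stop("t_since_stim must be >= 0", call. = FALSE)
  J <- calcium_fluxes(state, t_since_stim, params)
  beta <- fast_buffer_factor(max(state[["Cai"]], 0), params)
  c(
    Cai = unname(beta * (J[["J_in"]] + J[["J_rel"]] - J[["J_serca"]] -
                           J[["J_ncx"]] - J_trpn)),
    Ca_sr = unname(params$vr * (J[["J_serca"]] - J[["J_rel"]])),
    g = unname(-state[["g"]] / params$tau_rel)
  )
}

#' Total calcium content of the closed system
#'
#' Free cytosolic calcium plus fast-buffered, troponin-bound and SR
#' contributions (SR divided by the volume ratio). Conserved exactly when
#' the cell is closed (`A_in = 0`, `k_ncx = 0`); used to monitor
#' integration accuracy.
#'
#' @param state Named vector with `Cai`, `Ca_sr`, `g`, `CaTRPN`.
#' @param params A `cell_params` object.
#' @return Total calcium, uM (cytosolic reference volume).
#' @export
total_calcium <- function(state, params) {
  Cai <- state[["Cai"]]
  buffered <- params$B_cmdn * Cai / (params$K_cmdn + Cai)
  unname(Cai + buffered + params$TRPN_tot * state[["CaTRPN"]] +
           state[["Ca_sr"]] / params$vr)
}
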