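test_that("DRX fraction follows the odds algebra and is monotone in R", {
  expect_equal(drx_fraction(1, 1), 0.5)
  expect_equal(drx_fraction(1.3, 1), 1.3 / 2.3)
  expect_equal(drx_fraction(1e9, 1), 1, tolerance = 1e-8)
  f <- drx_fraction(seq(0.2, 3, by = 0.2), 1)
  expect_true(all(diff(f) > 0))
  expect_true(all(f > 0 & f < 1))
  expect_error(drx_fraction(0, 1), "R must be > 0")
  expect_error(drx_fraction(1, -2), "rho0 must be > 0")
})

test_that("availability scale is the control-normalised DRX fraction", {
  expect_equal(availability_scale(1, 1), 1)
  expect_equal(availability_scale(1.3, 1), (1.3 / 2.3) / 0.5)
  expect_equal(availability_scale(0.5, 1), (1 / 3) / 0.5)
  # normalisation holds for asymmetric control odds too
  expect_equal(availability_scale(1, 0.4), 1)
  expect_true(availability_scale(2, 0.4) > 1)
})

test_that("effective Ca50 applies the static feedback with clipping", {
  p <- cell_params(Ca50 = 0.8)
  expect_equal(ca50_effective(p), 0.8)
  p <- cell_params(Ca50 = 0.8, fb_mode = "static", gamma_fb = 0.7)
  expect_equal(ca50_effective(p), 0.8) # R = 1 deactivates feedback
  p <- cell_params(Ca50 = 0.8, fb_mode = "static", gamma_fb = 0.5, R = 1.3)
  expect_equal(ca50_effective(p), 0.8 * (1 - 0.15))
  # strong gain hits the lower clip bound
  p <- cell_params(Ca50 = 0.8, fb_mode = "static", gamma_fb = 5, R = 1.3,
                   fb_lo = 0.5, fb_hi = 1.5)
  expect_equal(ca50_effective(p), 0.8 * 0.5)
  # dynamic form needs a state
  p <- cell_params(fb_mode = "dynamic")
  expect_error(ca50_effective(p), "requires a state")
  st <- c(CaTRPN = 0.1, B = 0.8, W = 0.05, S = 0.05)
  expect_equal(ca50_effective(p, st),
               p$Ca50 * max(1 - p$gamma_fb * 0.1 / p$ctrl_ws_peak, p$fb_lo))
})

test_that("troponin occupancy has the closed-form steady state x/(1+x)", {
  p <- cell_params(k_on_trpn = 0.1, k_off_trpn = 0.1)
  for (cai in c(0.2, 0.8, 1.5)) {
    x <- (cai / p$Ca50)^p$n_trpn
    st <- c(CaTRPN = x / (1 + x), B = 0.9, W = 0.05, S = 0.03)
    d <- myofilament_derivatives(st, cai, p)
    expect_equal(d[["CaTRPN"]], 0, tolerance = 1e-12)
  }
  # at Cai = Ca50 with equal rates the equilibrium is exactly one half
  st <- c(CaTRPN = 0.5, B = 0.9, W = 0.05, S = 0.03)
  expect_equal(myofilament_derivatives(st, p$Ca50, p)[["CaTRPN"]], 0)
})

test_that("zero calcium drives troponin off and tropomyosin to blocked", {
  p <- cell_params()
  # start well below the blocked equilibrium for this occupancy
  st <- c(CaTRPN = 0.3, B = 0.2, W = 0.1, S = 0.1)
  d <- myofilament_derivatives(st, 0, p)
  expect_equal(d[["CaTRPN"]], -p$k_off_trpn * 0.3)
  expect_true(d[["B"]] > 0)
})

test_that("blocked/unblocked equilibrium matches the closed form", {
  # crossbridge cycling frozen; troponin held at its own steady state so
  # CaTRPN stays constant while B relaxes
  p <- cell_params(k_uw = 1e-12, k_wu = 1e-12, k_ws = 1e-12, k_su = 1e-12)
  cai <- 0.5
  x <- (cai / p$Ca50)^p$n_trpn
  ctrpn <- x / (1 + x)
  rhs <- function(t, y, parms) {
    list(myofilament_derivatives(y, cai, p))
  }
  y0 <- c(CaTRPN = ctrpn, B = 0.5, W = 0, S = 0)
  out <- deSolve::lsoda(y0, c(0, 5000), rhs, rtol = 1e-10, atol = 1e-12)
  B <- out[2, "B"]; U <- 1 - B
  ratio_expected <- p$k_ub * min(ctrpn^(-p$n_tm / 2), p$trpn_cap) /
    (p$k_bu * ctrpn^(p$n_tm / 2))
  expect_equal(unname(B / U), ratio_expected, tolerance = 1e-6)
})

test_that("active tension is linear in T_ref and strong fraction", {
  p <- cell_params(T_ref = 120)
  expect_equal(active_tension(c(S = 0), p), 0)
  expect_equal(active_tension(c(S = 0.1), p), 12)
  p2 <- cell_params(T_ref = 240)
  expect_equal(active_tension(c(S = 0.1), p2),
               2 * active_tension(c(S = 0.1), p))
})

test_that("troponin flux tracks occupancy kinetics", {
  p <- cell_params()
  cai <- 0.5
  x <- (cai / p$Ca50)^p$n_trpn
  st_eq <- c(CaTRPN = x / (1 + x), B = 0.9, W = 0.05, S = 0.03)
  expect_equal(troponin_flux(st_eq, cai, p), 0, tolerance = 1e-10)
  # decaying phase: occupancy above equilibrium releases calcium
  st <- c(CaTRPN = 0.8, B = 0.9, W = 0.05, S = 0.03)
  j_full <- troponin_flux(st, 0.1, p)
  expect_lt(j_full, 0)
  p_half <- cell_params(k_off_trpn = p$k_off_trpn * 0.5)
  j_half <- troponin_flux(st, 0.1, p_half)
  expect_lt(abs(j_half), abs(j_full))
  expect_equal(sign(j_half), sign(j_full))
})

test_that("compiled solver core agrees with the R reference derivatives", {
  p <- cell_params(rtol = 1e-10, atol = 1e-12)
  tr_c <- simulate_beats(p, n_beats = 2, record_last = 2, dt_out = 5,
                         full_state = TRUE)
  y0 <- hcmtwitch:::.initial_state(p)
  y0[["g"]] <- y0[["g"]] + p$g_amp
  out_r <- deSolve::lsoda(y0, seq(0, 2 * p$cl, by = 5), r_reference_rhs(p),
                          rtol = 1e-10, atol = 1e-12, hmax = p$max_step,
                          events = list(data = data.frame(
                            var = 3, time = p$cl, value = p$g_amp,
                            method = "add")))
  expect_equal(tr_c$cai_uM, unname(out_r[, "Cai"]), tolerance = 1e-6)
  expect_equal(tr_c$CaTRPN, unname(out_r[, "CaTRPN"]), tolerance = 1e-6)
  expect_equal(tr_c$S, unname(out_r[, "S"]), tolerance = 1e-6)
})

test_that("occupancy fractions stay within [0,1] and sum below one", {
  tr <- simulate_beats(cell_params(), n_beats = 3, record_last = 3,
                       full_state = TRUE)
  occ <- tr$B + tr$W + tr$S
  expect_true(all(tr$B >= -1e-9 & tr$W >= -1e-9 & tr$S >= -1e-9))
  expect_true(all(occ <= 1 + 1e-9))
})
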