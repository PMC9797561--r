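half_sine_trace <- function(A = 10, L = 300, dt = 0.1) {
  t <- seq(0, L, by = dt)
  x <- A * sin(pi * t / L)
  tibble::tibble(time_ms = t, cai_uM = x, tension_kPa = x)
}

test_that("half-sine twitch biomarkers match the closed form", {
  tr <- half_sine_trace()
  b <- extract_biomarkers(tr)
  expect_equal(b$tension_amp, 10, tolerance = 1e-6)
  expect_equal(b$tension_ttp, 150, tolerance = 0.1)
  expect_equal(b$tension_rt90, 300 * (0.5 - asin(0.1) / pi), tolerance = 0.1)
  expect_equal(b$tension_rt50, 300 * (0.5 - asin(0.5) / pi), tolerance = 0.1)
  expect_equal(b$ca_td50, 300 * (1 - asin(0.5) / pi), tolerance = 0.1)
})

test_that("a flat trace yields zero amplitude and undefined times", {
  tr <- tibble::tibble(time_ms = 0:100, cai_uM = 0.1, tension_kPa = 2)
  b <- extract_biomarkers(tr)
  expect_equal(b$tension_amp, 0)
  expect_equal(b$ca_amp, 0)
  expect_true(is.na(b$tension_rt90))
  expect_true(is.na(b$ca_ttp))
  expect_equal(b$tension_dia, 2)
})

test_that("a truncated decay flags the relaxation metric with a warning", {
  t <- seq(0, 200, by = 1)
  x <- pmin(t / 50, 1) # rises and never decays
  tr <- tibble::tibble(time_ms = t, cai_uM = x, tension_kPa = x)
  # both channels carry the same non-decaying waveform, so both warn
  expect_warning(expect_warning(b <- extract_biomarkers(tr), "truncated"),
                 "truncated")
  expect_true(is.na(b$tension_rt90))
  expect_gt(b$tension_amp, 0)
})

test_that("coarse-grid biomarkers match a dense-grid oracle", {
  cases <- list(c(30, 150), c(15, 90), c(60, 400))
  for (cs in cases) {
    coarse <- synth_twitch(amp = 10, tau_rise = cs[1], tau_decay = cs[2],
                           dt = 1, cycle = 2000)
    fine <- synth_twitch(amp = 10, tau_rise = cs[1], tau_decay = cs[2],
                         dt = 0.01, cycle = 2000)
    b <- extract_biomarkers(coarse)
    o <- extract_biomarkers(fine)
    expect_equal(b$tension_amp, o$tension_amp, tolerance = 1e-3)
    for (col in c("tension_ttp", "tension_rt50", "tension_rt90")) {
      expect_lt(abs(b[[col]] - o[[col]]), 0.5 * 1) # half a sample interval
    }
  }
})

test_that("biomarkers are invariant to time shifts", {
  tr <- synth_twitch(amp = 8, tau_rise = 25, tau_decay = 120)
  sh <- tr
  sh$time_ms <- sh$time_ms + 137.5
  expect_equal(extract_biomarkers(tr), extract_biomarkers(sh))
})

test_that("channel scaling rescales amplitude and preserves time metrics", {
  tr <- synth_twitch(amp = 8, tau_rise = 25, tau_decay = 120)
  sc <- tr
  sc$tension_kPa <- 3.7 * sc$tension_kPa
  b <- extract_biomarkers(tr)
  bs <- extract_biomarkers(sc)
  expect_equal(bs$tension_amp, 3.7 * b$tension_amp)
  expect_equal(bs$tension_ttp, b$tension_ttp)
  expect_equal(bs$tension_rt90, b$tension_rt90)
})

test_that("time metrics are robust to the sampling interval", {
  b1 <- extract_biomarkers(synth_twitch(10, 30, 150, dt = 1))
  b2 <- extract_biomarkers(synth_twitch(10, 30, 150, dt = 0.1))
  for (col in c("tension_ttp", "tension_rt50", "tension_rt90",
                "ca_td50", "ca_td95")) {
    expect_lt(abs(b1[[col]] - b2[[col]]), 1)
  }
})

test_that("beat windows select the analysed beat", {
  tr <- synth_twitch(amp = 10, tau_rise = 30, tau_decay = 150, cycle = 500)
  two <- tibble::tibble(
    time_ms = c(tr$time_ms, tr$time_ms + 500.5),
    cai_uM = rep(tr$cai_uM, 2), tension_kPa = rep(tr$tension_kPa, 2))
  b <- extract_biomarkers(two, beat_window = c(500.5, 1000))
  expect_equal(b$tension_amp, 10, tolerance = 1e-4)
})
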