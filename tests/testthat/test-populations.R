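stratum_occupancy <- function(x, n, lo = 0.5, hi = 2) {
  tabulate(pmin(floor((x - lo) / (hi - lo) * n) + 1, n), nbins = n)
}

test_that("Latin hypercube stratification places one sample per stratum", {
  tb <- lhs_sample(4, param_names = "Ca50", seed = 1)
  expect_equal(sort(stratum_occupancy(tb$Ca50, 4)), rep(1, 4))
  # paper-scale draw: full stratification on every default axis
  big <- lhs_sample(2000, seed = 2)
  for (ax in setdiff(names(big), "model_id")) {
    x <- big[[ax]]
    expect_gte(min(x), 0.5)
    expect_lte(max(x), 2)
    expect_equal(stratum_occupancy(x, 2000), rep(1L, 2000))
  }
})

test_that("sampling is reproducible under a fixed seed", {
  expect_identical(lhs_sample(50, seed = 9), lhs_sample(50, seed = 9))
  expect_false(identical(lhs_sample(50, seed = 9), lhs_sample(50, seed = 10)))
})

test_that("invalid sampling ranges are rejected", {
  expect_error(lhs_sample(5, param_names = "Ca50", range = c(2, 0.5)),
               "lo < hi")
})

test_that("scaling application composes multiplicatively", {
  p <- cell_params()
  a <- c(Ca50 = 0.7, V_serca = 1.3)
  b <- c(Ca50 = 1.2, k_uw = 0.9)
  p_ab <- scale_params(scale_params(p, a), b)
  prod <- c(Ca50 = 0.7 * 1.2, V_serca = 1.3, k_uw = 0.9)
  p_prod <- scale_params(p, prod)
  expect_equal(unclass(p_ab), unclass(p_prod))
  # same law at the spec level
  sa <- scaling_spec("a", scale = a)
  sb <- scaling_spec("b", scale = b)
  expect_equal(unclass(apply_spec(p, combine_specs(sa, sb))),
               unclass(p_ab))
})

test_that("calibration accepts everything on unbounded ranges", {
  tb <- lhs_sample(3, param_names = c("Ca50", "V_serca"), seed = 4)
  rng <- tibble::tibble(biomarker = c("tension_amp", "ca_amp"),
                        lo = -Inf, hi = Inf)
  cal <- calibrate_population(tb, rng, cell_params(), tol = 1e-4,
                              max_beats = 150)
  expect_true(all(cal$accepted))
  expect_equal(attr(cal, "rejection_tally"),
               c(tension_amp = 0L, ca_amp = 0L))
})

test_that("disjoint ranges reject everything with per-biomarker tallies", {
  tb <- lhs_sample(3, param_names = "Ca50", seed = 4)
  rng <- tibble::tibble(biomarker = c("tension_amp", "ca_amp"),
                        lo = c(1e5, 1e5), hi = c(2e5, 2e5))
  expect_warning(
    cal <- calibrate_population(tb, rng, cell_params(), tol = 1e-4,
                                max_beats = 150),
    "no models accepted")
  expect_false(any(cal$accepted))
  expect_gte(sum(attr(cal, "rejection_tally")), nrow(tb))
})

test_that("acceptance flags are deterministic given table and ranges", {
  tb <- lhs_sample(3, param_names = "Ca50", seed = 4)
  rng <- tibble::tibble(biomarker = "tension_amp", lo = 0, hi = 1e3)
  c1 <- calibrate_population(tb, rng, cell_params(), tol = 1e-4,
                             max_beats = 150)
  c2 <- calibrate_population(tb, rng, cell_params(), tol = 1e-4,
                             max_beats = 150)
  expect_identical(c1$accepted, c2$accepted)
  expect_identical(c1$tension_amp, c2$tension_amp)
})

test_that("identity scaling reproduces the calibration biomarkers", {
  tb <- lhs_sample(2, param_names = "V_serca", seed = 6)
  cal <- calibrate_population(tb, NULL, cell_params(), tol = 1e-5)
  rerun <- run_population(cal, variant_spec("control"), cell_params(),
                          tol = 1e-5)
  expect_equal(rerun$tension_amp, cal$tension_amp, tolerance = 1e-4)
  expect_equal(rerun$ca_rt90, cal$ca_rt90, tolerance = 1e-3)
})

test_that("raised myosin availability lifts every model's tension", {
  tb <- lhs_sample(10, param_names = c("V_serca", "k_uw"), seed = 8)
  cal <- calibrate_population(tb, NULL, cell_params(), tol = 1e-5)
  myh7 <- run_population(cal, variant_spec("MYH7_R403Q"), cell_params(),
                         tol = 1e-5)
  expect_true(all(myh7$tension_amp > cal$tension_amp))
})
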