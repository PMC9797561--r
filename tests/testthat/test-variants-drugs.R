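test_that("the genotype library encodes the published remodellings", {
  tn <- variant_spec("TNNT2_R92Q")
  expect_equal(tn$scale, c(Ca50 = 0.7, k_ub = 0.8))
  ti <- variant_spec("TNNI3_R21C")
  expect_equal(ti$scale, c(Ca50 = 0.7, k_off_trpn = 0.5))
  my <- variant_spec("MYH7_R403Q")
  expect_equal(my$scale, c(R = 1.3))
  expect_equal(my$fb_mode, "static")
  ct <- variant_spec("control")
  expect_length(ct$scale, 0)
  expect_error(variant_spec("MYBPC3"), "valid names")
})

test_that("specs remodel parameters and report through apply_spec", {
  p <- cell_params()
  q <- apply_spec(p, variant_spec("TNNT2_R92Q"))
  expect_equal(q$Ca50, 0.7 * p$Ca50)
  expect_equal(q$k_ub, 0.8 * p$k_ub)
  q <- apply_spec(p, variant_spec("MYH7_R403Q"))
  expect_equal(q$R, 1.3)
  expect_equal(q$fb_mode, "static")
})

test_that("Mavacamten maps dose to availability with Hill inhibition", {
  dr <- dose_response_params(E_max = 0.6, IC50 = 0.65, hill_h = 1.8)
  expect_equal(mavacamten_R(0, dr, 1.3), 1.3)
  dr1 <- dose_response_params(E_max = 0.6, IC50 = 0.5, hill_h = 1)
  expect_equal(mavacamten_R(0.5, dr1, 2), 2 * (1 - 0.3))
  expect_equal(mavacamten_R(1e9, dr, 1), 1 - 0.6, tolerance = 1e-6)
  r <- mavacamten_R(seq(0, 3, by = 0.25), dr, 1.3)
  expect_true(all(diff(r) < 0))
  expect_error(mavacamten_R(-0.1, dr), ">= 0")
})

test_that("drug scaling composes multiplicatively on the variant's R", {
  dr <- dose_response_params()
  sp <- combine_specs(variant_spec("MYH7_R403Q"), mavacamten_spec(0.5, dr))
  p <- apply_spec(cell_params(), sp)
  expect_equal(p$R, 1.3 * mavacamten_R(0.5, dr, 1))
  expect_equal(p$fb_mode, "static")
})

test_that("plasma concentration conversion follows unit algebra", {
  expect_equal(ng_per_ml_to_uM(1000, molar_mass = 1000, free_fraction = 1), 1)
  expect_equal(ng_per_ml_to_uM(0, molar_mass = 500, free_fraction = 0.1), 0)
  expect_equal(ng_per_ml_to_uM(2000, 1000, 0.5),
               2 * ng_per_ml_to_uM(1000, 1000, 0.5))
  expect_error(ng_per_ml_to_uM(100), "molar_mass")
  expect_error(ng_per_ml_to_uM(100, 500, 1.5), "free_fraction")
})

test_that("intervention levels map to the documented scalings", {
  expect_equal(intervention_spec("serca_up", 0.5)$scale,
               c(serca_scale = 1.5))
  expect_equal(intervention_spec("ical_block", 0.4)$scale,
               c(lcc_scale = 0.6))
  expect_equal(intervention_spec("inal_block", 0.6)$set,
               list(inal_block = 0.6))
  expect_equal(intervention_spec("desensitiser", 0.5)$scale, c(Ca50 = 1.5))
  expect_equal(intervention_spec("desensitiser", 0.5,
                                 desens_map = "reciprocal")$scale,
               c(Ca50 = 2))
  expect_error(intervention_spec("ito_block", 0.2), "valid kinds")
  expect_error(intervention_spec("serca_up", 1.2), "level")
})

test_that("dose-response calibration recovers known parameters", {
  truth <- dose_response_params(E_max = 0.55, IC50 = 0.8, hill_h = 1.8)
  resp <- function(conc, dr) mavacamten_R(conc, dr, 1) # amplitude ~ R here
  targets <- tibble::tibble(
    conc_uM = c(0.2, 0.5, 1, 2),
    amp_ratio = resp(c(0.2, 0.5, 1, 2), truth))
  fit <- calibrate_dose_response(targets, hill_h = 1.8, response_fn = resp)
  expect_lt(abs(fit$dr$E_max - truth$E_max) / truth$E_max, 0.05)
  expect_lt(abs(fit$dr$IC50 - truth$IC50) / truth$IC50, 0.05)
  td <- tidy(fit)
  expect_equal(td$term, c("E_max", "IC50", "hill_h"))
  expect_true(glance(fit)$converged)
})

test_that("an under-determined dose-response fit is refused", {
  expect_error(
    calibrate_dose_response(tibble::tibble(conc_uM = 0.5, amp_ratio = 0.8)),
    "under-determined")
})

test_that("a dose trial emits per-arm tables and Dunn comparisons", {
  tb <- lhs_sample(3, param_names = "V_serca", seed = 13)
  cal <- calibrate_population(tb, NULL, cell_params(), tol = 1e-4,
                              max_beats = 150)
  trial <- run_dose_trial(cal, "TNNT2_R92Q", doses = c(0.3, 1),
                          tol = 1e-4, max_beats = 150)
  expect_setequal(unique(trial$arms$arm),
                  c("untreated", "mavacamten_0.3uM", "mavacamten_1uM"))
  expect_equal(nrow(trial$arms), 9)
  expect_s3_class(trial$report$tests, "tbl_df")
  # amplitude falls with dose in every model
  wide <- split(trial$arms$tension_amp, trial$arms$arm)
  expect_true(all(wide$mavacamten_1uM < wide$untreated))
})

test_that("shipped dose-response returns MYH7 availability to control", {
  dr <- dose_response_params()
  expect_equal(mavacamten_R(0.5, dr, 1.3), 1, tolerance = 0.01)
})
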