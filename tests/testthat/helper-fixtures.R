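# Session-cached fixtures shared across test files. Everything is built in
# code; expensive objects (steady states, populations) are computed once.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# Control cell paced to steady state with default parameters.
ctrl_steady <- function() {
  fixture("ctrl_steady", function() run_to_steady_state(cell_params()))
}

# Steady state for a scaled/remodelled cell, warm-started from control.
scenario_steady <- function(tag, spec, max_beats = 500) {
  fixture(paste0("steady_", tag), function() {
    run_to_steady_state(apply_spec(cell_params(), spec),
                        max_beats = max_beats, y0 = ctrl_steady()$state)
  })
}

# Full R-side right-hand side of the coupled model, assembled from the
# exported module operations; independent of the compiled solver core.
r_reference_rhs <- function(params) {
  function(t, y, parms) {
    myo <- myofilament_derivatives(y[c("CaTRPN", "B", "W", "S")],
                                   Cai = max(y[["Cai"]], 0), params = params)
    jt <- params$TRPN_tot * myo[["CaTRPN"]]
    ca <- calcium_derivatives(y[c("Cai", "Ca_sr", "g")], J_trpn = jt,
                              t_since_stim = t %% params$cl, params = params)
    list(c(ca[["Cai"]], ca[["Ca_sr"]], ca[["g"]],
           myo[["CaTRPN"]], myo[["B"]], myo[["W"]], myo[["S"]]))
  }
}

# Calibrated study population (shared by phenotype and pharmacology tests).
study_population <- function() {
  fixture("study_population", function() build_study_population(n = 300,
                                                                seed = 1))
}

# Scenario medians on the accepted study population.
population_scenario <- function(tag, spec) {
  fixture(paste0("pop_", tag), function() {
    run_population(study_population(), spec, cell_params())
  })
}

accepted_controls <- function() {
  pop <- study_population()
  pop[pop$accepted, ]
}

med <- function(tb, col) stats::median(tb[[col]], na.rm = TRUE)
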