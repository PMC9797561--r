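# Genotype library, interventions, and scaling-spec algebra.

#' Create a scaling specification
#'
#' A scaling spec is a named recipe of multiplicative parameter factors
#' (`scale`), absolute assignments (`set`, e.g. a late-sodium block
#' fraction) and an optional feedback-mode override. Specs compose with
#' [combine_specs()]: scales multiply elementwise, so applying spec A then
#' spec B equals applying their product.
#'
#' @param name Spec label used in reports.
#' @param scale Named numeric vector of strictly positive multiplicative
#'   factors on `cell_params` fields (the DRX:SRX parameter `R` composes
#'   multiplicatively like any other factor).
#' @param set Named list of absolute parameter assignments.
#' @param fb_mode Optional feedback-mode override
#'   (`"off"`, `"static"`, `"dynamic"`).
#' @return A `scaling_spec` object.
#' @export
scaling_spec <- function(name, scale = numeric(), set = list(),
                         fb_mode = NULL) {
  if (length(scale) && any(scale <= 0)) {
    stop("scaling factors must be > 0", call. = FALSE)
  }
  template <- cell_params()
  bad <- setdiff(c(names(scale), names(set)), names(template))
  if (length(bad)) {
    stop("unknown parameter(s) in spec: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(fb_mode) && !fb_mode %in% names(.fb_modes)) {
    stop("fb_mode must be one of ", paste(names(.fb_modes), collapse = ", "),
         call. = FALSE)
  }
  structure(list(name = name, scale = scale, set = set, fb_mode = fb_mode),
            class = "scaling_spec")
}

#' @export
print.scaling_spec <- function(x, ...) {
  cat("<scaling_spec>", x$name, "\n")
  if (length(x$scale)) {
    cat("  scale:", paste(sprintf("%s x%g", names(x$scale), x$scale),
                          collapse = ", "), "\n")
  }
  if (length(x$set)) {
    cat("  set:  ", paste(sprintf("%s = %g", names(x$set), unlist(x$set)),
                          collapse = ", "), "\n")
  }
  if (!is.null(x$fb_mode)) cat("  fb_mode:", x$fb_mode, "\n")
  invisible(x)
}

#' Apply a scaling spec to a parameter set
#'
#' @param params A `cell_params` object.
#' @param spec A `scaling_spec`.
#' @return The remodelled, validated `cell_params`.
#' @export
apply_spec <- function(params, spec) {
  stopifnot(inherits(spec, "scaling_spec"))
  p <- scale_params(params, spec$scale)
  for (nm in names(spec$set)) p[[nm]] <- spec$set[[nm]]
  if (!is.null(spec$fb_mode)) p$fb_mode <- spec$fb_mode
  validate_params(p)
  p
}

#' Compose scaling specs
#'
#' Elementwise product of the scale maps; later `set` assignments and
#' feedback overrides win. Drug scalings on `R` therefore compose
#' multiplicatively on top of a variant's `R`.
#'
#' @param ... `scaling_spec` objects, applied left to right.
#' @param name Optional name for the combined spec.
#' @return A single `scaling_spec`.
#' @export
combine_specs <- function(..., name = NULL) {
  specs <- list(...)
  stopifnot(length(specs) >= 1)
  scale <- numeric()
  set <- list()
  fb <- NULL
  for (s in specs) {
    stopifnot(inherits(s, "scaling_spec"))
    for (nm in names(s$scale)) {
      scale[nm] <- if (nm %in% names(scale)) scale[[nm]] * s$scale[[nm]] else
        s$scale[[nm]]
    }
    for (nm in names(s$set)) set[nm] <- s$set[nm]
    if (!is.null(s$fb_mode)) fb <- s$fb_mode
  }
  if (is.null(name)) {
    name <- paste(vapply(specs, `[[`, "", "name"), collapse = " + ")
  }
  scaling_spec(name, scale = scale, set = set, fb_mode = fb)
}

#' Genotype-specific sarcomere remodelling
#'
#' Returns the parameter remodelling representing each hypertrophic
#' cardiomyopathy variant:
#' \describe{
#'   \item{control}{identity.}
#'   \item{MYH7_R403Q}{myosin SRX destabilisation, `R` x 1.3, with the
#'     static myosin-to-thin-filament feedback enabled.}
#'   \item{TNNT2_R92Q}{thin-filament calcium sensitisation and tropomyosin
#'     repositioning: `Ca50` x 0.7 and the blocked/unblocked reverse rate
#'     `k_ub` (the K_B knob) x 0.8.}
#'   \item{TNNI3_R21C}{increased troponin calcium binding: `Ca50` x 0.7 and
#'     dissociation `k_off_trpn` x 0.5.}
#' }
#'
#' @param name One of `"control"`, `"MYH7_R403Q"`, `"TNNT2_R92Q"`,
#'   `"TNNI3_R21C"`.
#' @return A `scaling_spec`.
#' @examples
#' variant_spec("TNNT2_R92Q")
#' @export
variant_spec <- function(name) {
  switch(name,
    control = scaling_spec("control"),
    MYH7_R403Q = scaling_spec("MYH7_R403Q", scale = c(R = 1.3),
                              fb_mode = "static"),
    TNNT2_R92Q = scaling_spec("TNNT2_R92Q",
                              scale = c(Ca50 = 0.7, k_ub = 0.8)),
    TNNI3_R21C = scaling_spec("TNNI3_R21C",
                              scale = c(Ca50 = 0.7, k_off_trpn = 0.5)),
    stop("unknown variant '", name, "'; valid names: control, MYH7_R403Q, ",
         "TNNT2_R92Q, TNNI3_R21C", call. = FALSE)
  )
}

#' In-silico Mavacamten dose trial
#'
#' Runs a dose grid of Mavacamten on a genotype population and reports the
#' arms against the untreated population: per-arm biomarker summaries plus
#' Kruskal-Wallis with Dunn post hoc comparisons (the layout of a
#' drug-trial figure, as a table).
#'
#' @param population Calibrated population (see [calibrate_population()]).
#' @param variant Genotype name for [variant_spec()].
#' @param doses Mavacamten concentrations, uM. The default grid covers the
#'   experimentally relevant arms (0.3, 1, 3 uM) plus the 0.5 uM
#'   reference-rescue dose.
#' @param dr A `dose_response` object.
#' @param params_base Control `cell_params`.
#' @param biomarkers Biomarker columns to report.
#' @param ... Passed to [run_population()].
#' @return A list: `arms` (combined biomarker tibble with a `scenario`
#'   column) and `report` (an `hcm_report`).
#' @export
run_dose_trial <- function(population, variant,
                           doses = c(0.3, 0.5, 1, 3),
                           dr = dose_response_params(),
                           params_base = cell_params(),
                           biomarkers = c("tension_amp", "tension_rt90"),
                           ...) {
  vs <- variant_spec(variant)
  arms <- list(untreated = run_population(population, vs, params_base, ...))
  for (d in doses) {
    arms[[sprintf("mavacamten_%guM", d)]] <- run_population(
      population, combine_specs(vs, mavacamten_spec(d, dr)), params_base,
      ...)
  }
  report <- scenario_report(arms, biomarkers = biomarkers,
                            compare = "kruskal_dunn")
  list(arms = dplyr::bind_rows(arms, .id = "arm"), report = report)
}

#' Pharmacological intervention specs
#'
#' \describe{
#'   \item{ical_block}{L-type calcium current block: trigger influx scaled
#'     by `(1 - level)`.}
#'   \item{inal_block}{late-sodium current block, represented
#'     phenomenologically as enhanced calcium extrusion (`inal_block` set
#'     to `level`).}
#'   \item{serca_up}{SERCA upregulation: uptake scaled by `(1 + level)`.}
#'   \item{desensitiser}{thin-filament calcium desensitiser: `Ca50` scaled
#'     by `(1 + level)` (or `1/(1 - level)` with
#'     `desens_map = "reciprocal"`), approximately inverting the variants'
#'     `Ca50 x 0.7` sensitisation at level 0.5.}
#' }
#'
#' @param kind One of `"ical_block"`, `"inal_block"`, `"serca_up"`,
#'   `"desensitiser"`.
#' @param level Fraction in `[0, 1)`.
#' @param desens_map Mapping from desensitisation level to the Ca50 factor.
#' @return A `scaling_spec`.
#' @examples
#' intervention_spec("serca_up", 0.5)
#' @export
intervention_spec <- function(kind, level,
                              desens_map = c("one_plus", "reciprocal")) {
  if (!is.numeric(level) || level < 0 || level >= 1) {
    stop("level must lie in [0, 1)", call. = FALSE)
  }
  desens_map <- match.arg(desens_map)
  nm <- sprintf("%s:%g", kind, level)
  switch(kind,
    ical_block = scaling_spec(nm, scale = c(lcc_scale = 1 - level)),
    inal_block = scaling_spec(nm, set = list(inal_block = level)),
    serca_up = scaling_spec(nm, scale = c(serca_scale = 1 + level)),
    desensitiser = scaling_spec(nm, scale = c(
      Ca50 = if (desens_map == "one_plus") 1 + level else 1 / (1 - level))),
    stop("unknown intervention '", kind, "'; valid kinds: ical_block, ",
         "inal_block, serca_up, desensitiser", call. = FALSE)
  )
}
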