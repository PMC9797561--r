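# ggplot2 views of traces, populations and sensitivities.

#' Plot a simulated trace
#'
#' Tension and calcium transients as stacked panels.
#'
#' @param object An `hcm_trace` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hcm_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[c("time_ms", "cai_uM", "tension_kPa")],
    cols = c("cai_uM", "tension_kPa"),
    names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel, levels = c("tension_kPa", "cai_uM"),
                         labels = c("Active tension (kPa)",
                                    "Free calcium (uM)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time_ms, .data$value)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (ms)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Compare biomarker distributions across scenarios
#'
#' Box plots of one biomarker for a set of scenario population tables,
#' mirroring per-panel population comparisons.
#'
#' @param tables Named list of population tibbles (each with the biomarker
#'   column), or a single tibble with a `scenario` column.
#' @param biomarker Biomarker column to plot.
#' @return A ggplot object.
#' @export
plot_population_biomarker <- function(tables, biomarker = "tension_amp") {
  df <- if (is.data.frame(tables)) {
    tables
  } else {
    dplyr::bind_rows(purrr::imap(tables, function(tb, nm) {
      if (!"scenario" %in% names(tb)) tb$scenario <- nm
      tb
    }))
  }
  if (!"scenario" %in% names(df)) df$scenario <- "population"
  df <- df[is.finite(df[[biomarker]]), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$scenario, .data[[biomarker]])) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = biomarker) +
    ggplot2::theme_minimal()
}

#' Plot a Mavacamten dose-response curve
#'
#' @param dr A `dose_response` object.
#' @param R_base Untreated R (e.g. 1.3 for MYH7 R403Q).
#' @param conc_max Upper concentration, uM.
#' @return A ggplot object.
#' @export
plot_dose_response <- function(dr, R_base = 1, conc_max = 3) {
  conc <- seq(0, conc_max, length.out = 200)
  df <- tibble::tibble(conc_uM = conc,
                       R = mavacamten_R(conc, dr, R_base))
  ggplot2::ggplot(df, ggplot2::aes(.data$conc_uM, .data$R)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Mavacamten (uM)", y = "Myosin availability R") +
    ggplot2::theme_minimal()
}
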