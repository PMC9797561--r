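# Nonparametric comparisons between scenario populations.

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) comparison of two samples,
#' the paper-standard test for simulated population biomarkers. Uses the
#' exact null distribution when both samples are small (combined n <= 12)
#' and tie-free, and the tie-corrected normal approximation otherwise.
#'
#' @param x,y Numeric samples (each length >= 1).
#' @return One-row tibble with `U` (statistic for `x`), `p`, and `method`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))
#' @export
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 12 && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  tibble::tibble(U = unname(wt$statistic), p = wt$p.value,
                 method = if (exact) "exact" else "normal approximation")
}

# Dunn's pairwise z-tests on the joint ranks, with tie correction.
.dunn_pairwise <- function(values, groups, p_adjust) {
  r <- rank(values)
  N <- length(values)
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  mean_ranks <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  gl <- names(mean_ranks)
  pairs <- utils::combn(gl, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    i <- pr[1]; j <- pr[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / ns[[i]] + 1 / ns[[j]]))
    z <- (mean_ranks[[i]] - mean_ranks[[j]]) / se
    tibble::tibble(group1 = i, group2 = j, z = z,
                   p = 2 * pnorm(-abs(z)))
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- pmin(p.adjust(out$p, method = p_adjust), 1)
  out
}

#' Kruskal-Wallis test with Dunn post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H across `>= 2` groups followed by Dunn's
#' pairwise z-tests on the joint ranks, with a family-wise multiplicity
#' adjustment (classical Dunn-Bonferroni by default).
#'
#' @param groups Named (or unnamed) list of numeric samples, each with
#'   `>= 1` observation.
#' @param p_adjust Multiplicity adjustment method (see [stats::p.adjust()]).
#' @return An `hcm_kruskal` object: `H`, overall `p`, and the `pairwise`
#'   tibble (`group1`, `group2`, `z`, `p`, `p_adj`). If every observation
#'   is identical across all groups, `H = 0` and `p = 1` by convention.
#' @examples
#' kruskal_dunn(list(a = c(1, 2), b = c(3, 4), c = c(5, 6)))
#' @export
kruskal_dunn <- function(groups, p_adjust = "bonferroni") {
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(!vapply(groups, length, integer(1)))) {
    stop("each group needs at least 1 observation", call. = FALSE)
  }
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  gf <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (length(unique(values)) == 1) {
    pairwise <- .dunn_pairwise(values, gf, p_adjust)
    pairwise$z <- 0; pairwise$p <- 1; pairwise$p_adj <- 1
    return(structure(list(H = 0, p = 1, pairwise = pairwise),
                     class = "hcm_kruskal"))
  }
  kt <- kruskal.test(values, gf)
  structure(list(H = unname(kt$statistic), p = kt$p.value,
                 pairwise = .dunn_pairwise(values, gf, p_adjust)),
            class = "hcm_kruskal")
}

#' @export
print.hcm_kruskal <- function(x, ...) {
  cat(sprintf("<hcm_kruskal> H = %.4g, p = %.4g\n", x$H, x$p))
  print(x$pairwise)
  invisible(x)
}

#' Tidy Kruskal-Dunn pairwise results
#'
#' @param x An `hcm_kruskal` from [kruskal_dunn()].
#' @param ... Unused.
#' @return The pairwise tibble.
#' @export
tidy.hcm_kruskal <- function(x, ...) x$pairwise

#' Glance at a Kruskal-Dunn result
#'
#' @inheritParams tidy.hcm_kruskal
#' @return One-row tibble with `H` and the overall `p`.
#' @export
glance.hcm_kruskal <- function(x, ...) tibble::tibble(H = x$H, p = x$p)

#' Scenario summary and comparison report
#'
#' Summarises biomarker distributions per scenario (mean, SD, median, IQR)
#' and runs the requested nonparametric comparisons: Mann-Whitney for a
#' `control` scenario against each other scenario, or Kruskal-Wallis with
#' Dunn post hoc across all scenarios (for example a mutant plus several
#' dose arms).
#'
#' @param tables List of population tibbles with biomarker columns and a
#'   `scenario` column (or names supplied via the list names).
#' @param biomarkers Biomarker columns to report.
#' @param compare `"none"`, `"mann_whitney"` (each scenario vs the first),
#'   or `"kruskal_dunn"` (all scenarios jointly).
#' @return An `hcm_report` list: `summary` tibble and `tests` tibble.
#' @export
scenario_report <- function(tables,
                            biomarkers = c("tension_amp", "tension_rt90",
                                           "ca_amp", "ca_ttp", "ca_rt90"),
                            compare = c("none", "mann_whitney",
                                        "kruskal_dunn")) {
  compare <- match.arg(compare)
  if (!length(tables)) stop("no tables supplied", call. = FALSE)
  if (is.data.frame(tables)) tables <- list(tables)
  if (is.null(names(tables))) {
    names(tables) <- vapply(seq_along(tables), function(i) {
      sc <- unique(tables[[i]][["scenario"]])
      if (length(sc) == 1) sc else paste0("scenario", i)
    }, character(1))
  }
  for (tb in tables) {
    missing_cols <- setdiff(biomarkers, names(tb))
    if (length(missing_cols)) {
      stop("table lacks biomarker column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
  }
  summary <- purrr::map_dfr(names(tables), function(nm) {
    purrr::map_dfr(biomarkers, function(b) {
      v <- tables[[nm]][[b]]
      v <- v[is.finite(v)]
      tibble::tibble(
        scenario = nm, biomarker = b, n = length(v),
        mean = mean(v), sd = sd(v), median = median(v),
        q25 = unname(quantile(v, 0.25)), q75 = unname(quantile(v, 0.75)))
    })
  })
  tests <- NULL
  if (compare == "mann_whitney" && length(tables) >= 2) {
    ref <- names(tables)[1]
    tests <- purrr::map_dfr(names(tables)[-1], function(nm) {
      purrr::map_dfr(biomarkers, function(b) {
        x <- tables[[ref]][[b]]; y <- tables[[nm]][[b]]
        mw <- mann_whitney(x[is.finite(x)], y[is.finite(y)])
        tibble::tibble(biomarker = b, group1 = ref, group2 = nm,
                       statistic = mw$U, p = mw$p,
                       significant = mw$p < 0.05)
      })
    })
  } else if (compare == "kruskal_dunn") {
    tests <- purrr::map_dfr(biomarkers, function(b) {
      gr <- lapply(tables, function(tb) {
        v <- tb[[b]]; v[is.finite(v)]
      })
      kd <- kruskal_dunn(gr)
      out <- kd$pairwise
      out$biomarker <- b
      out$H <- kd$H
      out$p_overall <- kd$p
      out$significant <- out$p_adj < 0.05
      out
    })
  }
  structure(list(summary = summary, tests = tests), class = "hcm_report")
}

#' @export
print.hcm_report <- function(x, ...) {
  cat("<hcm_report>\n")
  print(x$summary, n = 20)
  if (!is.null(x$tests)) {
    cat("tests:\n")
    print(x$tests, n = 20)
  }
  invisible(x)
}
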