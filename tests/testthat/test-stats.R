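# Brute-force Mann-Whitney: enumerate all group assignments of the pooled
# sample and count U statistics at least as extreme (two-sided).
brute_force_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  ustat <- function(ix) {
    r <- rank(pooled)
    sum(r[ix]) - length(ix) * (length(ix) + 1) / 2
  }
  u_obs <- ustat(seq_along(x))
  mu <- length(x) * length(y) / 2
  combos <- utils::combn(n, length(x), simplify = FALSE)
  us <- vapply(combos, ustat, numeric(1))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

test_that("Mann-Whitney matches enumeration on small samples", {
  out <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(out$U, 0)
  expect_equal(out$p, 1 / 3)
  expect_equal(out$method, "exact")
  set.seed(21)
  for (i in 1:5) {
    x <- round(rnorm(4), 3)
    y <- round(rnorm(5, 0.5), 3)
    out <- mann_whitney(x, y)
    expect_equal(out$p, brute_force_mw_p(x, y), tolerance = 1e-12)
  }
})

test_that("identical samples give the null-symmetric U", {
  x <- c(1, 2, 3)
  out <- mann_whitney(x, x)
  expect_equal(out$U, length(x)^2 / 2)
  expect_gt(out$p, 0.9)
  expect_error(mann_whitney(numeric(0), x), "empty")
})

test_that("large or tied samples fall back to the normal approximation", {
  set.seed(2)
  out <- mann_whitney(rnorm(50), rnorm(50, 1))
  expect_equal(out$method, "normal approximation")
  expect_lt(out$p, 0.01)
  out_tied <- mann_whitney(c(1, 1, 2), c(2, 3, 3))
  expect_equal(out_tied$method, "normal approximation")
  expect_true(out_tied$p >= 0 && out_tied$p <= 1)
})

test_that("Kruskal-Wallis H matches hand rank arithmetic", {
  g <- list(c(1, 2), c(3, 4), c(5, 6))
  kd <- kruskal_dunn(g)
  # ranks 1..6, group rank sums 3, 7, 11
  h_hand <- 12 / (6 * 7) * (3^2 / 2 + 7^2 / 2 + 11^2 / 2) - 3 * 7
  expect_equal(kd$H, h_hand)
  expect_equal(nrow(kd$pairwise), 3)
  expect_true(all(kd$pairwise$p_adj >= kd$pairwise$p - 1e-12))
})

test_that("Dunn z statistics match direct rank computation", {
  a <- c(1, 2); b <- c(3, 4)
  kd <- kruskal_dunn(list(a = a, b = b))
  # mean ranks 1.5 and 3.5 of N = 4; no ties
  se <- sqrt((4 * 5 / 12) * (1 / 2 + 1 / 2))
  z_hand <- (1.5 - 3.5) / se
  expect_equal(kd$pairwise$z, z_hand)
  expect_equal(kd$pairwise$p, 2 * pnorm(-abs(z_hand)))
})

test_that("group order does not change H or the p-value multiset", {
  g <- list(a = c(1, 5, 3), b = c(2, 8), c = c(9, 4, 7))
  k1 <- kruskal_dunn(g)
  k2 <- kruskal_dunn(g[c(3, 1, 2)])
  expect_equal(k1$H, k2$H)
  expect_equal(sort(k1$pairwise$p_adj), sort(k2$pairwise$p_adj))
})

test_that("identical constant groups collapse to H = 0, p = 1", {
  kd <- kruskal_dunn(list(rep(2, 3), rep(2, 4)))
  expect_equal(kd$H, 0)
  expect_equal(kd$p, 1)
  expect_equal(kd$pairwise$p_adj, 1)
  expect_error(kruskal_dunn(list(1:3)), "at least 2 groups")
})

test_that("scenario reports summarise and compare populations", {
  set.seed(31)
  mk <- function(shift, nm) tibble::tibble(
    scenario = nm,
    tension_amp = rnorm(30, 15 + shift), tension_rt90 = rnorm(30, 400),
    ca_amp = rnorm(30, 0.4, 0.05), ca_ttp = rnorm(30, 30, 3),
    ca_rt90 = rnorm(30, 500, 20))
  ctrl <- mk(0, "control"); var <- mk(5, "variant")
  rep1 <- scenario_report(list(ctrl))
  expect_equal(unique(rep1$summary$scenario), "control")
  expect_null(rep1$tests)
  rep2 <- scenario_report(list(ctrl, var), compare = "mann_whitney")
  expect_equal(nrow(rep2$tests), 5)
  amp_row <- rep2$tests[rep2$tests$biomarker == "tension_amp", ]
  expect_true(amp_row$significant)
  rep3 <- scenario_report(list(a = ctrl, b = var, c = mk(2, "c")),
                          compare = "kruskal_dunn")
  expect_equal(nrow(rep3$tests), 3 * 5) # three pairs per biomarker
  expect_error(scenario_report(list(tibble::tibble(x = 1))),
               "lacks biomarker")
})
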