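test_that("spearman correlation handles monotone limits and matches the midrank oracle", {
  x <- c(1, 2, 3, 5, 8, 13)
  expect_equal(spearman_test(x, x^2)$rho, 1)
  expect_equal(spearman_test(x, -x)$rho, -1)
  # invariance under strictly monotone transforms
  set.seed(2)
  a <- rnorm(30)
  b <- a + rnorm(30)
  expect_equal(spearman_test(a, b)$rho, spearman_test(exp(a), b)$rho)
  expect_equal(spearman_test(a, b)$rho, spearman_test(a, b^3)$rho)
  # tied 8-pair fixture against the rank-then-correlate oracle
  xt <- c(1, 2, 2, 3, 4, 4, 4, 5)
  yt <- c(0, 1, 1, 1, 3, 2, 4, 4)
  st <- spearman_test(xt, yt)
  expect_equal(st$rho, o_spearman(xt, yt), tolerance = 1e-12)
  t_stat <- st$rho * sqrt(6 / (1 - st$rho^2))
  expect_equal(st$p_value, 2 * pt(-abs(t_stat), 6), tolerance = 1e-12)
  expect_error(spearman_test(rep(1, 6), 1:6), "constant")
})

test_that("Kruskal-Wallis reproduces the hand-ranked oracle and degenerate case", {
  kw0 <- kruskal_wallis(list(rep(2, 3), rep(2, 4)))
  expect_equal(unname(kw0$statistic), 0)
  expect_equal(kw0$p_value, 1)

  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(unname(kw$statistic), o_kw_h(list(c(1, 2, 3), c(4, 5, 6))),
               tolerance = 1e-12)
  expect_equal(kw$df, 1)

  for (s in 1:8) {
    set.seed(s)
    groups <- lapply(c(6, 8, 7), function(n) sample(0:5, n, replace = TRUE))
    if (length(unique(unlist(groups))) == 1) next
    expect_equal(unname(kruskal_wallis(groups)$statistic), o_kw_h(groups),
                 tolerance = 1e-10)
  }
  expect_error(kruskal_wallis(list(1:3)), "two non-empty")
})

test_that("two-group Kruskal-Wallis equals the squared Mann-Whitney z", {
  set.seed(4)
  x <- sample(0:8, 30, replace = TRUE)
  y <- sample(2:10, 25, replace = TRUE)
  h <- unname(kruskal_wallis(list(x, y))$statistic)
  mw <- mann_whitney(x, y)
  u <- unname(mw$statistic)
  nn <- length(x) + length(y)
  ties <- table(c(x, y))
  var_u <- length(x) * length(y) / 12 *
    ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
  z2 <- (u - length(x) * length(y) / 2)^2 / var_u
  expect_equal(h, z2, tolerance = 1e-10)
  # and the p-values coincide (chi-square on 1 df vs two-sided normal)
  expect_equal(kruskal_wallis(list(x, y))$p_value, mw$p_value,
               tolerance = 1e-10)
})

test_that("Mann-Whitney U follows the pair-counting definition", {
  expect_equal(unname(mann_whitney(c(1, 2), c(3, 4))$statistic), 0)
  x <- c(1, 3, 5, 7)
  expect_equal(unname(mann_whitney(x, x)$statistic), length(x)^2 / 2)
  for (s in 1:10) {
    set.seed(s)
    a <- sample(0:6, 7, replace = TRUE)
    b <- sample(0:6, 6, replace = TRUE)
    expect_equal(unname(mann_whitney(a, b)$statistic), o_mw_u(a, b),
                 tolerance = 1e-12)
  }
})

test_that("small-sample Mann-Whitney p-values come from exact enumeration", {
  # tie-free case: agree with the exact distribution used by wilcox.test
  x <- c(1.2, 3.4, 2.2, 5.1)
  y <- c(0.8, 4.4, 6.2, 7.1)
  p_mine <- mann_whitney(x, y)$p_value
  p_ref <- wilcox.test(x, y, exact = TRUE)$p.value
  expect_equal(p_mine, p_ref, tolerance = 1e-12)
  # tied case: agree with an independently coded enumeration oracle
  for (s in 1:6) {
    set.seed(s)
    a <- sample(0:3, 4, replace = TRUE)
    b <- sample(0:3, 4, replace = TRUE)
    expect_equal(mann_whitney(a, b)$p_value, o_mw_exact_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("odds ratio applies the Haldane-Anscombe correction exactly when needed", {
  sym <- odds_ratio(2, 2, 2, 2)
  expect_equal(sym$or, 1)
  expect_false(sym$correction_applied)

  plain <- odds_ratio(10, 5, 2, 20)
  expect_equal(plain$or, 20)
  expect_false(plain$correction_applied)
  expect_equal(plain$or, o_odds_ratio(10, 5, 2, 20))

  # severity-threshold counts with an empty cell (complete separation)
  zc <- odds_ratio(5, 4, 0, 86)
  expect_true(zc$correction_applied)
  expect_equal(zc$or, (5.5 * 86.5) / (4.5 * 0.5), tolerance = 1e-12)
  se <- sqrt(1 / 5.5 + 1 / 4.5 + 1 / 0.5 + 1 / 86.5)
  expect_equal(zc$ci_low, exp(log(zc$or) - qnorm(0.975) * se),
               tolerance = 1e-12)
  expect_equal(zc$ci_high, exp(log(zc$or) + qnorm(0.975) * se),
               tolerance = 1e-12)
  expect_true(zc$ci_low <= zc$or && zc$or <= zc$ci_high)

  expect_error(odds_ratio(0, 0, 3, 4), "row or column")
})

test_that("threshold analysis reproduces the published partition arithmetic", {
  pp <- published_partition_pairs()
  res <- threshold_analysis(pp$totals, pp$nihss)
  expect_identical(res$groups$n, c(86L, 9L, 31L))
  expect_identical(sum(res$groups$n), length(pp$totals))
  expect_equal(res$groups$pct, 100 * c(86, 9, 31) / 126, tolerance = 1e-12)
  expect_equal(res$groups$pct[res$groups$group == "HIGH"], 24.6,
               tolerance = 0.005)
  expect_identical(res$groups$cases, c(0, 5, 26))
  # odds ratio of INTERMEDIATE vs LOW equals the corrected 2x2 estimate
  expect_equal(res$odds_ratio$or, odds_ratio(5, 4, 0, 86)$or)
  expect_true(res$odds_ratio$correction_applied)
  expect_false(is.null(res$kruskal))
})

test_that("threshold analysis degrades gracefully on a single occupied group", {
  res <- threshold_analysis(rep(1:2, 10), rep(c(2, 8), 10))
  expect_null(res$odds_ratio)
  expect_null(res$kruskal)
  expect_true(length(res$warnings) >= 1)
  expect_identical(sum(res$groups$n), 20L)
})

test_that("severity drives a positive severe-NIHSS association in simulated cohorts", {
  co <- generate_cohort(cohort_params(n_patients = 2000, seed = 3))
  totals <- cohort_totals(co)[, 1]
  comp <- co$companions
  nihss <- comp[comp$scale == "NIHSS" & comp$day == 1, ]
  v <- nihss$value[match(co$raters$patient_id, nihss$patient_id)]
  res <- threshold_analysis(totals, v)
  expect_gt(res$odds_ratio$or, 1)
  expect_gt(unname(res$kruskal$statistic), 0)
})

test_that("the validity panel reports eight correlations with the expected signs", {
  co <- generate_cohort(cohort_params(n_patients = 2000, seed = 1))
  panel <- validity_report(co)
  expect_identical(nrow(panel), 8L)
  expect_identical(panel$scale,
                   c("NIHSS", "Barthel", "mRS", "GCS", "IVBSS",
                     "NIHSS", "Barthel", "mRS"))
  expect_gt(panel$rho[panel$scale == "NIHSS" & panel$day == 1], 0.7)
  expect_lt(panel$rho[panel$scale == "Barthel" & panel$day == 1], 0)
  expect_lt(panel$rho[panel$scale == "GCS" & panel$day == 1], 0)
  expect_gt(panel$rho[panel$scale == "NIHSS" & panel$day == 90], 0)
})

test_that("a strictly monotone hand-built cohort yields perfect panel correlations", {
  items <- aspos_scale()$items
  n <- 6
  ids <- sprintf("P%02d", 1:n)
  # strictly increasing totals 1..6 via the Balance and Strength items
  balance <- c(1, 2, 3, 3, 3, 3)
  strength <- c(0, 0, 0, 1, 2, 3)
  scores <- function(i) {
    s <- setNames(rep(0L, 7), items)
    s["Balance"] <- balance[i]
    s["Strength"] <- strength[i]
    s
  }
  rows <- do.call(rbind, lapply(1:n, function(i) {
    do.call(rbind, lapply(c("day1_r1", "day1_r2", "day1_r3", "day1_retest"),
                          function(tp) {
      data.frame(patient_id = ids[i],
                 rater_id = c(day1_r1 = "R1", day1_r2 = "R2",
                              day1_r3 = "R3", day1_retest = "R1")[[tp]],
                 timepoint = tp, item = items,
                 score = as.integer(scores(i)),
                 stringsAsFactors = FALSE)
    }))
  }))
  comp <- do.call(rbind, lapply(c(1, 90), function(day) {
    rbind(
      data.frame(patient_id = ids, day = day, scale = "NIHSS", value = 1:n),
      data.frame(patient_id = ids, day = day, scale = "Barthel",
                 value = seq(100, 75, by = -5)),
      data.frame(patient_id = ids, day = day, scale = "mRS", value = 0:5),
      data.frame(patient_id = ids, day = day, scale = "GCS",
                 value = 15:10),
      data.frame(patient_id = ids, day = day, scale = "IVBSS", value = 2 * (1:n))
    )
  }))
  co <- as_cohort(rows, comp)
  panel <- validity_report(co)
  expect_true(all(abs(panel$rho) == 1))
  expect_identical(sign(panel$rho[panel$scale %in% c("Barthel", "GCS")]),
                   rep(-1, 3))
})
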