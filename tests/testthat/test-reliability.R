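random_block <- function(seed, n = 7, k = 3) {
  set.seed(seed)
  repeat {
    base <- sample(0:3, n, replace = TRUE)
    block <- sapply(seq_len(k), function(j) {
      pmin(pmax(base + sample(-1:1, n, replace = TRUE), 0), 3)
    })
    if (var(rowMeans(block)) > 0 && sum((block - rowMeans(block))^2) > 0 &&
        !identical(block[, 1], block[, 2])) return(block)
  }
}

test_that("perfect agreement gives a degenerate ICC of 1", {
  block <- cbind(c(0, 1, 2, 3), c(0, 1, 2, 3), c(0, 1, 2, 3))
  r <- icc_two_way(block)
  expect_equal(r$icc, 1)
  expect_true(r$degenerate)
  expect_true(is.na(r$ci_low) && is.na(r$ci_high))
})

test_that("ICC matches the aov-based oracle on fixed and random blocks", {
  fixed <- matrix(c(0, 1, 0,
                    2, 2, 3,
                    1, 1, 1,
                    3, 2, 3,
                    0, 0, 1), nrow = 5, byrow = TRUE)
  expect_equal(icc_two_way(fixed)$icc, o_icc(fixed, "agreement"),
               tolerance = 1e-12)
  expect_equal(icc_two_way(fixed, type = "consistency")$icc,
               o_icc(fixed, "consistency"), tolerance = 1e-12)
  for (s in 1:10) {
    b <- random_block(s)
    expect_equal(icc_two_way(b)$icc, o_icc(b, "agreement"),
                 tolerance = 1e-10)
  }
})

test_that("ICC point estimate and interval reproduce an independent reference", {
  # expected values computed with an external two-way mixed-model reference
  # implementation on this exact block
  block <- matrix(c(0, 1, 0,
                    2, 2, 3,
                    1, 1, 1,
                    3, 2, 3,
                    0, 0, 1,
                    2, 3, 2), ncol = 3, byrow = TRUE)
  r <- icc_two_way(block)
  expect_equal(r$icc, 0.789915966387, tolerance = 1e-9)
  expect_equal(r$ci_low, 0.40, tolerance = 0.02)
  expect_equal(r$ci_high, 0.96, tolerance = 0.02)
  rc <- icc_two_way(block, type = "consistency")
  expect_equal(rc$icc, 0.776859504132, tolerance = 1e-9)
  expect_equal(rc$ci_low, 0.36, tolerance = 0.02)
  expect_equal(rc$ci_high, 0.96, tolerance = 0.02)
})

test_that("a systematic rater shift lowers agreement ICC below consistency ICC", {
  b <- random_block(4, n = 10)
  b[, 3] <- pmin(b[, 3] + 2, 5)  # constant offset for one rater
  agree <- icc_two_way(b)$icc
  consist <- icc_two_way(b, type = "consistency")$icc
  expect_lt(agree, consist)
  expect_equal(agree, o_icc(b, "agreement"), tolerance = 1e-10)
})

test_that("ICC is invariant to common shifts and positive rescaling", {
  b <- random_block(6)
  r0 <- icc_two_way(b)$icc
  expect_equal(icc_two_way(b + 10)$icc, r0, tolerance = 1e-12)
  expect_equal(icc_two_way(b * 2.5)$icc, r0, tolerance = 1e-12)
  expect_error(icc_two_way(matrix(c(0, 1, 0, 1, 0, 1), 3, 2, byrow = TRUE)),
               "between-patient")
})

test_that("weighted kappa handles the canonical limiting cases", {
  x <- c(0, 1, 2, 2, 1, 0, 2)
  expect_equal(weighted_kappa(x, x)$kappa, 1)
  expect_equal(weighted_kappa(c(0, 1, 0, 1), c(1, 0, 1, 0))$kappa, -1)
  expect_error(weighted_kappa(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("weighted kappa matches the disagreement-form oracle", {
  x10 <- c(0, 1, 1, 0, 1, 0, 0, 1, 1, 0)
  y10 <- c(0, 1, 0, 0, 1, 1, 0, 1, 1, 0)
  expect_equal(weighted_kappa(x10, y10)$kappa, o_kappa(x10, y10),
               tolerance = 1e-12)
  for (s in 1:12) {
    set.seed(s)
    x <- sample(0:3, 15, replace = TRUE)
    y <- pmin(pmax(x + sample(-1:1, 15, replace = TRUE), 0), 3)
    if (length(unique(c(x, y))) < 2) next
    for (w in c("quadratic", "linear")) {
      expect_equal(weighted_kappa(x, y, weights = w)$kappa,
                   o_kappa(x, y, weights = w), tolerance = 1e-10)
    }
  }
})

test_that("kappa and its standard error reproduce an independent reference", {
  # expected values computed with an external weighted-kappa reference
  # implementation (Fleiss-Cohen-Everitt variance) on these exact pairs
  k1 <- weighted_kappa(c(0, 1, 2, 2, 3, 0, 1, 3, 2, 1),
                       c(0, 1, 2, 1, 3, 0, 2, 3, 2, 1))
  expect_equal(k1$kappa, 0.904761904762, tolerance = 1e-10)
  expect_equal(k1$se, 0.076158075391, tolerance = 1e-9)
  k2 <- weighted_kappa(c(0, 0, 1, 2, 2, 3, 3, 1, 0, 2, 1, 3),
                       c(0, 1, 1, 2, 3, 3, 2, 1, 0, 2, 1, 2))
  expect_equal(k2$kappa, 0.846153846154, tolerance = 1e-10)
  expect_equal(k2$se, 0.066419953611, tolerance = 1e-9)
})

test_that("weighted kappa agrees with exhaustive evaluation on all tiny blocks", {
  # every possible 2-patient, 2-rater block scored 0-2
  grid <- expand.grid(x1 = 0:2, x2 = 0:2, y1 = 0:2, y2 = 0:2)
  checked <- 0
  for (i in seq_len(nrow(grid))) {
    x <- c(grid$x1[i], grid$x2[i])
    y <- c(grid$y1[i], grid$y2[i])
    if (length(unique(c(x, y))) < 2) next
    mine <- tryCatch(weighted_kappa(x, y)$kappa, error = function(e) NA)
    theirs <- o_kappa(x, y)
    if (!is.na(mine) && is.finite(theirs)) {
      expect_equal(mine, theirs, tolerance = 1e-10)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 50)
})

test_that("Bland-Altman statistics follow their definitions", {
  # no disagreement at all
  z <- bland_altman(c(2, 3, 4, 5), c(2, 3, 4, 5))
  expect_equal(z$cr, 0)
  expect_equal(z$loa_low, 0)
  expect_equal(z$loa_high, 0)
  expect_identical(z$n_outside, 0L)

  # alternating unit disagreement: sd = sqrt(4/3), cr = 1.96 * sd
  ba <- bland_altman(c(3, 2, 4, 2), c(2, 3, 3, 3))
  expect_equal(ba$sd_diff, sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(ba$cr, 1.96 * sqrt(4 / 3), tolerance = 1e-4)
  expect_equal(ba$mean_diff, 0)

  # swapping the pair order negates the mean and limits, cr unchanged
  sw <- bland_altman(c(2, 3, 3, 3), c(3, 2, 4, 2))
  expect_equal(sw$mean_diff, -ba$mean_diff)
  expect_equal(sw$loa_low, -ba$loa_high)
  expect_equal(sw$loa_high, -ba$loa_low)
  expect_equal(sw$cr, ba$cr)
  expect_true(ba$loa_low <= ba$mean_diff && ba$mean_diff <= ba$loa_high)
})

test_that("the reliability table mirrors a zero-noise cohort with perfect scores", {
  co <- generate_cohort(cohort_params(n_patients = 126, seed = 2,
                                      rater_disagreement = 0,
                                      retest_disagreement = 0))
  rt <- reliability_table(co)
  expect_identical(nrow(rt), 7L)
  expect_identical(rt$item, aspos_scale()$items)
  defined <- !is.na(rt$icc_inter)
  expect_true(all(rt$icc_inter[defined] == 1))
  expect_true(all(rt$inter_degenerate[defined]))
  expect_true(all(rt$kappa[!is.na(rt$kappa)] == 1))
})

test_that("quadratic kappa tracks the agreement ICC on moderately noisy data", {
  co <- generate_cohort(cohort_params(n_patients = 600, seed = 10,
                                      rater_disagreement = 0.05,
                                      retest_disagreement = 0.05))
  rt <- reliability_table(co)
  ok <- !is.na(rt$kappa) & !is.na(rt$icc_intra)
  expect_true(all(abs(rt$kappa[ok] - rt$icc_intra[ok]) < 0.05))
})
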