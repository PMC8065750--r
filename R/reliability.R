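# Inter- and intra-rater reliability: two-way single-measure ICC with
# F-based confidence intervals, weighted Cohen's kappa with the large-sample
# (Fleiss-Cohen-Everitt) variance, and Bland-Altman repeatability of the
# total score.

#' Two-way single-measure intraclass correlation
#'
#' Computes ICC from the two-way ANOVA mean squares of a complete
#' patients x raters block. The default, `type = "agreement"`, is ICC(2,1):
#' two-way random effects, absolute agreement, single rater — the strictest
#' common form and the standard choice when trained raters are regarded as
#' interchangeable. `type = "consistency"` ignores systematic rater offsets.
#'
#' When every patient's raters agree exactly while patients differ, the
#' block carries no residual variance: the estimate is reported as 1 and
#' flagged `degenerate` with no confidence interval (the F construction is
#' undefined), mirroring how such rows are conventionally reported.
#'
#' @param block numeric matrix, patients in rows, raters (or occasions) in
#'   columns; complete, `n >= 3`, `k >= 2`.
#' @param type `"agreement"` (ICC(2,1), default) or `"consistency"`.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return An `icc_result`: list with `icc`, `ci_low`, `ci_high`,
#'   `degenerate`, the mean squares (`msr` rows, `msc` columns, `mse`
#'   residual) and the design sizes.
#' @references McGraw, K.O. & Wong, S.P. (1996) Forming inferences about
#'   some intraclass correlation coefficients. Psychological Methods 1:30-46.
#' @export
icc_two_way <- function(block, type = c("agreement", "consistency"),
                        conf_level = 0.95) {
  type <- match.arg(type)
  block <- as.matrix(block)
  if (anyNA(block)) stop("ratings block must be complete", call. = FALSE)
  n <- nrow(block)
  k <- ncol(block)
  if (n < 3 || k < 2) {
    stop("need at least 3 patients and 2 raters", call. = FALSE)
  }

  row_means <- rowMeans(block)
  col_means <- colMeans(block)
  grand <- mean(block)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((block - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))

  if (msr == 0) {
    stop("zero between-patient variance; ICC undefined", call. = FALSE)
  }

  degenerate <- FALSE
  if (ss_err <= .Machine$double.eps * ss_tot && ss_cols <= .Machine$double.eps * ss_tot) {
    # perfect agreement: all raters identical within every patient
    icc <- 1
    degenerate <- TRUE
    ci <- c(NA_real_, NA_real_)
  } else if (type == "agreement") {
    icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    ci <- icc_agreement_ci(icc, msr, msc, mse, n, k, conf_level)
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    ci <- icc_consistency_ci(msr, mse, n, k, conf_level)
  }

  structure(
    list(icc = icc, ci_low = ci[1], ci_high = ci[2], degenerate = degenerate,
         type = type, msr = msr, msc = msc, mse = mse, n = n, k = k,
         conf_level = conf_level),
    class = "icc_result"
  )
}

# McGraw & Wong (1996) interval for ICC(A,1)
icc_agreement_ci <- function(icc, msr, msc, mse, n, k, conf_level) {
  a <- (1 - conf_level) / 2
  fj <- msc / mse
  vn <- (k - 1) * (n - 1) *
    (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
  vd <- (n - 1) * k^2 * icc^2 * fj^2 +
    (n * (1 + (k - 1) * icc) - k * icc)^2
  v <- vn / vd
  fl <- stats::qf(1 - a, n - 1, v)
  fu <- stats::qf(1 - a, v, n - 1)
  low <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  high <- n * (fu * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fu * msr)
  c(low, high)
}

icc_consistency_ci <- function(msr, mse, n, k, conf_level) {
  a <- (1 - conf_level) / 2
  f <- msr / mse
  df2 <- (n - 1) * (k - 1)
  fl <- f / stats::qf(1 - a, n - 1, df2)
  fu <- f * stats::qf(1 - a, df2, n - 1)
  c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC (%s, single measure): %.3f", x$type, x$icc))
  if (x$degenerate) {
    cat("  [degenerate: perfect agreement, CI omitted]\n")
  } else {
    cat(sprintf("  %g%% CI %.3f-%.3f\n", 100 * x$conf_level,
                x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' Weighted Cohen's kappa
#'
#' Chance-corrected agreement between two paired ordinal ratings with
#' distance-based disagreement weights:
#' `kappa = 1 - sum(w * O) / sum(w * E)` where `O` is the observed
#' cross-tabulation, `E` the product-marginal expectation and `w` the
#' quadratic (default) or linear disagreement weights over the category
#' range. The confidence interval uses the large-sample variance of
#' Fleiss, Cohen and Everitt (1969).
#'
#' @param x,y equal-length integer score vectors on a shared ordinal range.
#' @param weights `"quadratic"` (default) or `"linear"`.
#' @param categories ordered category values spanning the shared range;
#'   defaults to `min:max` of the pooled observed scores.
#' @param conf_level confidence level (default 0.95).
#' @return A `kappa_result`: list with `kappa`, `ci_low`, `ci_high`, `se`,
#'   `weights` and `n`.
#' @export
weighted_kappa <- function(x, y, weights = c("quadratic", "linear"),
                           categories = NULL, conf_level = 0.95) {
  weights <- match.arg(weights)
  if (length(x) != length(y) || length(x) == 0) {
    stop("x and y must be non-empty and of equal length", call. = FALSE)
  }
  if (is.null(categories)) {
    categories <- seq(min(c(x, y)), max(c(x, y)))
  }
  if (length(categories) < 2) {
    stop("degenerate marginals: only one category present; kappa undefined",
         call. = FALSE)
  }
  n <- length(x)
  fx <- factor(x, levels = categories)
  fy <- factor(y, levels = categories)
  if (anyNA(fx) || anyNA(fy)) {
    stop("scores outside the declared categories", call. = FALSE)
  }
  p <- table(fx, fy) / n
  d <- abs(outer(seq_along(categories), seq_along(categories), "-"))
  dmax <- max(d)
  w <- if (weights == "quadratic") 1 - (d / dmax)^2 else 1 - d / dmax

  pi_ <- rowSums(p)
  pj_ <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(pi_, pj_))
  if (1 - pe <= .Machine$double.eps) {
    stop("degenerate marginals: chance agreement is 1; kappa undefined",
         call. = FALSE)
  }
  kappa <- (po - pe) / (1 - pe)

  # Fleiss, Cohen & Everitt (1969) asymptotic variance (non-null)
  wi <- as.vector(w %*% pj_)  # E_j[w_ij] per row category
  wj <- as.vector(pi_ %*% w)  # E_i[w_ij] per column category
  term <- (w - outer(wi, wj, "+") * (1 - kappa))^2
  var_k <- (sum(p * term) - (kappa - pe * (1 - kappa))^2) /
    (n * (1 - pe)^2)
  se <- sqrt(max(var_k, 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(
    list(kappa = kappa, se = se,
         ci_low = max(-1, kappa - z * se), ci_high = min(1, kappa + z * se),
         weights = weights, categories = categories, n = n,
         conf_level = conf_level),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Weighted kappa (%s weights): %.3f  %g%% CI %.3f-%.3f  (n = %d)\n",
              x$weights, x$kappa, 100 * x$conf_level, x$ci_low, x$ci_high,
              x$n))
  invisible(x)
}

#' Bland-Altman repeatability analysis
#'
#' For paired total scores (two raters or two occasions), analyses the
#' per-pair differences `d = first - second`: mean difference, SD of
#' differences (n-1 denominator), limits of agreement
#' `mean +/- 1.96 * sd`, and the coefficient of repeatability
#' `CR = 1.96 * sd`. Confidence intervals: each limit via
#' `SE = sd * sqrt(3/n)`; the CR via the chi-square interval for a standard
#' deviation, scaled by 1.96. The sign of the differences follows the
#' (arbitrary) pair order.
#'
#' @param first,second numeric vectors of paired scores (`n >= 3`).
#' @param conf_level confidence level (default 0.95).
#' @return A `bland_altman` object with `mean_diff`, `sd_diff`, `cr`,
#'   `loa_low`/`loa_high` with their CIs, `cr_ci`, `n_outside` (pairs beyond
#'   the limits), and the per-pair `means`/`diffs` for plotting.
#' @export
bland_altman <- function(first, second, conf_level = 0.95) {
  if (length(first) != length(second) || length(first) < 3) {
    stop("need at least 3 complete pairs", call. = FALSE)
  }
  d <- first - second
  n <- length(d)
  mean_diff <- mean(d)
  sd_diff <- stats::sd(d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  cr <- z * sd_diff
  loa_low <- mean_diff - cr
  loa_high <- mean_diff + cr
  se_limit <- sd_diff * sqrt(3 / n)
  a <- (1 - conf_level) / 2
  sd_ci <- sd_diff * sqrt((n - 1) / stats::qchisq(c(1 - a, a), n - 1))
  structure(
    list(mean_diff = mean_diff, sd_diff = sd_diff, cr = cr,
         loa_low = loa_low, loa_high = loa_high,
         loa_low_ci = loa_low + c(-1, 1) * z * se_limit,
         loa_high_ci = loa_high + c(-1, 1) * z * se_limit,
         cr_ci = z * sd_ci,
         n_outside = sum(d < loa_low | d > loa_high),
         n = n, means = (first + second) / 2, diffs = d,
         conf_level = conf_level),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman on %d pairs\n", x$n))
  cat(sprintf("  mean difference %.3f, SD %.3f\n", x$mean_diff, x$sd_diff))
  cat(sprintf("  CR %.2f (%g%% CI %.2f-%.2f)\n", x$cr,
              100 * x$conf_level, x$cr_ci[1], x$cr_ci[2]))
  cat(sprintf("  limits of agreement %.2f to %.2f; %d pair(s) outside\n",
              x$loa_low, x$loa_high, x$n_outside))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Mean of each pair against its difference, with the mean difference, the
#' limits of agreement and the regression of differences on means.
#'
#' @param x a [bland_altman()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs,
                 xlab = "Mean of paired totals",
                 ylab = "Difference between paired totals",
                 pch = 16, ...)
  graphics::abline(h = x$mean_diff, col = "blue")
  graphics::abline(h = c(x$loa_low, x$loa_high), col = "red", lty = 2)
  fit <- stats::lm(x$diffs ~ x$means)
  graphics::abline(fit, col = "darkorange", lty = 3)
  invisible(x)
}

#' Per-item reliability table
#'
#' Reproduces the reliability panel of a multi-rater validation study: for
#' each item, the inter-rater ICC across the three day-1 raters, the
#' intra-rater (test-retest) ICC between the retest rater's two occasions,
#' and the intra-rater weighted kappa, each with its confidence interval.
#' Items whose statistic is undefined on the given cohort (e.g. a score
#' that never varies) are reported as `NA` with a note.
#'
#' @param cohort an `aspos_cohort`.
#' @param icc_type passed to [icc_two_way()].
#' @param kappa_weights passed to [weighted_kappa()].
#' @param conf_level confidence level (default 0.95).
#' @return A data frame (class `reliability_table`) with one row per item:
#'   inter-rater ICC and CI, intra-rater ICC and CI, weighted kappa and CI,
#'   degeneracy flags and notes.
#' @export
reliability_table <- function(cohort, icc_type = "agreement",
                              kappa_weights = "quadratic",
                              conf_level = 0.95) {
  items <- dimnames(cohort$scores)[[2]]
  n <- dim(cohort$scores)[1]
  retest_slot <- cohort$raters$retest_slot
  rows <- lapply(items, function(it) {
    inter_block <- cohort$scores[, it, 1:3]
    test <- cohort$scores[cbind(seq_len(n), match(it, items), retest_slot)]
    retest <- cohort$scores[, it, 4]
    intra_block <- cbind(test, retest)

    note <- character(0)
    inter <- try_stat(icc_two_way(inter_block, type = icc_type,
                                  conf_level = conf_level))
    intra <- try_stat(icc_two_way(intra_block, type = icc_type,
                                  conf_level = conf_level))
    kap <- try_stat(weighted_kappa(test, retest, weights = kappa_weights,
                                   conf_level = conf_level))
    if (is.null(inter)) note <- c(note, "inter-rater ICC undefined")
    if (is.null(intra)) note <- c(note, "intra-rater ICC undefined")
    if (is.null(kap)) note <- c(note, "kappa undefined")
    data.frame(
      item = it,
      icc_inter = inter$icc %||% NA_real_,
      icc_inter_low = inter$ci_low %||% NA_real_,
      icc_inter_high = inter$ci_high %||% NA_real_,
      inter_degenerate = inter$degenerate %||% NA,
      icc_intra = intra$icc %||% NA_real_,
      icc_intra_low = intra$ci_low %||% NA_real_,
      icc_intra_high = intra$ci_high %||% NA_real_,
      intra_degenerate = intra$degenerate %||% NA,
      kappa = kap$kappa %||% NA_real_,
      kappa_low = kap$ci_low %||% NA_real_,
      kappa_high = kap$ci_high %||% NA_real_,
      note = paste(note, collapse = "; "),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("reliability_table", "data.frame")
  out
}

try_stat <- function(expr) {
  tryCatch(expr, error = function(e) NULL)
}
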