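# Construct and predictive validity: Spearman rank correlation,
# Kruskal-Wallis and Mann-Whitney comparisons, and the severity-threshold
# odds ratio with the Haldane-Anscombe zero-cell correction.

#' Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation with midranks for ties; the two-sided p-value uses the
#' t approximation with n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors, `n >= 4`, both non-constant.
#' @return List with `rho`, `p_value` and `n`.
#' @export
spearman_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 4) {
    stop("need at least 4 complete pairs", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("constant variable; rank correlation undefined", call. = FALSE)
  }
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Kruskal-Wallis rank test across severity groups
#'
#' Tie-corrected H with a chi-square p-value on g - 1 degrees of freedom
#' (delegated to [stats::kruskal.test()]); the fully tied case (all
#' observations identical) is reported as H = 0, p = 1 rather than as
#' undefined.
#'
#' @param groups list of numeric vectors, one per group (each non-empty,
#'   total n >= 5).
#' @return A `group_comparison` list: `statistic` (H), `df`, `p_value`,
#'   per-group `medians` and `n`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    stop("need at least two non-empty groups", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  if (length(values) < 5) stop("total n must be at least 5", call. = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(values)) == 1) {
    h <- 0
    p <- 1
    df <- length(groups) - 1
  } else {
    kt <- stats::kruskal.test(values, g)
    h <- unname(kt$statistic)
    p <- kt$p.value
    df <- unname(kt$parameter)
  }
  structure(
    list(statistic = c(H = h), df = df, p_value = p,
         medians = vapply(groups, stats::median, numeric(1)),
         n = lengths(groups), method = "Kruskal-Wallis"),
    class = "group_comparison"
  )
}

#' Mann-Whitney U test
#'
#' U is computed from the rank sum with midranks for ties. When both groups
#' have at most 8 observations the two-sided p-value is obtained by exact
#' enumeration over all group labelings (valid under ties); otherwise the
#' tie-corrected normal approximation (without continuity correction) is
#' used, so that for two groups the squared z statistic coincides with the
#' Kruskal-Wallis H.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return A `group_comparison` list: `statistic` (U for the first group),
#'   `p_value`, per-group `medians`, `n` and the method used.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (n1 <= 8 && n2 <= 8) {
    method <- "exact enumeration"
    combos <- utils::combn(n1 + n2, n1)
    u_all <- apply(combos, 2, function(idx) {
      sum(r[idx]) - n1 * (n1 + 1) / 2
    })
    mu <- n1 * n2 / 2
    # two-sided: as extreme or more extreme in distance from the mean
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
  } else {
    method <- "normal approximation"
    nn <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    var_u <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    if (var_u == 0) {
      p <- 1
    } else {
      z <- (u - n1 * n2 / 2) / sqrt(var_u)
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  structure(
    list(statistic = c(U = u), p_value = min(p, 1),
         medians = c(stats::median(x), stats::median(y)),
         n = c(n1, n2), method = paste("Mann-Whitney,", method)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: %s = %.4f, p = %.4g (n = %s)\n",
              x$method %||% "rank test", names(x$statistic), x$statistic,
              x$p_value, paste(x$n, collapse = "/")))
  invisible(x)
}

#' Odds ratio with Haldane-Anscombe zero-cell correction
#'
#' Cross-product odds ratio of a 2x2 table with a Wald confidence interval
#' on the log scale. When any cell is zero (e.g. complete separation of the
#' outcome between severity groups, which leaves plain
#' logistic-regression maximum likelihood unidentified), 0.5 is added to
#' every cell before estimation and the result is flagged
#' `correction_applied`.
#'
#' @param a,b,c,d cell counts: `a`/`b` outcome present/absent in the first
#'   group, `c`/`d` in the second; alternatively `a` may be a 2x2 matrix
#'   (rows = groups, columns = outcome present/absent).
#' @param conf_level confidence level (default 0.95).
#' @return An `odds_ratio` object: `or`, `ci_low`, `ci_high`, `p_value`
#'   (Wald), `correction_applied` and the (corrected) cells.
#' @examples
#' odds_ratio(10, 5, 2, 20)  # OR = 20
#' @export
odds_ratio <- function(a, b = NULL, c = NULL, d = NULL, conf_level = 0.95) {
  # the argument named `c` shadows base::c inside this function
  if (is.matrix(a)) {
    stopifnot(identical(dim(a), base::c(2L, 2L)))
    cells <- base::c(a = a[1, 1], b = a[1, 2], c = a[2, 1], d = a[2, 2])
  } else {
    cells <- base::c(a = a, b = b, c = c, d = d)
  }
  if (any(cells < 0) || sum(cells) == 0) {
    stop("cell counts must be non-negative with a positive total",
         call. = FALSE)
  }
  if (cells["a"] + cells["b"] == 0 || cells["c"] + cells["d"] == 0 ||
      cells["a"] + cells["c"] == 0 || cells["b"] + cells["d"] == 0) {
    stop("a row or column of the table is empty; odds ratio undefined",
         call. = FALSE)
  }
  correction <- any(cells == 0)
  cc <- if (correction) cells + 0.5 else cells
  or <- (cc["a"] * cc["d"]) / (cc["b"] * cc["c"])
  se <- sqrt(sum(1 / cc))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- exp(log(or) + base::c(-1, 1) * z * se)
  wald_z <- log(or) / se
  structure(
    list(or = unname(or), ci_low = unname(ci[1]), ci_high = unname(ci[2]),
         p_value = 2 * stats::pnorm(-abs(unname(wald_z))),
         correction_applied = correction, cells = cc,
         conf_level = conf_level),
    class = "odds_ratio"
  )
}

#' @export
print.odds_ratio <- function(x, ...) {
  cat(sprintf("OR = %.2f  %g%% CI %.2f-%.2f  p = %.4g%s\n", x$or,
              100 * x$conf_level, x$ci_low, x$ci_high, x$p_value,
              if (x$correction_applied)
                "  [Haldane-Anscombe correction applied]" else ""))
  invisible(x)
}

#' Severity-threshold analysis
#'
#' Partitions patients by [severity_group()] of their total score, counts
#' cases at or above the NIHSS severity cutoff per group, compares NIHSS
#' across the groups by Kruskal-Wallis, and estimates the odds ratio of a
#' severe NIHSS (>= cutoff) for the INTERMEDIATE versus the LOW group with
#' the zero-cell-safe [odds_ratio()].
#'
#' @param totals integer vector of day-1 total scores.
#' @param nihss paired NIHSS values.
#' @param cutoff NIHSS severity cutoff (default 6, the conventional
#'   thrombectomy-consideration threshold).
#' @param scale an `aspos_scale`.
#' @return A `threshold_analysis` object: `groups` (data frame with `group`,
#'   `n`, `pct`, `cases`), `kruskal` (or `NULL` when fewer than two groups
#'   are occupied), `odds_ratio` (`NULL` when LOW or INTERMEDIATE is
#'   empty), `cutoff`, and any `warnings` recorded for empty groups.
#' @export
threshold_analysis <- function(totals, nihss, cutoff = 6,
                               scale = aspos_scale()) {
  if (length(totals) != length(nihss)) {
    stop("totals and nihss must be paired", call. = FALSE)
  }
  grp <- severity_group(totals, scale)
  tab <- data.frame(
    group = levels(grp),
    n = as.integer(table(grp)),
    pct = 100 * as.integer(table(grp)) / length(grp),
    cases = vapply(levels(grp),
                   function(g) sum(nihss[grp == g] >= cutoff), numeric(1)),
    stringsAsFactors = FALSE
  )
  warnings <- character(0)
  occupied <- tab$group[tab$n > 0]
  empty <- setdiff(levels(grp), occupied)
  if (length(empty)) {
    warnings <- c(warnings,
                  paste("empty severity group(s) dropped:",
                        paste(empty, collapse = ", ")))
  }

  kw <- NULL
  if (length(occupied) >= 2) {
    kw <- kruskal_wallis(split(nihss, droplevels(grp)))
  } else {
    warnings <- c(warnings, "fewer than two occupied groups; Kruskal-Wallis skipped")
  }

  or <- NULL
  if (all(c("LOW", "INTERMEDIATE") %in% occupied)) {
    i_int <- tab$group == "INTERMEDIATE"
    i_low <- tab$group == "LOW"
    or <- tryCatch(
      odds_ratio(tab$cases[i_int], tab$n[i_int] - tab$cases[i_int],
                 tab$cases[i_low], tab$n[i_low] - tab$cases[i_low]),
      error = function(e) {
        warnings <<- c(warnings, paste("odds ratio undefined:",
                                       conditionMessage(e)))
        NULL
      })
  } else {
    warnings <- c(warnings,
                  "LOW or INTERMEDIATE group empty; odds ratio skipped")
  }

  structure(
    list(groups = tab, kruskal = kw, odds_ratio = or, cutoff = cutoff,
         warnings = warnings),
    class = "threshold_analysis"
  )
}

#' @export
print.threshold_analysis <- function(x, ...) {
  cat("Severity-threshold analysis (NIHSS cutoff", x$cutoff, ")\n")
  tab <- x$groups
  tab$pct <- sprintf("%.1f", tab$pct)
  print(tab, row.names = FALSE)
  if (!is.null(x$kruskal)) print(x$kruskal)
  if (!is.null(x$odds_ratio)) {
    cat("INTERMEDIATE vs LOW, NIHSS >=", x$cutoff, ": ")
    print(x$odds_ratio)
  }
  for (w in x$warnings) cat("warning:", w, "\n")
  invisible(x)
}

#' Construct and predictive validity panel
#'
#' Spearman correlations of the day-1 total score (designated rater)
#' against each companion scale: NIHSS, Barthel, mRS, GCS and IVBSS at day
#' 1 (construct validity) and NIHSS, Barthel and mRS at day 90 (predictive
#' validity) — eight correlations in all. Signs are reported as computed
#' (Barthel and GCS run opposite to severity).
#'
#' @param cohort an `aspos_cohort`.
#' @param rater which day-1 assessment provides the totals (see
#'   [item_matrix()]).
#' @return Data frame (class `validity_panel`) with `scale`, `day`, `rho`,
#'   `p_value`, `n`.
#' @export
validity_report <- function(cohort, rater = "first") {
  occ <- c(first = 1L, second = 2L, third = 3L)[[rater]]
  totals <- cohort_totals(cohort)[, occ]
  ids <- cohort$raters$patient_id
  panels <- rbind(
    data.frame(scale = c("NIHSS", "Barthel", "mRS", "GCS", "IVBSS"), day = 1),
    data.frame(scale = c("NIHSS", "Barthel", "mRS"), day = 90)
  )
  rows <- lapply(seq_len(nrow(panels)), function(i) {
    comp <- cohort$companions
    sel <- comp[comp$scale == panels$scale[i] & comp$day == panels$day[i], ]
    v <- sel$value[match(ids, sel$patient_id)]
    st <- spearman_test(totals, v)
    data.frame(scale = panels$scale[i], day = panels$day[i],
               rho = st$rho, p_value = st$p_value, n = st$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("validity_panel", "data.frame")
  out
}

#' Published severity partition of the original validation cohort
#'
#' The group breakdown reported for the original ASPOS validation cohort
#' (n = 126): patients per severity group and the number in each group with
#' NIHSS of at least 6 points. Useful as a worked fixture for
#' [severity_group()] percentages and the zero-cell-safe [odds_ratio()].
#'
#' @return Data frame with `group`, `n` and `cases` (NIHSS >= 6).
#' @export
published_severity_partition <- function() {
  data.frame(
    group = c("LOW", "INTERMEDIATE", "HIGH"),
    n = c(86L, 9L, 31L),
    cases = c(0L, 5L, 26L),
    stringsAsFactors = FALSE
  )
}
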