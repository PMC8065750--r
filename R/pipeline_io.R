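# File I/O and the end-to-end validation run.
#
# Canonical on-disk format is long (one row per item score): a
# non-assessable item is represented by absence of its row. All tables are
# comma-separated UTF-8 text with a header row.

#' Read and validate a long-format ratings table
#'
#' Expects columns `patient_id`, `rater_id`, `timepoint`, `item`, `score`.
#' Unknown items, scores outside the item's range, invalid timepoints and
#' duplicate (patient, rater, timepoint, item) rows are rejected with the
#' offending row numbers (header = row 1).
#'
#' @param path CSV file path.
#' @param scale an `aspos_scale` used for validation.
#' @return The validated ratings data frame.
#' @export
read_ratings <- function(path, scale = aspos_scale()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "rater_id", "timepoint", "item", "score")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("ratings file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rowno <- seq_len(nrow(df)) + 1L  # file row numbers including header

  bad_item <- !df$item %in% scale$items
  if (any(bad_item)) {
    i <- which(bad_item)[1]
    stop("row ", rowno[i], ": unknown item '", df$item[i], "'",
         call. = FALSE)
  }
  bad_tp <- !df$timepoint %in% c("day1_r1", "day1_r2", "day1_r3",
                                 "day1_retest")
  if (any(bad_tp)) {
    i <- which(bad_tp)[1]
    stop("row ", rowno[i], ": invalid timepoint '", df$timepoint[i], "'",
         call. = FALSE)
  }
  maxs <- scale$max[df$item]
  bad_score <- is.na(df$score) | df$score < 0 | df$score > maxs
  if (any(bad_score)) {
    i <- which(bad_score)[1]
    stop("row ", rowno[i], ": score ", df$score[i], " out of range 0-",
         maxs[i], " for item '", df$item[i], "'", call. = FALSE)
  }
  key <- paste(df$patient_id, df$rater_id, df$timepoint, df$item, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    i <- which(dup)[1]
    first <- which(key == key[i])[1]
    stop("row ", rowno[i], ": duplicate of row ", rowno[first],
         " (same patient, rater, timepoint and item)", call. = FALSE)
  }
  df
}

#' @rdname read_ratings
#' @param ratings long-format ratings data frame; rows with `NA` score
#'   (non-assessable) are dropped on write.
#' @export
write_ratings <- function(ratings, path) {
  out <- ratings[!is.na(ratings$score), ]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the companion-scale table
#'
#' Long format with columns `patient_id`, `day` (1 or 90), `scale`
#' (NIHSS, mRS, Barthel, GCS, IVBSS) and `value`.
#'
#' @param path CSV file path.
#' @return `read_companions` returns the validated data frame.
#' @export
read_companions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("patient_id", "day", "scale", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("companions file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ranges <- list(NIHSS = c(0, 42), mRS = c(0, 6), Barthel = c(0, 100),
                 GCS = c(3, 15), IVBSS = c(0, Inf))
  rowno <- seq_len(nrow(df)) + 1L
  bad_scale <- !df$scale %in% names(ranges)
  if (any(bad_scale)) {
    i <- which(bad_scale)[1]
    stop("row ", rowno[i], ": unknown scale '", df$scale[i], "'",
         call. = FALSE)
  }
  lo <- vapply(df$scale, function(s) ranges[[s]][1], numeric(1))
  hi <- vapply(df$scale, function(s) ranges[[s]][2], numeric(1))
  bad <- is.na(df$value) | df$value < lo | df$value > hi
  if (any(bad)) {
    i <- which(bad)[1]
    stop("row ", rowno[i], ": value ", df$value[i], " out of range for ",
         df$scale[i], call. = FALSE)
  }
  df$value <- as.numeric(df$value)
  df
}

#' @rdname read_companions
#' @param companions companion-scale data frame to write.
#' @export
write_companions <- function(companions, path) {
  utils::write.csv(companions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble a cohort object from long-format tables
#'
#' Rebuilds the internal cohort representation (scores array, rater
#' assignment) from validated ratings and companion tables, e.g. after
#' [read_ratings()]. The retest rater must match one of the patient's three
#' day-1 raters.
#'
#' @param ratings long-format ratings data frame.
#' @param companions long-format companion-scale data frame (optional;
#'   required only for validity analyses).
#' @param scale an `aspos_scale`.
#' @return An `aspos_cohort` (without latent-trait fields).
#' @export
as_cohort <- function(ratings, companions = NULL, scale = aspos_scale()) {
  occasions <- c("day1_r1", "day1_r2", "day1_r3", "day1_retest")
  ids <- unique(ratings$patient_id)
  n <- length(ids)
  scores <- array(NA_integer_, dim = c(n, length(scale$items), 4),
                  dimnames = list(ids, scale$items, occasions))
  idx <- cbind(match(ratings$patient_id, ids),
               match(ratings$item, scale$items),
               match(ratings$timepoint, occasions))
  scores[idx] <- as.integer(ratings$score)

  rater_of <- function(tp) {
    sel <- ratings[ratings$timepoint == tp, c("patient_id", "rater_id")]
    sel <- sel[!duplicated(sel$patient_id), ]
    sel$rater_id[match(ids, sel$patient_id)]
  }
  raters <- data.frame(
    patient_id = ids,
    day1_r1 = rater_of("day1_r1"),
    day1_r2 = rater_of("day1_r2"),
    day1_r3 = rater_of("day1_r3"),
    retest_rater = rater_of("day1_retest"),
    stringsAsFactors = FALSE
  )
  slot_mat <- cbind(raters$day1_r1, raters$day1_r2, raters$day1_r3)
  raters$retest_slot <- vapply(seq_len(n), function(i) {
    match(raters$retest_rater[i], slot_mat[i, ])
  }, integer(1))
  if (anyNA(raters$retest_slot)) {
    bad <- raters$patient_id[which(is.na(raters$retest_slot))[1]]
    stop("retest rater of patient ", bad,
         " is not one of the day-1 raters", call. = FALSE)
  }
  structure(
    list(ratings = ratings, companions = companions, scores = scores,
         raters = raters, theta = NULL, consensus = NULL, params = NULL),
    class = "aspos_cohort"
  )
}

#' Read a cohort previously written with [write_cohort()]
#'
#' @param dir directory containing `ratings.csv` and `companions.csv`.
#' @param scale an `aspos_scale`.
#' @return An `aspos_cohort`.
#' @export
read_cohort <- function(dir, scale = aspos_scale()) {
  ratings <- read_ratings(file.path(dir, "ratings.csv"), scale)
  cpath <- file.path(dir, "companions.csv")
  companions <- if (file.exists(cpath)) read_companions(cpath) else NULL
  as_cohort(ratings, companions, scale)
}

#' Configure a validation run
#'
#' Exactly one input source is active per run: either paths to existing
#' ratings/companion tables, or simulation parameters (the default
#' parameters are used when neither is supplied).
#'
#' @param ratings,companions paths to input tables, or `NULL` to simulate.
#' @param params a [cohort_params()] object, or `NULL` for defaults.
#' @param seed seed controlling simulation and the rater-pair draw.
#' @param rater designated day-1 rater for item analysis and validity
#'   (`"first"`, `"second"` or `"third"`).
#' @param icc_type ICC form (see [icc_two_way()]).
#' @param kappa_weights kappa weighting scheme (see [weighted_kappa()]).
#' @param nihss_cutoff NIHSS severity cutoff for the threshold analysis.
#' @return A `run_config` list.
#' @export
run_config <- function(ratings = NULL, companions = NULL, params = NULL,
                       seed = 1L, rater = "first", icc_type = "agreement",
                       kappa_weights = "quadratic", nihss_cutoff = 6) {
  if (!is.null(ratings) && !is.null(params)) {
    stop("supply either input paths or simulation parameters, not both",
         call. = FALSE)
  }
  structure(
    list(ratings = ratings, companions = companions, params = params,
         seed = as.integer(seed), rater = rater, icc_type = icc_type,
         kappa_weights = kappa_weights, nihss_cutoff = nihss_cutoff),
    class = "run_config"
  )
}

#' Run the complete validation pipeline
#'
#' Simulates or loads a cohort, then runs every stage: item analysis
#' (internal consistency), per-item reliability, Bland-Altman repeatability
#' of the total score between a randomly selected rater pair, the
#' construct/predictive validity panel, and the severity-threshold
#' analysis. Fully deterministic given the configuration seed.
#'
#' @param config a [run_config()].
#' @return A `validation_report`: list with `consistency`, `reliability`,
#'   `bland_altman`, `validity`, `threshold`, `rater_pairs` and
#'   `provenance`.
#' @export
run_full_validation <- function(config = run_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  cohort <- stage("input", {
    if (!is.null(config$ratings)) {
      as_cohort(read_ratings(config$ratings),
                if (!is.null(config$companions))
                  read_companions(config$companions))
    } else {
      params <- config$params
      if (is.null(params)) params <- cohort_params(seed = config$seed)
      generate_cohort(params)
    }
  })

  consistency <- stage("consistency",
                       item_analysis(item_matrix(cohort, config$rater)))
  reliability <- stage("reliability",
                       reliability_table(cohort, icc_type = config$icc_type,
                                         kappa_weights = config$kappa_weights))
  pairs <- stage("rater_pairs", select_rater_pair(cohort, seed = config$seed))
  ba <- stage("bland_altman", bland_altman(pairs$total_a, pairs$total_b))
  validity <- NULL
  threshold <- NULL
  if (!is.null(cohort$companions)) {
    validity <- stage("validity", validity_report(cohort, config$rater))
    occ <- c(first = 1L, second = 2L, third = 3L)[[config$rater]]
    totals <- cohort_totals(cohort)[, occ]
    comp <- cohort$companions
    nihss <- comp[comp$scale == "NIHSS" & comp$day == 1, ]
    nihss_v <- nihss$value[match(cohort$raters$patient_id, nihss$patient_id)]
    threshold <- stage("threshold",
                       threshold_analysis(totals, nihss_v,
                                          cutoff = config$nihss_cutoff))
  }

  structure(
    list(consistency = consistency, reliability = reliability,
         bland_altman = ba, validity = validity, threshold = threshold,
         rater_pairs = pairs,
         provenance = list(
           seed = config$seed, rater = config$rater,
           icc_type = config$icc_type, kappa_weights = config$kappa_weights,
           nihss_cutoff = config$nihss_cutoff,
           input = if (is.null(config$ratings)) "simulated" else config$ratings,
           package_version = as.character(utils::packageVersion("aspos")))),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("== Validation report (seed", x$provenance$seed, ") ==\n\n")
  print(x$consistency)
  cat("\nPer-item reliability:\n")
  rt <- x$reliability
  show <- data.frame(item = rt$item,
                     icc_inter = round(rt$icc_inter, 2),
                     icc_intra = round(rt$icc_intra, 2),
                     kappa = round(rt$kappa, 2))
  print(show, row.names = FALSE)
  cat("\n")
  print(x$bland_altman)
  if (!is.null(x$validity)) {
    cat("\nValidity panel (Spearman):\n")
    vp <- x$validity
    vp$rho <- round(vp$rho, 3)
    vp$p_value <- signif(vp$p_value, 3)
    print(vp, row.names = FALSE)
  }
  if (!is.null(x$threshold)) {
    cat("\n")
    print(x$threshold)
  }
  invisible(x)
}

#' Write a validation report as delimited text
#'
#' One CSV per sub-report (consistency, reliability, Bland-Altman,
#' validity panel, threshold analysis) plus `provenance.json`. Percentages
#' are written with one decimal; underlying objects keep full precision.
#'
#' @param report a `validation_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_validation_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  cons <- report$consistency
  wr(data.frame(item = c(cons$items$item, "TOTAL"),
                item_rest_r = c(round(cons$items$item_rest_r, 4), NA),
                alpha_if_deleted = c(round(cons$items$alpha_if_deleted, 4), NA),
                alpha = c(rep(NA, nrow(cons$items)), round(cons$alpha, 4))),
     "consistency.csv")
  wr(report$reliability, "reliability.csv")
  ba <- report$bland_altman
  wr(data.frame(mean_diff = ba$mean_diff, sd_diff = ba$sd_diff, cr = ba$cr,
                cr_low = ba$cr_ci[1], cr_high = ba$cr_ci[2],
                loa_low = ba$loa_low, loa_high = ba$loa_high,
                n_outside = ba$n_outside, n = ba$n),
     "bland_altman.csv")
  if (!is.null(report$validity)) wr(report$validity, "validity.csv")
  if (!is.null(report$threshold)) {
    th <- report$threshold
    tab <- th$groups
    tab$pct <- sprintf("%.1f", tab$pct)
    tab$kruskal_H <- if (!is.null(th$kruskal)) th$kruskal$statistic else NA
    tab$kruskal_p <- if (!is.null(th$kruskal)) th$kruskal$p_value else NA
    tab$or <- if (!is.null(th$odds_ratio)) th$odds_ratio$or else NA
    tab$or_low <- if (!is.null(th$odds_ratio)) th$odds_ratio$ci_low else NA
    tab$or_high <- if (!is.null(th$odds_ratio)) th$odds_ratio$ci_high else NA
    wr(tab, "threshold.csv")
  }
  pp <- file.path(dir, "provenance.json")
  jsonlite::write_json(report$provenance, pp, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, pp)
  invisible(paths)
}
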