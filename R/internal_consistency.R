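# Item analysis: Cronbach's alpha, corrected item-rest correlation and
# alpha-if-item-deleted. Sample (n-1) variances are used throughout;
# mixing variance denominators is the most common source of third-decimal
# irreproducibility in alpha.

#' Item-score matrix of one designated rater
#'
#' Extracts the patients x items integer matrix that feeds the item
#' analysis. Which day-1 assessment is used is a study choice; the default
#' is the first randomly selected rater. Patients with any non-assessable
#' item are dropped (complete-case restriction).
#'
#' @param cohort an `aspos_cohort`.
#' @param rater which assessment to use: `"first"`, `"second"`, `"third"`
#'   day-1 rater or `"retest"`.
#' @return Integer matrix, one row per patient, one column per item.
#' @export
item_matrix <- function(cohort,
                        rater = c("first", "second", "third", "retest")) {
  rater <- match.arg(rater)
  occ <- c(first = 1L, second = 2L, third = 3L, retest = 4L)[[rater]]
  m <- cohort$scores[, , occ]
  m[stats::complete.cases(m), , drop = FALSE]
}

check_item_matrix <- function(m, min_cols = 2) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("item matrix must have no missing cells", call. = FALSE)
  if (nrow(m) < 3) stop("item matrix needs at least 3 rows", call. = FALSE)
  if (ncol(m) < min_cols) {
    stop("item matrix needs at least ", min_cols, " columns", call. = FALSE)
  }
  m
}

#' Cronbach's alpha
#'
#' Internal consistency of a set of items:
#' `alpha = k/(k-1) * (1 - sum(var_i) / var_total)`, with sample variances
#' and `var_total` the variance of the row sums.
#'
#' @param m patients x items score matrix (no missing cells).
#' @return Alpha, a unitless value in (-Inf, 1].
#' @examples
#' m <- cbind(a = c(0, 1, 2, 3), b = c(0, 1, 1, 3), c = c(1, 1, 2, 2))
#' cronbach_alpha(m)
#' @export
cronbach_alpha <- function(m) {
  m <- check_item_matrix(m)
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) {
    stop("total score variance is zero; alpha undefined", call. = FALSE)
  }
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}

#' Corrected item-rest correlation (discriminatory power)
#'
#' Pearson correlation between one item and the sum of the remaining items
#' ("rest"). Values above 0.3 are conventionally required for an item to be
#' considered discriminating.
#'
#' @param m patients x items score matrix.
#' @param item column name or index.
#' @return Pearson correlation coefficient.
#' @export
item_rest_correlation <- function(m, item) {
  m <- check_item_matrix(m, min_cols = 2)
  j <- item_column(m, item)
  x <- m[, j]
  rest <- rowSums(m[, -j, drop = FALSE])
  if (stats::var(x) == 0) {
    stop("item '", colnames(m)[j] %||% j, "' is constant; correlation undefined",
         call. = FALSE)
  }
  if (stats::var(rest) == 0) {
    stop("rest-sum is constant; correlation undefined", call. = FALSE)
  }
  stats::cor(x, rest)
}

#' Alpha if an item is deleted
#'
#' Cronbach's alpha of the matrix with one column removed. An increase over
#' the full-scale alpha indicates the removed item degrades internal
#' consistency.
#'
#' @inheritParams item_rest_correlation
#' @return Alpha of the reduced scale.
#' @export
alpha_if_deleted <- function(m, item) {
  m <- check_item_matrix(m, min_cols = 3)
  j <- item_column(m, item)
  cronbach_alpha(m[, -j, drop = FALSE])
}

item_column <- function(m, item) {
  if (is.character(item)) {
    j <- match(item, colnames(m))
    if (is.na(j)) stop("unknown item '", item, "'", call. = FALSE)
    j
  } else {
    if (item < 1 || item > ncol(m)) stop("item index out of range", call. = FALSE)
    as.integer(item)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full item analysis
#'
#' Assembles the per-item psychometric table: corrected item-rest
#' correlation and alpha-if-item-deleted per item, the overall Cronbach's
#' alpha, and the conventional flags (alpha at least 0.7, Nunnally's
#' criterion; item-rest correlation below 0.3 flags low discrimination).
#'
#' @param m patients x items score matrix.
#' @param alpha_threshold consistency criterion (default 0.7).
#' @param discrimination_threshold item-rest criterion (default 0.3).
#' @return An `item_analysis` object: list with `alpha`, `items` (data
#'   frame `item`, `item_rest_r`, `alpha_if_deleted`), `meets_nunnally`
#'   and `low_discrimination` (character vector of flagged items).
#' @export
item_analysis <- function(m, alpha_threshold = 0.7,
                          discrimination_threshold = 0.3) {
  m <- check_item_matrix(m, min_cols = 3)
  if (is.null(colnames(m))) colnames(m) <- paste0("item", seq_len(ncol(m)))
  alpha <- cronbach_alpha(m)
  tab <- data.frame(
    item = colnames(m),
    item_rest_r = vapply(seq_len(ncol(m)),
                         function(j) item_rest_correlation(m, j), numeric(1)),
    alpha_if_deleted = vapply(seq_len(ncol(m)),
                              function(j) alpha_if_deleted(m, j), numeric(1)),
    stringsAsFactors = FALSE
  )
  structure(
    list(alpha = alpha, items = tab,
         meets_nunnally = alpha >= alpha_threshold,
         low_discrimination = tab$item[tab$item_rest_r < discrimination_threshold],
         thresholds = c(alpha = alpha_threshold,
                        discrimination = discrimination_threshold),
         n = nrow(m)),
    class = "item_analysis"
  )
}

#' @export
print.item_analysis <- function(x, digits = 2, ...) {
  cat(sprintf("Cronbach's alpha: %.4f (n = %d)%s\n", x$alpha, x$n,
              if (x$meets_nunnally) "" else "  [below consistency criterion]"))
  tab <- x$items
  tab$item_rest_r <- round(tab$item_rest_r, digits)
  tab$alpha_if_deleted <- round(tab$alpha_if_deleted, digits)
  print(tab, row.names = FALSE)
  if (length(x$low_discrimination)) {
    cat("Low discriminatory power (<", x$thresholds[["discrimination"]], "):",
        paste(x$low_discrimination, collapse = ", "), "\n")
  }
  invisible(x)
}
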