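# Instrument definition, scoring and severity grouping for ASPOS.

# Level labels of the published instrument. Bold items of the published
# score sheet (those closest to their NIHSS counterparts) carry
# nihss_like = TRUE.
.aspos_levels <- function() {
  lv <- function(item, nihss_like, ...) {
    labels <- c(...)
    data.frame(
      item = item,
      code = seq_along(labels) - 1L,
      label = labels,
      nihss_like = nihss_like,
      stringsAsFactors = FALSE
    )
  }
  rbind(
    lv("Reactivity", TRUE,
       "conscious",
       "somnolence, confusion",
       "sopor",
       "coma"),
    lv("Eyes", TRUE,
       "normal eye movement and visual fields",
       "nystagmus, double vision, hemianopia",
       "eye movement disturbances",
       "oftalmoplegia, cortical blindness"),
    lv("Pharynx", FALSE,
       "normal swallowing, no dysarthria",
       "mild dysarthria",
       "moderate dysarthria, choking on liquids",
       "anarthria, choking on solid foods, nosogastric tube"),
    lv("Strength", TRUE,
       "without motor deficit of limbs or face",
       "mild motor deficit of limbs or face",
       "moderate/severe motor deficit of limbs or face",
       "limb paralysis"),
    lv("Balance", FALSE,
       "Romberg's attempt negative, normal gait",
       "guided walk, Romberg's attempt unstable",
       "walking with aids or help of another person",
       "bedridden"),
    lv("Ataxia", TRUE,
       "without ataxia",
       "ataxia present in one limb",
       "ataxia present in two limbs"),
    lv("Sensory", TRUE,
       "without reactive and defective sensory deficit",
       "paraesthesia, facial or single limb hypoaesthesia",
       "hemianesthesia")
  )
}

#' The ASPOS instrument
#'
#' Builds the Adam's Scale of Posterior Stroke: seven ordinal items
#' (Reactivity, Eyes, Pharynx, Strength, Balance, Ataxia, Sensory), each
#' scored from 0 up to a per-item maximum of 2 or 3, for a maximum total of
#' 19 points. Items that closely mirror NIHSS components are flagged
#' `nihss_like`.
#'
#' @return An object of class `aspos_scale`: a list with elements
#'   `items` (ordered item names), `levels` (data frame with columns
#'   `item`, `code`, `label`, `nihss_like`), `max` (named integer vector of
#'   per-item maxima) and `nihss_like` (named logical vector).
#' @examples
#' sc <- aspos_scale()
#' sc$max
#' sum(sc$max)  # 19
#' @export
aspos_scale <- function() {
  new_scale(.aspos_levels())
}

# Constructor shared by aspos_scale() and read_scale_definition().
new_scale <- function(levels) {
  stopifnot(all(c("item", "code", "label", "nihss_like") %in% names(levels)))
  items <- unique(levels$item)
  for (it in items) {
    codes <- sort(levels$code[levels$item == it])
    if (!identical(as.integer(codes), seq_along(codes) - 1L)) {
      stop("level codes for item '", it,
           "' must be consecutive integers starting at 0", call. = FALSE)
    }
  }
  maxes <- vapply(items, function(it) max(levels$code[levels$item == it]),
                  integer(1))
  nihss_like <- vapply(items, function(it) levels$nihss_like[levels$item == it][1],
                       logical(1))
  structure(
    list(items = items, levels = levels, max = maxes, nihss_like = nihss_like),
    class = "aspos_scale"
  )
}

#' @export
print.aspos_scale <- function(x, ...) {
  cat("Ordinal severity scale with", length(x$items), "items, maximum total",
      sum(x$max), "\n")
  for (it in x$items) {
    cat(sprintf("  %-10s 0-%d%s\n", it, x$max[[it]],
                if (x$nihss_like[[it]]) " [NIHSS-like]" else ""))
  }
  invisible(x)
}

#' Score one item from the set of applicable level descriptions
#'
#' When several level descriptions of one item apply to a patient (or the
#' examiner is in doubt between adjacent levels), the scoring rule of the
#' instrument selects the option with the higher score.
#'
#' @param applicable_levels integer vector of level codes judged applicable.
#' @param item item name (used to validate the codes).
#' @param scale an `aspos_scale`; defaults to the ASPOS instrument.
#' @return The single level code to record: `max(applicable_levels)`.
#' @examples
#' score_item(c(1, 2), "Pharynx")  # 2
#' @export
score_item <- function(applicable_levels, item, scale = aspos_scale()) {
  if (length(applicable_levels) == 0) {
    stop("no applicable levels supplied for item '", item, "'", call. = FALSE)
  }
  check_item(item, scale)
  bad <- setdiff(applicable_levels, 0:scale$max[[item]])
  if (length(bad)) {
    stop("invalid level code(s) ", paste(bad, collapse = ", "),
         " for item '", item, "' (valid range 0-", scale$max[[item]], ")",
         call. = FALSE)
  }
  as.integer(max(applicable_levels))
}

check_item <- function(item, scale) {
  if (!item %in% scale$items) {
    stop("unknown item '", item, "'; expected one of: ",
         paste(scale$items, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Total score of one assessment
#'
#' Sums the recorded item scores. Items marked not assessable (`NA`), e.g.
#' a parameter that cannot be examined for reasons unrelated to the stroke,
#' are simply not added to the total (no pro-rating), mirroring NIHSS
#' convention. The number of items that contributed is attached as the
#' attribute `n_assessable`.
#'
#' @param scores named integer vector with one entry per scale item; `NA`
#'   marks a non-assessable item.
#' @param scale an `aspos_scale`.
#' @return Integer total with attribute `n_assessable`.
#' @examples
#' s <- c(Reactivity = 0, Eyes = 0, Pharynx = NA, Strength = 2,
#'        Balance = 1, Ataxia = 0, Sensory = 0)
#' total_score(s)  # 3, with 6 assessable items
#' @export
total_score <- function(scores, scale = aspos_scale()) {
  if (is.null(names(scores)) || !setequal(names(scores), scale$items) ||
      anyDuplicated(names(scores))) {
    stop("scores must be named with each scale item exactly once",
         call. = FALSE)
  }
  scores <- scores[scale$items]
  ok <- !is.na(scores)
  if (!any(ok)) {
    stop("degenerate assessment: all items non-assessable", call. = FALSE)
  }
  out_of_range <- ok & (scores < 0 | scores > scale$max[names(scores)])
  if (any(out_of_range)) {
    bad <- names(scores)[out_of_range][1]
    stop("score ", scores[[bad]], " out of range 0-", scale$max[[bad]],
         " for item '", bad, "'", call. = FALSE)
  }
  structure(as.integer(sum(scores[ok])), n_assessable = sum(ok))
}

#' Severity group of a total score
#'
#' Partitions the 0-19 total-score range into the three severity strata used
#' for threshold analysis: LOW (total 0-2), INTERMEDIATE (total 3) and HIGH
#' (total 4 or more). A total of 3 marks the point at which the probability
#' of severe stroke by NIHSS criteria rises sharply.
#'
#' @param total integer vector of total scores.
#' @param scale an `aspos_scale` (sets the admissible range).
#' @return Factor with levels `LOW`, `INTERMEDIATE`, `HIGH`.
#' @examples
#' severity_group(c(2, 3, 11))
#' @export
severity_group <- function(total, scale = aspos_scale()) {
  max_total <- sum(scale$max)
  if (any(is.na(total)) || any(total < 0 | total > max_total)) {
    stop("total scores must lie in 0-", max_total, call. = FALSE)
  }
  cut(total, breaks = c(-0.5, 2.5, 3.5, max_total + 0.5),
      labels = c("LOW", "INTERMEDIATE", "HIGH"))
}

#' Write / read a scale definition
#'
#' Serializes an instrument as delimited text, one record per level
#' (`item`, `code`, `label`, `nihss_like`), so that alternative instruments
#' can be declared without code changes.
#'
#' @param scale an `aspos_scale`.
#' @param path file path.
#' @return `read_scale_definition` returns an `aspos_scale`.
#' @export
write_scale_definition <- function(scale, path) {
  utils::write.csv(scale$levels, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scale_definition
#' @export
read_scale_definition <- function(path) {
  levels <- utils::read.csv(path, stringsAsFactors = FALSE)
  new_scale(levels)
}
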