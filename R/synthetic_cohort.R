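# Synthetic multi-rater validation cohorts.
#
# A right-skewed latent severity trait theta drives consensus item scores
# through per-item ordered cutpoints (a deterministic cumulative-threshold
# model), raters perturb the consensus locally (+/- one level), and the
# companion scales are monotone functions of theta plus rounding, range
# clipping and noise. One item ("Eyes") is, with high probability,
# generated independently of theta: a controlled off-scale item that
# reproduces the near-zero discriminatory power this item shows in item
# analysis of the real instrument.

#' Default parameters for the synthetic validation cohort
#'
#' The defaults emulate the design and the published marginal summaries of
#' the ASPOS validation study: 126 patients, three day-1 raters drawn from a
#' pool of four plus a 3-hour retest by one of them, total-score median 2
#' with observed range about 1-11, companion-scale medians NIHSS 2, mRS 1,
#' Barthel 90, GCS 15, and day-90 outcomes driven by an attenuated trait.
#' Rater disagreement is rare and local (one level), matching the published
#' repeatability (coefficient of repeatability about 0.46 total-score
#' points, maximum between-rater total difference of one point).
#'
#' @param n_patients cohort size.
#' @param theta_scale scale of the exponential latent severity trait.
#' @param item_cutpoints named list of strictly increasing cutpoints on the
#'   latent scale, one vector per item; the consensus score of an item is
#'   the number of cutpoints exceeded by `discrimination * theta`.
#' @param item_discrimination named multiplier per item applied to theta
#'   before thresholding.
#' @param offscale_item item generated independently of theta with
#'   probability `offscale_prob` (`NULL` disables the mechanism).
#' @param offscale_prob probability that a patient's off-scale item is drawn
#'   independently of theta.
#' @param offscale_level_probs level probabilities for independent draws of
#'   the off-scale item.
#' @param rater_disagreement probability that a rater records an item one
#'   level off the consensus (plus or minus one, clipped to the item range).
#' @param retest_disagreement same probability for the 3-hour retest.
#' @param recovery_shift multiplicative attenuation of theta at day 90, in
#'   (0, 1].
#' @param companion_links named list (NIHSS, mRS, Barthel, GCS, IVBSS) of
#'   linear links `value = clip(step * round((intercept + slope * theta +
#'   noise) / step), min, max)`.
#' @param ivbss_max maximum of the IVBSS comparator total (not fixed by the
#'   validation study; configurable).
#' @param n_raters_pool number of trained raters the three day-1 raters are
#'   drawn from.
#' @param seed integer seed making the cohort fully reproducible.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n_patients = 126,
                          theta_scale = 0.75,
                          item_cutpoints = list(
                            Reactivity = c(2.8, 4.6, 6.2),
                            Eyes       = c(1.1, 2.6, 4.4),
                            Pharynx    = c(1.6, 3.4, 5.4),
                            Strength   = c(0.55, 2.1, 4.6),
                            Balance    = c(0.05, 1.8, 4.2),
                            Ataxia     = c(1.2, 3.2),
                            Sensory    = c(1.4, 3.8)
                          ),
                          item_discrimination = NULL,
                          offscale_item = "Eyes",
                          offscale_prob = 0.9,
                          offscale_level_probs = c(0.68, 0.24, 0.05, 0.03),
                          rater_disagreement = 0.004,
                          retest_disagreement = 0.004,
                          recovery_shift = 0.6,
                          companion_links = NULL,
                          ivbss_max = 30,
                          n_raters_pool = 4,
                          seed = 1L) {
  scale <- aspos_scale()
  if (is.null(item_discrimination)) {
    item_discrimination <- stats::setNames(rep(1, length(scale$items)),
                                           scale$items)
  }
  if (is.null(companion_links)) {
    companion_links <- list(
      NIHSS   = list(intercept = -0.1, slope = 4.3,  sd = 0.7, min = 0,
                     max = 42, step = 1),
      mRS     = list(intercept = 0.3,  slope = 1.0,  sd = 0.3, min = 0,
                     max = 6, step = 1),
      Barthel = list(intercept = 100,  slope = -19,  sd = 5,   min = 0,
                     max = 100, step = 5),
      GCS     = list(intercept = 15.4, slope = -1.0, sd = 0.8, min = 3,
                     max = 15, step = 1),
      IVBSS   = list(intercept = -0.3, slope = 5.2,  sd = 1.0, min = 0,
                     max = ivbss_max, step = 1)
    )
  }
  p <- structure(
    list(n_patients = n_patients, theta_scale = theta_scale,
         item_cutpoints = item_cutpoints,
         item_discrimination = item_discrimination,
         offscale_item = offscale_item, offscale_prob = offscale_prob,
         offscale_level_probs = offscale_level_probs,
         rater_disagreement = rater_disagreement,
         retest_disagreement = retest_disagreement,
         recovery_shift = recovery_shift,
         companion_links = companion_links, ivbss_max = ivbss_max,
         n_raters_pool = n_raters_pool, seed = as.integer(seed),
         scale = scale),
    class = "cohort_params"
  )
  validate_cohort_params(p)
  p
}

validate_cohort_params <- function(p) {
  scale <- p$scale
  if (!is.numeric(p$n_patients) || p$n_patients < 2) {
    stop("n_patients must be at least 2", call. = FALSE)
  }
  if (!setequal(names(p$item_cutpoints), scale$items)) {
    stop("item_cutpoints must name every scale item exactly once",
         call. = FALSE)
  }
  for (it in scale$items) {
    cp <- p$item_cutpoints[[it]]
    if (length(cp) != scale$max[[it]] || any(diff(cp) <= 0)) {
      stop("cutpoints for '", it, "' must be ", scale$max[[it]],
           " strictly increasing values", call. = FALSE)
    }
  }
  probs <- c(p$offscale_prob, p$rater_disagreement, p$retest_disagreement)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (p$recovery_shift <= 0 || p$recovery_shift > 1) {
    stop("recovery_shift must lie in (0, 1]", call. = FALSE)
  }
  if (!is.null(p$offscale_item)) check_item(p$offscale_item, scale)
  if (p$theta_scale <= 0) stop("theta_scale must be positive", call. = FALSE)
  if (p$n_raters_pool < 3) {
    stop("n_raters_pool must be at least 3", call. = FALSE)
  }
  invisible(TRUE)
}

# consensus item scores from the latent trait (deterministic: monotone in
# theta for every non-offscale item)
consensus_scores <- function(theta, params) {
  scale <- params$scale
  sc <- vapply(scale$items, function(it) {
    eff <- params$item_discrimination[[it]] * theta
    as.integer(rowSums(outer(eff, params$item_cutpoints[[it]], ">")))
  }, integer(length(theta)))
  matrix(sc, nrow = length(theta), dimnames = list(NULL, scale$items))
}

# local rater noise: with probability p, shift one level (+/-1, clipped)
perturb_scores <- function(consensus, p, maxs) {
  n <- nrow(consensus)
  k <- ncol(consensus)
  flip <- matrix(stats::runif(n * k) < p, n, k)
  dir <- matrix(sign(stats::runif(n * k) - 0.5), n, k)
  out <- consensus + flip * dir
  out <- pmax(out, 0L)
  out <- pmin(out, matrix(maxs, n, k, byrow = TRUE))
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(consensus)
  out
}

companion_values <- function(theta, link) {
  raw <- link$intercept + link$slope * theta +
    stats::rnorm(length(theta), 0, link$sd)
  val <- link$step * round(raw / link$step)
  pmin(pmax(val, link$min), link$max)
}

#' Generate a synthetic validation cohort
#'
#' Draws the latent severity trait, derives consensus item scores through
#' the threshold model, produces four assessments per patient (three day-1
#' raters and a 3-hour retest by one of them) through the local rater
#' disagreement process, and links the companion scales (NIHSS, mRS,
#' Barthel, GCS, IVBSS) to the trait at day 1 and, after attenuation by
#' `recovery_shift`, at day 90. Fully deterministic given `params$seed`.
#'
#' @param params a [cohort_params()] object.
#' @return An `aspos_cohort`: list with `ratings` (long data frame
#'   `patient_id`, `rater_id`, `timepoint`, `item`, `score`), `companions`
#'   (long data frame `patient_id`, `day`, `scale`, `value`), `scores`
#'   (patients x items x occasions integer array), `raters` (per-patient
#'   rater assignment including the retest rater), `theta`, `consensus`,
#'   and `params`.
#' @export
generate_cohort <- function(params = cohort_params()) {
  validate_cohort_params(params)
  scale <- params$scale
  n <- params$n_patients
  set.seed(params$seed)

  theta <- stats::rexp(n, rate = 1 / params$theta_scale)
  consensus <- consensus_scores(theta, params)

  if (!is.null(params$offscale_item)) {
    it <- params$offscale_item
    off <- stats::runif(n) < params$offscale_prob
    codes <- 0:scale$max[[it]]
    indep <- sample(codes, n, replace = TRUE, prob = params$offscale_level_probs)
    consensus[off, it] <- indep[off]
  }

  pool <- paste0("R", seq_len(params$n_raters_pool))
  slots <- t(vapply(seq_len(n), function(i) sample(pool, 3), character(3)))
  retest_slot <- sample.int(3, n, replace = TRUE)
  raters <- data.frame(
    patient_id = patient_ids(n),
    day1_r1 = slots[, 1], day1_r2 = slots[, 2], day1_r3 = slots[, 3],
    retest_slot = retest_slot,
    retest_rater = slots[cbind(seq_len(n), retest_slot)],
    stringsAsFactors = FALSE
  )

  rownames(consensus) <- raters$patient_id
  occasions <- c("day1_r1", "day1_r2", "day1_r3", "day1_retest")
  scores <- array(NA_integer_, dim = c(n, length(scale$items), 4),
                  dimnames = list(raters$patient_id, scale$items, occasions))
  for (j in 1:3) {
    scores[, , j] <- perturb_scores(consensus, params$rater_disagreement,
                                    scale$max)
  }
  scores[, , 4] <- perturb_scores(consensus, params$retest_disagreement,
                                  scale$max)

  comp <- list()
  for (day in c(1, 90)) {
    th <- if (day == 1) theta else params$recovery_shift * theta
    for (sc_name in names(params$companion_links)) {
      comp[[length(comp) + 1]] <- data.frame(
        patient_id = raters$patient_id, day = day, scale = sc_name,
        value = companion_values(th, params$companion_links[[sc_name]]),
        stringsAsFactors = FALSE
      )
    }
  }
  companions <- do.call(rbind, comp)

  ratings <- ratings_long(scores, raters)

  structure(
    list(ratings = ratings, companions = companions, scores = scores,
         raters = raters, theta = theta, consensus = consensus,
         params = params),
    class = "aspos_cohort"
  )
}

patient_ids <- function(n) {
  sprintf(paste0("P%0", max(3, nchar(n)), "d"), seq_len(n))
}

# long-format ratings table from the scores array and rater assignment
ratings_long <- function(scores, raters) {
  n <- dim(scores)[1]
  items <- dimnames(scores)[[2]]
  occasions <- dimnames(scores)[[3]]
  rater_of <- cbind(raters$day1_r1, raters$day1_r2, raters$day1_r3,
                    raters$retest_rater)
  blocks <- lapply(seq_along(occasions), function(j) {
    data.frame(
      patient_id = rep(raters$patient_id, times = length(items)),
      rater_id = rep(rater_of[, j], times = length(items)),
      timepoint = occasions[j],
      item = rep(items, each = n),
      score = as.integer(scores[, , j]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, blocks)
  out <- out[order(out$patient_id, out$timepoint,
                   match(out$item, items)), ]
  rownames(out) <- NULL
  out
}

#' @export
print.aspos_cohort <- function(x, ...) {
  tot <- cohort_totals(x)
  cat("Synthetic validation cohort:", nrow(tot), "patients,",
      dim(x$scores)[3], "assessments each\n")
  cat("Total score (first rater): median", stats::median(tot[, 1]),
      "range", min(tot[, 1]), "-", max(tot[, 1]), "\n")
  invisible(x)
}

#' Total scores per patient and occasion
#'
#' @param cohort an `aspos_cohort`.
#' @return Integer matrix, patients x occasions (`day1_r1`, `day1_r2`,
#'   `day1_r3`, `day1_retest`); non-assessable items are not added.
#' @export
cohort_totals <- function(cohort) {
  apply(cohort$scores, c(1, 3), sum, na.rm = TRUE)
}

#' Randomly pair two day-1 raters per patient
#'
#' Emulates the repeatability design in which the total-score difference
#' between two randomly selected raters is analysed: for each patient an
#' unordered pair of its three day-1 raters is drawn uniformly.
#'
#' @param cohort an `aspos_cohort`.
#' @param seed integer seed for the pair draw (independent of the cohort
#'   seed; the caller's RNG state is preserved).
#' @return Data frame with `patient_id`, the paired rater ids and their
#'   total scores (`total_a`, `total_b`).
#' @export
select_rater_pair <- function(cohort, seed = 1L) {
  n <- dim(cohort$scores)[1]
  if (dim(cohort$scores)[3] < 3) {
    stop("cohort must contain three day-1 raters", call. = FALSE)
  }
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  idx <- with_seed(seed, sample.int(3, n, replace = TRUE))
  sel <- pairs[idx, , drop = FALSE]
  totals <- cohort_totals(cohort)
  rater_of <- cbind(cohort$raters$day1_r1, cohort$raters$day1_r2,
                    cohort$raters$day1_r3)
  data.frame(
    patient_id = cohort$raters$patient_id,
    rater_a = rater_of[cbind(seq_len(n), sel[, 1])],
    rater_b = rater_of[cbind(seq_len(n), sel[, 2])],
    slot_a = sel[, 1], slot_b = sel[, 2],
    total_a = totals[cbind(seq_len(n), sel[, 1])],
    total_b = totals[cbind(seq_len(n), sel[, 2])],
    stringsAsFactors = FALSE
  )
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Write / read a cohort as delimited text
#'
#' Writes the ratings and companion tables as CSV plus a JSON sidecar with
#' the generating seed, so a simulated cohort can be archived and re-read
#' with [read_cohort()].
#'
#' @param cohort an `aspos_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rp <- file.path(dir, "ratings.csv")
  cp <- file.path(dir, "companions.csv")
  sp <- file.path(dir, "cohort_params.json")
  write_ratings(cohort$ratings, rp)
  write_companions(cohort$companions, cp)
  meta <- list(seed = cohort$params$seed,
               n_patients = cohort$params$n_patients,
               rater_disagreement = cohort$params$rater_disagreement,
               retest_disagreement = cohort$params$retest_disagreement,
               recovery_shift = cohort$params$recovery_shift,
               theta_scale = cohort$params$theta_scale)
  jsonlite::write_json(meta, sp, auto_unbox = TRUE, digits = NA)
  invisible(c(rp, cp, sp))
}
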