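# Independent brute-force implementations of the defining formulas, used
# only as oracles. They deliberately take different computational routes
# than the package (raw-sum Pearson, aov() mean squares, disagreement-form
# kappa, pair-counting U) so agreement is evidence, not tautology.

o_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# alpha from the covariance matrix: k/(k-1) * (1 - trace(C) / sum(C))
o_alpha <- function(m) {
  C <- cov(m)
  k <- ncol(m)
  k / (k - 1) * (1 - sum(diag(C)) / sum(C))
}

# two-way mean squares via aov(), then the single-measure ICC formulas
o_icc <- function(block, type = "agreement") {
  n <- nrow(block)
  k <- ncol(block)
  df <- data.frame(score = as.vector(block),
                   p = factor(rep(seq_len(n), k)),
                   r = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(score ~ p + r, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  if (type == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

# kappa in disagreement form: 1 - sum(w * O) / sum(w * E)
o_kappa <- function(x, y, weights = "quadratic") {
  cats <- seq(min(c(x, y)), max(c(x, y)))
  O <- table(factor(x, cats), factor(y, cats))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  d <- abs(outer(seq_along(cats), seq_along(cats), "-"))
  w <- if (weights == "quadratic") d^2 else d
  1 - sum(w * O) / sum(w * E)
}

o_spearman <- function(x, y) o_pearson(rank(x), rank(y))

# U by pair counting: number of (x_i, y_j) pairs with x_i > y_j, ties 0.5
o_mw_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# exact two-sided p by enumerating all group labelings (tie-safe)
o_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  u_obs <- o_mw_u(x, y)
  combos <- utils::combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) {
    o_mw_u(pooled[idx], pooled[-idx])
  })
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# tie-corrected Kruskal-Wallis H from first principles
o_kw_h <- function(groups) {
  values <- unlist(groups)
  n <- length(values)
  r <- rank(values)
  idx <- rep(seq_along(groups), lengths(groups))
  rg <- tapply(r, idx, sum)
  h <- 12 / (n * (n + 1)) * sum(rg^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

o_odds_ratio <- function(a, b, cc, d) {
  if (any(c(a, b, cc, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  (a * d) / (b * cc)
}

# population per-item ICC implied by the generative model: between-patient
# variance of the expected recorded score over within-patient recording
# variance, both derived from the exact consensus-score distribution under
# the exponential latent trait and the clipped one-level disagreement
# process.
expected_item_icc <- function(params, item) {
  scale <- params$scale
  M <- scale$max[[item]]
  cuts <- params$item_cutpoints[[item]]
  a <- params$item_discrimination[[item]]
  p_ge <- c(1, exp(-cuts / (a * params$theta_scale)))  # P(score >= l)
  p_thresh <- -diff(c(p_ge, 0))                         # P(score == l)
  if (!is.null(params$offscale_item) && item == params$offscale_item) {
    p_score <- (1 - params$offscale_prob) * p_thresh +
      params$offscale_prob * params$offscale_level_probs
  } else {
    p_score <- p_thresh
  }
  codes <- 0:M
  pd <- params$rater_disagreement
  e_rec <- codes + (pd / 2) * ((codes < M) - (codes > 0))
  v_rec <- (pd / 2) * ((codes < M) + (codes > 0)) - (e_rec - codes)^2
  mu <- sum(p_score * e_rec)
  var_b <- sum(p_score * (e_rec - mu)^2)
  var_w <- sum(p_score * v_rec)
  var_b / (var_b + var_w)
}

# compound-symmetric sample covariance by construction: whiten, recolour
exchangeable_items <- function(n, k, rho, seed = 1) {
  set.seed(seed)
  x0 <- matrix(rnorm(n * k), n, k)
  xw <- x0 %*% solve(chol(cov(x0)))
  sigma <- matrix(rho, k, k)
  diag(sigma) <- 1
  xw %*% chol(sigma)
}

# reconstruction of the published severity partition as paired vectors
published_partition_pairs <- function(cutoff = 6) {
  part <- published_severity_partition()
  totals <- rep(c(2L, 3L, 5L), part$n)
  nihss <- unlist(lapply(seq_len(nrow(part)), function(i) {
    c(rep(cutoff, part$cases[i]), rep(2L, part$n[i] - part$cases[i]))
  }))
  list(totals = totals, nihss = nihss)
}

# small deterministic integer item matrix with guaranteed variation
random_item_matrix <- function(seed, n = 8, k = 5, max_code = 3) {
  set.seed(seed)
  repeat {
    m <- matrix(sample(0:max_code, n * k, replace = TRUE), n, k)
    ok_cols <- all(apply(m, 2, var) > 0)
    if (ok_cols && var(rowSums(m)) > 0) return(m)
  }
}
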