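#' Kruskal--Wallis H test with exact small-sample option
#'
#' The H statistic (midranks, tie-corrected) comes from
#' [stats::kruskal.test()]. The p-value uses the chi-square approximation
#' with k-1 df, except for small samples (total n at or below
#' `exact_max`) where the exact permutation distribution of H is obtained
#' by full enumeration of group-label assignments.
#'
#' @param values numeric vector.
#' @param groups group labels (>= 2 groups, each non-empty).
#' @param exact_max largest total n for exact enumeration (default 10).
#' @return list with `H`, `df`, `p_value`, `method` (`"chisq"` or
#'   `"exact"`).
#' @export
kruskal_wallis <- function(values, groups, exact_max = 10) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) == 0L)) stop("empty group")
  kt <- stats::kruskal.test(values, groups)
  H <- unname(kt$statistic)
  df <- unname(kt$parameter)
  n <- length(values)
  if (n <= exact_max) {
    p <- kw_exact_p(values, groups)
    method <- "exact"
  } else {
    p <- unname(kt$p.value)
    method <- "chisq"
  }
  if (is.nan(H)) {  # all values identical: no evidence against the null
    H <- 0
    p <- 1
  }
  list(H = H, df = df, p_value = p, method = method)
}

# Exact permutation p-value: enumerate all distinct assignments of the
# observed values to the group sizes and compare H statistics.
kw_exact_p <- function(values, groups) {
  sizes <- as.integer(table(groups))
  n <- length(values)
  r <- rank(values)
  h_of <- function(assign) {
    kw_h_stat(r, assign)
  }
  H_obs <- kw_h_stat(r, as.integer(groups))
  perms <- permutations_of_groups(sizes)
  Hs <- apply(perms, 1L, h_of)
  mean(Hs >= H_obs - 1e-12)
}

# H on precomputed ranks with tie correction.
kw_h_stat <- function(r, g) {
  n <- length(r)
  means <- tapply(r, g, mean)
  sizes <- tapply(r, g, length)
  H <- 12 / (n * (n + 1)) * sum(sizes * (means - (n + 1) / 2)^2)
  ties <- table(r)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) H <- H / corr
  H
}

# All distinct assignments of n items into groups of the given sizes,
# as a matrix of group labels (rows = assignments).
permutations_of_groups <- function(sizes) {
  n <- sum(sizes)
  recurse <- function(free, labels, g) {
    if (g == length(sizes)) {
      labels[free] <- g
      out[[length(out) + 1L]] <<- labels
      return(invisible(NULL))
    }
    picks <- utils::combn(free, sizes[g])
    for (c in seq_len(ncol(picks))) {
      lab <- labels
      lab[picks[, c]] <- g
      recurse(setdiff(free, picks[, c]), lab, g + 1L)
    }
    invisible(NULL)
  }
  out <- list()
  recurse(seq_len(n), integer(n), 1L)
  do.call(rbind, out)
}

#' Dunn post-hoc pairwise comparisons with Bonferroni correction
#'
#' \eqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - T)(1/n_i +
#' 1/n_j)}} with tie term \eqn{T = \sum(t^3 - t) / (12(N-1))}; raw
#' two-sided normal p-values are Bonferroni-multiplied by the number of
#' comparisons \eqn{k(k-1)/2} and capped at 1.
#'
#' @param values numeric vector.
#' @param groups group labels.
#' @param alpha significance level used for the `significant` flag.
#' @return data.frame: `level_i`, `level_j`, `z`, `p_raw`, `p_adjusted`,
#'   `significant`.
#' @export
dunn_posthoc <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  k <- nlevels(groups)
  if (k < 2L) stop("need at least two groups")
  N <- length(values)
  r <- rank(values)
  means <- tapply(r, groups, mean)
  sizes <- tapply(r, groups, length)
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(levels(groups), 2L)
  z <- p_raw <- numeric(ncol(pairs))
  for (c in seq_len(ncol(pairs))) {
    i <- pairs[1L, c]; j <- pairs[2L, c]
    se <- sqrt((N * (N + 1) / 12 - tie_term) *
                 (1 / sizes[[i]] + 1 / sizes[[j]]))
    z[c] <- if (se > 0) (means[[i]] - means[[j]]) / se else 0
    p_raw[c] <- 2 * stats::pnorm(-abs(z[c]))
  }
  p_adj <- pmin(1, p_raw * ncol(pairs))
  data.frame(level_i = pairs[1L, ], level_j = pairs[2L, ], z = z,
             p_raw = p_raw, p_adjusted = p_adj,
             significant = p_adj < alpha,
             stringsAsFactors = FALSE)
}

#' Partial eta-squared effect size for a Kruskal--Wallis H
#'
#' \eqn{\eta_p^2 = (H - k + 1)/(n - k)}, clipped to \[0, 1\]. Because a
#' single factor is tested at a time, this coincides with the plain
#' eta-squared. An alternative `H/(n-1)` formula is available.
#'
#' @param H Kruskal--Wallis statistic.
#' @param k number of groups.
#' @param n total observations (> k).
#' @param formula `"epsilon"` (default, `(H-k+1)/(n-k)`) or `"simple"`
#'   (`H/(n-1)`).
#' @return effect size in \[0, 1\].
#' @export
partial_eta_squared <- function(H, k, n, formula = c("epsilon", "simple")) {
  formula <- match.arg(formula)
  if (n <= k) stop("need n > k")
  v <- switch(formula,
              epsilon = (H - k + 1) / (n - k),
              simple = H / (n - 1))
  min(1, max(0, v))
}

#' Pearson product-moment correlation with two-sided test
#'
#' Thin wrapper over [stats::cor.test()]; zero-variance input is reported
#' as undefined rather than an error.
#'
#' @param x,y paired numeric vectors (>= 3 complete pairs).
#' @return list with `rho`, `p_value`, `n`.
#' @export
pearson_corr <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least three paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x),
                note = "zero variance"))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Screen candidate fixed effects against the traits
#'
#' For every factor x trait combination: Kruskal--Wallis H, df, p,
#' partial eta-squared, and the count of Bonferroni-significant Dunn
#' pairs. Screening is diagnostic output only; no factor is dropped from
#' the genetic model automatically.
#'
#' @param data data.frame of records.
#' @param traits trait column names (numeric).
#' @param factors factor column names (categorical).
#' @param alpha significance level for the post-hoc flag.
#' @return long-format data.frame, one row per factor x trait.
#' @export
screen_factors <- function(data, traits, factors, alpha = 0.05) {
  rows <- list()
  for (f in factors) {
    g <- factor(data[[f]])
    if (nlevels(g) < 2L) next
    for (tr in traits) {
      kw <- kruskal_wallis(data[[tr]], g)
      eta <- partial_eta_squared(kw$H, nlevels(g), length(g))
      dn <- dunn_posthoc(data[[tr]], g, alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        factor = f, trait = tr, H = kw$H, df = kw$df,
        p_value = kw$p_value, eta_p2 = eta,
        n_significant_pairs = sum(dn$significant),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Purge records outside configured trait ranges
#'
#' Simple min/max filter used to discard records falling outside the
#' ranges reported for the breed.
#'
#' @param data data.frame of records.
#' @param ranges named list `trait -> c(min, max)`.
#' @return the filtered data.frame; attribute `n_purged` gives the count
#'   removed.
#' @export
purge_ranges <- function(data, ranges) {
  keep <- rep(TRUE, nrow(data))
  for (tr in names(ranges)) {
    r <- ranges[[tr]]
    keep <- keep & data[[tr]] >= r[1] & data[[tr]] <= r[2]
  }
  out <- data[keep, , drop = FALSE]
  attr(out, "n_purged") <- sum(!keep)
  out
}
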