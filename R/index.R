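#' Selection index weights
#'
#' Solves \eqn{P b = g}: `b` is the vector of index weights, `P` the
#' phenotypic (co)variance matrix of the index traits, `g` the vector of
#' genetic covariances of each trait with the aggregate genotype.
#'
#' @param P symmetric positive-definite phenotypic covariance matrix.
#' @param g genetic covariance vector.
#' @return weight vector `b`.
#' @examples
#' index_weights(matrix(c(2, 1, 1, 2), 2), c(1, 1))  # 1/3, 1/3
#' @export
index_weights <- function(P, g) {
  P <- as.matrix(P)
  if (!isSymmetric(unname(P), tol = 1e-8)) stop("P must be symmetric")
  b <- tryCatch(solve(P, g),
                error = function(e) stop("P is singular: ",
                                         conditionMessage(e)))
  as.numeric(b)
}

#' Combined selection index (ICO) score
#'
#' \deqn{ICO = \sum_t PBV_t \, W_t / \mu_t}
#' over the index traits milk yield, fat, protein and lactose (solids is
#' excluded from the index by construction: its information is redundant
#' with fat and protein). PBVs and means are on the 210-day kg basis.
#'
#' @param pbv named list/data.frame/matrix of per-animal PBVs; columns
#'   (or names, for a single animal) must cover the index traits.
#' @param weights named weights per trait (default 1:1:1:1).
#' @param means named trait means (kg, > 0).
#' @param traits index traits (default milk, fat, protein, lactose).
#' @return numeric ICO score(s), one per animal.
#' @export
ico <- function(pbv, weights = NULL, means,
                traits = c("milk", "fat", "protein", "lactose")) {
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(traits)),
                                                   traits)
  if (any(means[traits] <= 0)) stop("trait means must be positive")
  if (is.null(dim(pbv))) pbv <- t(as.matrix(pbv[traits]))
  pbv <- as.matrix(as.data.frame(pbv)[traits])
  drop(pbv %*% (weights[traits] / means[traits]))
}

#' Stratified rank sampling of index scores
#'
#' Picks the `n_low` lowest-scoring animals, the `n_high` highest, and
#' `n_mid` animals centered on the median rank. Ties are broken by id
#' order, so the selection is deterministic and invariant to input
#' order.
#'
#' @param scores named numeric vector (names = animal ids).
#' @param n_low,n_mid,n_high stratum sizes.
#' @return data.frame `animal`, `score`, `rank`, `stratum` for the
#'   selected animals; strata are disjoint.
#' @export
stratified_rank_sample <- function(scores, n_low, n_mid, n_high) {
  n <- length(scores)
  if (n_low + n_mid + n_high > n) {
    stop("requested strata exceed the population size")
  }
  ord <- order(scores, names(scores))
  ranked <- data.frame(animal = names(scores)[ord],
                       score = unname(scores[ord]),
                       rank = seq_len(n), stringsAsFactors = FALSE)
  low <- seq_len(n_low)
  high <- if (n_high > 0) seq(n - n_high + 1L, n) else integer(0)
  med <- (n + 1) / 2
  mid_start <- max(1L, floor(med - n_mid / 2 + 0.5))
  mid <- seq(mid_start, length.out = n_mid)
  if (n_mid > 0 && (min(mid) <= max(low, 0) ||
                    (n_high > 0 && max(mid) >= min(high)))) {
    stop("strata overlap: population too small for the requested sizes")
  }
  sel <- rbind(
    if (n_low > 0) cbind(ranked[low, ], stratum = "low"),
    if (n_mid > 0) cbind(ranked[mid, ], stratum = "mid"),
    if (n_high > 0) cbind(ranked[high, ], stratum = "high"))
  rownames(sel) <- NULL
  sel
}
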