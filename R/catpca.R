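#' Categorical principal component analysis by optimal scaling
#'
#' Alternating least squares jointly estimates a numeric quantification
#' for every level of each nominal variable and a low-rank component
#' structure: given the current quantified (standardized) variables, the
#' component solution is the ordinary PCA of their correlation matrix;
#' given component scores and loadings, each nominal variable's level
#' quantifications are the within-level means of its model projection.
#' Iteration stops when the fit (sum of the leading eigenvalues)
#' changes by less than `tol`. Variables declared `"numeric"` keep their
#' codes (standardized), so an all-numeric fit reduces to standard PCA of
#' the correlation matrix.
#'
#' Two starts are tried: a deterministic one quantifying levels by their
#' integer codes, and a random start from the seeded generator; the
#' solution with the larger fit is kept. The sign of each dimension is
#' fixed so its largest-|loading| variable loads positively.
#'
#' @param x matrix or data.frame of factor codes (rows = animals); an
#'   `encoded_factors` object is accepted (its additive codes are used).
#' @param n_dims number of dimensions to extract.
#' @param level `"nominal"` (default, recycled) or `"numeric"` per column.
#' @param max_iter,tol ALS controls (loss change threshold `1e-8`).
#' @param seed seed for the random start.
#' @return a `catpca` object: `loadings` (variable x dimension),
#'   `eigenvalues`, `cronbach_alpha` per dimension, `quantifications`
#'   (per variable: level -> score), `object_scores` (zero mean, unit
#'   variance per dimension), `fit` (sum of eigenvalues) and `loss_trace`.
#' @export
fit_catpca <- function(x, n_dims = 2, level = "nominal", max_iter = 200,
                       tol = 1e-8, seed = 42L) {
  if (inherits(x, "encoded_factors")) x <- x$additive
  x <- as.data.frame(x)
  keep <- vapply(x, function(v) length(unique(v[!is.na(v)])) > 1L,
                 logical(1))
  dropped <- names(x)[!keep]
  x <- x[keep]
  m <- ncol(x)
  if (m < 2L) stop("need at least two non-constant variables")
  if (n_dims >= m) stop("n_dims must be smaller than the number of variables")
  level <- rep_len(level, m)
  n <- nrow(x)

  # indicator structure per variable
  cats <- lapply(x, function(v) sort(unique(v)))
  gidx <- Map(function(v, cs) match(v, cs), x, cats)

  standardize <- function(z) {
    z <- z - mean(z)
    s <- sqrt(sum(z^2) / n)
    if (s < 1e-12) z else z / s
  }

  run <- function(z0) {
    Z <- z0
    fit_old <- -Inf
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      R <- crossprod(Z) / n
      ev <- eigen(R, symmetric = TRUE)
      lam <- ev$values[seq_len(n_dims)]
      V <- ev$vectors[, seq_len(n_dims), drop = FALSE]
      fit <- sum(lam)
      trace <- c(trace, m - fit)  # loss = unexplained variance
      # object scores: standardized principal components
      Xs <- Z %*% V %*% diag(1 / sqrt(pmax(lam, 1e-12) * n), n_dims)
      Xs <- Xs * sqrt(n)           # columns: mean 0, var 1 (times n)
      A <- crossprod(Z, Xs) / n    # loadings = correlations
      # update quantifications
      for (j in seq_len(m)) {
        if (level[j] == "numeric") next
        t_j <- drop(Xs %*% A[j, ]) / max(sum(A[j, ]^2), 1e-12)
        q <- tapply(t_j, gidx[[j]], mean)
        Z[, j] <- standardize(q[gidx[[j]]])
      }
      if (abs(fit - fit_old) < tol) break
      fit_old <- fit
    }
    if (it == max_iter && abs(fit - fit_old) >= tol) {
      warning("CATPCA did not converge in ", max_iter,
              " iterations; final loss ", signif(m - fit, 6))
    }
    list(Z = Z, fit = fit, lam = lam, A = A, Xs = Xs, trace = trace)
  }

  # deterministic start: numeric values as given (numeric variables keep
  # them throughout), integer level codes for nominal variables
  Z_det <- vapply(seq_len(m), function(j)
    standardize(if (level[j] == "numeric") as.numeric(x[[j]])
                else as.numeric(gidx[[j]])), numeric(n))
  best <- run(Z_det)
  if (any(level == "nominal")) {
    set.seed(seed)
    Z_rnd <- Z_det
    for (j in which(level == "nominal")) {
      q <- stats::rnorm(length(cats[[j]]))
      Z_rnd[, j] <- standardize(q[gidx[[j]]])
    }
    cand <- run(Z_rnd)
    if (cand$fit > best$fit + 1e-10) best <- cand
  }

  A <- best$A
  lam <- best$lam
  Xs <- best$Xs
  # sign convention: largest-|loading| variable positive per dimension
  for (d in seq_len(n_dims)) {
    jmax <- which.max(abs(A[, d]))
    if (A[jmax, d] < 0) {
      A[, d] <- -A[, d]
      Xs[, d] <- -Xs[, d]
    }
  }
  dimnames(A) <- list(colnames(x), paste0("dim", seq_len(n_dims)))
  quant <- lapply(seq_len(m), function(j) {
    z <- best$Z[, j]
    stats::setNames(tapply(z, gidx[[j]], mean)[seq_along(cats[[j]])],
                    cats[[j]])
  })
  names(quant) <- colnames(x)
  alpha <- vapply(lam, cronbach_alpha, numeric(1), m = m)
  structure(list(
    n_dims = n_dims, loadings = A, eigenvalues = lam,
    cronbach_alpha = alpha, quantifications = quant,
    object_scores = Xs, fit = best$fit, loss_trace = best$trace,
    dropped_constant = dropped, n = n, m = m, level = level
  ), class = "catpca")
}

#' Varimax rotation with Kaiser normalization
#'
#' Orthogonal rotation of a loading matrix maximizing the Varimax
#' criterion, rows normalized to unit communality during rotation
#' (Kaiser). A single-dimension matrix is returned unchanged. Communality
#' of every variable is preserved.
#'
#' @param loadings variable x dimension matrix (or a `catpca` object).
#' @return list with `loadings` (rotated), `rotmat` (orthogonal), and
#'   `criterion` values before and after.
#' @export
varimax_rotate <- function(loadings) {
  if (inherits(loadings, "catpca")) loadings <- loadings$loadings
  loadings <- as.matrix(loadings)
  if (ncol(loadings) < 2L) {
    return(list(loadings = loadings,
                rotmat = diag(ncol(loadings)),
                criterion = c(before = varimax_criterion(loadings),
                              after = varimax_criterion(loadings))))
  }
  before <- varimax_criterion(loadings)
  vr <- stats::varimax(loadings, normalize = TRUE, eps = 1e-10)
  rot <- loadings %*% vr$rotmat
  dimnames(rot) <- dimnames(loadings)
  list(loadings = rot, rotmat = vr$rotmat,
       criterion = c(before = before, after = varimax_criterion(rot)))
}

#' Varimax simplicity criterion
#'
#' Sum over dimensions of the variance of squared loadings, by default
#' after Kaiser row normalization (rows scaled to unit communality) —
#' the quantity the rotation maximizes.
#'
#' @param L loading matrix.
#' @param normalize apply Kaiser row normalization first (default TRUE).
#' @return scalar criterion value.
#' @export
varimax_criterion <- function(L, normalize = TRUE) {
  if (normalize) {
    h <- sqrt(rowSums(L^2))
    h[h < 1e-12] <- 1
    L <- L / h
  }
  L2 <- L^2
  sum(apply(L2, 2L, function(c) mean(c^2) - mean(c)^2))
}

#' Cronbach's alpha for a principal dimension
#'
#' \eqn{\alpha = \frac{m}{m-1}\left(1 - \frac{1}{\lambda}\right)} for a
#' dimension with eigenvalue \eqn{\lambda} extracted from \eqn{m}
#' variables.
#'
#' @param eigenvalue dimension eigenvalue (> 0).
#' @param m number of variables (>= 2).
#' @return alpha (can be negative for eigenvalues below 1).
#' @export
cronbach_alpha <- function(eigenvalue, m) {
  stopifnot(m >= 2)
  if (eigenvalue <= 0) return(NA_real_)
  (m / (m - 1)) * (1 - 1 / eigenvalue)
}

#' Assign SNP factors to dimensions by loading threshold
#'
#' A variable is retained on every dimension where its absolute (rotated)
#' loading meets the threshold (inclusive); variables qualifying nowhere
#' are reported discarded. With `assign = "max"` a variable is kept only
#' on its largest-|loading| qualifying dimension.
#'
#' @param result a `catpca` object or a loading matrix.
#' @param threshold absolute-loading cutoff (default 0.5).
#' @param rotate apply [varimax_rotate()] first (default TRUE for `catpca`
#'   input).
#' @param assign `"all"` (default) or `"max"`.
#' @return list with `retained` (per dimension, character vector of
#'   variables), `discarded`, and the loading matrix used.
#' @export
select_snps <- function(result, threshold = 0.5, rotate = TRUE,
                        assign = c("all", "max")) {
  assign <- match.arg(assign)
  L <- if (inherits(result, "catpca")) result$loadings else as.matrix(result)
  if (rotate && ncol(L) > 1L) L <- varimax_rotate(L)$loadings
  q <- abs(L) >= threshold
  if (assign == "max") {
    for (j in seq_len(nrow(q))) {
      if (any(q[j, ])) {
        keep <- which.max(abs(L[j, ]))
        q[j, ] <- FALSE
        q[j, keep] <- TRUE
      }
    }
  }
  retained <- lapply(seq_len(ncol(L)), function(d) rownames(L)[q[, d]])
  names(retained) <- colnames(L)
  discarded <- rownames(L)[rowSums(q) == 0L]
  list(retained = retained, discarded = discarded, loadings = L,
       threshold = threshold)
}

#' Composite cluster fixed-effect levels
#'
#' For each dimension, builds one nominal factor over animals from the
#' cross-classification of the retained SNPs' codes; combinations rarer
#' than `min_count` are merged into an `"other"` level so the resulting
#' fixed effect stays estimable.
#'
#' @param codes animal x SNP matrix of nominal codes (e.g. the additive
#'   codes of [encode_additive_dominance()]).
#' @param retained list (per dimension) of SNP names, as returned in
#'   `select_snps()$retained`.
#' @param min_count minimum animals per level before merging (default 3).
#' @return data.frame of factors, one column per non-empty dimension,
#'   rownames = animals.
#' @export
cluster_factors <- function(codes, retained, min_count = 3) {
  out <- list()
  for (d in names(retained)) {
    snps <- retained[[d]]
    if (!length(snps)) next
    key <- apply(codes[, snps, drop = FALSE], 1L, paste, collapse = "-")
    tab <- table(key)
    rare <- names(tab)[tab < min_count]
    key[key %in% rare] <- "other"
    out[[d]] <- factor(key)
  }
  if (!length(out)) {
    return(data.frame(row.names = rownames(codes)))
  }
  as.data.frame(out, row.names = rownames(codes))
}
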