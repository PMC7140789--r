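#' Nonlinear canonical correlation analysis over variable sets (OVERALS)
#'
#' Alternating least squares minimizes the average squared distance
#' between common object scores \eqn{X} (n x p, centered, \eqn{X'X = nI})
#' and each set's score \eqn{S_k = \sum_{j \in k} z_j a_j'}, where the
#' \eqn{z_j} are optimally scaled (nominal) or fixed standardized
#' (numeric) variable transforms and \eqn{a_j} their loadings. The
#' eigenvalue of dimension d is \eqn{1 - } mean loss on that dimension,
#' so it lies in \[0, 1\]; with two numeric singleton sets the first
#' eigenvalue equals \eqn{(1 + |r|)/2} of classical canonical
#' correlation.
#'
#' @param x data.frame or matrix of variables (columns).
#' @param sets list of column-name (or index) vectors, one per set
#'   (>= 2 sets).
#' @param n_dims dimensions to fit (default 2).
#' @param level `"nominal"` (default) or `"numeric"`, recycled per column.
#' @param max_iter,tol ALS controls.
#' @param inner_iter backfitting sweeps per set update.
#' @param seed seed for the random start (a deterministic code start is
#'   also tried; best loss kept).
#' @return an `overals` object: `eigenvalues` per dimension,
#'   `total_fit`, `average_loss`, `component_loadings` (variable x
#'   dimension, correlation of each scaled variable with the object
#'   scores), `multiple_fit` per variable, `object_scores`,
#'   `quantifications`, `loss_trace`, `sets`.
#' @export
fit_overals <- function(x, sets, n_dims = 2, level = "nominal",
                        max_iter = 200, tol = 1e-8, inner_iter = 2,
                        seed = 42L) {
  x <- as.data.frame(x)
  n <- nrow(x)
  if (length(sets) < 2L) stop("need at least two sets")
  sets <- lapply(sets, function(s) {
    if (is.numeric(s)) colnames(x)[s] else as.character(s)
  })
  vars <- unlist(sets)
  if (!all(vars %in% colnames(x))) {
    stop("unknown variables in sets: ",
         paste(setdiff(vars, colnames(x)), collapse = ", "))
  }
  x <- x[vars]
  level <- stats::setNames(rep_len(level, length(vars)), vars)
  const <- vapply(x, function(v) length(unique(v)) <= 1L, logical(1))
  for (k in seq_along(sets)) {
    if (all(const[sets[[k]]])) {
      stop("set ", k, " is wholly constant: ",
           paste(sets[[k]], collapse = ", "))
    }
    sets[[k]] <- sets[[k]][!const[sets[[k]]]]
  }
  vars <- unlist(sets)
  x <- x[vars]
  m <- length(vars)
  K <- length(sets)

  cats <- lapply(x, function(v) sort(unique(v)))
  gidx <- Map(function(v, cs) match(v, cs), x, cats)
  standardize <- function(z) {
    z <- z - mean(z)
    s <- sqrt(sum(z^2) / n)
    if (s < 1e-12) z else z / s
  }
  orth_scores <- function(M) {
    # nearest column-orthonormal (times sqrt(n)) matrix to M: X = sqrt(n) UV'
    M <- sweep(M, 2L, colMeans(M))
    sv <- svd(M)
    sqrt(n) * sv$u %*% t(sv$v)
  }

  run <- function(Z) {
    A <- matrix(0, m, n_dims, dimnames = list(vars, NULL))
    X <- orth_scores(matrix(stats::rnorm(n * n_dims), n, n_dims))
    loss_old <- Inf
    trace <- numeric(0)
    for (it in seq_len(max_iter)) {
      # update each set's loadings/quantifications given X
      for (k in seq_len(K)) {
        js <- match(sets[[k]], vars)
        for (sweep_i in seq_len(inner_iter)) {
          for (j in js) {
            others <- setdiff(js, j)
            Rk <- X - if (length(others))
              Z[, others, drop = FALSE] %*% A[others, , drop = FALSE] else 0
            A[j, ] <- crossprod(Z[, j], Rk) / n
            if (level[j] == "nominal") {
              denom <- max(sum(A[j, ]^2), 1e-12)
              t_j <- drop(Rk %*% A[j, ]) / denom
              q <- tapply(t_j, gidx[[j]], mean)
              Z[, j] <- standardize(q[gidx[[j]]])
              A[j, ] <- crossprod(Z[, j], Rk) / n
            }
          }
        }
      }
      # set scores and loss
      S <- vector("list", K)
      loss_d <- numeric(n_dims)
      for (k in seq_len(K)) {
        js <- match(sets[[k]], vars)
        S[[k]] <- Z[, js, drop = FALSE] %*% A[js, , drop = FALSE]
        loss_d <- loss_d + colSums((X - S[[k]])^2) / n
      }
      loss_d <- loss_d / K
      loss <- sum(loss_d)
      trace <- c(trace, loss)
      if (abs(loss_old - loss) < tol) break
      loss_old <- loss
      # update object scores: nearest orthonormal to the mean set score
      X <- orth_scores(Reduce(`+`, S) / K)
    }
    if (it == max_iter && abs(loss_old - loss) >= tol) {
      warning("OVERALS did not converge in ", max_iter,
              " iterations; loss trace tail: ",
              paste(signif(utils::tail(trace, 3), 6), collapse = ", "))
    }
    list(Z = Z, A = A, X = X, loss_d = loss_d, loss = loss, trace = trace)
  }

  # deterministic start: numeric variables keep their (standardized)
  # values; nominal variables start from integer level codes
  Z_det <- vapply(seq_len(m), function(j)
    standardize(if (level[j] == "numeric") as.numeric(x[[j]])
                else as.numeric(gidx[[j]])), numeric(n))
  colnames(Z_det) <- vars
  set.seed(seed)
  best <- run(Z_det)
  if (any(level == "nominal")) {
    Z_rnd <- Z_det
    for (j in which(level == "nominal")) {
      q <- stats::rnorm(length(cats[[j]]))
      Z_rnd[, j] <- standardize(q[gidx[[j]]])
    }
    cand <- run(Z_rnd)
    if (cand$loss < best$loss - 1e-10) best <- cand
  }

  # The total loss is invariant to orthogonal rotation of the object
  # scores within the fitted subspace, so the per-dimension split is
  # indeterminate after ALS. Rotate to the principal axes of the fit
  # matrix Q = X' S-bar / n (symmetric PSD): its ordered eigenvalues are
  # the canonical per-dimension fits.
  Sbar <- Reduce(`+`, lapply(seq_len(K), function(k) {
    js <- match(sets[[k]], vars)
    best$Z[, js, drop = FALSE] %*% best$A[js, , drop = FALSE]
  })) / K
  Q <- crossprod(best$X, Sbar) / n
  Q <- (Q + t(Q)) / 2
  eQ <- eigen(Q, symmetric = TRUE)
  eig <- pmin(1, pmax(0, eQ$values))
  X <- best$X %*% eQ$vectors
  A <- best$A %*% eQ$vectors
  # component loadings: correlations of scaled variables with object scores
  CL <- crossprod(best$Z, X) / n
  dimnames(CL) <- list(vars, paste0("dim", seq_len(n_dims)))
  dimnames(A) <- dimnames(CL)
  # multiple fit: fit of the unrestricted (multiple nominal) projection
  mf <- vapply(seq_len(m), function(j) {
    if (level[j] == "numeric") return(sum(CL[j, ]^2))
    cnt <- tabulate(gidx[[j]], nbins = length(cats[[j]]))
    Q <- apply(X, 2L, function(xd) tapply(xd, gidx[[j]], mean))
    sum(colSums(cnt * Q^2) / n)
  }, numeric(1))
  names(mf) <- vars
  quant <- lapply(seq_len(m), function(j)
    stats::setNames(tapply(best$Z[, j], gidx[[j]], mean)[
      seq_along(cats[[j]])], cats[[j]]))
  names(quant) <- vars

  res <- list(n_dims = n_dims, eigenvalues = unname(eig),
              component_loadings = CL, weights = A,
              multiple_fit = mf, object_scores = X,
              quantifications = quant, sets = sets,
              loss_trace = best$trace, n = n)
  res <- c(res, fit_statistics(res$eigenvalues, n_dims))
  class(res) <- "overals"
  res
}

#' Fit statistics from canonical eigenvalues
#'
#' For eigenvalues \eqn{\lambda_d \in [0,1]} of an `n_dims`-dimensional
#' solution: total fit \eqn{\sum_d \lambda_d}; average loss
#' \eqn{n_{dims} - \sum_d \lambda_d}; per-dimension share of the actual
#' fit \eqn{\lambda_d / \sum \lambda}; and percentage of the maximum
#' possible fit \eqn{\sum \lambda / n_{dims}}. Shares and percentage are
#' reported in percent.
#'
#' @param eigenvalues numeric vector in \[0, 1\].
#' @param n_dims number of dimensions (default `length(eigenvalues)`).
#' @return list with `total_fit`, `average_loss`, `fit_share` (percent,
#'   sums to 100), `pct_of_max` (percent).
#' @examples
#' fit_statistics(c(0.917, 0.676))  # total 1.593, loss 0.407
#' @export
fit_statistics <- function(eigenvalues, n_dims = length(eigenvalues)) {
  stopifnot(all(eigenvalues >= -1e-8), all(eigenvalues <= 1 + 1e-8))
  total <- sum(eigenvalues)
  list(total_fit = total,
       average_loss = n_dims - total,
       fit_share = 100 * eigenvalues / total,
       pct_of_max = 100 * total / n_dims)
}

#' Encode the epistatic signature as a nominal fixed effect
#'
#' Variables with an absolute component loading at or above
#' `loading_threshold` on any dimension and multiple fit above
#' `multiple_fit_threshold` define the epistatic signature. Animals are
#' assigned a nominal level from the cross-classification of those
#' variables' codes; rare combinations are merged (smallest first) until
#' at most `max_levels` levels remain. If no variable qualifies, a
#' single-level factor is returned with a warning.
#'
#' @param result an `overals` object.
#' @param codes animal x variable matrix of nominal codes (the same data
#'   the OVERALS was fitted on).
#' @param loading_threshold absolute loading cutoff (default 0.5).
#' @param multiple_fit_threshold multiple-fit cutoff (default 0.1,
#'   strict).
#' @param max_levels cap on the number of levels (default 10).
#' @return list with `factor` (one level per animal), `qualifying`
#'   (variable names), `n_levels`.
#' @export
encode_epistasis <- function(result, codes, loading_threshold = 0.5,
                             multiple_fit_threshold = 0.1,
                             max_levels = 10) {
  CL <- result$component_loadings
  qual <- rownames(CL)[apply(abs(CL) >= loading_threshold, 1L, any) &
                         result$multiple_fit > multiple_fit_threshold]
  if (!length(qual)) {
    warning("no variable met the epistasis thresholds; ",
            "returning a single-level factor")
    f <- factor(rep("E1", nrow(codes)))
    return(list(factor = f, qualifying = character(0), n_levels = 1L))
  }
  key <- apply(codes[, qual, drop = FALSE], 1L, paste, collapse = "-")
  tab <- sort(table(key))
  while (length(tab) > max_levels) {
    # merge the two rarest combinations
    merged <- paste0("m(", names(tab)[1L], "|", names(tab)[2L], ")")
    key[key %in% names(tab)[1:2]] <- merged
    tab <- sort(table(key))
  }
  f <- factor(key, labels = sprintf("E%d", seq_along(unique(key))))
  list(factor = f, qualifying = qual, n_levels = nlevels(f))
}
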