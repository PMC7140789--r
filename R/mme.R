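#' Assemble Henderson's mixed-model equations
#'
#' Repeatability animal model for one trait:
#' \deqn{y = Xb + Z_a a + Z_{pe} p + e,\quad
#'   a \sim N(0, A\sigma^2_a),\; p \sim N(0, I\sigma^2_{pe}),\;
#'   e \sim N(0, I\sigma^2_e)}
#' The coefficient matrix is the unscaled form
#' \eqn{W'W/\sigma^2_e + \mathrm{diag}(0, A^{-1}/\sigma^2_a,
#' I/\sigma^2_{pe})}, whose inverse directly carries prediction error
#' (co)variances. Rank-deficient fixed blocks are handled by dropping
#' columns found dependent in a pivoted QR (reference-level
#' constraints); factor levels unused after data subsetting are dropped
#' with a warning.
#'
#' @param data data.frame of records with an animal id column `goat`.
#' @param trait response column name.
#' @param fixed character vector of categorical fixed-effect columns.
#' @param covariates character vector of numeric covariate columns
#'   (centered before use).
#' @param pedigree a [new_pedigree()]; all record animals must appear.
#' @param vc list/vector with `sigma2_a`, `sigma2_pe`, `sigma2_e`
#'   (strictly positive for included random terms).
#' @param include_pe include the permanent environment term (default
#'   TRUE; must be FALSE when no animal has repeated records).
#' @return an object of class `mme`: sparse coefficient matrix `C`, right
#'   hand side `rhs`, index vectors for the fixed/animal/PE blocks, the
#'   design pieces, and bookkeeping (inbreeding, log-determinants).
#' @export
build_mme <- function(data, trait, fixed = character(),
                      covariates = character(), pedigree, vc,
                      include_pe = TRUE) {
  if (nrow(data) == 0L) stop("no records")
  if (!all(data$goat %in% pedigree$animal)) {
    stop("records refer to animals missing from the pedigree: ",
         paste(utils::head(setdiff(data$goat, pedigree$animal)),
               collapse = ", "))
  }
  vc <- as.list(vc)
  stopifnot(vc$sigma2_a > 0, vc$sigma2_e > 0,
            !include_pe || vc$sigma2_pe > 0)
  if (include_pe && !any(duplicated(data$goat))) {
    stop("permanent environment effect is not identifiable with a single ",
         "record per animal; set include_pe = FALSE")
  }
  y <- as.numeric(data[[trait]])
  n <- length(y)
  X <- design_fixed(data, fixed, covariates)
  p <- ncol(X)
  q <- nrow(pedigree)
  rec_animals <- sort(unique(data$goat))
  qr_ <- length(rec_animals)
  ai <- match(data$goat, pedigree$animal)
  Za <- Matrix::sparseMatrix(i = seq_len(n), j = ai, x = 1,
                             dims = c(n, q))
  Zpe <- if (include_pe) {
    Matrix::sparseMatrix(i = seq_len(n),
                         j = match(data$goat, rec_animals), x = 1,
                         dims = c(n, qr_))
  } else NULL
  W <- if (include_pe) cbind(Matrix::Matrix(X, sparse = TRUE), Za, Zpe)
       else cbind(Matrix::Matrix(X, sparse = TRUE), Za)
  Ainv <- ainverse(pedigree)
  logdetA <- attr(Ainv, "logdetA")
  s2e <- vc$sigma2_e
  G <- if (include_pe) {
    Matrix::bdiag(Matrix::Diagonal(p, 0), Ainv / vc$sigma2_a,
                  Matrix::Diagonal(qr_, 1 / vc$sigma2_pe))
  } else {
    Matrix::bdiag(Matrix::Diagonal(p, 0), Ainv / vc$sigma2_a)
  }
  C <- Matrix::forceSymmetric(Matrix::crossprod(W) / s2e + G, uplo = "U")
  rhs <- as.numeric(Matrix::crossprod(W, y)) / s2e
  idx_f <- seq_len(p)
  idx_a <- p + seq_len(q)
  idx_pe <- if (include_pe) p + q + seq_len(qr_) else integer(0)
  structure(list(
    C = C, rhs = rhs, W = W, X = X, y = y,
    idx_fixed = idx_f, idx_animal = idx_a, idx_pe = idx_pe,
    pedigree = pedigree, rec_animals = rec_animals,
    Ainv = Ainv, logdetA = logdetA, vc = vc,
    include_pe = include_pe, trait = trait,
    n = n, p = p, q = q, q_pe = qr_
  ), class = "mme")
}

# Fixed-effects design matrix with intercept, treatment contrasts,
# centered covariates, and pivoted-QR rank repair.
design_fixed <- function(data, fixed, covariates) {
  df <- data.frame(row.names = seq_len(nrow(data)))
  for (f in fixed) {
    v <- droplevels(factor(data[[f]]))
    if (nlevels(v) < 2L) {
      warning("fixed factor '", f, "' is constant after subsetting; dropped")
      next
    }
    df[[f]] <- v
  }
  for (cv in covariates) {
    df[[cv]] <- as.numeric(data[[cv]]) - mean(as.numeric(data[[cv]]))
  }
  X <- if (ncol(df)) {
    stats::model.matrix(stats::reformulate(colnames(df)), df)
  } else {
    matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[-keep]
    warning("rank-deficient fixed block; dropping: ",
            paste(dropped, collapse = ", "))
    X <- X[, sort(keep), drop = FALSE]
  }
  X
}

#' Solve the mixed-model equations
#'
#' Sparse symmetric solve of the assembled system: BLUE estimates for the
#' fixed effects and BLUP predictions (PBVs) for animal and permanent
#' environment effects.
#'
#' @param mme a [build_mme()] object.
#' @return list with `fixed` (data.frame term/estimate), `pbv` (named,
#'   every pedigree animal), `pe` (named, recorded animals), and the full
#'   solution vector `solution`.
#' @export
solve_blup <- function(mme) {
  sol <- tryCatch(
    as.numeric(Matrix::solve(mme$C, mme$rhs)),
    error = function(e) stop("mixed-model equations are singular after ",
                             "constraints: ", conditionMessage(e)))
  fixed <- data.frame(term = colnames(mme$X),
                      estimate = sol[mme$idx_fixed],
                      stringsAsFactors = FALSE)
  pbv <- stats::setNames(sol[mme$idx_animal], mme$pedigree$animal)
  pe <- if (mme$include_pe)
    stats::setNames(sol[mme$idx_pe], mme$rec_animals) else NULL
  list(fixed = fixed, pbv = pbv, pe = pe, solution = sol)
}

#' Prediction error variance, accuracy and reliability per animal
#'
#' The animal block of the inverted coefficient matrix is the PEV matrix.
#' \eqn{SEP_i = \sqrt{PEV_i}}, \eqn{RTi_i = \sqrt{1 - PEV_i /
#' ((1+F_i)\sigma^2_a)}} (clipped to 0 when PEV numerically exceeds the
#' prior variance), \eqn{Rap_i = RTi_i^2}. A dense inverse is used below
#' `dense_limit` equations; larger systems fall back to columnwise sparse
#' solves for the animal block only.
#'
#' @param mme a [build_mme()] object.
#' @param use_inbreeding divide by \eqn{(1+F_i)\sigma^2_a} (default) or
#'   plain \eqn{\sigma^2_a}.
#' @param dense_limit dense-inverse cutoff (default 4000 equations).
#' @return data.frame `animal`, `pev`, `sep`, `rti`, `rap`, `inbreeding`.
#' @export
prediction_stats <- function(mme, use_inbreeding = TRUE,
                             dense_limit = 4000) {
  s2a <- mme$vc$sigma2_a
  FF <- inbreeding(mme$pedigree)
  ndim <- nrow(mme$C)
  if (ndim <= dense_limit) {
    Cd <- as.matrix(mme$C)
    ch <- chol(Cd)
    Cinv <- chol2inv(ch)
    pev <- diag(Cinv)[mme$idx_animal]
  } else {
    # columnwise solves for the animal equations only
    pev <- vapply(mme$idx_animal, function(j) {
      e <- numeric(ndim); e[j] <- 1
      as.numeric(Matrix::solve(mme$C, e))[j]
    }, numeric(1))
  }
  denom <- if (use_inbreeding) (1 + FF) * s2a else rep(s2a, length(FF))
  ratio <- pmin(1, pmax(0, 1 - pev / denom))
  rti <- sqrt(ratio)
  data.frame(animal = mme$pedigree$animal, pev = pev, sep = sqrt(pev),
             rti = rti, rap = rti^2, inbreeding = FF,
             stringsAsFactors = FALSE)
}

#' Fit an animal model at fixed variance components
#'
#' Convenience wrapper: [build_mme()] + [solve_blup()] +
#' [prediction_stats()], returning the per-animal evaluation table.
#'
#' @inheritParams build_mme
#' @param use_inbreeding see [prediction_stats()].
#' @return list with `evaluation` (data.frame animal/pbv/sep/rti/rap),
#'   `fixed` (BLUE table), and the `mme`.
#' @export
animal_model <- function(data, trait, fixed = character(),
                         covariates = character(), pedigree, vc,
                         include_pe = TRUE, use_inbreeding = TRUE) {
  mme <- build_mme(data, trait, fixed, covariates, pedigree, vc,
                   include_pe = include_pe)
  sol <- solve_blup(mme)
  ps <- prediction_stats(mme, use_inbreeding = use_inbreeding)
  ev <- data.frame(animal = ps$animal, trait = trait,
                   pbv = sol$pbv[ps$animal], sep = ps$sep, rti = ps$rti,
                   rap = ps$rap, stringsAsFactors = FALSE)
  rownames(ev) <- NULL
  list(evaluation = ev, fixed = sol$fixed, mme = mme)
}

#' Compare evaluations from two model variants
#'
#' Descriptive statistics of SEP and accuracy per model variant, and
#' cross-model Pearson correlations of PBV, SEP and accuracy, per trait.
#'
#' @param eval_incl,eval_excl evaluation data.frames (from
#'   [animal_model()]) for the genetic-effects-included and -excluded
#'   variants; must cover the same animals.
#' @return list with `descriptives` (per trait x model x parameter:
#'   min/max/mean/sd) and `correlations` (per trait: Pearson rho of PBV,
#'   SEP, RTi across models).
#' @export
compare_models <- function(eval_incl, eval_excl) {
  traits <- unique(eval_incl$trait)
  if (!length(intersect(eval_incl$animal, eval_excl$animal))) {
    stop("the two evaluations share no animals")
  }
  desc <- list(); corr <- list()
  for (tr in traits) {
    a <- eval_incl[eval_incl$trait == tr, ]
    b <- eval_excl[eval_excl$trait == tr, ]
    m <- merge(a, b, by = "animal", suffixes = c("_incl", "_excl"))
    for (par in c("sep", "rti")) {
      for (side in c("incl", "excl")) {
        v <- m[[paste0(par, "_", side)]]
        desc[[length(desc) + 1L]] <- data.frame(
          trait = tr, model = side, parameter = par,
          min = min(v), max = max(v), mean = mean(v), sd = stats::sd(v))
      }
    }
    safe_cor <- function(u, v) {
      if (stats::sd(u) == 0 || stats::sd(v) == 0) NA_real_ else
        stats::cor(u, v)
    }
    corr[[length(corr) + 1L]] <- data.frame(
      trait = tr,
      pbv = safe_cor(m$pbv_incl, m$pbv_excl),
      sep = safe_cor(m$sep_incl, m$sep_excl),
      rti = safe_cor(m$rti_incl, m$rti_excl))
  }
  list(descriptives = do.call(rbind, desc),
       correlations = do.call(rbind, corr))
}
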