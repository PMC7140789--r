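#' Univariate REML for the repeatability animal model
#'
#' Estimates \eqn{(\sigma^2_a, \sigma^2_{pe}, \sigma^2_e)} by restricted
#' maximum likelihood. Each iteration factorizes the mixed-model
#' equations at the current components; an average-information (AI)
#' Newton step is attempted first and accepted only when it keeps all
#' components positive and does not decrease the restricted
#' log-likelihood; otherwise the EM update (monotone by construction) is
#' taken. The recorded \eqn{-2\log L} trace is therefore non-increasing.
#' Convergence: squared relative component change below `tol` (default
#' \eqn{10^{-12}}).
#'
#' @param data records data.frame with animal id column `goat`.
#' @param trait response column.
#' @param fixed,covariates fixed-effect specification, see [build_mme()].
#' @param pedigree a [new_pedigree()].
#' @param start optional named start values (`sigma2_a`, `sigma2_pe`,
#'   `sigma2_e`); default splits the phenotypic variance 0.3/0.2/0.5.
#' @param include_pe fit a permanent environment term (default TRUE;
#'   requires repeated records).
#' @param tol convergence criterion on squared relative change.
#' @param max_iter iteration cap; hitting it without converging is an
#'   error reporting the final components unless `on_nonconv = "warn"`.
#' @param method `"ai"` (AI with EM fallback, default) or `"em"` (pure
#'   EM).
#' @param on_nonconv `"error"` or `"warn"`.
#' @return a `reml_fit` list: `vc` (components, sigma2_p, h2,
#'   repeatability with SEs), `minus2logL` trace, `iterations`,
#'   `converged`, `boundary` flag, `step_type` per iteration, `vcov_vc`
#'   (AI-based covariance of the components), plus the model description.
#' @export
reml_univariate <- function(data, trait, fixed = character(),
                            covariates = character(), pedigree,
                            start = NULL, include_pe = TRUE,
                            tol = 1e-12, max_iter = 200,
                            method = c("ai", "em"),
                            on_nonconv = c("error", "warn")) {
  method <- match.arg(method)
  on_nonconv <- match.arg(on_nonconv)
  if (length(unique(data$goat)) < 2L) stop("need records on >= 2 animals")
  if (include_pe && !any(duplicated(data$goat))) {
    stop("one record per animal: the permanent environment variance is ",
         "not identifiable; rerun with include_pe = FALSE")
  }
  y <- as.numeric(data[[trait]])
  X <- design_fixed(data, fixed, covariates)
  n <- length(y); p <- ncol(X)
  q <- nrow(pedigree)
  rec_animals <- sort(unique(data$goat))
  q_pe <- length(rec_animals)
  ai_rec <- match(data$goat, pedigree$animal)
  Za <- Matrix::sparseMatrix(i = seq_len(n), j = ai_rec, x = 1,
                             dims = c(n, q))
  Zpe <- if (include_pe)
    Matrix::sparseMatrix(i = seq_len(n), j = match(data$goat, rec_animals),
                         x = 1, dims = c(n, q_pe)) else NULL
  W <- if (include_pe) cbind(Matrix::Matrix(X, sparse = TRUE), Za, Zpe)
       else cbind(Matrix::Matrix(X, sparse = TRUE), Za)
  Ainv <- ainverse(pedigree)
  logdetA <- attr(Ainv, "logdetA")
  # general (not symmetric-storage) triplets: both triangles needed for
  # the elementwise trace sum(Ainv * Caa)
  AinvT <- methods::as(methods::as(Ainv, "generalMatrix"), "TsparseMatrix")
  ai_i <- AinvT@i + 1L; ai_j <- AinvT@j + 1L; ai_x <- AinvT@x
  WtW <- as.matrix(Matrix::crossprod(W))
  Wty <- as.numeric(Matrix::crossprod(W, y))
  yty <- sum(y^2)
  idx_a <- p + seq_len(q)
  idx_pe <- if (include_pe) p + q + seq_len(q_pe) else integer(0)
  ndim <- ncol(WtW)

  vp <- stats::var(y)
  th <- if (is.null(start)) {
    c(sigma2_a = 0.3 * vp,
      sigma2_pe = if (include_pe) 0.2 * vp else NA_real_,
      sigma2_e = 0.5 * vp)
  } else {
    c(sigma2_a = start[["sigma2_a"]],
      sigma2_pe = if (include_pe) start[["sigma2_pe"]] else NA_real_,
      sigma2_e = start[["sigma2_e"]])
  }
  floor_v <- 1e-8 * vp

  # factorize the MME at given components; return every per-iteration
  # quantity (solutions, traces, -2logL, EM update, AI matrix, score)
  state_at <- function(th, want_ai = TRUE) {
    s2a <- th[["sigma2_a"]]; s2e <- th[["sigma2_e"]]
    s2pe <- if (include_pe) th[["sigma2_pe"]] else NA
    C <- WtW / s2e
    C[idx_a, idx_a] <- C[idx_a, idx_a] + as.matrix(Ainv) / s2a
    if (include_pe) {
      dg <- cbind(idx_pe, idx_pe)
      C[dg] <- C[dg] + 1 / s2pe
    }
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Cinv <- chol2inv(ch)
    rhs <- Wty / s2e
    sol <- drop(Cinv %*% rhs)
    logdetC <- 2 * sum(log(diag(ch)))
    yPy <- (yty - sum(sol * Wty)) / s2e
    # -2 logL_R = ln|R| + ln|G| + ln|C| + y'Py (constants dropped)
    m2ll <- n * log(s2e) + q * log(s2a) + logdetA + logdetC + yPy +
      if (include_pe) q_pe * log(s2pe) else 0
    a_hat <- sol[idx_a]
    Ainv_a <- numeric(q)
    # A^{-1} %*% a_hat via triplet form
    Ainv_a <- as.numeric(Ainv %*% a_hat)
    aAa <- sum(a_hat * Ainv_a)
    tra <- sum(ai_x * Cinv[cbind(idx_a[ai_i], idx_a[ai_j])])
    em <- c(sigma2_a = (aAa + tra) / q,
            sigma2_pe = NA_real_,
            sigma2_e = (yty - sum(sol * Wty)) / (n - p))
    pe_hat <- NULL; trpe <- NA
    if (include_pe) {
      pe_hat <- sol[idx_pe]
      trpe <- sum(diag(Cinv)[idx_pe])
      em[["sigma2_pe"]] <- (sum(pe_hat^2) + trpe) / q_pe
    }
    out <- list(th = th, m2ll = m2ll, sol = sol, em = em, Cinv = Cinv,
                a_hat = a_hat, pe_hat = pe_hat, aAa = aAa, tra = tra,
                trpe = trpe, yPy = yPy)
    if (want_ai) {
      e_res <- (y - as.numeric(W %*% sol))
      Py <- e_res / s2e
      U <- cbind(as.numeric(Za %*% a_hat) / s2a,
                 if (include_pe) as.numeric(Zpe %*% pe_hat) / s2pe,
                 Py)
      WtU <- as.matrix(Matrix::crossprod(W, U))
      PU <- (U - as.matrix(W %*% (Cinv %*% (WtU / s2e)))) / s2e
      AImat <- 0.5 * crossprod(U, PU)
      # REML score vector
      tr_PZAZ <- (q - tra / s2a) / s2a
      sc_a <- -0.5 * (tr_PZAZ - aAa / s2a^2)
      sc <- sc_a
      tr_PZpe <- NA
      if (include_pe) {
        tr_PZpe <- (q_pe - trpe / s2pe) / s2pe
        sc_pe <- -0.5 * (tr_PZpe - sum(pe_hat^2) / s2pe^2)
        sc <- c(sc, sc_pe)
      }
      trP <- ((n - p) - s2a * tr_PZAZ -
                (if (include_pe) s2pe * tr_PZpe else 0)) / s2e
      sc_e <- -0.5 * (trP - sum(Py^2))
      out$score <- c(sc, sc_e)
      out$AImat <- AImat
    }
    out
  }

  pick <- function(v) if (include_pe) v else v[c("sigma2_a", "sigma2_e")]
  st <- state_at(pick(th))
  if (is.null(st)) stop("mixed-model equations not positive definite at ",
                        "the starting values")
  m2ll_trace <- st$m2ll
  step_type <- character(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    cur <- pick(th)
    cand <- NULL; type <- "em"
    if (method == "ai" && !is.null(st$AImat)) {
      # components pinned at the floor are held there and dropped from
      # the Newton system (it is near-singular in their direction)
      pinned <- cur <= floor_v * 1.01
      step <- rep(0, length(cur))
      free_i <- which(!pinned)
      step_f <- tryCatch(
        solve(st$AImat[free_i, free_i, drop = FALSE], st$score[free_i]),
        error = function(e) NULL)
      if (!is.null(step_f)) step[free_i] <- step_f else step <- NULL
      if (!is.null(step) && length(free_i)) {
        # components pushed negative are clamped at the floor (boundary
        # estimates); a halved step is tried if the full one is rejected
        for (frac in c(1, 0.5, 0.25)) {
          prop <- pmax(cur + frac * step, floor_v)
          st_prop <- state_at(prop)
          if (!is.null(st_prop) && st_prop$m2ll <= st$m2ll + 1e-10) {
            cand <- st_prop; type <- "ai"
            break
          }
        }
      }
    }
    if (is.null(cand)) {
      em_th <- pmax(st$em[names(cur)], floor_v)
      cand <- state_at(em_th)
      type <- "em"
      if (is.null(cand)) stop("EM update produced a singular system")
    }
    new <- cand$th
    # components drifting to the zero boundary (below 0.1% of the
    # phenotypic variance) are excluded from the relative-change
    # criterion: their relative change never settles
    free <- new > 1e-3 * vp
    delta <- if (any(free))
      sum(((new[free] - cur[free]) / new[free])^2) else 0
    dll <- abs(st$m2ll - cand$m2ll)
    th[names(new)] <- new
    st <- cand
    m2ll_trace <- c(m2ll_trace, st$m2ll)
    step_type <- c(step_type, type)
    if (delta < tol || (dll < 1e-10 && delta < 1e-4)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    msg <- paste0("REML did not converge in ", max_iter,
                  " iterations; final components: ",
                  paste(sprintf("%s=%.6g", names(pick(th)), pick(th)),
                        collapse = ", "))
    if (on_nonconv == "error") stop(msg) else warning(msg)
  }
  boundary <- any(pick(th) <= floor_v * 1.01)

  # component covariance from the AI matrix at convergence
  st_fin <- state_at(pick(th))
  vcov_vc <- tryCatch(solve(st_fin$AImat), error = function(e) NULL)
  s2a <- th[["sigma2_a"]]
  s2pe <- if (include_pe) th[["sigma2_pe"]] else 0
  s2e <- th[["sigma2_e"]]
  s2p <- s2a + s2pe + s2e
  h2 <- s2a / s2p
  rep_t <- (s2a + s2pe) / s2p
  se_h2 <- NA_real_
  if (!is.null(vcov_vc)) {
    g <- if (include_pe) c((s2p - s2a) / s2p^2, -s2a / s2p^2,
                           -s2a / s2p^2)
         else c((s2p - s2a) / s2p^2, -s2a / s2p^2)
    se_h2 <- sqrt(max(0, drop(t(g) %*% vcov_vc %*% g)))
  }
  vc <- data.frame(
    trait = trait, sigma2_a = s2a, sigma2_pe = s2pe, sigma2_e = s2e,
    sigma2_p = s2p, h2 = h2, repeatability = rep_t, se_h2 = se_h2,
    stringsAsFactors = FALSE)
  structure(list(
    vc = vc, minus2logL = m2ll_trace, iterations = length(step_type),
    converged = converged, boundary = boundary, step_type = step_type,
    vcov_vc = vcov_vc, trait = trait, fixed = fixed,
    covariates = covariates, include_pe = include_pe, n = n,
    n_animals = q, n_recorded = q_pe
  ), class = "reml_fit")
}

#' Heritability and its standard error from variance components
#'
#' \eqn{h^2 = \sigma^2_a / (\sigma^2_a + \sigma^2_{pe} + \sigma^2_e)};
#' the SE comes from the delta method on a supplied component covariance
#' matrix (ordered a, pe, e), when available.
#'
#' @param sigma2_a,sigma2_pe,sigma2_e variance components (phenotypic
#'   variance must be positive). Alternatively pass a `reml_fit` as the
#'   single first argument.
#' @param vcov optional 3x3 covariance matrix of the components.
#' @return list with `h2`, `se`, `sigma2_p`.
#' @examples
#' heritability(0.7545, 0.140011, 0.7418)  # 0.46 at 2 dp
#' @export
heritability <- function(sigma2_a, sigma2_pe = 0, sigma2_e = NULL,
                         vcov = NULL) {
  if (inherits(sigma2_a, "reml_fit")) {
    fit <- sigma2_a
    return(heritability(fit$vc$sigma2_a, fit$vc$sigma2_pe,
                        fit$vc$sigma2_e, vcov = fit$vcov_vc))
  }
  stopifnot(!is.null(sigma2_e))
  s2p <- sigma2_a + sigma2_pe + sigma2_e
  if (s2p <= 0) stop("phenotypic variance must be positive")
  h2 <- sigma2_a / s2p
  se <- NA_real_
  if (!is.null(vcov) && nrow(vcov) == 3L) {
    g <- c((s2p - sigma2_a) / s2p^2, -sigma2_a / s2p^2, -sigma2_a / s2p^2)
    se <- sqrt(max(0, drop(t(g) %*% vcov %*% g)))
  }
  list(h2 = h2, se = se, sigma2_p = s2p)
}
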