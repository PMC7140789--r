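#' Bivariate REML: genetic and phenotypic correlations
#'
#' Two-trait repeatability animal model with both traits recorded on
#' every record and a common design. The additive (`G0`), permanent
#' environment (`P0`) and residual (`R0`) 2x2 covariance matrices are
#' estimated by EM-REML (expectation-conditional-maximization on the
#' mixed-model equations), with a guarded extrapolation step every few
#' iterations to accelerate the EM's linear convergence. Updates that
#' leave a covariance matrix non-positive-definite are projected to the
#' nearest PSD matrix (eigenvalue clipping) and flagged. The restricted
#' \eqn{-2\log L} trace is non-increasing for accepted steps.
#'
#' @param data records data.frame with animal id column `goat`.
#' @param traits length-2 character vector of response columns.
#' @param fixed,covariates fixed-effect specification (shared by both
#'   traits), see [build_mme()].
#' @param pedigree a [new_pedigree()].
#' @param start optional list with `G0`, `P0`, `R0` (2x2 matrices).
#' @param include_pe include permanent environment terms.
#' @param tol convergence criterion on squared relative parameter change.
#' @param max_iter iteration cap.
#' @param se compute standard errors of the correlations by a
#'   central-difference observed-information approximation (adds ~90
#'   likelihood evaluations; default FALSE).
#' @param on_nonconv `"error"` or `"warn"`.
#' @return a `reml_biv_fit` list: per-trait `vc`, `correlations`
#'   (data.frame with `r_G`, `r_P`, optional SEs, boundary flags), the
#'   estimated `G0`, `P0`, `R0`, `minus2logL` trace, `iterations`,
#'   `converged`.
#' @export
reml_bivariate <- function(data, traits, fixed = character(),
                           covariates = character(), pedigree,
                           start = NULL, include_pe = TRUE,
                           tol = 1e-10, max_iter = 500, se = FALSE,
                           on_nonconv = c("error", "warn")) {
  on_nonconv <- match.arg(on_nonconv)
  stopifnot(length(traits) == 2L)
  Y <- cbind(as.numeric(data[[traits[1L]]]),
             as.numeric(data[[traits[2L]]]))
  if (any(!stats::complete.cases(Y))) stop("missing trait values")
  X <- design_fixed(data, fixed, covariates)
  n <- nrow(Y); p <- ncol(X)
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
  Ainv_d <- as.matrix(Ainv)
  logdetA <- attr(Ainv, "logdetA")
  WtW <- as.matrix(Matrix::crossprod(W))
  WtY <- as.matrix(Matrix::crossprod(W, Y))
  ndim <- ncol(WtW)
  idx_a <- p + seq_len(q)
  idx_pe <- if (include_pe) p + q + seq_len(q_pe) else integer(0)

  vp <- apply(Y, 2L, stats::var)
  if (is.null(start)) {
    co <- 0.1 * sqrt(vp[1L] * vp[2L])
    mk <- function(f) matrix(c(f * vp[1L], f * co / 0.5 * 0.5,
                               f * co / 0.5 * 0.5, f * vp[2L]), 2L)
    G0 <- mk(0.3); P0 <- if (include_pe) mk(0.2) else NULL; R0 <- mk(0.5)
  } else {
    G0 <- start$G0; P0 <- start$P0; R0 <- start$R0
  }

  psd_project <- function(M, floor_frac = 1e-6) {
    ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
    floor_v <- floor_frac * max(abs(ev$values), 1e-12)
    if (min(ev$values) > floor_v) return(list(M = M, projected = FALSE))
    v <- pmax(ev$values, floor_v)
    list(M = ev$vectors %*% diag(v) %*% t(ev$vectors), projected = TRUE)
  }

  tr_idx <- function(t) (t - 1L) * ndim
  projected_any <- FALSE

  state_at <- function(G0, P0, R0) {
    R0inv <- tryCatch(solve(R0), error = function(e) NULL)
    G0inv <- tryCatch(solve(G0), error = function(e) NULL)
    P0inv <- if (include_pe) tryCatch(solve(P0), error = function(e) NULL)
             else NULL
    if (is.null(R0inv) || is.null(G0inv) ||
        (include_pe && is.null(P0inv))) return(NULL)
    C <- kronecker(R0inv, WtW)
    for (t1 in 1:2) for (t2 in 1:2) {
      ia <- tr_idx(t1) + idx_a; ja <- tr_idx(t2) + idx_a
      C[ia, ja] <- C[ia, ja] + G0inv[t1, t2] * Ainv_d
      if (include_pe) {
        ip <- tr_idx(t1) + idx_pe; jp <- tr_idx(t2) + idx_pe
        dg <- cbind(ip, jp)
        C[dg] <- C[dg] + P0inv[t1, t2]
      }
    }
    rhs <- as.vector(WtY %*% R0inv)
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    Cinv <- chol2inv(ch)
    sol <- drop(Cinv %*% rhs)
    logdetC <- 2 * sum(log(diag(ch)))
    yRy <- sum(diag(R0inv %*% crossprod(Y)))
    yPy <- yRy - sum(sol * rhs)
    m2ll <- n * determinant_log(R0) + q * determinant_log(G0) +
      2 * logdetA + logdetC + yPy +
      if (include_pe) q_pe * determinant_log(P0) else 0
    list(C = C, Cinv = Cinv, sol = sol, m2ll = m2ll)
  }

  em_update <- function(st) {
    sol <- st$sol; Cinv <- st$Cinv
    a1 <- sol[tr_idx(1L) + idx_a]; a2 <- sol[tr_idx(2L) + idx_a]
    G0n <- matrix(0, 2, 2)
    amat <- cbind(a1, a2)
    for (t1 in 1:2) for (t2 in t1:2) {
      quad <- sum(amat[, t1] * (Ainv_d %*% amat[, t2]))
      trc <- sum(Ainv_d * Cinv[tr_idx(t1) + idx_a, tr_idx(t2) + idx_a])
      G0n[t1, t2] <- G0n[t2, t1] <- (quad + trc) / q
    }
    P0n <- NULL
    if (include_pe) {
      p1 <- sol[tr_idx(1L) + idx_pe]; p2 <- sol[tr_idx(2L) + idx_pe]
      pmat <- cbind(p1, p2)
      P0n <- matrix(0, 2, 2)
      for (t1 in 1:2) for (t2 in t1:2) {
        quad <- sum(pmat[, t1] * pmat[, t2])
        trc <- sum(diag(Cinv[tr_idx(t1) + idx_pe,
                             tr_idx(t2) + idx_pe, drop = FALSE]))
        P0n[t1, t2] <- P0n[t2, t1] <- (quad + trc) / q_pe
      }
    }
    # residual: e_k e_k' plus the W_k Cinv W_k' correction summed over
    # records equals elementwise products of Cinv blocks with W'W
    E <- Y - cbind(as.numeric(W %*% sol[tr_idx(1L) + seq_len(ndim)]),
                   as.numeric(W %*% sol[tr_idx(2L) + seq_len(ndim)]))
    R0n <- matrix(0, 2, 2)
    for (t1 in 1:2) for (t2 in t1:2) {
      quad <- sum(E[, t1] * E[, t2])
      trc <- sum(WtW * Cinv[tr_idx(t1) + seq_len(ndim),
                            tr_idx(t2) + seq_len(ndim)])
      R0n[t1, t2] <- R0n[t2, t1] <- (quad + trc) / n
    }
    list(G0 = G0n, P0 = P0n, R0 = R0n)
  }

  par_vec <- function(G0, P0, R0) {
    v <- c(G0[1, 1], G0[1, 2], G0[2, 2], R0[1, 1], R0[1, 2], R0[2, 2])
    if (include_pe) v <- c(v, P0[1, 1], P0[1, 2], P0[2, 2])
    v
  }

  mk2 <- function(v) matrix(c(v[1], v[2], v[2], v[3]), 2L)
  unpack <- function(v) list(
    G0 = mk2(v[1:3]), R0 = mk2(v[4:6]),
    P0 = if (include_pe) mk2(v[7:9]) else NULL)
  okpsd <- function(M) is.null(M) ||
    min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) > 0
  state_par <- function(v) {
    u <- unpack(v)
    if (!okpsd(u$G0) || !okpsd(u$R0) || !okpsd(u$P0)) return(NULL)
    state_at(u$G0, u$P0, u$R0)
  }
  em_from <- function(st) {
    up <- em_update(st)
    # progressively stronger eigenvalue floors until the system is
    # factorizable (degenerate data, e.g. duplicated traits, drive a
    # covariance matrix singular)
    for (ff in c(1e-6, 1e-4, 1e-2)) {
      pg <- psd_project(up$G0, ff); pr <- psd_project(up$R0, ff)
      pp <- if (include_pe) psd_project(up$P0, ff) else
        list(M = NULL, projected = FALSE)
      th <- par_vec(pg$M, pp$M, pr$M)
      stn <- state_par(th)
      if (!is.null(stn)) {
        projected_any <<- projected_any || pg$projected ||
          pr$projected || pp$projected
        return(list(th = th, st = stn))
      }
    }
    stop("EM update produced a singular system")
  }

  st <- state_at(G0, P0, R0)
  if (is.null(st)) stop("starting covariance matrices give a singular ",
                        "system")
  m2ll_trace <- st$m2ll
  converged <- FALSE
  th0 <- par_vec(G0, P0, R0)
  it <- 0L
  last_rel <- Inf
  # SQUAREM acceleration: two EM maps per cycle plus a guarded
  # extrapolated jump; the accepted state never increases -2logL
  for (cycle in seq_len(max_iter)) {
    it <- cycle
    e1 <- em_from(st)
    th1 <- e1$th
    e2 <- em_from(e1$st)
    th2 <- e2$th
    r <- th1 - th0
    v <- (th2 - th1) - r
    best_st <- e2$st; best_th <- th2
    if (sum(v^2) > 0) {
      alpha <- -sqrt(sum(r^2) / sum(v^2))
      thx <- th0 - 2 * alpha * r + alpha^2 * v
      stx <- state_par(thx)
      if (!is.null(stx) && stx$m2ll <= e2$st$m2ll) {
        # polish the jump with one EM map
        ep <- em_from(stx)
        if (ep$st$m2ll <= stx$m2ll) {
          best_st <- ep$st; best_th <- ep$th
        } else {
          best_st <- stx; best_th <- thx
        }
      }
    }
    rel <- sum(((best_th - th0) / pmax(abs(best_th), 1e-12))^2)
    last_rel <- rel
    th0 <- best_th
    st <- best_st
    m2ll_trace <- c(m2ll_trace, st$m2ll)
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  u <- unpack(th0)
  G0 <- u$G0; R0 <- u$R0
  P0 <- if (include_pe) u$P0 else NULL
  if (!converged) {
    msg <- paste0("bivariate REML did not converge in ", max_iter,
                  " cycles (last squared relative change ",
                  signif(last_rel, 3), ")")
    if (on_nonconv == "error") stop(msg) else warning(msg)
  }

  if (!include_pe) P0 <- matrix(0, 2, 2)
  Ptot <- G0 + P0 + R0
  r_G <- G0[1, 2] / sqrt(G0[1, 1] * G0[2, 2])
  r_P <- Ptot[1, 2] / sqrt(Ptot[1, 1] * Ptot[2, 2])
  bound <- abs(r_G) > 1 - 1e-3 | abs(r_P) > 1 - 1e-3 | projected_any
  r_G <- max(-1, min(1, r_G)); r_P <- max(-1, min(1, r_P))

  se_rG <- se_rP <- NA_real_
  if (se) {
    ses <- biv_correlation_se(function(G0x, P0x, R0x)
      state_at(G0x, P0x, R0x)$m2ll, G0, P0, R0, include_pe)
    se_rG <- ses["r_G"]; se_rP <- ses["r_P"]
  }

  vc <- data.frame(
    trait = traits,
    sigma2_a = diag(G0), sigma2_pe = diag(P0), sigma2_e = diag(R0),
    sigma2_p = diag(Ptot), h2 = diag(G0) / diag(Ptot),
    stringsAsFactors = FALSE)
  structure(list(
    vc = vc, G0 = G0, P0 = P0, R0 = R0,
    correlations = data.frame(
      trait_1 = traits[1L], trait_2 = traits[2L],
      sigma_a12 = G0[1, 2], sigma_p12 = Ptot[1, 2],
      r_G = r_G, r_P = r_P, se_rG = unname(se_rG), se_rP = unname(se_rP),
      boundary = bound),
    minus2logL = m2ll_trace, iterations = it, converged = converged,
    psd_projected = projected_any, traits = traits
  ), class = "reml_biv_fit")
}

determinant_log <- function(M) {
  as.numeric(determinant(M, logarithm = TRUE)$modulus)
}

# Delta-method SEs of r_G and r_P from a central-difference observed
# information over the 6 (or 9) covariance parameters.
biv_correlation_se <- function(m2ll_fun, G0, P0, R0, include_pe) {
  mk2 <- function(v) matrix(c(v[1], v[2], v[2], v[3]), 2L)
  pack <- c(G0[1, 1], G0[1, 2], G0[2, 2], R0[1, 1], R0[1, 2], R0[2, 2],
            if (include_pe) c(P0[1, 1], P0[1, 2], P0[2, 2]))
  npar <- length(pack)
  f <- function(v) {
    G <- mk2(v[1:3]); R <- mk2(v[4:6])
    P <- if (include_pe) mk2(v[7:9]) else NULL
    0.5 * m2ll_fun(G, P, R)  # negative log-likelihood
  }
  h <- pmax(abs(pack), 1e-6) * 1e-4
  H <- matrix(0, npar, npar)
  f0 <- f(pack)
  for (i in seq_len(npar)) {
    for (j in i:npar) {
      vpp <- pack; vpp[i] <- vpp[i] + h[i]; vpp[j] <- vpp[j] + h[j]
      vpm <- pack; vpm[i] <- vpm[i] + h[i]; vpm[j] <- vpm[j] - h[j]
      vmp <- pack; vmp[i] <- vmp[i] - h[i]; vmp[j] <- vmp[j] + h[j]
      vmm <- pack; vmm[i] <- vmm[i] - h[i]; vmm[j] <- vmm[j] - h[j]
      H[i, j] <- H[j, i] <-
        (f(vpp) - f(vpm) - f(vmp) + f(vmm)) / (4 * h[i] * h[j])
    }
  }
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V)) return(c(r_G = NA_real_, r_P = NA_real_))
  grad_corr <- function(get) {
    eps <- h
    g <- numeric(npar)
    for (i in seq_len(npar)) {
      vp <- pack; vp[i] <- vp[i] + eps[i]
      vm <- pack; vm[i] <- vm[i] - eps[i]
      g[i] <- (get(vp) - get(vm)) / (2 * eps[i])
    }
    g
  }
  rg_of <- function(v) v[2] / sqrt(v[1] * v[3])
  rp_of <- function(v) {
    G <- mk2(v[1:3]); R <- mk2(v[4:6])
    P <- if (include_pe) mk2(v[7:9]) else matrix(0, 2, 2)
    S <- G + P + R
    S[1, 2] / sqrt(S[1, 1] * S[2, 2])
  }
  gG <- grad_corr(rg_of); gP <- grad_corr(rp_of)
  c(r_G = sqrt(max(0, drop(t(gG) %*% V %*% gG))),
    r_P = sqrt(max(0, drop(t(gP) %*% V %*% gP))))
}
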