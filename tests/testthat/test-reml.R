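test_that("balanced one-way REML matches the ANOVA expected-mean-squares
           closed form", {
  set.seed(4)
  nb <- 100; r <- 4
  ped <- new_pedigree(sprintf("b%03d", 1:nb), rep(NA, nb), rep(NA, nb))
  b <- rnorm(nb, 0, sqrt(2))
  dat <- data.frame(goat = rep(ped$animal, each = r),
                    y = 5 + rep(b, each = r) + rnorm(nb * r, 0, 1))
  fit <- reml_univariate(dat, "y", pedigree = ped, include_pe = FALSE)
  m <- matrix(dat$y, nrow = r)
  mse <- mean(apply(m, 2, var))
  msb <- r * var(colMeans(m))
  expect_equal(fit$vc$sigma2_a, (msb - mse) / r, tolerance = 1e-4)
  expect_equal(fit$vc$sigma2_e, mse, tolerance = 1e-4)
})

test_that("pure-noise data drive the additive variance to the boundary", {
  set.seed(3)
  ns <- 10; ndo <- 100
  sires <- sprintf("S%02d", 1:ns)
  does <- sprintf("D%03d", 1:ndo)
  ped <- new_pedigree(c(sires, does),
                      c(rep(NA, ns), rep(sires, each = 10)),
                      rep(NA, ns + ndo))
  dat <- data.frame(goat = rep(does, each = 3), y = rnorm(300))
  fit <- reml_univariate(dat, "y", pedigree = ped, on_nonconv = "warn")
  expect_lt(fit$vc$h2, 0.05)
  expect_true(fit$boundary)
})

test_that("the -2 logL trace is monotone non-increasing", {
  s <- halfsib_records(77, n_sires = 15, n_does = 150, n_rec = 3)
  for (m in c("ai", "em")) {
    fit <- reml_univariate(s$dat, "y", pedigree = s$ped, method = m,
                           tol = 1e-10, max_iter = 60,
                           on_nonconv = "warn")
    expect_true(all(diff(fit$minus2logL) <= 1e-8))
  }
})

test_that("a half-sib replicate recovers its variance components", {
  s <- halfsib_records(123, h2 = 0.3, rep_t = 0.45)
  fit <- reml_univariate(s$dat, "y", pedigree = s$ped,
                         on_nonconv = "warn")
  expect_true(fit$converged)
  # single replicate: allow 3 approximate standard errors
  expect_lt(abs(fit$vc$h2 - 0.3), 3 * max(fit$vc$se_h2, 0.05))
  expect_equal(fit$vc$sigma2_p,
               fit$vc$sigma2_a + fit$vc$sigma2_pe + fit$vc$sigma2_e,
               tolerance = 1e-10)
  expect_equal(fit$vc$repeatability,
               (fit$vc$sigma2_a + fit$vc$sigma2_pe) / fit$vc$sigma2_p)
  # estimated PBVs track the simulated truth
  am <- animal_model(s$dat, "y", pedigree = s$ped,
                     vc = as.list(fit$vc[c("sigma2_a", "sigma2_pe",
                                           "sigma2_e")]))
  r <- cor(am$evaluation$pbv, s$bv[am$evaluation$animal])
  expect_gt(r, 0.5)
})

test_that("REML refuses non-identifiable single-record PE models", {
  ped <- new_pedigree(c("A", "B", "C"), rep(NA, 3), rep(NA, 3))
  dat <- data.frame(goat = c("A", "B", "C"), y = c(1, 2, 3))
  expect_error(reml_univariate(dat, "y", pedigree = ped),
               "permanent environment")
  expect_error(reml_univariate(dat[1, ], "y", pedigree = ped,
                               include_pe = FALSE),
               ">= 2 animals")
})

test_that("heritability arithmetic and delta-method SE behave", {
  h <- heritability(0.5, 0.25, 0.25)
  expect_equal(h$h2, 0.5)
  expect_equal(h$sigma2_p, 1)
  expect_true(is.na(h$se))
  V <- diag(c(0.01, 0.005, 0.005))
  h2 <- heritability(0.5, 0.25, 0.25, vcov = V)
  g <- c(0.5, -0.5, -0.5)
  expect_equal(h2$se, sqrt(drop(t(g) %*% V %*% g)))
  expect_equal(heritability(0, 0.3, 0.7)$h2, 0)
  expect_error(heritability(0, 0, 0), "positive")
})

test_that("bivariate REML matches the balanced MANOVA closed form", {
  set.seed(77)
  nb <- 120; r <- 4
  ped <- new_pedigree(sprintf("b%03d", 1:nb), rep(NA, nb), rep(NA, nb))
  G0t <- matrix(c(0.6, 0.36, 0.36, 0.6), 2)
  a <- matrix(rnorm(nb * 2), nb) %*% chol(G0t)
  dat <- data.frame(goat = rep(ped$animal, each = r),
                    y1 = 5 + rep(a[, 1], each = r) + rnorm(nb * r),
                    y2 = 7 + rep(a[, 2], each = r) + rnorm(nb * r))
  fit <- reml_bivariate(dat, c("y1", "y2"), pedigree = ped,
                        include_pe = FALSE, tol = 1e-9, max_iter = 300,
                        on_nonconv = "warn")
  expect_true(all(diff(fit$minus2logL) <= 1e-6))
  Y <- cbind(dat$y1, dat$y2)
  means <- apply(Y, 2, function(v) tapply(v, dat$goat, mean))
  W <- Reduce(`+`, lapply(split(as.data.frame(Y), dat$goat), function(m) {
    mm <- as.matrix(m)
    crossprod(sweep(mm, 2, colMeans(mm)))
  })) / (nb * (r - 1))
  B <- r * cov(means)
  expect_equal(unname(fit$G0), unname((B - W) / r), tolerance = 1e-3)
  expect_equal(unname(fit$R0), unname(W), tolerance = 1e-3)
  # recovered genetic correlation close to the simulated 0.6
  expect_lt(abs(fit$correlations$r_G - 0.6), 0.15)
})

test_that("bivariate REML recovers null correlations and respects
           degenerate bounds", {
  set.seed(10)
  ns <- 15; ndo <- 150; nrec <- 3
  sires <- sprintf("S%02d", 1:ns); does <- sprintf("D%03d", 1:ndo)
  ped <- new_pedigree(c(sires, does),
                      c(rep(NA, ns), rep(sires, each = ndo / ns)),
                      rep(NA, ns + ndo))
  # independent traits: r_G near zero
  set.seed(200)
  bv1 <- rnorm(ndo, 0, sqrt(0.6)); bv2 <- rnorm(ndo, 0, sqrt(0.6))
  bvs1 <- rnorm(ns, 0, sqrt(0.6)); bvs2 <- rnorm(ns, 0, sqrt(0.6))
  b1 <- 0.5 * bvs1[rep(1:ns, each = 10)] + sqrt(0.75) * bv1
  b2 <- 0.5 * bvs2[rep(1:ns, each = 10)] + sqrt(0.75) * bv2
  dat0 <- data.frame(goat = rep(does, each = nrec),
                     y1 = rep(b1, each = nrec) + rnorm(ndo * nrec),
                     y2 = rep(b2, each = nrec) + rnorm(ndo * nrec))
  fit0 <- reml_bivariate(dat0, c("y1", "y2"), pedigree = ped,
                         tol = 1e-8, max_iter = 200, on_nonconv = "warn")
  expect_lt(abs(fit0$correlations$r_G), 0.45)
  # duplicated trait: both correlations at the unit boundary
  datd <- dat0
  datd$y2 <- datd$y1
  fitd <- reml_bivariate(datd, c("y1", "y2"), pedigree = ped,
                         tol = 1e-8, max_iter = 100, on_nonconv = "warn")
  expect_gt(fitd$correlations$r_G, 0.98)
  expect_gt(fitd$correlations$r_P, 0.98)
  expect_true(fitd$correlations$boundary)
})
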