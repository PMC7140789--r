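test_that("numeric-declared input reduces to correlation-matrix PCA", {
  set.seed(3)
  X <- matrix(rnorm(200 * 6), 200, 6) %*% matrix(rnorm(36), 6)
  colnames(X) <- paste0("v", 1:6)
  fit <- fit_catpca(X, n_dims = 2, level = "numeric")
  ev <- eigen(cor(X), symmetric = TRUE)
  ref <- ev$vectors[, 1:2] %*% diag(sqrt(ev$values[1:2]))
  expect_lt(max(abs(fit$eigenvalues - ev$values[1:2])), 1e-6)
  expect_lt(max(abs(abs(fit$loadings) - abs(ref))), 1e-6)
  # object scores standardized per dimension
  expect_lt(max(abs(colMeans(fit$object_scores))), 1e-10)
  expect_equal(unname(colSums(fit$object_scores^2) / 200), c(1, 1),
               tolerance = 1e-8)
  # eigenvalue = sum of squared loadings
  expect_equal(colSums(fit$loadings^2), fit$eigenvalues,
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("a duplicated factor receives identical loadings", {
  set.seed(4)
  x <- data.frame(a = sample(1:3, 150, TRUE), b = sample(1:3, 150, TRUE),
                  c = sample(1:2, 150, TRUE))
  x$a2 <- x$a
  fit <- fit_catpca(x, n_dims = 2)
  expect_equal(fit$loadings["a", ], fit$loadings["a2", ],
               tolerance = 1e-6)
})

test_that("two independent latent blocks are recovered at |0.5| loading", {
  set.seed(14)
  n <- 300
  lat1 <- rnorm(n); lat2 <- rnorm(n)
  tern <- function(v) as.integer(cut(v, 3, labels = FALSE))
  x <- data.frame(
    a1 = tern(lat1 + rnorm(n, 0, 0.6)), a2 = tern(lat1 + rnorm(n, 0, 0.6)),
    a3 = tern(lat1 + rnorm(n, 0, 0.6)), b1 = tern(lat2 + rnorm(n, 0, 0.6)),
    b2 = tern(lat2 + rnorm(n, 0, 0.6)), b3 = tern(lat2 + rnorm(n, 0, 0.6)),
    noise = sample(1:3, n, TRUE))
  fit <- fit_catpca(x, n_dims = 2)
  sel <- select_snps(fit, threshold = 0.5)
  got <- lapply(sel$retained, sort)
  expect_setequal(got[[1]], if ("a1" %in% got[[1]]) c("a1", "a2", "a3")
                  else c("b1", "b2", "b3"))
  expect_setequal(unlist(got), c("a1", "a2", "a3", "b1", "b2", "b3"))
  # the variable with no latent involvement is discarded
  expect_true("noise" %in% sel$discarded)
})

test_that("varimax preserves communalities and is orthogonal", {
  set.seed(11)
  L <- matrix(rnorm(18), 9, 2)
  vr <- varimax_rotate(L)
  expect_lt(max(abs(rowSums(L^2) - rowSums(vr$loadings^2))), 1e-10)
  expect_lt(max(abs(crossprod(vr$rotmat) - diag(2))), 1e-10)
  expect_gte(vr$criterion["after"], vr$criterion["before"] - 1e-12)
  # simple structure is a fixed point (up to sign/permutation)
  Ls <- rbind(c(0.9, 0), c(0.8, 0), c(0, 0.7), c(0, 0.85))
  vs <- varimax_rotate(Ls)
  agree <- abs(vs$loadings) - abs(Ls)
  perm <- abs(vs$loadings[, 2:1]) - abs(Ls)
  expect_true(max(abs(agree)) < 1e-6 || max(abs(perm)) < 1e-6)
  # single dimension: identity no-op
  v1 <- varimax_rotate(matrix(c(0.3, -0.5, 0.8), 3, 1))
  expect_equal(unname(v1$rotmat), matrix(1))
})

test_that("Cronbach's alpha follows the eigenvalue formula", {
  expect_equal(cronbach_alpha(1, 10), 0)
  expect_equal(cronbach_alpha(4.607, 40), 0.803, tolerance = 5e-4)
  expect_equal(cronbach_alpha(1000, 1000), 1, tolerance = 2e-3)
  expect_true(is.na(cronbach_alpha(-1, 10)))
})

test_that("SNP selection applies an inclusive threshold", {
  L <- rbind(s1 = c(0.5, 0.1), s2 = c(0.49, 0.2), s3 = c(-0.6, 0.55))
  colnames(L) <- c("dim1", "dim2")
  sel <- select_snps(L, threshold = 0.5, rotate = FALSE)
  expect_true("s1" %in% sel$retained$dim1)  # boundary inclusive
  expect_false("s2" %in% sel$retained$dim1)
  expect_setequal(sel$retained$dim2, "s3")  # multi-dimension assignment
  expect_equal(sel$discarded, "s2")
  selmax <- select_snps(L, threshold = 0.5, rotate = FALSE,
                        assign = "max")
  expect_false("s3" %in% selmax$retained$dim2)  # |-0.6| > |0.55|
  # all below threshold -> everything discarded
  sel0 <- select_snps(L / 10, threshold = 0.5, rotate = FALSE)
  expect_equal(sort(sel0$discarded), c("s1", "s2", "s3"))
  expect_true(all(lengths(sel0$retained) == 0))
})

test_that("total fit is non-decreasing in the number of dimensions", {
  set.seed(15)
  x <- as.data.frame(matrix(sample(1:3, 120 * 6, TRUE), 120, 6))
  fits <- sapply(1:4, function(d)
    fit_catpca(x, n_dims = d, max_iter = 300)$fit)
  expect_true(all(diff(fits) > -1e-6))
})

test_that("degenerate inputs raise informative errors", {
  x <- data.frame(a = rep(1, 10), b = rep(2, 10))
  expect_error(fit_catpca(x, 1), "non-constant")
  x2 <- data.frame(a = rep(1:2, 5), b = rep(1:2, each = 5))
  expect_error(fit_catpca(x2, 2), "n_dims")
})

test_that("cluster factors merge rare code combinations", {
  codes <- cbind(S1 = c(rep(1L, 8), 2L, 3L), S2 = c(rep(2L, 8), 1L, 1L))
  rownames(codes) <- sprintf("i%02d", 1:10)
  cf <- cluster_factors(codes, list(dim1 = c("S1", "S2")), min_count = 3)
  expect_equal(nlevels(cf$dim1), 2L)
  expect_equal(sum(cf$dim1 == "other"), 2L)
})
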