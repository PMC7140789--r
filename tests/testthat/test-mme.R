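test_that("single-record unrelated animals shrink by the heritability ratio", {
  set.seed(1)
  n <- 40
  ped <- new_pedigree(sprintf("a%02d", 1:n), rep(NA, n), rep(NA, n))
  y <- rnorm(n, 10, 2)
  dat <- data.frame(goat = ped$animal, y = y)
  vc <- list(sigma2_a = 1.5, sigma2_pe = 1, sigma2_e = 2)
  mme <- build_mme(dat, "y", pedigree = ped, vc = vc, include_pe = FALSE)
  sol <- solve_blup(mme)
  k <- 1.5 / (1.5 + 2)
  expect_lt(max(abs(sol$pbv - k * (y - mean(y)))), 1e-8)
  # bookkeeping: equations = fixed columns + animal block (no PE here)
  expect_equal(nrow(mme$C), 1 + n)
  # with PE the system is fixed + 2 x animals
  dat2 <- rbind(dat, dat)
  mme2 <- build_mme(dat2, "y", pedigree = ped, vc = vc)
  expect_equal(nrow(mme2$C), 1 + 2 * n)
})

test_that("vanishing additive variance drives every PBV to zero", {
  set.seed(2)
  n <- 30
  ped <- new_pedigree(sprintf("a%02d", 1:n), rep(NA, n), rep(NA, n))
  dat <- data.frame(goat = rep(ped$animal, 2), y = rnorm(2 * n, 5, 1))
  mme <- build_mme(dat, "y", pedigree = ped,
                   vc = list(sigma2_a = 1e-10, sigma2_pe = 0.5,
                             sigma2_e = 1))
  sol <- solve_blup(mme)
  expect_lt(max(abs(sol$pbv)), 1e-6)
})

test_that("a non-recorded offspring's PBV equals the parent average", {
  ped <- new_pedigree(c("S", "D", "O"), c(NA, NA, "S"), c(NA, NA, "D"))
  dat <- data.frame(goat = c("S", "S", "D", "D"), y = c(5, 6, 9, 8))
  mme <- build_mme(dat, "y", pedigree = ped,
                   vc = list(sigma2_a = 1, sigma2_pe = 0.5, sigma2_e = 1))
  sol <- solve_blup(mme)
  expect_lt(abs(sol$pbv["O"] - (sol$pbv["S"] + sol$pbv["D"]) / 2), 1e-8)
})

test_that("sparse MME solutions match a dense direct solve", {
  set.seed(5)
  ped <- random_pedigree(41, n_max = 15)
  rec <- sample(ped$animal, 8)
  dat <- data.frame(goat = rep(rec, each = 2),
                    y = rnorm(16, 20, 3),
                    farm = sample(c("A", "B"), 16, TRUE))
  mme <- build_mme(dat, "y", fixed = "farm", pedigree = ped,
                   vc = list(sigma2_a = 2, sigma2_pe = 1, sigma2_e = 3))
  sol <- solve_blup(mme)
  dense <- solve(as.matrix(mme$C), mme$rhs)
  expect_lt(max(abs(sol$solution - dense)), 1e-8)
})

test_that("prediction statistics obey their information-theoretic bounds", {
  set.seed(6)
  # one recorded founder, one fully disconnected founder
  ped <- new_pedigree(c("R", "X"), c(NA, NA), c(NA, NA))
  dat <- data.frame(goat = c("R", "R", "R"), y = c(4, 5, 6))
  vc <- list(sigma2_a = 2, sigma2_pe = 0.5, sigma2_e = 1)
  mme <- build_mme(dat, "y", pedigree = ped, vc = vc)
  ps <- prediction_stats(mme)
  # disconnected animal with no records: PEV = sigma2_a, accuracy 0
  expect_equal(ps$pev[ps$animal == "X"], 2, tolerance = 1e-8)
  expect_equal(ps$rti[ps$animal == "X"], 0, tolerance = 1e-4)
  expect_true(all(ps$rti >= 0 & ps$rti <= 1))
  expect_equal(ps$rap, ps$rti^2)
  # SEP matches the dense-inverse oracle
  Cinv <- solve(as.matrix(mme$C))
  expect_equal(ps$pev, diag(Cinv)[mme$idx_animal], tolerance = 1e-8,
               ignore_attr = TRUE)
  # denominator variant without inbreeding
  ps2 <- prediction_stats(mme, use_inbreeding = FALSE)
  expect_equal(ps2$rti[ps2$animal == "X"], 0, tolerance = 1e-4)
})

test_that("identifiability guards reject impossible specifications", {
  ped <- new_pedigree(c("A", "B"), c(NA, NA), c(NA, NA))
  one <- data.frame(goat = c("A", "B"), y = c(1, 2))
  expect_error(build_mme(one, "y", pedigree = ped,
                         vc = list(sigma2_a = 1, sigma2_pe = 1,
                                   sigma2_e = 1)),
               "permanent environment")
  expect_error(build_mme(one[0, ], "y", pedigree = ped,
                         vc = list(sigma2_a = 1, sigma2_pe = 1,
                                   sigma2_e = 1)),
               "no records")
  stranger <- data.frame(goat = "Z", y = 1)
  expect_error(build_mme(stranger, "y", pedigree = ped,
                         vc = list(sigma2_a = 1, sigma2_pe = 1,
                                   sigma2_e = 1)),
               "missing from the pedigree")
})

test_that("model comparison reports descriptives and cross-correlations", {
  set.seed(7)
  ev1 <- data.frame(animal = sprintf("a%02d", 1:20), trait = "milk",
                    pbv = rnorm(20), sep = runif(20, 0.4, 0.6),
                    rti = runif(20, 0.2, 0.8))
  ev1$rap <- ev1$rti^2
  ev2 <- ev1
  ev2$sep <- ev1$sep * 1.2
  cmp <- compare_models(ev1, ev2)
  # identical PBVs across variants -> correlation exactly 1
  expect_equal(cmp$correlations$pbv, 1)
  expect_equal(nrow(cmp$descriptives), 4L)  # 1 trait x 2 models x 2 params
  expect_error(compare_models(ev1, transform(ev2, animal = paste0("z", animal))),
               "no animals")
})
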