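test_that("simulated pedigrees respect demography, order and seeds", {
  cfg0 <- sim_config(n_founders = 2, n_generations = 0, seed = 5)
  ped0 <- simulate_pedigree(cfg0)
  expect_equal(nrow(ped0), 2L)
  expect_true(all(is.na(ped0$sire)))

  cfg <- sim_config(n_founders = 20, n_generations = 3, seed = 5)
  ped <- simulate_pedigree(cfg)
  ped_b <- simulate_pedigree(cfg)
  expect_identical(ped, ped_b)
  # graph-traversal oracle: walking ancestors from any animal only ever
  # moves to earlier rows
  idx <- seq_len(nrow(ped))
  expect_true(all(ped$sire_idx < idx))
  expect_true(all(ped$dam_idx < idx))
  expect_true(all(ped$sex[ped$sire_idx[ped$sire_idx > 0]] == "M"))
  expect_true(all(ped$sex[ped$dam_idx[ped$dam_idx > 0]] == "F"))

  # one founder cannot breed a population
  expect_error(sim_config(n_founders = 1), "n_founders")
})

test_that("founder genotypes are near HWE and blocks carry the LD", {
  cfg <- sim_config(n_founders = 800, n_generations = 0,
                    maf_range = c(0.5, 0.5), n_snps = 12,
                    ld_block_sizes = c(6, 6), ld_rho = 0.85, seed = 2)
  ped <- simulate_pedigree(cfg)
  gt <- simulate_genotypes(ped, cfg)
  het <- gt$hap1[, 1] + gt$hap2[, 1]
  freq <- table(factor(het, levels = 0:2)) / length(het)
  expect_equal(unname(as.vector(freq)), c(0.25, 0.5, 0.25),
               tolerance = 0.07)
  ld <- ld_table(gt)
  blk <- function(s) ifelse(as.integer(sub("SNP", "", s)) <= 6, 1L, 2L)
  within <- blk(ld$snp_i) == blk(ld$snp_j)
  expect_gt(mean(ld$r2[within]), mean(ld$r2[!within]))
})

test_that("offspring genotypes are Mendelian-consistent for all trios", {
  cfg <- sim_config(n_founders = 40, n_generations = 2, seed = 3)
  ped <- simulate_pedigree(cfg)
  gt <- simulate_genotypes(ped, cfg)
  off <- which(ped$sire_idx > 0 & ped$dam_idx > 0)
  for (i in off) {
    # each transmitted haplotype must equal one of the parent's two
    # within every block
    blocks <- rep(seq_along(cfg$ld_block_sizes), cfg$ld_block_sizes)
    for (b in unique(blocks)) {
      cols <- which(blocks == b)
      s <- ped$sire_idx[i]; d <- ped$dam_idx[i]
      expect_true(all(gt$hap1[i, cols] == gt$hap1[s, cols]) ||
                  all(gt$hap1[i, cols] == gt$hap2[s, cols]))
      expect_true(all(gt$hap2[i, cols] == gt$hap1[d, cols]) ||
                  all(gt$hap2[i, cols] == gt$hap2[d, cols]))
    }
  }
})

test_that("lactation records carry the configured genetic architecture", {
  cfg <- sim_config(n_founders = 400, n_generations = 1, seed = 11,
                    traits = c("milk", "fat"),
                    phen_var = c(milk = 2, fat = 1.7),
                    trait_mean = c(milk = 380, fat = 20),
                    true_h2 = c(milk = 0.3, fat = 0.25),
                    true_repeatability = c(milk = 0.45, fat = 0.45),
                    true_genetic_corr = diag(2),
                    snp_additive_effects = NULL,
                    records_per_doe = c(3, 5))
  ped <- simulate_pedigree(cfg)
  gt <- simulate_genotypes(ped, cfg)
  lac <- simulate_lactations(ped, gt, cfg)
  expect_true(all(c("goat", "milk", "fat", "age_months") %in%
                    names(lac$records)))
  # realized var(BV)/s2p close to h2 among founders (known truth)
  founders <- ped$animal[ped$generation == 0]
  bv <- lac$truth$true_breeding_value[founders, "milk"]
  expect_equal(var(bv) / 2, 0.3, tolerance = 0.05)
  # determinism
  lac2 <- simulate_lactations(ped, gt, cfg)
  expect_identical(lac$records, lac2$records)
  # zero-heritability, zero-SNP variant: between-animal variance of
  # record means is PE + residual/k only
  cfg0 <- sim_config(n_founders = 400, n_generations = 1, seed = 12,
                     traits = "milk", phen_var = c(milk = 2),
                     trait_mean = c(milk = 380),
                     true_h2 = c(milk = 0), true_genetic_corr = diag(1),
                     true_repeatability = c(milk = 0.4),
                     snp_additive_effects = NULL,
                     records_per_doe = c(4, 4), fixed_effect_sd = 0)
  ped0 <- simulate_pedigree(cfg0)
  gt0 <- simulate_genotypes(ped0, cfg0)
  lac0 <- simulate_lactations(ped0, gt0, cfg0)
  expect_true(all(lac0$truth$true_breeding_value == 0))
  vm <- var(tapply(lac0$records$milk, lac0$records$goat, mean))
  expect_equal(vm, 0.4 * 2 + 0.6 * 2 / 4, tolerance = 0.25)
})

test_that("offspring breeding values are parent average plus Mendelian noise", {
  cfg <- sim_config(n_founders = 300, n_generations = 2, seed = 21,
                    traits = "milk", phen_var = c(milk = 2),
                    trait_mean = c(milk = 380), true_h2 = c(milk = 0.4),
                    true_repeatability = c(milk = 0.5),
                    true_genetic_corr = diag(1),
                    snp_additive_effects = NULL)
  ped <- simulate_pedigree(cfg)
  gt <- simulate_genotypes(ped, cfg)
  lac <- simulate_lactations(ped, gt, cfg)
  bv <- lac$truth$true_breeding_value[, "milk"]
  off <- which(ped$sire_idx > 0 & ped$dam_idx > 0)
  pa <- (bv[ped$sire_idx[off]] + bv[ped$dam_idx[off]]) / 2
  fit <- stats::lm(bv[off] ~ pa)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.15)
  # Mendelian deviation variance ~ 0.5 * s2a for non-inbred parents
  expect_equal(var(bv[off] - pa), 0.5 * 0.4 * 2, tolerance = 0.12)
})

test_that("genotype tables round-trip through the PLINK-like dialect", {
  cfg <- sim_config(n_founders = 30, n_generations = 1, seed = 8)
  ped <- simulate_pedigree(cfg)
  gt <- simulate_genotypes(ped, cfg)
  f <- tempfile(fileext = ".tsv")
  write_genotypes(gt, f)
  gt2 <- read_genotypes(f)
  expect_equal(gt2$animals, gt$animals)
  # the unordered genotype must survive (alleles may swap within a call)
  g1 <- paste0(pmin(gt$allele1, gt$allele2), pmax(gt$allele1, gt$allele2))
  g2 <- paste0(pmin(gt2$allele1, gt2$allele2), pmax(gt2$allele1, gt2$allele2))
  expect_equal(g2, g1)
  unlink(f)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(ld_block_sizes = c(10, 10)), "sum")
  expect_error(sim_config(true_h2 = c(milk = 0.5, fat = 0.24,
                                      protein = 0.24, solids = 0.24,
                                      lactose = 0.22, scc = 0.2),
                          true_repeatability = c(milk = 0.4, fat = 0.44,
                                                 protein = 0.44,
                                                 solids = 0.44,
                                                 lactose = 0.42,
                                                 scc = 0.4)),
               "repeatability")
  bad_corr <- matrix(0.99, 6, 6); diag(bad_corr) <- 1
  bad_corr[1, 2] <- bad_corr[2, 1] <- -0.99
  expect_error(sim_config(true_genetic_corr = bad_corr), "semi-definite")
})
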