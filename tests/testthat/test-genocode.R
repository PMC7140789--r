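test_that("additive/dominance encoding follows the nominal 1/2/3 scheme", {
  calls <- rbind(i1 = c("AA", "AA"), i2 = c("AG", "AA"),
                 i3 = c("GG", "AA"), i4 = c("AA", "AA"),
                 i5 = c("AG", "AA"))
  colnames(calls) <- c("S1", "S2")
  gt <- genotypes_from_calls(calls)
  enc <- encode_additive_dominance(gt)
  # A is major at S1 (6 A vs 4 G)
  expect_equal(unname(enc$additive[, "S1"]), c(1L, 2L, 3L, 1L, 2L))
  expect_equal(unname(enc$dominance[, "S1"]), c(1L, 2L, 1L, 1L, 2L))
  expect_false(enc$monomorphic["S1"][[1]])
  # S2 constant
  expect_true(enc$monomorphic[["S2"]])
  expect_equal(unname(enc$additive[, "S2"]), rep(1L, 5))

  # >2 alleles errors naming the SNP
  bad <- rbind(i1 = c("AC"), i2 = c("AG"))
  colnames(bad) <- "S9"
  expect_error(encode_additive_dominance(genotypes_from_calls(bad)), "S9")
})

test_that("encoding is invariant to allele relabeling", {
  set.seed(5)
  a <- sample(c("AA", "AG", "GG"), 40, replace = TRUE,
              prob = c(0.5, 0.35, 0.15))
  calls <- cbind(S1 = a,
                 S1_swapped = chartr("AG", "GA", a))
  rownames(calls) <- sprintf("i%02d", 1:40)
  enc <- encode_additive_dominance(genotypes_from_calls(calls))
  # identical partition of animals (same codes; A major maps to G major)
  expect_equal(unname(enc$additive[, 1]), unname(enc$additive[, 2]))
  expect_equal(unname(enc$dominance[, 1]), unname(enc$dominance[, 2]))
})

test_that("minor allele frequency matches the counting oracle", {
  counts <- c(AA = 25, AG = 50, GG = 25)
  calls <- cbind(S1 = rep(names(counts), counts))
  rownames(calls) <- sprintf("i%03d", seq_len(sum(counts)))
  maf <- minor_allele_freq(genotypes_from_calls(calls))
  expect_equal(maf$maf, 0.5)
  expect_false(maf$rare)

  counts2 <- c(AA = 99, AG = 1)
  calls2 <- cbind(S1 = rep(names(counts2), counts2))
  rownames(calls2) <- sprintf("i%03d", 1:100)
  maf2 <- minor_allele_freq(genotypes_from_calls(calls2))
  expect_equal(maf2$maf, 0.005)
  expect_true(maf2$rare)

  # random table vs (2 hom_minor + het) / 2N
  set.seed(6)
  g <- sample(c("AA", "AG", "GG"), 200, replace = TRUE,
              prob = c(0.6, 0.3, 0.1))
  calls3 <- cbind(S1 = g)
  rownames(calls3) <- sprintf("i%03d", 1:200)
  maf3 <- minor_allele_freq(genotypes_from_calls(calls3))
  oracle <- (2 * sum(g == "GG") + sum(g == "AG")) / 400
  expect_equal(maf3$maf, min(oracle, 1 - oracle))
})

test_that("LD from phased toy haplotypes matches the direct formula", {
  # haplotype counts AB:40 Ab:10 aB:10 ab:40 paired without double
  # heterozygotes, so EM reproduces the direct counts exactly:
  # 10 AB|Ab, 10 AB|aB, 10 AB|AB, 20 ab|ab
  h1 <- c(rep("AB", 30), rep("ab", 20))
  h2 <- c(rep("Ab", 10), rep("aB", 10), rep("AB", 10), rep("ab", 20))
  gt <- genotypes_from_haplotypes(h1, h2)
  r <- ld_pair(gt, "S1", "S2")
  expect_equal(r$D, 0.15, tolerance = 1e-6)
  expect_equal(r$D_prime, 0.6, tolerance = 1e-6)
  expect_equal(r$r2, 0.36, tolerance = 1e-6)
  expect_equal(unname(r$haplotype_freqs),
               c(0.4, 0.1, 0.1, 0.4), tolerance = 1e-6)
})

test_that("self-LD is complete and equilibrium gives D = 0", {
  set.seed(7)
  g <- sample(c("AA", "AG", "GG"), 300, replace = TRUE,
              prob = c(0.36, 0.48, 0.16))
  calls <- cbind(S1 = g, S1b = g)
  rownames(calls) <- sprintf("i%03d", 1:300)
  gt <- genotypes_from_calls(calls)
  r <- ld_pair(gt, "S1", "S1b")
  expect_equal(r$D_prime, 1, tolerance = 1e-6)
  expect_equal(r$r2, 1, tolerance = 1e-6)

  # exact linkage equilibrium: haplotype freqs are products (p=0.5, q=0.5)
  # all 16 ordered haplotype pairs equally represented, no ambiguity issue
  haps <- c("AB", "Ab", "aB", "ab")
  pairs <- expand.grid(h1 = haps, h2 = haps, stringsAsFactors = FALSE)
  gt2 <- genotypes_from_haplotypes(rep(pairs$h1, 4), rep(pairs$h2, 4))
  r2 <- ld_pair(gt2, "S1", "S2")
  expect_equal(r2$D, 0, tolerance = 1e-6)
})

test_that("monomorphic SNPs yield undefined LD and are reported", {
  calls <- cbind(S1 = rep("AA", 10), S2 = rep(c("AG", "GG"), 5))
  rownames(calls) <- sprintf("i%02d", 1:10)
  gt <- genotypes_from_calls(calls)
  expect_error(ld_pair(gt, "S1", "S2"), "monomorphic")
  # ld_table silently restricts itself to polymorphic SNPs
  expect_equal(nrow(ld_table(gt)), 0L)
})

test_that("heterozygosity summary reflects the panel", {
  cfg <- sim_config(n_founders = 300, n_generations = 0, seed = 9,
                    maf_range = c(0.3, 0.5))
  ped <- simulate_pedigree(cfg)
  gt <- simulate_genotypes(ped, cfg)
  het <- heterozygosity(gt)
  expect_equal(het$mean, 0.45, tolerance = 0.12)
})
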