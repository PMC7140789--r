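# Shared fixtures, built in code at test time.

# Paternal half-sib design with repeated records and known components:
# n_sires unrelated sires, n_does/n_sires does per sire, dams unknown.
halfsib_records <- function(seed, n_sires = 80, n_does = 800, n_rec = 4,
                            h2 = 0.3, rep_t = 0.45, s2p = 2, mu = 10) {
  set.seed(seed)
  sires <- sprintf("S%03d", seq_len(n_sires))
  does <- sprintf("D%04d", seq_len(n_does))
  ped <- new_pedigree(c(sires, does),
                      c(rep(NA, n_sires), rep(sires, each = n_does / n_sires)),
                      rep(NA, n_sires + n_does))
  s2a <- h2 * s2p; s2pe <- (rep_t - h2) * s2p; s2e <- (1 - rep_t) * s2p
  bv_s <- stats::rnorm(n_sires, 0, sqrt(s2a))
  bv_d <- 0.5 * bv_s[rep(seq_len(n_sires), each = n_does / n_sires)] +
    stats::rnorm(n_does, 0, sqrt(0.75 * s2a))
  pe <- stats::rnorm(n_does, 0, sqrt(s2pe))
  dat <- data.frame(
    goat = rep(does, each = n_rec),
    y = mu + rep(bv_d + pe, each = n_rec) +
      stats::rnorm(n_does * n_rec, 0, sqrt(s2e)))
  list(ped = ped, dat = dat, bv = stats::setNames(c(bv_s, bv_d), c(sires, does)),
       s2a = s2a, s2pe = s2pe, s2e = s2e)
}

# Random valid pedigree for relationship-matrix checks.
random_pedigree <- function(seed, n_max = 200) {
  set.seed(seed)
  n <- sample(20:n_max, 1L)
  nf <- max(4L, round(n * 0.3))
  animal <- sprintf("P%04d", seq_len(n))
  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.3, 0.7))
  sex[1:2] <- c("M", "F")
  sire <- dam <- rep(NA_character_, n)
  for (i in seq(nf + 1L, n)) {
    males <- which(sex[seq_len(i - 1L)] == "M")
    females <- which(sex[seq_len(i - 1L)] == "F")
    if (length(males) && stats::runif(1) < 0.9)
      sire[i] <- animal[males[sample.int(length(males), 1L)]]
    if (length(females) && stats::runif(1) < 0.9)
      dam[i] <- animal[females[sample.int(length(females), 1L)]]
  }
  new_pedigree(animal, sire, dam, sex)
}

# Genotype table from explicit haplotype-pair strings like "AB" (allele
# at SNP1, allele at SNP2), one pair of strings per animal.
genotypes_from_haplotypes <- function(h1, h2, snps = c("S1", "S2")) {
  n <- length(h1)
  gt <- list(animals = sprintf("i%03d", seq_len(n)), snps = snps,
             allele1 = cbind(substr(h1, 1, 1), substr(h1, 2, 2)),
             allele2 = cbind(substr(h2, 1, 1), substr(h2, 2, 2)))
  dimnames(gt$allele1) <- dimnames(gt$allele2) <- list(gt$animals, snps)
  class(gt) <- "genotype_table"
  gt
}

# Small genotype table straight from calls (animal x SNP matrix of
# two-letter strings).
genotypes_from_calls <- function(calls) {
  gt <- list(animals = rownames(calls), snps = colnames(calls),
             allele1 = substr(calls, 1, 1), allele2 = substr(calls, 2, 2))
  dim(gt$allele1) <- dim(gt$allele2) <- dim(calls)
  dimnames(gt$allele1) <- dimnames(gt$allele2) <- dimnames(calls)
  class(gt) <- "genotype_table"
  gt
}
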