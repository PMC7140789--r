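#' Simulation configuration
#'
#' Bundles every knob of the synthetic herd generator: demography, SNP
#' panel and LD structure, true variance components per trait, SNP
#' additive/dominance/epistatic effects, and the management fixed-effect
#' layout of the lactation records. Defaults emulate the structure of a
#' Murciano-Granadina-style herdbook study: a 48-SNP casein-complex panel
#' in four LD blocks (the four casein genes), repeated 210-day lactation
#' records on does, and six milk traits (milk, fat, protein, solids,
#' lactose in kg; somatic cell count in cells/mL, simulated on the log
#' scale and exponentiated).
#'
#' @param n_founders founder animals (generation 0).
#' @param n_generations generations bred after the founders.
#' @param male_frac fraction of males among founders and offspring.
#' @param n_snps SNP panel size.
#' @param ld_block_sizes integer vector summing to `n_snps`; one entry per
#'   LD block (gene).
#' @param ld_rho within-block haplotype copying probability in \[0,1);
#'   larger values give stronger within-block LD.
#' @param maf_range founder minor-allele-frequency range, within (0, 0.5].
#' @param traits character vector of trait names.
#' @param phen_var true phenotypic variance per trait (on the simulation
#'   scale; `scc` is log-scale).
#' @param trait_mean trait means (210-day kg; `scc` log cells/mL).
#' @param true_h2,true_repeatability named per-trait proportions;
#'   `true_h2 <= true_repeatability <= 1` elementwise.
#' @param true_genetic_corr trait x trait genetic correlation matrix
#'   (symmetric positive semi-definite).
#' @param snp_additive_effects,snp_dominance_effects data.frames with
#'   columns `snp`, `trait`, `effect` (trait units per minor-allele copy /
#'   per heterozygote).
#' @param epistatic_pairs data.frame with columns `snp1`, `snp2`, `trait`,
#'   `effect`: the effect is added when both SNPs carry at least one minor
#'   allele (a dominance-by-dominance interaction).
#' @param records_per_doe integer range (min, max) of lactations per doe.
#' @param controls_per_lactation mean number of test-day controls per
#'   lactation (spacing ~35 days).
#' @param fixed_effect_levels named integer vector of level counts for the
#'   simulated management factors.
#' @param fixed_effect_sd standard deviation of the per-level shifts, as a
#'   fraction of the trait phenotypic SD.
#' @param scc_log should somatic cell count be generated on the log scale
#'   and exponentiated (default) or kept on the simulated (raw) scale.
#' @param seed integer seed; all randomness flows from one generator.
#' @return a `sim_config` list (validated).
#' @export
sim_config <- function(n_founders = 120,
                       n_generations = 2,
                       male_frac = 0.2,
                       n_snps = 48,
                       ld_block_sizes = c(14, 10, 12, 12),
                       ld_rho = 0.8,
                       maf_range = c(0.15, 0.5),
                       traits = c("milk", "fat", "protein", "solids",
                                  "lactose", "scc"),
                       phen_var = c(milk = 1.64, fat = 1.73, protein = 0.25,
                                    solids = 2.58, lactose = 0.112,
                                    scc = 0.25),
                       trait_mean = c(milk = 380, fat = 20, protein = 13,
                                      solids = 55, lactose = 18, scc = 13.3),
                       true_h2 = c(milk = 0.21, fat = 0.24, protein = 0.24,
                                   solids = 0.24, lactose = 0.22,
                                   scc = 0.20),
                       true_repeatability = true_h2 + 0.2,
                       true_genetic_corr = NULL,
                       snp_additive_effects = default_snp_effects(traits,
                                                                  phen_var),
                       snp_dominance_effects = NULL,
                       epistatic_pairs = NULL,
                       records_per_doe = c(2, 5),
                       controls_per_lactation = 5,
                       fixed_effect_levels = c(farm = 8, parity = 5,
                                               control_month = 12,
                                               birth_type = 3),
                       fixed_effect_sd = 0.25,
                       scc_log = TRUE,
                       seed = 1L) {
  stopifnot(n_founders >= 2, n_generations >= 0,
            male_frac > 0, male_frac < 1,
            sum(ld_block_sizes) == n_snps,
            ld_rho >= 0, ld_rho < 1)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop("maf_range must lie within (0, 0.5]")
  }
  traits <- as.character(traits)
  for (v in list(phen_var, trait_mean, true_h2, true_repeatability)) {
    if (!all(traits %in% names(v))) {
      stop("per-trait parameters must be named for every trait")
    }
  }
  if (any(true_h2[traits] < 0) || any(true_h2[traits] > 1)) {
    stop("true_h2 must lie in [0, 1]")
  }
  if (any(true_repeatability[traits] < true_h2[traits]) ||
      any(true_repeatability[traits] > 1)) {
    stop("need true_h2 <= repeatability <= 1 per trait")
  }
  if (is.null(true_genetic_corr)) {
    true_genetic_corr <- default_genetic_corr(traits)
  }
  stopifnot(nrow(true_genetic_corr) == length(traits))
  if (!isSymmetric(unname(true_genetic_corr)) ||
      min(eigen(true_genetic_corr, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8) {
    stop("true_genetic_corr must be symmetric positive semi-definite")
  }
  cfg <- list(n_founders = n_founders, n_generations = n_generations,
              male_frac = male_frac, n_snps = n_snps,
              ld_block_sizes = ld_block_sizes, ld_rho = ld_rho,
              maf_range = maf_range, traits = traits,
              phen_var = phen_var[traits], trait_mean = trait_mean[traits],
              true_h2 = true_h2[traits],
              true_repeatability = true_repeatability[traits],
              true_genetic_corr = true_genetic_corr,
              snp_additive_effects = snp_additive_effects,
              snp_dominance_effects = snp_dominance_effects,
              epistatic_pairs = epistatic_pairs,
              records_per_doe = records_per_doe,
              controls_per_lactation = controls_per_lactation,
              fixed_effect_levels = fixed_effect_levels,
              fixed_effect_sd = fixed_effect_sd,
              scc_log = scc_log, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Default architecture: a few casein SNPs with additive effects on yield
# and composition, sized at ~0.2 phenotypic SD per allele copy.
default_snp_effects <- function(traits, phen_var) {
  snps <- c(1, 18, 25, 40)
  tr <- intersect(c("milk", "fat", "protein"), traits)
  if (!length(tr)) return(NULL)
  d <- expand.grid(snp = snps, trait = tr, stringsAsFactors = FALSE)
  d$effect <- 0.2 * sqrt(phen_var[d$trait])
  d
}

default_genetic_corr <- function(traits) {
  k <- length(traits)
  G <- diag(k)
  dimnames(G) <- list(traits, traits)
  comp <- intersect(c("fat", "protein", "solids"), traits)
  G[comp, comp] <- 0.3
  diag(G) <- 1
  G
}

#' Simulate a pedigree
#'
#' Founders form generation 0; each later generation draws a sire and an
#' unrelated-by-id dam at random from the previous generations. Sires are
#' male, dams female; parents always precede offspring.
#'
#' @param config a [sim_config()].
#' @return a [new_pedigree()] with extra column `generation`.
#' @export
simulate_pedigree <- function(config) {
  set.seed(config$seed)
  nf <- config$n_founders
  n_m <- max(1L, round(nf * config$male_frac))
  if (nf >= 2 && n_m >= nf) n_m <- nf - 1L
  sex <- c(rep("M", n_m), rep("F", nf - n_m))
  id <- sprintf("G0_%04d", seq_len(nf))
  animal <- id; sire <- rep(NA_character_, nf); dam <- rep(NA_character_, nf)
  gen <- rep(0L, nf)
  if (config$n_generations > 0 && (n_m < 1 || nf - n_m < 1)) {
    stop("cannot breed generations from a single-sex founder population")
  }
  for (g in seq_len(config$n_generations)) {
    males <- animal[sex == "M"]
    females <- animal[sex == "F"]
    n_off <- nf
    off_id <- sprintf("G%d_%04d", g, seq_len(n_off))
    off_sire <- sample(males, n_off, replace = TRUE)
    off_dam <- sample(females, n_off, replace = TRUE)
    off_sex <- ifelse(stats::runif(n_off) < config$male_frac, "M", "F")
    animal <- c(animal, off_id)
    sire <- c(sire, off_sire)
    dam <- c(dam, off_dam)
    sex <- c(sex, off_sex)
    gen <- c(gen, rep(g, n_off))
  }
  ped <- new_pedigree(animal, sire, dam, sex)
  ped$generation <- gen[match(ped$animal, animal)]
  ped
}

#' Simulate LD-blocked genotypes down a pedigree
#'
#' Founder haplotypes are drawn blockwise with a first-order copying
#' process: within a block, each SNP's allele copies the previous SNP's
#' state with probability `ld_rho` and is otherwise drawn fresh at its own
#' founder frequency, which reproduces LD decay with distance inside a
#' block and linkage equilibrium across blocks. Non-founders receive one
#' gamete per parent, with the transmitted parental haplotype chosen
#' independently per block (free recombination at block boundaries, none
#' within), so all genotypes are Mendelian-consistent.
#'
#' @param pedigree a [new_pedigree()].
#' @param config a [sim_config()].
#' @return a `genotype_table`: list with `animals`, `snps`, character
#'   matrices `allele1`/`allele2` (animal x SNP), and the haplotype pair
#'   kept as 0/1 minor-allele indicator matrices `hap1`/`hap2`.
#' @export
simulate_genotypes <- function(pedigree, config) {
  set.seed(config$seed + 1L)
  if (sum(config$ld_block_sizes) != config$n_snps) {
    stop("ld_block_sizes must sum to n_snps")
  }
  n <- nrow(pedigree)
  m <- config$n_snps
  block <- rep(seq_along(config$ld_block_sizes), config$ld_block_sizes)
  p <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  alleles <- t(replicate(m, sample(c("A", "C", "G", "T"), 2)))
  hap1 <- matrix(0L, n, m)
  hap2 <- matrix(0L, n, m)
  draw_founder_hap <- function() {
    h <- integer(m)
    for (k in seq_len(m)) {
      if (k > 1L && block[k] == block[k - 1L] &&
          stats::runif(1) < config$ld_rho) {
        h[k] <- h[k - 1L]
      } else {
        h[k] <- as.integer(stats::runif(1) < p[k])
      }
    }
    h
  }
  gamete <- function(h1, h2) {
    pick <- sample(c(TRUE, FALSE), length(config$ld_block_sizes),
                   replace = TRUE)
    ifelse(pick[block], h1, h2)
  }
  for (i in seq_len(n)) {
    si <- pedigree$sire_idx[i]; di <- pedigree$dam_idx[i]
    hap1[i, ] <- if (si > 0L) gamete(hap1[si, ], hap2[si, ]) else
      draw_founder_hap()
    hap2[i, ] <- if (di > 0L) gamete(hap1[di, ], hap2[di, ]) else
      draw_founder_hap()
  }
  to_allele <- function(hap) {
    out <- matrix("", n, m)
    for (k in seq_len(m)) {
      out[, k] <- ifelse(hap[, k] == 1L, alleles[k, 2L], alleles[k, 1L])
    }
    out
  }
  snps <- sprintf("SNP%d", seq_len(m))
  gt <- list(animals = pedigree$animal, snps = snps,
             allele1 = to_allele(hap1), allele2 = to_allele(hap2),
             hap1 = hap1, hap2 = hap2,
             founder_freq = stats::setNames(p, snps))
  dimnames(gt$allele1) <- dimnames(gt$allele2) <-
    dimnames(gt$hap1) <- dimnames(gt$hap2) <- list(pedigree$animal, snps)
  class(gt) <- "genotype_table"
  gt
}

#' Simulate repeated lactation records with known genetic architecture
#'
#' Each record is built as mean + management fixed effects + SNP additive,
#' dominance and epistatic contributions + the animal's true breeding
#' value + its permanent environment effect + residual. Repeated records
#' of a doe share her breeding value and permanent environment effect.
#' Breeding values follow the pedigree: founders are drawn from
#' \eqn{N(0, \sigma^2_a)} (multivariate over traits via the genetic
#' correlation matrix) and offspring get the parent average plus a
#' Mendelian sampling deviation with variance
#' \eqn{\tfrac12 \sigma^2_a (1 - \bar F_{parents})}.
#'
#' Besides the per-lactation trait records, ~5 test-day controls per
#' lactation are generated whose test-interval accumulation returns the
#' lactation's 210-day value (constant daily rate within lactation).
#'
#' @param pedigree a [new_pedigree()].
#' @param genotypes a [simulate_genotypes()] table.
#' @param config a [sim_config()].
#' @return list with `records` (one row per doe-lactation: trait columns,
#'   management factors, `age_months`), `controls` (test-day table:
#'   `goat`, `lactation`, `kidding_date`, `control_date`, `daily_milk`,
#'   `fat_pct`, `protein_pct`, `solids_pct`, `lactose_pct`, `scc`), and
#'   `truth` (true breeding values, permanent environment effects, and
#'   realized variance components per trait).
#' @export
simulate_lactations <- function(pedigree, genotypes, config) {
  set.seed(config$seed + 2L)
  traits <- config$traits
  if (!"milk" %in% traits) {
    stop("the lactation generator needs a 'milk' trait (test-day ",
         "controls are expressed through the daily milk rate)")
  }
  k <- length(traits)
  s2p <- config$phen_var
  s2a <- config$true_h2 * s2p
  s2pe <- (config$true_repeatability - config$true_h2) * s2p
  s2e <- (1 - config$true_repeatability) * s2p
  n <- nrow(pedigree)
  FF <- inbreeding(pedigree)

  # genetic covariance among traits and its Cholesky factor
  Gcov <- diag(sqrt(s2a), k) %*% config$true_genetic_corr %*%
    diag(sqrt(s2a), k)
  Gch <- chol_psd(Gcov)

  BV <- matrix(0, n, k, dimnames = list(pedigree$animal, traits))
  for (i in seq_len(n)) {
    si <- pedigree$sire_idx[i]; di <- pedigree$dam_idx[i]
    if (si == 0L && di == 0L) {
      BV[i, ] <- drop(crossprod(Gch, stats::rnorm(k)))
    } else {
      pa <- (if (si > 0L) BV[si, ] else 0) / 2 +
            (if (di > 0L) BV[di, ] else 0) / 2
      fbar <- mean(c(if (si > 0L) FF[si] else 0,
                     if (di > 0L) FF[di] else 0))
      ms <- sqrt(0.5 * (1 - fbar)) * drop(crossprod(Gch, stats::rnorm(k)))
      BV[i, ] <- pa + ms
    }
  }
  PE <- matrix(stats::rnorm(n * k), n, k) %*% diag(sqrt(s2pe), k)
  dimnames(PE) <- dimnames(BV)

  # SNP genotype contributions per animal and trait
  minor_count <- genotypes$hap1 + genotypes$hap2  # 0/1/2 minor alleles
  Gsnp <- matrix(0, n, k, dimnames = dimnames(BV))
  ae <- config$snp_additive_effects
  if (!is.null(ae) && nrow(ae)) {
    for (r in seq_len(nrow(ae))) {
      Gsnp[, ae$trait[r]] <- Gsnp[, ae$trait[r]] +
        ae$effect[r] * minor_count[, ae$snp[r]]
    }
  }
  de <- config$snp_dominance_effects
  if (!is.null(de) && nrow(de)) {
    for (r in seq_len(nrow(de))) {
      Gsnp[, de$trait[r]] <- Gsnp[, de$trait[r]] +
        de$effect[r] * (minor_count[, de$snp[r]] == 1L)
    }
  }
  ep <- config$epistatic_pairs
  if (!is.null(ep) && nrow(ep)) {
    for (r in seq_len(nrow(ep))) {
      both <- (minor_count[, ep$snp1[r]] > 0L) &
              (minor_count[, ep$snp2[r]] > 0L)
      Gsnp[, ep$trait[r]] <- Gsnp[, ep$trait[r]] + ep$effect[r] * both
    }
  }

  # management fixed-effect level shifts (drawn once per level)
  fel <- config$fixed_effect_levels
  shifts <- lapply(names(fel), function(f) {
    matrix(stats::rnorm(fel[[f]] * k, 0,
                        config$fixed_effect_sd * sqrt(s2p)),
           fel[[f]], k, byrow = TRUE, dimnames = list(NULL, traits))
  })
  names(shifts) <- names(fel)

  does <- which(pedigree$sex == "F" & pedigree$generation > 0)
  if (!length(does)) does <- which(pedigree$sex == "F")
  rec <- list(); ctl <- list()
  rid <- 0L
  for (i in does) {
    nl <- sample(seq(config$records_per_doe[1], config$records_per_doe[2]),
                 1L)
    birth <- as.Date("2008-01-01") +
      round(stats::runif(1, 0, 2000))
    for (l in seq_len(nl)) {
      rid <- rid + 1L
      lev <- vapply(names(fel), function(f) sample.int(fel[[f]], 1L),
                    integer(1))
      age_m <- 12 + 11 * (l - 1) + round(stats::runif(1, 0, 3))
      y <- config$trait_mean[traits] + BV[i, ] + PE[i, ] + Gsnp[i, ] +
        stats::rnorm(k, 0, sqrt(s2e))
      for (f in names(fel)) y <- y + shifts[[f]][lev[[f]], ]
      row <- as.list(y)
      names(row) <- traits
      rec[[rid]] <- c(list(goat = pedigree$animal[i], lactation = l,
                           age_months = age_m), row,
                      as.list(stats::setNames(sprintf("L%02d", lev),
                                              names(fel))))
      # test-day controls reproducing the 210-day totals at constant
      # rate: roughly monthly-to-six-weekly recording from ~day 20 until
      # past day 210, so the test-interval total closes exactly
      kid_date <- birth + 365 * (l - 1)
      spacing <- 210 / config$controls_per_lactation
      days <- round(stats::runif(1, 15, 25))
      while (utils::tail(days, 1) <= 215) {
        days <- c(days, utils::tail(days, 1) +
                    round(spacing + stats::runif(1, -5, 5)))
      }
      milk210 <- y[["milk"]]
      cdf <- data.frame(
        goat = pedigree$animal[i], lactation = l,
        kidding_date = kid_date,
        control_date = kid_date + days,
        daily_milk = milk210 / 210,
        stringsAsFactors = FALSE
      )
      for (cn in c("fat", "protein", "solids", "lactose")) {
        if (cn %in% traits) {
          cdf[[paste0(cn, "_pct")]] <- 100 * y[[cn]] / milk210
        }
      }
      if ("scc" %in% traits) {
        cdf$scc <- if (config$scc_log) exp(y[["scc"]]) else y[["scc"]]
      }
      ctl[[rid]] <- cdf
    }
  }
  records <- do.call(rbind, lapply(rec, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (config$scc_log && "scc" %in% traits) {
    records$scc_log <- records$scc
    records$scc <- exp(records$scc)
  }
  controls <- do.call(rbind, ctl)
  rownames(records) <- rownames(controls) <- NULL

  truth <- list(
    true_breeding_value = BV,
    true_pe_effect = PE,
    snp_genetic_value = Gsnp,
    realized_variance_components = data.frame(
      trait = traits,
      sigma2_a = apply(BV, 2, stats::var),
      sigma2_pe = s2pe,
      sigma2_e = s2e,
      true_sigma2_a = s2a,
      row.names = NULL
    )
  )
  list(records = records, controls = controls, truth = truth)
}

# Cholesky tolerant of semi-definite matrices (zero variances allowed).
chol_psd <- function(S) {
  ev <- eigen(S, symmetric = TRUE)
  ev$values[ev$values < 0] <- 0
  R <- diag(sqrt(ev$values), nrow(S)) %*% t(ev$vectors)
  R
}

#' Simulate a complete dataset
#'
#' Convenience wrapper running [simulate_pedigree()],
#' [simulate_genotypes()] and [simulate_lactations()].
#'
#' @param config a [sim_config()].
#' @return list with `pedigree`, `genotypes`, `records`, `controls`,
#'   `truth`, and the `config` used.
#' @export
simulate_dataset <- function(config = sim_config()) {
  ped <- simulate_pedigree(config)
  gt <- simulate_genotypes(ped, config)
  lac <- simulate_lactations(ped, gt, config)
  c(list(pedigree = ped, genotypes = gt), lac, list(config = config))
}

#' Write a genotype table
#'
#' Tab-separated animal x SNP table of two-letter allele calls (a
#' PLINK-.ped-like dialect without a map file).
#'
#' @param gt a `genotype_table`.
#' @param path output file.
#' @export
write_genotypes <- function(gt, path) {
  calls <- matrix(paste0(gt$allele1, gt$allele2),
                  nrow = length(gt$animals),
                  dimnames = list(gt$animals, gt$snps))
  utils::write.table(data.frame(animal = gt$animals, calls,
                                check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a genotype table written by [write_genotypes()] or a wide CSV
#'
#' @param path input file; tab- or comma-separated, first column animal
#'   ids, remaining columns two-letter genotype calls.
#' @return a `genotype_table` (without haplotype matrices).
#' @export
read_genotypes <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  d <- utils::read.table(path, sep = sep, header = TRUE,
                         check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  animals <- d[[1L]]
  calls <- as.matrix(d[, -1L, drop = FALSE])
  bad <- nchar(calls) != 2L & calls != ""
  if (any(bad)) stop("genotype calls must be two-letter strings")
  gt <- list(animals = animals, snps = colnames(calls),
             allele1 = substr(calls, 1L, 1L),
             allele2 = substr(calls, 2L, 2L))
  dimnames(gt$allele1) <- dimnames(gt$allele2) <-
    list(animals, colnames(calls))
  gt$allele1[calls == ""] <- NA
  gt$allele2[calls == ""] <- NA
  class(gt) <- "genotype_table"
  gt
}
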