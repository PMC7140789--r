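#' Encode SNP genotypes as nominal additive and dominance factors
#'
#' Per SNP, the major-allele homozygote is coded 1, the heterozygote 2 and
#' the minor-allele homozygote 3 (additive factor); homozygotes are coded
#' 1 and heterozygotes 2 (dominance factor). The codes are nominal labels:
#' nothing downstream assumes an order. Major/minor status is decided by
#' allele frequency (alphabetical order breaks exact ties), so the
#' encoding is invariant to how the input labels its alleles. Monomorphic
#' SNPs are flagged constant; SNPs with more than two alleles raise an
#' error naming the SNP.
#'
#' @param gt a `genotype_table` (see [read_genotypes()]).
#' @return an `encoded_factors` list: integer matrices `additive`
#'   (levels 1/2/3) and `dominance` (levels 1/2), logical `monomorphic`
#'   per SNP, and `level_dictionary` mapping each SNP's alleles to codes.
#' @export
encode_additive_dominance <- function(gt) {
  m <- length(gt$snps)
  n <- length(gt$animals)
  add <- matrix(NA_integer_, n, m, dimnames = list(gt$animals, gt$snps))
  dom <- add
  mono <- stats::setNames(logical(m), gt$snps)
  dict <- vector("list", m)
  names(dict) <- gt$snps
  for (k in seq_len(m)) {
    a1 <- gt$allele1[, k]; a2 <- gt$allele2[, k]
    ok <- !is.na(a1) & !is.na(a2)
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    if (length(alleles) > 2L) {
      stop("SNP ", gt$snps[k], " has more than two alleles: ",
           paste(alleles, collapse = ", "))
    }
    if (length(alleles) <= 1L) {
      mono[k] <- TRUE
      add[ok, k] <- 1L
      dom[ok, k] <- 1L
      dict[[k]] <- stats::setNames(1L, alleles[1L])
      next
    }
    cnt <- table(factor(c(a1[ok], a2[ok]), levels = alleles))
    major <- if (cnt[1L] == cnt[2L]) alleles[1L] else
      alleles[which.max(cnt)]
    minor <- setdiff(alleles, major)
    nminor <- (a1 == minor) + (a2 == minor)
    add[, k] <- ifelse(ok, nminor + 1L, NA_integer_)
    dom[, k] <- ifelse(ok, ifelse(nminor == 1L, 2L, 1L), NA_integer_)
    mono[k] <- all(nminor[ok] == nminor[ok][1L])
    dict[[k]] <- stats::setNames(c(1L, 3L), c(major, minor))
  }
  structure(list(additive = add, dominance = dom, monomorphic = mono,
                 level_dictionary = dict),
            class = "encoded_factors")
}

#' Minor allele frequency per SNP
#'
#' Allele-count estimate \eqn{(2 \cdot hom_{minor} + het) / 2N} over
#' non-missing calls, with a rare-variant flag at MAF < 0.05. All-missing
#' SNPs are reported with `NA`.
#'
#' @param gt a `genotype_table`.
#' @param rare_threshold rare-variant cutoff (default 0.05).
#' @return data.frame with columns `snp`, `maf`, `n`, `rare`.
#' @export
minor_allele_freq <- function(gt, rare_threshold = 0.05) {
  m <- length(gt$snps)
  maf <- rep(NA_real_, m); nn <- integer(m)
  for (k in seq_len(m)) {
    a1 <- gt$allele1[, k]; a2 <- gt$allele2[, k]
    ok <- !is.na(a1) & !is.na(a2)
    nn[k] <- sum(ok)
    if (!nn[k]) next
    cnt <- table(c(a1[ok], a2[ok]))
    if (length(cnt) == 1L) {
      maf[k] <- 0
    } else {
      maf[k] <- min(cnt) / sum(cnt)
    }
  }
  data.frame(snp = gt$snps, maf = maf, n = nn,
             rare = !is.na(maf) & maf < rare_threshold)
}

#' Observed heterozygosity per SNP and overall
#'
#' @param gt a `genotype_table`.
#' @return list with per-SNP heterozygosity and the panel mean.
#' @export
heterozygosity <- function(gt) {
  het <- vapply(seq_along(gt$snps), function(k) {
    a1 <- gt$allele1[, k]; a2 <- gt$allele2[, k]
    ok <- !is.na(a1) & !is.na(a2)
    if (!sum(ok)) return(NA_real_)
    mean(a1[ok] != a2[ok])
  }, numeric(1))
  list(per_snp = stats::setNames(het, gt$snps),
       mean = mean(het, na.rm = TRUE))
}

#' Pairwise linkage disequilibrium from unphased genotypes
#'
#' Haplotype frequencies for a biallelic SNP pair are estimated from the
#' 3x3 genotype table by expectation-maximization (the double
#' heterozygote's phase is the only latent quantity; the likelihood is
#' unimodal for non-degenerate data). From the haplotype frequencies:
#' \eqn{D = p_{AB} - p_A p_B}, \eqn{D' = |D| / D_{max}},
#' \eqn{r^2 = D^2 / (p_A p_a p_B p_b)}.
#'
#' @param gt a `genotype_table`.
#' @param snp_i,snp_j SNP names or indices.
#' @param max_iter,tol EM controls.
#' @return list with `haplotype_freqs` (named 4-vector), `D`, `D_prime`,
#'   `r2`, and the marginal allele frequencies.
#' @export
ld_pair <- function(gt, snp_i, snp_j, max_iter = 100, tol = 1e-8) {
  code_of <- function(s) {
    a1 <- gt$allele1[, s]; a2 <- gt$allele2[, s]
    ok <- !is.na(a1) & !is.na(a2)
    alleles <- sort(unique(c(a1[ok], a2[ok])))
    if (length(alleles) < 2L) {
      stop("SNP ", s, " is monomorphic: LD undefined")
    }
    cnt <- table(factor(c(a1[ok], a2[ok]), levels = alleles))
    major <- if (cnt[1L] == cnt[2L]) alleles[1L] else alleles[which.max(cnt)]
    minor <- setdiff(alleles, major)
    # count of MAJOR alleles (2 / 1 / 0)
    (a1 == major) + (a2 == major)
  }
  gi <- code_of(if (is.numeric(snp_i)) gt$snps[snp_i] else snp_i)
  gj <- code_of(if (is.numeric(snp_j)) gt$snps[snp_j] else snp_j)
  ok <- !is.na(gi) & !is.na(gj)
  gi <- gi[ok]; gj <- gj[ok]
  n <- length(gi)
  if (!n) stop("no jointly observed genotypes for this SNP pair")

  # EM over haplotype frequencies (pAB, pAb, paB, pab), A/B = major alleles
  p <- c(AB = 0.25, Ab = 0.25, aB = 0.25, ab = 0.25)
  ndh <- sum(gi == 1L & gj == 1L)
  # determined haplotype contributions from the nine genotype cells; only
  # the double heterozygote (1,1) is phase-ambiguous
  cell <- table(factor(gi, levels = 0:2), factor(gj, levels = 0:2))
  nc <- function(i, j) cell[as.character(i), as.character(j)]
  fixed <- c(
    AB = 2 * nc(2, 2) + nc(2, 1) + nc(1, 2),
    Ab = 2 * nc(2, 0) + nc(2, 1) + nc(1, 0),
    aB = 2 * nc(0, 2) + nc(0, 1) + nc(1, 2),
    ab = 2 * nc(0, 0) + nc(0, 1) + nc(1, 0)
  )
  total <- 2 * n
  for (it in seq_len(max_iter)) {
    # E step: split double heterozygotes between AB/ab and Ab/aB phase
    w <- p["AB"] * p["ab"] /
      (p["AB"] * p["ab"] + p["Ab"] * p["aB"] + 1e-300)
    e <- fixed + ndh * c(AB = w, Ab = 1 - w, aB = 1 - w, ab = w)
    p_new <- e / total
    if (max(abs(p_new - p)) < tol) {
      p <- p_new
      break
    }
    p <- p_new
  }
  pA <- p["AB"] + p["Ab"]; pB <- p["AB"] + p["aB"]
  D <- unname(p["AB"] - pA * pB)
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  D_prime <- if (dmax > 0) abs(D) / dmax else NA_real_
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r2 <- if (denom > 0) D^2 / denom else NA_real_
  list(haplotype_freqs = p, D = D, D_prime = unname(D_prime),
       r2 = unname(r2), p_major_i = unname(pA), p_major_j = unname(pB))
}

#' Long-format LD table for all SNP pairs
#'
#' @param gt a `genotype_table`.
#' @param snps subset of SNP names (default all polymorphic).
#' @return data.frame `snp_i`, `snp_j`, `D`, `D_prime`, `r2`.
#' @export
ld_table <- function(gt, snps = NULL) {
  if (is.null(snps)) {
    maf <- minor_allele_freq(gt)
    snps <- maf$snp[!is.na(maf$maf) & maf$maf > 0]
  }
  if (length(snps) < 2L) {
    return(data.frame(snp_i = character(), snp_j = character(),
                      D = numeric(), D_prime = numeric(), r2 = numeric()))
  }
  pairs <- utils::combn(snps, 2L)
  rows <- apply(pairs, 2L, function(pr) {
    r <- ld_pair(gt, pr[1L], pr[2L])
    data.frame(snp_i = pr[1L], snp_j = pr[2L], D = r$D,
               D_prime = r$D_prime, r2 = r$r2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
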