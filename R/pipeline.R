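#' Run the full genetic-evaluation pipeline
#'
#' Orchestrates: simulate (or ingest) -> standardize test-day controls to
#' 210 days -> encode SNPs -> MAF/LD summaries -> CATPCA clustering with
#' Varimax and |0.5|-loading retention -> OVERALS epistasis factor ->
#' nonparametric screening -> univariate REML + BLUP evaluation under the
#' model variant including the SNP cluster/epistasis fixed effects and
#' the variant excluding them -> model comparison -> combined selection
#' index with stratified rank sampling. All stage outputs are returned
#' and optionally written to `out_dir` together with a manifest recording
#' seed and every threshold.
#'
#' @param config list with elements (all optional): `sim` (a
#'   [sim_config()] or arguments for one), `traits` (default all
#'   simulated traits; somatic cell count is analyzed on the log scale),
#'   `variants` (`"including"`, `"excluding"` or both), `n_catpca_dims`,
#'   `alpha_floor` (Cronbach floor used when `n_catpca_dims` is `NULL`),
#'   `loading_threshold` (0.5), `multiple_fit_threshold` (0.1),
#'   `maf_threshold` (0.05), `reml_tol` (1e-12), `nlcc_dims` (2),
#'   `seed`.
#' @param out_dir optional output directory for CSV reports and the
#'   manifest.
#' @return list with every stage's result: `data`, `standardized`,
#'   `encoded`, `maf`, `ld`, `catpca`, `selection`, `overals`,
#'   `epistasis`, `screening`, `fits` and `evaluations` per variant,
#'   `variance_components`, `comparison`, `index`, `manifest`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- utils::modifyList(list(
    traits = NULL, variants = c("including", "excluding"),
    n_catpca_dims = NULL, alpha_floor = 0.8, loading_threshold = 0.5,
    multiple_fit_threshold = 0.1, maf_threshold = 0.05,
    reml_tol = 1e-12, reml_max_iter = 200, nlcc_dims = 2,
    min_cluster_count = 5, max_epistasis_levels = 10,
    seed = 1L), config)
  sim <- cfg$sim
  if (is.null(sim)) sim <- sim_config(seed = cfg$seed)
  if (!inherits(sim, "sim_config")) sim <- do.call(sim_config, sim)

  dat <- simulate_dataset(sim)
  traits <- cfg$traits
  if (is.null(traits)) {
    traits <- sim$traits
    # somatic cell count analyzed on the log scale
    traits[traits == "scc"] <- if ("scc_log" %in% names(dat$records))
      "scc_log" else "scc"
  }

  std <- standardize_lactations(dat$controls)
  enc <- encode_additive_dominance(dat$genotypes)
  maf <- minor_allele_freq(dat$genotypes, rare_threshold = cfg$maf_threshold)
  ld <- ld_table(dat$genotypes)

  # CATPCA on polymorphic additive codes; the whole genetic-factor
  # branch is skipped when only the excluding variant is requested
  run_genetic <- "including" %in% cfg$variants
  poly <- colnames(enc$additive)[!enc$monomorphic]
  ndims <- cfg$n_catpca_dims
  cat_fit <- NULL
  if (!run_genetic) {
    ndims <- 0L
  } else if (is.null(ndims)) {
    # largest dimensionality whose every dimension keeps Cronbach's alpha
    # above the floor
    for (d in seq(min(7L, length(poly) - 1L), 1L)) {
      cand <- fit_catpca(enc$additive[, poly, drop = FALSE], n_dims = d,
                         seed = cfg$seed)
      if (all(cand$cronbach_alpha > cfg$alpha_floor) || d == 1L) {
        cat_fit <- cand
        ndims <- d
        break
      }
    }
  } else {
    cat_fit <- fit_catpca(enc$additive[, poly, drop = FALSE],
                          n_dims = ndims, seed = cfg$seed)
  }
  sel <- NULL; sets <- list()
  clusters <- data.frame(row.names = rownames(enc$additive))
  if (!is.null(cat_fit)) {
    sel <- select_snps(cat_fit, threshold = cfg$loading_threshold)
    clusters <- cluster_factors(enc$additive, sel$retained,
                                min_count = cfg$min_cluster_count)
    sets <- Filter(length, sel$retained)
  }

  # OVERALS across the CATPCA clusters (sets with >= 1 SNP)
  ov <- NULL; epi <- NULL
  if (length(sets) >= 2L) {
    ov <- fit_overals(as.data.frame(enc$additive[, unique(unlist(sets)),
                                                 drop = FALSE]),
                      sets = sets, n_dims = cfg$nlcc_dims,
                      seed = cfg$seed)
    epi <- encode_epistasis(ov, enc$additive,
                            loading_threshold = cfg$loading_threshold,
                            multiple_fit_threshold =
                              cfg$multiple_fit_threshold,
                            max_levels = cfg$max_epistasis_levels)
  }

  # attach genetic factors to the records
  rec <- dat$records
  gen_cols <- character(0)
  if (ncol(clusters)) {
    for (d in colnames(clusters)) {
      cn <- paste0("PC_", d)
      rec[[cn]] <- clusters[rec$goat, d]
      gen_cols <- c(gen_cols, cn)
    }
  }
  if (!is.null(epi) && epi$n_levels > 1L) {
    lev <- stats::setNames(as.character(epi$factor),
                           rownames(enc$additive))
    rec$NLCC <- factor(lev[rec$goat])
    gen_cols <- c(gen_cols, "NLCC")
  }
  rec$age_c <- rec$age_months - mean(rec$age_months)
  rec$age_c2 <- rec$age_c^2
  mgmt <- intersect(names(sim$fixed_effect_levels), names(rec))

  screening <- screen_factors(rec, traits, c(mgmt, gen_cols))

  fits <- list(); evals <- list(); vc_rows <- list()
  for (variant in cfg$variants) {
    fx <- if (variant == "including") c(mgmt, gen_cols) else mgmt
    for (tr in traits) {
      fit <- reml_univariate(rec, tr, fixed = fx,
                             covariates = c("age_c", "age_c2"),
                             pedigree = dat$pedigree,
                             tol = cfg$reml_tol,
                             max_iter = cfg$reml_max_iter,
                             on_nonconv = "warn")
      am <- animal_model(rec, tr, fixed = fx,
                         covariates = c("age_c", "age_c2"),
                         pedigree = dat$pedigree,
                         vc = as.list(fit$vc[c("sigma2_a", "sigma2_pe",
                                               "sigma2_e")]))
      fits[[variant]][[tr]] <- fit
      evals[[variant]][[tr]] <- am$evaluation
      vc_rows[[length(vc_rows) + 1L]] <-
        cbind(model = variant, fit$vc)
    }
  }
  vc_table <- do.call(rbind, vc_rows)

  comparison <- NULL
  if (all(c("including", "excluding") %in% names(evals))) {
    comparison <- compare_models(do.call(rbind, evals$including),
                                 do.call(rbind, evals$excluding))
  }

  # combined selection index from the primary variant's PBVs
  primary <- if ("including" %in% names(evals)) "including" else
    names(evals)[1L]
  index <- NULL
  idx_traits <- intersect(c("milk", "fat", "protein", "lactose"), traits)
  if (length(idx_traits) == 4L) {
    pbv_mat <- sapply(idx_traits, function(tr) {
      ev <- evals[[primary]][[tr]]
      stats::setNames(ev$pbv, ev$animal)
    })
    means <- sapply(idx_traits, function(tr) mean(rec[[tr]]))
    scores <- ico(pbv_mat, means = means, traits = idx_traits)
    names(scores) <- rownames(pbv_mat)
    n <- length(scores)
    ns <- pmin(c(67L, 66L, 67L),
               rep(floor(n / 3), 3L))
    strata <- stratified_rank_sample(scores, ns[1L], ns[2L], ns[3L])
    index <- list(scores = scores, strata = strata, means = means)
  }

  manifest <- list(
    seed = cfg$seed, traits = traits, variants = cfg$variants,
    n_catpca_dims = ndims, alpha_floor = cfg$alpha_floor,
    loading_threshold = cfg$loading_threshold,
    multiple_fit_threshold = cfg$multiple_fit_threshold,
    maf_threshold = cfg$maf_threshold, reml_tol = cfg$reml_tol,
    nlcc_dims = cfg$nlcc_dims,
    min_cluster_count = cfg$min_cluster_count,
    max_epistasis_levels = cfg$max_epistasis_levels,
    n_records = nrow(rec), n_animals = nrow(dat$pedigree),
    n_snps = sim$n_snps)

  out <- list(data = dat, standardized = std, encoded = enc, maf = maf,
              ld = ld, catpca = cat_fit, selection = sel,
              clusters = clusters, overals = ov, epistasis = epi,
              screening = screening, fits = fits, evaluations = evals,
              variance_components = vc_table, comparison = comparison,
              index = index, manifest = manifest)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

# CSV reports + JSON manifest
write_pipeline_outputs <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                       row.names = FALSE)
  write_pedigree(out$data$pedigree, file.path(out_dir, "pedigree.csv"))
  write_genotypes(out$data$genotypes, file.path(out_dir, "genotypes.tsv"))
  w(out$standardized, "standardized_lactations.csv")
  w(out$maf, "maf.csv")
  w(out$ld, "ld_pairs.csv")
  if (!is.null(out$selection)) {
    w(data.frame(snp = rownames(out$selection$loadings),
                 out$selection$loadings), "catpca_loadings.csv")
  }
  w(out$screening, "screening.csv")
  w(out$variance_components, "variance_components.csv")
  if (!is.null(out$comparison)) {
    w(out$comparison$descriptives, "model_comparison_descriptives.csv")
    w(out$comparison$correlations, "model_comparison_correlations.csv")
  }
  for (variant in names(out$evaluations)) {
    ev <- do.call(rbind, out$evaluations[[variant]])
    w(ev, paste0("evaluation_", variant, ".csv"))
  }
  if (!is.null(out$index)) w(out$index$strata, "index_strata.csv")
  jsonlite::write_json(out$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
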