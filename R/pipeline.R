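#' Pipeline run configuration
#'
#' Flat key-value configuration for [run_all()]. Every stochastic stage has
#' an explicit seed derived from the single `seed` unless overridden.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param sim a [sim_config()] (the pipeline starts from simulation).
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "ancestry", "de", "mash", "eqtl", "predict", "methyl",
#'   "pst", "share")`.
#' @param lfsr_cut significance threshold.
#' @param subset_frac mash EM random-subset fraction.
#' @param window_kb cis window.
#' @param n_perms permutations for top associations.
#' @param k_folds elastic-net folds.
#' @param vmr_top_frac fraction of CpGs selected as variable before VMR
#'   calling. The conventional value is 0.01 on genome-scale data; on the
#'   compressed simulated genome the caller sets it to the simulated
#'   fraction of cluster CpGs.
#' @param panel_args extra arguments for [simulate_panel()] (for example a
#'   larger `high_div_frac` when the compressed panel must still contain
#'   enough ancestry-informative markers).
#' @return list of class `RunConfig`.
#' @export
run_config <- function(out_dir, seed = 1L, sim = sim_config(),
                       stages = c("simulate", "ancestry", "de", "mash",
                                  "eqtl", "predict", "methyl", "pst",
                                  "share"),
                       lfsr_cut = 0.05, subset_frac = 1,
                       window_kb = 500, n_perms = 200, k_folds = 5,
                       vmr_top_frac = 0.01, panel_args = list()) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  cfg <- as.list(environment())
  class(cfg) <- "RunConfig"
  cfg
}

#' Run the full pipeline on a simulated cohort
#'
#' Executes, per the stage toggles: cohort simulation, AIM selection and
#' global-ancestry estimation, per-region ancestry differential expression,
#' multivariate shrinkage, cis-eQTL mapping with shrinkage across regions,
#' genotype-based expression prediction and ancestry-effect variance
#' decomposition, methylation VMR calling, P_ST / delta-P_ST, and sharing
#' summaries. Writes TSV outputs plus a JSON manifest recording parameters
#' and per-stage row counts.
#'
#' @param config a [run_config()].
#' @return list with the in-memory stage results and the manifest.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list(),
                   parameters = list(lfsr_cut = config$lfsr_cut,
                                     window_kb = config$window_kb,
                                     n_perms = config$n_perms,
                                     k_folds = config$k_folds))
  res <- list()
  on <- function(s) s %in% config$stages
  note <- function(stage, n_rows, files = character(0)) {
    manifest$stages[[stage]] <<- list(rows = n_rows, files = files)
  }
  ## evaluate a stage body; on error, write the partial manifest and abort
  ## naming the stage
  run_stage <- function(stage, expr) {
    e <- substitute(expr)
    pf <- parent.frame()
    tryCatch(eval(e, pf), error = function(err) {
      manifest$error <<- list(stage = stage,
                              message = conditionMessage(err))
      jsonlite::write_json(manifest,
                           file.path(config$out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      stop("stage '", stage, "' failed: ", conditionMessage(err),
           call. = FALSE)
    })
  }

  if (on("simulate")) run_stage("simulate", {
    panel <- do.call(simulate_panel,
                     c(list(config$sim$n_variants,
                            config$sim$chrom_length_bp,
                            seed = config$seed), config$panel_args))
    cohort <- simulate_cohort(panel, config$sim, seed = config$seed,
                              methylation = on("methyl"))
    res$panel <- panel
    res$cohort <- cohort
    f <- file.path(config$out_dir, "genotypes.vcf")
    write_vcf(cohort$genotypes, f)
    write_truth_json(cohort$truth,
                     file.path(config$out_dir, "truth.json"))
    for (r in names(cohort$regions))
      write_matrix_tsv(cohort$regions[[r]]$counts,
                       file.path(config$out_dir,
                                 paste0("counts_", r, ".tsv")))
    note("simulate", nrow(panel),
         c(f, file.path(config$out_dir, "truth.json")))
  })
  if (!length(config$stages)) {
    manifest$n_stages <- 0
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    return(list(results = res, manifest = manifest))
  }
  stopifnot(!is.null(res$cohort))  # downstream stages need the cohort
  cohort <- res$cohort
  theta_true <- cohort$truth$theta

  if (on("ancestry")) run_stage("ancestry", {
    pops <- list(
      AFR = matrix(rbinom(nrow(res$panel) * 60, 2,
                          rep(res$panel$freq_afr, 60)),
                   nrow(res$panel),
                   dimnames = list(res$panel$variant_id, NULL)),
      EUR = matrix(rbinom(nrow(res$panel) * 60, 2,
                          rep(res$panel$freq_eur, 60)),
                   nrow(res$panel),
                   dimnames = list(res$panel$variant_id, NULL)))
    aims <- select_aims(res$panel, pops)
    anc <- estimate_global_ancestry(cohort$genotypes, res$panel, aims)
    res$ancestry <- anc
    f <- file.path(config$out_dir, "ancestry.tsv")
    data.table::fwrite(anc, f, sep = "\t")
    note("ancestry", nrow(anc), f)
  })
  theta <- if (!is.null(res$ancestry)) res$ancestry$theta_hat
           else theta_true

  if (on("de")) run_stage("de", {
    fits <- lapply(cohort$regions, function(set)
      fit_ancestry_de(set, theta, cohort$covariates))
    res$effects <- combine_effects(fits)
    write_matrix_tsv(res$effects$beta,
                     file.path(config$out_dir, "de_beta.tsv"))
    write_matrix_tsv(res$effects$se,
                     file.path(config$out_dir, "de_se.tsv"))
    note("de", nrow(res$effects$beta))
  })
  if (on("mash")) run_stage("mash", {
    stopifnot(!is.null(res$effects))
    m <- mash_lite(res$effects, subset_frac = config$subset_frac,
                   seed = config$seed)
    res$mash <- m
    res$degs <- significant_features(m$posterior, config$lfsr_cut)
    write_matrix_tsv(m$posterior$lfsr,
                     file.path(config$out_dir, "de_lfsr.tsv"))
    note("mash", nrow(m$posterior$lfsr))
  })
  if (on("eqtl")) run_stage("eqtl", {
    set1 <- cohort$regions[[1]]
    resid <- residualize(set1, cohort$covariates)
    qtl <- map_cis_nominal(resid, cohort$genotypes, set1$features,
                           cohort$covariates,
                           window_kb = config$window_kb)
    res$eqtl <- qtl
    top <- qtl[order(qtl$feature_id, qtl$p_nominal), ]
    top <- top[!duplicated(top$feature_id), ]
    top$q_value <- qvalues(pmax(pmin(
      top$p_nominal * tabulate(match(qtl$feature_id, top$feature_id)),
      1), 1e-300))
    res$eqtl_top <- top
    f <- file.path(config$out_dir, "eqtl_nominal.tsv")
    data.table::fwrite(qtl, f, sep = "\t")
    note("eqtl", nrow(qtl), f)
  })
  if (on("predict")) run_stage("predict", {
    stopifnot(!is.null(res$mash), !is.null(res$eqtl_top))
    set1 <- cohort$regions[[1]]
    resid <- residualize(set1, cohort$covariates)
    dosage <- cohort$genotypes$dosage
    pos <- res$panel$pos
    tss <- set1$features$tss
    egenes <- res$eqtl_top$feature_id[res$eqtl_top$q_value < 0.05]
    feats <- intersect(intersect(res$degs$per_region[[1]], egenes),
                       rownames(resid))
    ## small cohorts may not fill the DEG-and-eGene set; fall back to DEGs
    if (length(feats) < 10)
      feats <- intersect(res$degs$per_region[[1]], rownames(resid))
    if (length(feats) < 10)
      feats <- head(intersect(res$eqtl_top$feature_id, rownames(resid)), 50)
    pred <- matrix(NA_real_, length(feats), ncol(resid),
                   dimnames = list(feats, colnames(resid)))
    for (f in feats) {
      j <- match(f, set1$features$feature_id)
      win <- which(abs(pos - tss[j]) <= config$window_kb * 1000)
      mod <- fit_elastic_net(resid[f, ], dosage[win, , drop = FALSE],
                             k_folds = config$k_folds,
                             seed = config$seed + j)
      if (!isTRUE(mod$empty))
        pred[f, ] <- predict_expression(mod, dosage[win, , drop = FALSE])
    }
    pred <- pred[stats::complete.cases(pred), , drop = FALSE]
    ve <- ancestry_effect_variance_explained(
      pred, theta, cohort$covariates,
      setNames(res$mash$posterior$post_mean[, 1],
               rownames(res$mash$posterior$post_mean)),
      region = names(cohort$regions)[1])
    res$variance_explained <- ve
    note("predict", nrow(pred))
  })
  if (on("methyl")) run_stage("methyl", {
    stopifnot(!is.null(cohort$cpgs))
    cp <- filter_cpg_coverage(cohort$cpgs)
    cp <- smooth_methylation(cp)
    sel <- select_variable_cpgs(cp, theta, top_frac = config$vmr_top_frac)
    vmrs <- call_vmrs(cp, sel)
    res$vmrs <- vmrs
    res$meth_pcs <- attr(sel, "pcs")
    res$cpgs_filtered <- cp
    note("methyl", nrow(vmrs$regions))
  })
  if (on("pst")) run_stage("pst", {
    stopifnot(!is.null(res$vmrs), !is.null(res$degs))
    set1 <- cohort$regions[[1]]
    ann <- annotate_vmrs(res$vmrs, set1$features)
    la <- cohort$cpgs$local_ancestry
    vm_res <- residualize_vmrs(
      res$vmrs,
      .vmr_local_ancestry(res$vmrs, set1$features, la),
      cohort$covariates$age, cohort$covariates$sex, res$meth_pcs)
    y <- log2_cpm(set1$counts)
    covs <- cohort$covariates
    genes <- intersect(res$degs$per_region[[1]], unique(ann$feature_id))
    tab <- lapply(genes, function(g) {
      vi <- ann$vmr_index[ann$feature_id == g]
      p0 <- pst(y[g, ], theta, covs)
      p1 <- pst(y[g, ], theta, covs,
                vmr_covariates = t(vm_res[vi, , drop = FALSE]))
      data.frame(gene_id = g, pst = p0, pst_vmr = p1,
                 delta_pst = delta_pst(p0, p1), n_vmrs_used = length(vi))
    })
    if (!length(tab))
      tab <- list(data.frame(gene_id = character(0), pst = numeric(0),
                             pst_vmr = numeric(0), delta_pst = numeric(0),
                             n_vmrs_used = integer(0)))
    res$pst <- do.call(rbind, tab)
    class(res$pst) <- c("PstTable", "data.frame")
    f <- file.path(config$out_dir, "pst.tsv")
    data.table::fwrite(res$pst, f, sep = "\t")
    note("pst", nrow(res$pst), f)
  })
  if (on("share")) run_stage("share", {
    stopifnot(!is.null(res$mash))
    res$sharing <- pairwise_sharing(res$mash$posterior, config$lfsr_cut)
    note("share", length(res$sharing$counts))
  })

  manifest$n_stages <- length(manifest$stages)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(results = res, manifest = manifest)
}

## per-VMR local ancestry: the feature-cluster local ancestry of the nearest
## annotated feature (simulation carries it per feature cluster)
.vmr_local_ancestry <- function(vmrs, features, la_by_feature) {
  reg <- vmrs$regions
  mid <- (reg$start + reg$end) / 2
  fmid <- (features$start + features$end) / 2
  idx <- vapply(mid, function(x) which.min(abs(fmid - x)), 0L)
  la_by_feature[idx, , drop = FALSE]
}
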