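#' Construct an ancestral reference panel
#'
#' A panel holds per-variant allele frequencies in the two ancestral
#' populations (African and European) used for admixture simulation,
#' ancestry-informative-marker selection and allele-frequency-difference
#' statistics.
#'
#' @param variant_id character vector of unique variant ids.
#' @param chrom chromosome per variant.
#' @param pos 1-based position, strictly increasing within chromosome.
#' @param ref,alt single-character alleles.
#' @param freq_afr,freq_eur alternate-allele frequency in each ancestral
#'   population, in `[0, 1]`.
#' @return A `data.frame` of class `AncestralPanel`.
#' @export
ancestral_panel <- function(variant_id, chrom, pos, ref, alt,
                            freq_afr, freq_eur) {
  stopifnot(!anyDuplicated(variant_id),
            all(freq_afr >= 0 & freq_afr <= 1),
            all(freq_eur >= 0 & freq_eur <= 1))
  p <- data.frame(variant_id = as.character(variant_id),
                  chrom = as.character(chrom), pos = as.integer(pos),
                  ref = as.character(ref), alt = as.character(alt),
                  freq_afr = as.numeric(freq_afr),
                  freq_eur = as.numeric(freq_eur),
                  stringsAsFactors = FALSE)
  for (ch in unique(p$chrom)) {
    d <- diff(p$pos[p$chrom == ch])
    if (length(d) && any(d <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  class(p) <- c("AncestralPanel", "data.frame")
  p
}

#' Simulate an ancestral reference panel
#'
#' Draws variant positions uniformly along one chromosome and allele
#' frequencies whose between-population divergence mirrors real genomes:
#' most variants have small frequency differences, with a minority of
#' strongly divergent sites (the pool from which ancestry-informative
#' markers and simulated causal variants are drawn). If the bulk of the
#' panel were strongly divergent, any collection of cis variants would tag
#' global ancestry almost perfectly, which no real cis window does.
#'
#' @param n_variants number of variants.
#' @param chrom_length_bp chromosome length in bp.
#' @param chrom chromosome name.
#' @param seed integer seed (required for reproducibility).
#' @param high_div_frac fraction of strongly divergent variants
#'   (default 0.05).
#' @param high_div_range absolute-frequency-difference range of the
#'   divergent subset (default `c(0.3, 0.6)`).
#' @param low_div_scale,low_div_shape2 the bulk divergence is
#'   `low_div_scale * Beta(1, low_div_shape2)` (defaults give mean ~0.04).
#' @return An [ancestral_panel()].
#' @export
simulate_panel <- function(n_variants, chrom_length_bp = 5e7,
                           chrom = "chr1", seed,
                           high_div_frac = 0.05,
                           high_div_range = c(0.3, 0.6),
                           low_div_scale = 0.5, low_div_shape2 = 12) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  pos <- sort(sample.int(chrom_length_bp - 2L, n_variants))
  is_div <- runif(n_variants) < high_div_frac
  delta <- low_div_scale * rbeta(n_variants, 1, low_div_shape2)
  delta[is_div] <- runif(sum(is_div), high_div_range[1], high_div_range[2])
  ## draw the lower frequency with headroom so the intended divergence is
  ## realized (no boundary clipping), then randomize which population is
  ## higher
  lo <- runif(n_variants, 0.02, pmax(0.98 - delta, 0.021))
  hi <- pmin(lo + delta, 0.99)
  flip <- runif(n_variants) < 0.5
  p_eur <- ifelse(flip, hi, lo)
  p_afr <- ifelse(flip, lo, hi)
  ancestral_panel(
    variant_id = sprintf("var%05d", seq_len(n_variants)),
    chrom = chrom, pos = pos, ref = "A", alt = "G",
    freq_afr = p_afr, freq_eur = p_eur)
}

#' Simulation configuration
#'
#' Bundles and validates all generator parameters. The defaults emulate an
#' admixed African-American brain cohort: Beta-distributed global African
#' ancestry with mean 0.79 (European mean 0.21), four correlated brain
#' regions, ancestry effects on the log2 scale, and WGBS-style methylation
#' at mean depth 30.
#'
#' @param n_samples cohort size.
#' @param n_regions number of tissue regions sharing (correlated) effects.
#' @param n_features number of expression features (genes).
#' @param n_variants number of panel variants.
#' @param chrom_length_bp simulated chromosome length.
#' @param theta_beta_params `c(a, b)` of the Beta prior on global African
#'   ancestry.
#' @param recomb_rate_per_bp ancestry-switch rate of the Markovian tract
#'   process; mean tract length is `1 / recomb_rate_per_bp`.
#' @param effect_sharing_correlation correlation of true ancestry effects
#'   across regions, in `[0, 1]`.
#' @param noise_sd residual s.d. of latent log2 expression.
#' @param ancestry_effect_sd s.d. of the per-feature total ancestry slope
#'   (log2 expression per unit African-ancestry proportion).
#' @param genetic_fraction,env_fraction target variance shares of the
#'   ancestry effect mediated by the cis variant and by the environmental
#'   factor; their sum must be at most 1.
#' @param env_theta_cor correlation between the standardized environmental
#'   factor and global ancestry.
#' @param causal_min_afd minimum absolute allele-frequency difference of the
#'   designated causal variant.
#' @param cis_window_kb half-width of the cis window around the TSS.
#' @param mean_depth mean sequencing depth of the methylation coverage model.
#' @param cpgs_per_cluster CpGs per feature-linked cluster.
#' @param n_background_cpgs unstructured background CpGs.
#' @param n_batch_factors dense latent batch factors in methylation.
#' @param meth_batch_sd s.d. of per-cluster batch loadings, on the
#'   proportion scale: batch is modelled as a measurement-level artefact
#'   (conversion-efficiency-like), additive in the observed proportion, so
#'   that it is exactly removable by the linear PC adjustment and its total
#'   variance dominates the environmental loading in the PCA ordering.
#' @param meth_env_loading logit-scale loading of the environmental factor on
#'   environmentally responsive CpG clusters.
#' @param env_active_frac fraction of features whose loci respond to the
#'   environmental factor (their expression carries the env_fraction share
#'   and their CpG cluster is E-loaded); the remaining features have no
#'   environmentally mediated ancestry effect.
#' @param meth_la_sd s.d. of per-cluster local-ancestry loadings.
#' @param n_qsv number of simulated quality-surrogate covariate columns.
#' @param cov_effect_sd s.d. of covariate effects on latent expression.
#' @param baseline_log2_mean,baseline_log2_sd baseline abundance of features
#'   (log2 counts).
#' @param dispersion_meanlog,dispersion_sdlog log-normal parameters of the
#'   fixed per-feature negative-binomial dispersion.
#' @return A validated list of class `SimConfig`.
#' @export
sim_config <- function(n_samples = 150, n_regions = 4, n_features = 200,
                       n_variants = 4000, chrom_length_bp = 5e7,
                       theta_beta_params = c(7.9, 2.1),
                       recomb_rate_per_bp = 1e-6,
                       effect_sharing_correlation = 0.8,
                       noise_sd = 0.4, ancestry_effect_sd = 1.25,
                       genetic_fraction = 0.6, env_fraction = 0.15,
                       env_theta_cor = 0.15,
                       causal_min_afd = 0.3, cis_window_kb = 500,
                       mean_depth = 30, cpgs_per_cluster = 12,
                       n_background_cpgs = 2000, n_batch_factors = 5,
                       meth_batch_sd = 0.1,
                       meth_env_loading = 0.5, meth_la_sd = 0.5,
                       env_active_frac = 0.5,
                       n_qsv = 2, cov_effect_sd = 0.2,
                       baseline_log2_mean = 7, baseline_log2_sd = 1,
                       dispersion_meanlog = log(0.02),
                       dispersion_sdlog = 0.3) {
  cfg <- as.list(environment())
  counts <- c("n_samples", "n_regions", "n_features", "n_variants",
              "chrom_length_bp")
  for (nm in counts)
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop(nm, " must be positive")
  stopifnot(length(theta_beta_params) == 2, all(theta_beta_params > 0),
            effect_sharing_correlation >= 0,
            effect_sharing_correlation <= 1,
            genetic_fraction >= 0, env_fraction >= 0,
            genetic_fraction + env_fraction <= 1,
            env_theta_cor >= -1, env_theta_cor <= 1)
  if (env_fraction > 0 && env_theta_cor == 0)
    stop("env_fraction > 0 requires a nonzero env_theta_cor")
  class(cfg) <- "SimConfig"
  cfg
}

## ancestry origin (1 = AFR) at positions `pos` for one haplotype described
## by switchpoints `brk` (0-based, sorted) and per-segment origins
.origin_at <- function(pos, brk, origins) {
  origins[findInterval(pos, brk) + 1L]
}

#' Simulate admixed genotypes with ancestry tracts
#'
#' Per sample a target African-ancestry proportion is drawn from the Beta
#' prior; each of the two haplotypes is tiled by a Markovian tract process
#' with switch rate `recomb_rate_per_bp` whose segment origins are Bernoulli
#' draws at the target proportion. Alleles are drawn from the ancestral
#' frequency of the tract origin, and dosage is the sum over haplotypes.
#' The recorded truth `theta` is the realized length-weighted African tract
#' fraction (it equals the Beta draw only in expectation).
#'
#' @param panel an [ancestral_panel()].
#' @param config a [sim_config()].
#' @param seed integer seed (required).
#' @return A list with `genotypes` (class `GenotypeMatrix`: dosage matrix
#'   variants x samples, per-haplotype African origin matrix, panel, sample
#'   ids) and `truth` (class `SimTruth`: realized and target theta, tract
#'   table, seed).
#' @export
simulate_genotypes <- function(panel, config, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(inherits(panel, "AncestralPanel"), nrow(panel) > 0,
            inherits(config, "SimConfig"))
  L <- config$chrom_length_bp
  if (L <= 0) stop("zero-length chromosome")
  set.seed(seed)
  n <- config$n_samples
  theta_target <- rbeta(n, config$theta_beta_params[1],
                        config$theta_beta_params[2])

  n_hap <- 2L * n
  pos <- panel$pos
  dosage <- matrix(0L, nrow(panel), n,
                   dimnames = list(panel$variant_id,
                                   sprintf("sample%03d", seq_len(n))))
  la_hap <- matrix(0L, nrow(panel), n_hap)
  tract_list <- vector("list", n_hap)
  afr_len <- numeric(n)

  for (h in seq_len(n_hap)) {
    s <- (h + 1L) %/% 2L
    th <- theta_target[s]
    n_sw <- rpois(1L, config$recomb_rate_per_bp * L)
    brk <- sort(runif(n_sw, 0, L))
    origins <- as.integer(runif(n_sw + 1L) < th)   # 1 = AFR
    start <- c(0, brk)
    end <- c(brk, L)
    tract_list[[h]] <- data.frame(
      sample = s, haplotype = h, chrom = panel$chrom[1],
      start = start, end = end,
      origin = ifelse(origins == 1L, "AFR", "EUR"))
    afr_len[s] <- afr_len[s] + sum((end - start)[origins == 1L])
    ori <- .origin_at(pos, brk, origins)
    la_hap[, h] <- ori
    freq <- ifelse(ori == 1L, panel$freq_afr, panel$freq_eur)
    dosage[, s] <- dosage[, s] + as.integer(runif(nrow(panel)) < freq)
  }
  theta <- afr_len / (2 * L)
  tracts <- do.call(rbind, tract_list)

  genotypes <- structure(
    list(dosage = dosage, la_hap = la_hap, panel = panel,
         sample_id = colnames(dosage)),
    class = "GenotypeMatrix")
  truth <- structure(
    list(theta = theta, theta_target = theta_target, tracts = tracts,
         genetic_fraction = config$genetic_fraction,
         env_fraction = config$env_fraction, seed = seed),
    class = "SimTruth")
  list(genotypes = genotypes, truth = truth)
}

#' Simulate multi-region expression counts with a known ancestry-effect
#' decomposition
#'
#' Latent log2 expression per feature is
#' `baseline + b_gen * dosage(causal) + b_env * E + b_dir * theta +
#' covariate effects + N(0, noise_sd)`, where `E` is a standardized
#' environmental factor with correlation `env_theta_cor` with global
#' ancestry. Writing the total ancestry slope of feature j as `S_j ~ N(0,
#' ancestry_effect_sd^2)`, the environmental component is `alpha * S_j` with
#' `alpha = 1 - sqrt(1 - env_fraction)` (so that removing it lowers the
#' ancestry-explained variance by exactly `env_fraction`), and the genetic
#' component is `(1 - alpha) * w_j * S_j` with `w_j` normal such that the
#' squared correlation between the genetic component and `S_j` across
#' features equals `genetic_fraction`. Counts are negative binomial with a
#' fixed log-normal per-feature dispersion; effects are correlated across
#' regions with correlation `effect_sharing_correlation`.
#'
#' @param genotypes,truth output of [simulate_genotypes()].
#' @param config the [sim_config()] used to generate them.
#' @return A list with `regions` (one `ExpressionSet` per region: counts,
#'   latent log2 matrix, feature annotation, library sizes), `covariates`
#'   (sex, age, qSV-like columns) and the augmented `truth` (per-feature x
#'   region slopes `beta_true` and their genetic/environmental/direct parts,
#'   causal variants, the environmental factor `E`).
#' @export
simulate_expression <- function(genotypes, truth, config) {
  stopifnot(inherits(genotypes, "GenotypeMatrix"),
            inherits(truth, "SimTruth"), inherits(config, "SimConfig"))
  set.seed(truth$seed + 1L)
  n <- length(truth$theta)
  J <- config$n_features
  R <- config$n_regions
  panel <- genotypes$panel
  L <- config$chrom_length_bp
  win <- config$cis_window_kb * 1000

  ## feature annotation: TSS spread along the chromosome
  tss <- sort(round(seq(win, L - win, length.out = J) +
                    runif(J, -win / 10, win / 10)))
  len <- sample(1000:5000, J, replace = TRUE)
  features <- data.frame(
    feature_id = sprintf("gene%04d", seq_len(J)),
    chrom = panel$chrom[1], start = tss, end = tss + len,
    strand = "+", length_bp = len, tss = tss,
    stringsAsFactors = FALSE)

  ## causal variant per feature: informative variant inside the cis window
  afd_v <- abs(panel$freq_afr - panel$freq_eur)
  causal <- character(J)
  for (j in seq_len(J)) {
    in_win <- which(abs(panel$pos - tss[j]) <= win)
    if (!length(in_win))
      stop("no variant within the cis window of ", features$feature_id[j])
    ok <- in_win[afd_v[in_win] >= config$causal_min_afd]
    ## fall back to the most divergent window variant when none passes;
    ## such genes carry no genetically mediated ancestry effect (below)
    if (!length(ok)) ok <- in_win[which.max(afd_v[in_win])]
    causal[j] <- panel$variant_id[if (length(ok) > 1) sample(ok, 1L) else ok]
  }
  d <- (panel$freq_afr - panel$freq_eur)[match(causal, panel$variant_id)]
  weak_causal <- abs(d) < config$causal_min_afd

  ## environmental factor with the stated ancestry correlation realized
  ## exactly in-sample (the correlation, not its sampling noise, is the
  ## study condition: every downstream env-share estimand scales with it)
  theta <- truth$theta
  zt <- as.numeric(scale(theta))
  rho <- config$env_theta_cor
  eta <- rnorm(n)
  eta <- qr.resid(qr(cbind(1, zt)), eta)
  eta <- eta / sd(eta)
  E <- rho * zt + sqrt(max(0, 1 - rho^2)) * eta
  sd_theta <- sd(theta)

  ## per-feature x region total slopes, correlated across regions
  cshare <- config$effect_sharing_correlation
  tau <- config$ancestry_effect_sd
  shared <- rnorm(J)
  S <- tau * (sqrt(cshare) * matrix(shared, J, R) +
              sqrt(1 - cshare) * matrix(rnorm(J * R), J, R))

  ## decomposition into genetic / environmental / direct parts.
  ## genetic: G = u * S with u such that cor^2(G, S) = genetic_fraction,
  ## realized exactly in this cohort (weighted in-sample moments, bounded
  ## deviations). environmental: alpha * S with
  ## alpha = 1 - sqrt(1 - env_fraction) (variance-scale share) on the
  ## environmentally responsive features only.
  gf <- config$genetic_fraction
  ef <- config$env_fraction
  alpha <- 1 - sqrt(1 - ef)
  sd_u <- sqrt(max(0, gf * (1 - gf)))
  z <- rnorm(J)
  if (sd_u > 0 && J > 2) {
    v <- rowMeans(S^2)
    for (it in 1:2) {
      z <- pmin(pmax(z, -3), 3)   # bound the mediation weights
      z <- z - sum(v * z) / sum(v)
      z <- z / sqrt(sum(v * z^2) / sum(v))
    }
  }
  u <- gf + sd_u * z
  u[weak_causal] <- 0  # no divergent cis variant: effect is not mediated
  env_active <- runif(J) < config$env_active_frac
  alpha_j <- alpha * env_active
  G <- u * S                        # theta-slope through the causal variant
  Epart <- alpha_j * S              # theta-slope through E
  D <- S - G - Epart                # direct
  b_gen <- G / (2 * d)              # dosage slope (E[dosage|theta] = 2d*theta + c)
  b_env <- if (rho != 0) Epart * sd_theta / rho else Epart * 0

  ## covariates
  sex <- rbinom(n, 1, 0.5)
  age <- rnorm(n, 45, 15)
  qsv <- matrix(rnorm(n * config$n_qsv), n,
                dimnames = list(NULL, paste0("qsv", seq_len(config$n_qsv))))
  covariates <- data.frame(sex = sex, age = age, qsv)
  covX <- cbind(sex = sex, age_z = as.numeric(scale(age)), qsv)

  baseline <- rnorm(J, config$baseline_log2_mean, config$baseline_log2_sd)
  dispersion <- rlnorm(J, config$dispersion_meanlog, config$dispersion_sdlog)
  cov_eff <- matrix(rnorm(J * ncol(covX), 0, config$cov_effect_sd), J)

  dos <- genotypes$dosage[causal, , drop = FALSE]
  regions <- vector("list", R)
  names(regions) <- paste0("region", seq_len(R))
  for (r in seq_len(R)) {
    ## per-region parts scale with the region's total slope
    Gr <- u * S[, r]
    Er <- alpha_j * S[, r]
    Dr <- S[, r] - Gr - Er
    bg <- Gr / (2 * d)
    be <- if (rho != 0) Er * sd_theta / rho else Er * 0
    latent <- matrix(baseline, J, n) +
      bg * dos +
      outer(be, E) +
      outer(Dr, theta) +
      cov_eff %*% t(covX) +
      matrix(rnorm(J * n, 0, config$noise_sd), J, n)
    ## compositional read model: a sample's reads are distributed over
    ## features in proportion to latent abundance, so no feature can blow
    ## up the library size
    lib <- round(rlnorm(n, 0, 0.2) * 200 * J)
    frac <- sweep(2^latent, 2, colSums(2^latent), "/")
    ## dynamic-range ceiling: no feature takes more than 5% of a library
    for (it in 1:2) {
      frac <- pmin(frac, 0.05)
      frac <- sweep(frac, 2, colSums(frac), "/")
    }
    mu <- sweep(frac, 2, lib, "*")
    counts <- matrix(rnbinom(J * n, mu = mu, size = 1 / dispersion), J, n,
                     dimnames = list(features$feature_id,
                                     genotypes$sample_id))
    regions[[r]] <- structure(
      list(counts = counts, latent = latent, features = features,
           region = names(regions)[r], lib_size = colSums(counts)),
      class = "ExpressionSet")
  }

  truth$features <- features
  truth$causal_variant <- setNames(causal, features$feature_id)
  truth$beta_true <- S
  truth$beta_genetic <- u * S
  truth$beta_env <- alpha_j * S
  truth$beta_direct <- S - truth$beta_genetic - truth$beta_env
  truth$b_gen_dosage <- b_gen
  truth$env_active <- env_active
  truth$E <- E
  truth$covariates <- covariates
  list(regions = regions, covariates = covariates, truth = truth)
}

#' Simulate WGBS-style CpG methylation counts
#'
#' CpGs come in clusters near feature TSSs plus unstructured background
#' CpGs. The latent methylation proportion is
#' `logistic(base + la_loading * local_ancestry + env_loading * E + batch)`,
#' with dense latent batch factors on all CpGs and the environmental factor
#' loading only on feature-linked clusters. Read depth is Poisson and
#' methylated counts are binomial at the latent proportion.
#'
#' @param truth a `SimTruth` augmented by [simulate_expression()] (it must
#'   carry `features`, `tracts` and `E`).
#' @param config the [sim_config()].
#' @return A list of class `CpGTable`: `chrom`, `pos` (0-based), `meth` and
#'   `total` count matrices (CpG x sample), `cluster` feature id or NA, and
#'   the true environmentally loaded regions in `vmr_truth`.
#' @export
simulate_methylation <- function(truth, config) {
  stopifnot(inherits(truth, "SimTruth"), inherits(config, "SimConfig"))
  if (is.null(truth$features) || is.null(truth$E))
    stop("run simulate_expression() first: methylation is wired to its ",
         "features and environmental factor")
  if (config$mean_depth < 1) stop("mean depth must be at least 1")
  set.seed(truth$seed + 2L)

  n <- length(truth$theta)
  feats <- truth$features
  J <- nrow(feats)
  k <- config$cpgs_per_cluster
  E <- truth$E

  ## cluster CpGs within ~1 kb upstream of each TSS
  cl_pos <- lapply(seq_len(J), function(j)
    sort(feats$tss[j] - sample.int(1000, k)))
  bg_pos <- sort(sample.int(config$chrom_length_bp, config$n_background_cpgs))
  pos <- c(unlist(cl_pos), bg_pos)
  cluster <- c(rep(feats$feature_id, each = k),
               rep(NA_character_, config$n_background_cpgs))
  o <- order(pos)
  pos <- pos[o]; cluster <- cluster[o]
  m <- length(pos)

  ## local ancestry (AFR haplotype fraction) at each cluster
  la_cl <- matrix(0, J, n)
  tr <- truth$tracts
  for (s in seq_len(n)) {
    hs <- unique(tr$haplotype[tr$sample == s])
    for (h in hs) {
      th <- tr[tr$haplotype == h, ]
      idx <- findInterval(feats$tss, th$start)
      la_cl[, s] <- la_cl[, s] + (th$origin[idx] == "AFR") / 2
    }
  }

  base_cl <- rnorm(J, 0, 0.3)
  la_load <- rnorm(J, 0, config$meth_la_sd)
  base <- rnorm(m, 0, 1)
  cl_idx <- match(cluster, feats$feature_id)
  is_cl <- !is.na(cl_idx)
  base[is_cl] <- base_cl[cl_idx[is_cl]] + rnorm(sum(is_cl), 0, 0.2)

  B <- matrix(rnorm(n * config$n_batch_factors), n)
  ## batch loadings are locally coherent (one loading per CpG cluster plus
  ## jitter): batch artefacts act on regions, and local smoothing must not
  ## average them away relative to the cluster-level environmental loading
  batch_load <- matrix(rnorm(m * config$n_batch_factors, 0,
                             config$meth_batch_sd), m)
  cl_load <- matrix(rnorm(J * config$n_batch_factors, 0,
                          config$meth_batch_sd), J)
  batch_load[is_cl, ] <- cl_load[cl_idx[is_cl], ] +
    matrix(rnorm(sum(is_cl) * config$n_batch_factors, 0,
                 config$meth_batch_sd / 5), sum(is_cl))

  ## biology (local ancestry, environment) acts on the logit scale; batch
  ## is a measurement artefact additive on the proportion scale
  logit <- matrix(base, m, n) + matrix(rnorm(m * n, 0, 0.1), m, n)
  env_load <- config$meth_env_loading *
    (if (is.null(truth$env_active)) rep(1, J) else truth$env_active)
  logit[is_cl, ] <- logit[is_cl, ] +
    la_load[cl_idx[is_cl]] * la_cl[cl_idx[is_cl], , drop = FALSE] +
    env_load[cl_idx[is_cl]] * matrix(E, sum(is_cl), n, byrow = TRUE)

  p <- plogis(logit) + batch_load %*% t(B)
  p <- pmin(pmax(p, 0.005), 0.995)
  total <- matrix(rpois(m * n, config$mean_depth), m, n)
  meth <- matrix(rbinom(m * n, as.vector(total), as.vector(p)), m, n)
  colnames(meth) <- colnames(total) <- sprintf("sample%03d", seq_len(n))

  vmr_truth <- data.frame(
    chrom = feats$chrom, start = vapply(cl_pos, min, 0) - 1,
    end = vapply(cl_pos, max, 0), feature_id = feats$feature_id,
    stringsAsFactors = FALSE)

  structure(list(chrom = rep(feats$chrom[1], m), pos = pos - 1L,
                 meth = meth, total = total, cluster = cluster,
                 local_ancestry = la_cl, vmr_truth = vmr_truth),
            class = "CpGTable")
}

#' Simulate a complete admixed cohort
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_expression()] and [simulate_methylation()] with one seed.
#'
#' @inheritParams simulate_genotypes
#' @param methylation also generate methylation (default TRUE).
#' @return List with `genotypes`, `regions`, `covariates`, `cpgs`, `truth`.
#' @export
simulate_cohort <- function(panel, config, seed, methylation = TRUE) {
  g <- simulate_genotypes(panel, config, seed)
  e <- simulate_expression(g$genotypes, g$truth, config)
  cpgs <- if (methylation) simulate_methylation(e$truth, config) else NULL
  list(genotypes = g$genotypes, regions = e$regions,
       covariates = e$covariates, cpgs = cpgs, truth = e$truth)
}
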