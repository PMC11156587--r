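#' Select ancestry-informative markers
#'
#' Markers pass all of: absolute allele-frequency difference between the two
#' ancestral populations above `delta_min`; pairwise r-squared below
#' `r2_max` within each reference population (greedy pruning in genomic
#' order over a sliding window); and a Hardy-Weinberg exact test P above
#' `hwe_p_min` within each population.
#'
#' @param panel an [ancestral_panel()] with the candidate variants.
#' @param genotypes_ref named list of dosage matrices (variants x samples),
#'   one per reference population, used for the r-squared and HWE checks;
#'   rownames must match panel variant ids.
#' @param delta_min minimum absolute frequency difference (default 0.5).
#' @param r2_max maximum pairwise r-squared within a population (default 0.1).
#' @param hwe_p_min minimum HWE exact-test P within a population (default
#'   0.01).
#' @param prune_window_bp window for greedy LD pruning (default 1 Mb).
#' @return Character vector of retained variant ids.
#' @export
select_aims <- function(panel, genotypes_ref, delta_min = 0.5,
                        r2_max = 0.1, hwe_p_min = 0.01,
                        prune_window_bp = 1e6) {
  stopifnot(inherits(panel, "AncestralPanel"), is.list(genotypes_ref))
  keep <- !is.na(panel$freq_afr) & !is.na(panel$freq_eur)
  if (any(!keep)) warning(sum(!keep), " variants skipped: missing frequency")
  cand <- panel[keep & abs(panel$freq_afr - panel$freq_eur) > delta_min, ]
  if (nrow(cand) == 0) {
    warning("no candidate variants pass the frequency-difference threshold")
    return(character(0))
  }

  ## HWE exact test within each population
  hwe_ok <- rep(TRUE, nrow(cand))
  for (pop in genotypes_ref) {
    idx <- match(cand$variant_id, rownames(pop))
    p <- vapply(idx, function(i) {
      if (is.na(i)) return(1)
      hwe_exact_test(pop[i, ])
    }, 0)
    hwe_ok <- hwe_ok & (p > hwe_p_min)
  }
  cand <- cand[hwe_ok, ]
  if (nrow(cand) == 0) return(character(0))

  ## greedy LD pruning in genomic order within each population
  keep_id <- cand$variant_id
  for (pop in genotypes_ref) {
    kept <- character(0)
    kept_g <- list()
    for (i in seq_len(nrow(cand))) {
      id <- cand$variant_id[i]
      if (!(id %in% keep_id)) next
      ri <- match(id, rownames(pop))
      g <- if (is.na(ri)) NULL else pop[ri, ]
      ok <- TRUE
      if (!is.null(g) && sd(g) > 0) {
        for (k in seq_along(kept)) {
          ki <- match(kept[k], cand$variant_id)
          if (cand$chrom[i] != cand$chrom[ki]) next
          if (abs(cand$pos[i] - cand$pos[ki]) > prune_window_bp) next
          gk <- kept_g[[kept[k]]]
          if (is.null(gk) || sd(gk) == 0) next
          if (cor(g, gk)^2 >= r2_max) { ok <- FALSE; break }
        }
      }
      if (ok) {
        kept <- c(kept, id)
        kept_g[id] <- list(g)
      }
    }
    keep_id <- intersect(keep_id, kept)
  }
  cand$variant_id[cand$variant_id %in% keep_id]
}

#' Hardy-Weinberg exact test
#'
#' Exact conditional test (no mid-P): the two-sided P is the sum of
#' heterozygote-count probabilities not exceeding that of the observed
#' count, conditional on the minor-allele count.
#'
#' @param dosage integer vector of genotype dosages (0/1/2).
#' @return P value.
#' @export
hwe_exact_test <- function(dosage) {
  dosage <- dosage[!is.na(dosage)]
  n <- length(dosage)
  if (n == 0) return(1)
  n_het <- sum(dosage == 1)
  n_alt <- sum(dosage)
  n_minor <- min(n_alt, 2L * n - n_alt)
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2L, n_minor, by = 2L)
  ## P(het = h | minor count) via the standard conditional distribution,
  ## computed in logs for stability
  logp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_min + 1) -
      lgamma(hom_maj + 1) + h * log(2)
  }, 0)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_het, hets)]
  sum(pr[pr <= obs * (1 + 1e-9)])
}

#' Estimate global ancestry by supervised maximum likelihood
#'
#' For each sample the African-ancestry proportion maximizes the
#' binomial log-likelihood \eqn{\sum_v \log \mathrm{Bin}(dosage_v \mid 2,
#' \theta p_{AFR,v} + (1-\theta) p_{EUR,v})} over \eqn{\theta \in [0,1]}
#' (golden-section search, tolerance 1e-6). Sites where the two ancestral
#' frequencies coincide are uninformative; if all sites are uninformative
#' the sample is flagged unidentifiable with `theta_hat = 0.5`.
#'
#' @param genotypes a `GenotypeMatrix` (or plain dosage matrix with variant
#'   rownames).
#' @param panel an [ancestral_panel()] holding the ancestral frequencies.
#' @param aims character vector of marker ids to use.
#' @return `data.frame` of class `AncestryTable`: `sample_id`, `theta_hat`,
#'   `loglik`, `n_markers_used`, `unidentifiable`.
#' @export
estimate_global_ancestry <- function(genotypes, panel, aims) {
  dosage <- if (inherits(genotypes, "GenotypeMatrix")) genotypes$dosage
            else genotypes
  stopifnot(length(aims) > 0)
  idx <- match(aims, panel$variant_id)
  if (anyNA(idx)) stop("aims missing from panel")
  pa <- panel$freq_afr[idx]
  pe <- panel$freq_eur[idx]
  D <- dosage[match(aims, rownames(dosage)), , drop = FALSE]
  informative <- pa != pe
  out <- data.frame(sample_id = colnames(D), theta_hat = NA_real_,
                    loglik = NA_real_, n_markers_used = length(aims),
                    unidentifiable = FALSE, stringsAsFactors = FALSE)
  for (s in seq_len(ncol(D))) {
    g <- D[, s]
    ok <- !is.na(g)
    if (!any(informative & ok)) {
      out$theta_hat[s] <- 0.5
      out$unidentifiable[s] <- TRUE
      out$loglik[s] <- ancestry_loglik(0.5, g[ok], pa[ok], pe[ok])
      next
    }
    opt <- optimize(ancestry_loglik, c(0, 1), dosage = g[ok],
                    p_afr = pa[ok], p_eur = pe[ok],
                    maximum = TRUE, tol = 1e-6)
    out$theta_hat[s] <- opt$maximum
    out$loglik[s] <- opt$objective
    out$n_markers_used[s] <- sum(ok)
  }
  ## boundary polish: golden-section cannot land exactly on 0/1
  for (s in seq_len(nrow(out))) {
    if (out$unidentifiable[s]) next
    g <- D[, s]; ok <- !is.na(g)
    for (b in c(0, 1)) {
      lb <- ancestry_loglik(b, g[ok], pa[ok], pe[ok])
      if (lb >= out$loglik[s]) {
        out$theta_hat[s] <- b
        out$loglik[s] <- lb
      }
    }
  }
  class(out) <- c("AncestryTable", "data.frame")
  out
}

#' Binomial admixture log-likelihood at a given ancestry proportion
#'
#' @param theta African-ancestry proportion.
#' @param dosage per-marker dosages for one sample.
#' @param p_afr,p_eur ancestral allele frequencies.
#' @return log-likelihood.
#' @export
ancestry_loglik <- function(theta, dosage, p_afr, p_eur) {
  p <- theta * p_afr + (1 - theta) * p_eur
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(dbinom(dosage, 2, p, log = TRUE))
}

#' Per-feature local-ancestry scores
#'
#' Averages the African-ancestry posterior over all SNPs falling in a window
#' around each feature and over both haplotypes, per sample. The window is
#' the feature span padded by `window_kb` on each side (the conventional
#' 200-kbp window by default).
#'
#' @param tract_posteriors matrix of African posteriors, SNPs x haplotypes
#'   (two consecutive columns per sample), plus a `pos` attribute or
#'   accompanying `snp_pos` argument.
#' @param snp_pos SNP positions (1-based), aligned to rows.
#' @param features data.frame with `feature_id`, `start`, `end` (and
#'   optionally `chrom`, assumed single-chromosome here).
#' @param window_kb padding in kb (default 200).
#' @return `data.frame` of class `LocalAncestryScore` in long-ish form:
#'   one row per feature with a `score` matrix column removed — instead a
#'   list with `scores` (features x samples) and `meta` (window, n_snps,
#'   flagged features with no SNPs).
#' @export
local_ancestry_feature_score <- function(tract_posteriors, snp_pos, features,
                                         window_kb = 200) {
  stopifnot(nrow(tract_posteriors) == length(snp_pos))
  w <- window_kb * 1000
  n_hap <- ncol(tract_posteriors)
  stopifnot(n_hap %% 2 == 0)
  n <- n_hap / 2
  J <- nrow(features)
  scores <- matrix(NA_real_, J, n,
                   dimnames = list(features$feature_id, NULL))
  n_snps <- integer(J)
  for (j in seq_len(J)) {
    lo <- features$start[j] - w
    hi <- features$end[j] + w
    in_win <- which(snp_pos >= lo & snp_pos <= hi)
    n_snps[j] <- length(in_win)
    if (!length(in_win)) next
    hapmean <- colMeans(tract_posteriors[in_win, , drop = FALSE])
    scores[j, ] <- (hapmean[seq(1, n_hap, 2)] + hapmean[seq(2, n_hap, 2)]) / 2
  }
  meta <- data.frame(feature_id = features$feature_id,
                     window_start = features$start - w,
                     window_end = features$end + w,
                     n_snps = n_snps, flagged = n_snps == 0)
  structure(list(scores = scores, meta = meta, window_kb = window_kb),
            class = "LocalAncestryScore")
}
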