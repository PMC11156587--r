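## transcription start site: annotated start on +, end on -
.feature_tss <- function(features) {
  ifelse(features$strand == "-", features$end, features$start)
}

#' Nominal cis-QTL mapping
#'
#' Main-effect mode regresses (residualized) expression on dosage plus
#' covariates and reports the dosage term; interaction mode fits
#' `expr ~ dosage + theta + dosage:theta + covariates` and reports the
#' product term (the ancestry-dependent effect). Variants are paired with
#' features by distance from the TSS; minor-allele-frequency floors default
#' to 0.01 (main) and 0.05 (interaction). Two-sided t-test p-values.
#'
#' @param expr_resid feature x sample expression matrix (typically from
#'   [residualize()]).
#' @param genotypes `GenotypeMatrix` or dosage matrix (variants x samples)
#'   with a `pos` attribute / accompanying panel.
#' @param features feature annotation with `feature_id`, `start`, `end`,
#'   `strand`.
#' @param covariates per-sample covariates (may be NULL).
#' @param window_kb cis window half-width from the TSS (default 500).
#' @param maf_min MAF floor; default depends on `mode`.
#' @param mode `"main"` or `"interaction"`.
#' @param ancestry per-sample global ancestry (required for interaction
#'   mode).
#' @return data.frame of class `QtlResult`: feature_id, variant_id,
#'   distance_to_tss, beta, se, t, p_nominal, maf, mode.
#' @export
map_cis_nominal <- function(expr_resid, genotypes, features,
                            covariates = NULL, window_kb = 500,
                            maf_min = NULL,
                            mode = c("main", "interaction"),
                            ancestry = NULL) {
  mode <- match.arg(mode)
  if (is.null(maf_min)) maf_min <- if (mode == "main") 0.01 else 0.05
  if (mode == "interaction" && is.null(ancestry))
    stop("interaction mode requires ancestry")
  dosage <- if (inherits(genotypes, "GenotypeMatrix")) genotypes$dosage
            else genotypes
  pos <- if (inherits(genotypes, "GenotypeMatrix")) genotypes$panel$pos
         else attr(genotypes, "pos")
  stopifnot(!is.null(pos), length(pos) == nrow(dosage))
  n <- ncol(expr_resid)
  stopifnot(ncol(dosage) == n)
  w <- window_kb * 1000
  tss <- .feature_tss(features)

  maf_all <- {
    f <- rowMeans(dosage) / 2
    pmin(f, 1 - f)
  }
  C <- cbind(`(Intercept)` = rep(1, n),
             if (!is.null(covariates)) as.matrix(covariates))
  qc <- qr(C)
  if (qc$rank < ncol(C))
    stop("rank-deficient covariates: ",
         paste(colnames(C)[-seq_len(qc$rank)], collapse = ", "))

  out <- vector("list", nrow(features))
  for (j in seq_len(nrow(features))) {
    fid <- features$feature_id[j]
    if (!fid %in% rownames(expr_resid)) next
    vid <- which(abs(pos - tss[j]) <= w & maf_all >= maf_min &
                 maf_all > 0)
    if (!length(vid)) next
    y <- expr_resid[fid, ]
    G <- dosage[vid, , drop = FALSE]

    if (mode == "main") {
      p_cov <- ncol(C)
      df <- n - p_cov - 1L
      if (df <= 0) stop("n <= p")
      yr <- qr.resid(qc, y)
      Gr <- t(qr.resid(qc, t(G)))
      ss <- rowSums(Gr^2)
      keep <- ss > 1e-12
      if (!any(keep)) next
      Gr <- Gr[keep, , drop = FALSE]
      vid <- vid[keep]
      ss <- ss[keep]
      beta <- as.vector(Gr %*% yr) / ss
      rss <- sum(yr^2) - beta^2 * ss
      sigma2 <- rss / df
      se <- sqrt(sigma2 / ss)
      tval <- beta / se
      pval <- 2 * pt(-abs(tval), df)
    } else {
      res <- lapply(seq_along(vid), function(k) {
        g <- G[k, ]
        X <- cbind(C, g = g, theta = ancestry, gxt = g * ancestry)
        if (n <= ncol(X)) stop("n <= p")
        fit <- lm.fit(X, y)
        if (fit$rank < ncol(X)) return(NULL)
        dfk <- n - ncol(X)
        sigma2 <- sum(fit$residuals^2) / dfk
        XtXi <- chol2inv(chol(crossprod(X)))
        b <- fit$coefficients[["gxt"]]
        s <- sqrt(sigma2 * XtXi[ncol(X), ncol(X)])
        c(b, s, b / s, 2 * pt(-abs(b / s), dfk))
      })
      keep <- !vapply(res, is.null, TRUE)
      if (!any(keep)) next
      res <- do.call(rbind, res[keep])
      vid <- vid[keep]
      beta <- res[, 1]; se <- res[, 2]; tval <- res[, 3]; pval <- res[, 4]
    }
    out[[j]] <- data.frame(
      feature_id = fid, variant_id = rownames(dosage)[vid],
      distance_to_tss = pos[vid] - tss[j],
      beta = beta, se = se, t = tval, p_nominal = pmax(pval, 1e-300),
      maf = maf_all[vid], mode = mode, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(feature_id = character(0), variant_id = character(0),
                      distance_to_tss = integer(0), beta = numeric(0),
                      se = numeric(0), t = numeric(0),
                      p_nominal = numeric(0), maf = numeric(0),
                      mode = character(0))
  rownames(res) <- NULL
  class(res) <- c("QtlResult", "data.frame")
  res
}

#' Permutation test for the top cis association of one feature
#'
#' Permutes the covariate-residualized phenotype a fixed number of times and
#' compares the observed minimum nominal p across window variants with the
#' permutation minima: `empirical_p = (1 + #{min p_perm <= min p_obs}) /
#' (n_perms + 1)`.
#'
#' @param y per-sample phenotype (residualized expression of one feature).
#' @param G dosage matrix of window variants (variants x samples).
#' @param covariates per-sample covariates (may be NULL).
#' @param n_perms number of permutations (default 1000).
#' @param seed integer seed (required).
#' @return one-row data.frame of class `PermutationRecord`: `top_variant`,
#'   `p_nominal`, `empirical_p`, `n_perms`.
#' @export
permute_top_association <- function(y, G, covariates = NULL,
                                    n_perms = 1000, seed) {
  if (missing(seed)) stop("seed is required")
  if (is.null(G) || nrow(G) == 0) {
    return(structure(data.frame(top_variant = NA_character_,
                                p_nominal = NA_real_,
                                empirical_p = NA_real_, n_perms = n_perms),
                     class = c("PermutationRecord", "data.frame")))
  }
  n <- length(y)
  C <- cbind(rep(1, n), if (!is.null(covariates)) as.matrix(covariates))
  qc <- qr(C)
  yr <- qr.resid(qc, y)
  Gr <- t(qr.resid(qc, t(G)))
  keep <- rowSums(Gr^2) > 1e-12
  Gr <- Gr[keep, , drop = FALSE]
  if (!nrow(Gr)) {
    return(structure(data.frame(top_variant = NA_character_,
                                p_nominal = NA_real_,
                                empirical_p = NA_real_, n_perms = n_perms),
                     class = c("PermutationRecord", "data.frame")))
  }
  Gs <- Gr / sqrt(rowSums(Gr^2))

  abscor <- function(v) {
    v <- v / sqrt(sum(v^2))
    abs(as.vector(Gs %*% v))
  }
  obs <- abscor(yr)
  top <- which.max(obs)
  set.seed(seed)
  perm_max <- vapply(seq_len(n_perms),
                     function(i) max(abscor(yr[sample.int(n)])), 0)
  ## max |cor| is a monotone transform of min nominal p
  emp <- (1 + sum(perm_max >= max(obs) - 1e-12)) / (n_perms + 1)
  df <- n - ncol(C) - 1L
  tval <- max(obs) * sqrt(df) / sqrt(1 - min(max(obs)^2, 1 - 1e-12))
  structure(data.frame(top_variant = rownames(G)[keep][top],
                       p_nominal = 2 * pt(-abs(tval), df),
                       empirical_p = emp, n_perms = n_perms),
            class = c("PermutationRecord", "data.frame"))
}

#' Storey q-values
#'
#' `q_i = min_{j: p_j >= p_i} pi0 * m * p_j / rank(p_j)` with the null
#' proportion estimated at `lambda = 0.5` and clipped at 1.
#'
#' @param pvals p-values in (0, 1].
#' @param lambda tuning point for the pi0 estimate (default 0.5).
#' @return q-values, monotone non-decreasing in p.
#' @export
qvalues <- function(pvals, lambda = 0.5) {
  if (!length(pvals)) return(numeric(0))
  stopifnot(all(pvals > 0 & pvals <= 1))
  m <- length(pvals)
  pi0 <- min(1, sum(pvals > lambda) / (m * (1 - lambda)))
  o <- order(pvals)
  q <- pi0 * m * pvals[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Absolute allele-frequency difference
#'
#' @param freq_afr,freq_eur frequencies of the same allele in the two
#'   ancestral populations.
#' @return `|freq_afr - freq_eur|`, in `[0, 1]`.
#' @export
afd <- function(freq_afr, freq_eur) abs(freq_afr - freq_eur)

#' Align allele frequencies from a second source to a first
#'
#' Returns the second-source frequency expressed on the first source's
#' ref/alt orientation: unchanged when alleles match, `1 - f` when ref and
#' alt are swapped, NA (variant skipped) when neither orientation matches.
#'
#' @param ref1,alt1 alleles of the reference orientation.
#' @param ref2,alt2,freq2 alleles and allele frequency of the second source
#'   (freq2 refers to `alt2`... for symmetric use, to whichever allele the
#'   source reports; callers must be consistent).
#' @return aligned frequencies with NA for unmatched variants.
#' @export
align_allele_freq <- function(ref1, alt1, ref2, alt2, freq2) {
  same <- ref1 == ref2 & alt1 == alt2
  flip <- ref1 == alt2 & alt1 == ref2
  out <- rep(NA_real_, length(freq2))
  out[same] <- freq2[same]
  out[flip] <- 1 - freq2[flip]
  out
}

#' Mean absolute allele-frequency difference of a gene's significant eQTLs
#'
#' @param gene feature id.
#' @param significant_eqtls data.frame with `feature_id` and `variant_id`
#'   (e.g. LFSR-significant eQTLs).
#' @param panel [ancestral_panel()] with matched alleles.
#' @return mean AFD across the gene's significant eQTL variants (NA when
#'   none match).
#' @export
gene_afd <- function(gene, significant_eqtls, panel) {
  v <- significant_eqtls$variant_id[significant_eqtls$feature_id == gene]
  i <- match(v, panel$variant_id)
  i <- i[!is.na(i)]
  if (!length(i)) return(NA_real_)
  mean(afd(panel$freq_afr[i], panel$freq_eur[i]))
}
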