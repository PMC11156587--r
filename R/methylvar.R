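#' Coverage-filter CpGs
#'
#' Retains CpGs with sequencing coverage of more than `min_depth` reads in
#' more than `min_frac` of samples.
#'
#' @param cpgs a `CpGTable`.
#' @param min_depth coverage threshold (strictly greater; default 5).
#' @param min_frac sample fraction (strictly greater; default 0.8).
#' @return filtered `CpGTable`.
#' @export
filter_cpg_coverage <- function(cpgs, min_depth = 5, min_frac = 0.8) {
  keep <- rowMeans(cpgs$total > min_depth) > min_frac
  .subset_cpgs(cpgs, keep)
}

.subset_cpgs <- function(cpgs, keep) {
  out <- cpgs
  out$chrom <- cpgs$chrom[keep]
  out$pos <- cpgs$pos[keep]
  out$meth <- cpgs$meth[keep, , drop = FALSE]
  out$total <- cpgs$total[keep, , drop = FALSE]
  if (!is.null(cpgs$cluster)) out$cluster <- cpgs$cluster[keep]
  if (!is.null(cpgs$smoothed))
    out$smoothed <- cpgs$smoothed[keep, , drop = FALSE]
  out
}

#' Locally smooth methylation proportions
#'
#' Coverage-weighted rolling mean with triangular distance weights over a
#' window of `window_bp` (half-width `window_bp / 2`) around each CpG; a
#' desk-scale stand-in for local-likelihood smoothing that preserves the
#' "locally smoothed proportions" contract.
#'
#' @param cpgs a `CpGTable` (coverage-filtered).
#' @param window_bp smoothing window width (default 1000).
#' @return the `CpGTable` with a `smoothed` proportion matrix added.
#' @export
smooth_methylation <- function(cpgs, window_bp = 1000) {
  pos <- cpgs$pos
  h <- window_bp / 2
  m <- length(pos)
  sm <- matrix(NA_real_, m, ncol(cpgs$meth))
  lo <- findInterval(pos - h, pos) + 1L
  hi <- findInterval(pos + h, pos)
  for (i in seq_len(m)) {
    idx <- lo[i]:hi[i]
    w <- 1 - abs(pos[idx] - pos[i]) / (h + 1)
    wm <- w * cpgs$meth[idx, , drop = FALSE]
    wt <- w * cpgs$total[idx, , drop = FALSE]
    sm[i, ] <- colSums(wm) / pmax(colSums(wt), 1e-12)
  }
  colnames(sm) <- colnames(cpgs$meth)
  cpgs$smoothed <- sm
  cpgs
}

## residuals of rows of Y on design X (with intercept prepended)
.row_residuals <- function(Y, X = NULL) {
  D <- cbind(rep(1, ncol(Y)), X)
  t(qr.resid(qr(D), t(Y)))
}

#' Principal components of ancestry-residualized methylation
#'
#' PCs computed from smoothed methylation after regressing out global
#' ancestry per CpG — the technical/biological-factor axes to be removed
#' before ranking CpG variability.
#'
#' @param smoothed CpG x sample smoothed proportions.
#' @param theta per-sample global ancestry.
#' @param n_pcs number of components (default 5).
#' @return sample x n_pcs score matrix.
#' @export
methylation_pcs <- function(smoothed, theta, n_pcs = 5) {
  res <- .row_residuals(smoothed, cbind(theta))
  n_pcs <- min(n_pcs, ncol(smoothed) - 1, nrow(smoothed))
  pr <- prcomp(t(res), center = TRUE, scale. = FALSE)
  pr$x[, seq_len(n_pcs), drop = FALSE]
}

#' Rank CpGs by residual variability and select the top fraction
#'
#' Per CpG, smoothed methylation is residualized on global ancestry
#' (preserving ancestry-driven variation in what follows), principal
#' components are computed from the residuals, each CpG is re-residualized
#' on the top `n_pcs` components, and CpGs are ranked by the standard
#' deviation of the final residuals. The top `top_frac` with nonzero
#' residual sd are returned.
#'
#' @param cpgs a `CpGTable` with `smoothed` (see [smooth_methylation()]).
#' @param theta per-sample global ancestry.
#' @param n_pcs PCs to remove (default 5, reduced with a warning if needed).
#' @param top_frac selected fraction (default 0.01).
#' @return data.frame of selected CpGs: `index`, `chrom`, `pos`,
#'   `residual_sd`, ordered by position; the PC scores are attached as an
#'   attribute `pcs`.
#' @export
select_variable_cpgs <- function(cpgs, theta, n_pcs = 5, top_frac = 0.01) {
  stopifnot(!is.null(cpgs$smoothed))
  sm <- cpgs$smoothed
  if (n_pcs > ncol(sm) - 1) {
    warning("fewer samples than requested PCs; reducing n_pcs")
    n_pcs <- ncol(sm) - 1
  }
  res <- .row_residuals(sm, cbind(theta))
  pcs <- methylation_pcs(sm, theta, n_pcs)
  res2 <- .row_residuals(res, pcs)
  s <- apply(res2, 1, sd)
  n_top <- max(1L, ceiling(top_frac * length(s)))
  ord <- order(s, decreasing = TRUE)
  sel <- ord[seq_len(n_top)]
  sel <- sel[s[sel] > 1e-10]
  sel <- sort(sel)
  out <- data.frame(index = sel, chrom = cpgs$chrom[sel],
                    pos = cpgs$pos[sel], residual_sd = s[sel])
  attr(out, "pcs") <- pcs
  out
}

#' Call variably methylated regions
#'
#' Consecutive selected CpGs closer than `max_gap_bp` are merged; regions
#' with at least `min_cpgs` CpGs are retained (`min_cpgs = 6` implements
#' "more than five CpGs"). The per-sample region level is the summed
#' methylated reads over summed total reads across the region's CpGs.
#'
#' @param cpgs the `CpGTable` the selection indexes into.
#' @param selected output of [select_variable_cpgs()] (or a data.frame with
#'   `index` and `pos`).
#' @param max_gap_bp maximum within-region gap (default 1000).
#' @param min_cpgs minimum CpGs per retained region (default 6).
#' @return list of class `VmrSet`: `regions` (chrom, start, end half-open
#'   0-based, n_cpgs) and `levels` (region x sample methylation levels).
#' @export
call_vmrs <- function(cpgs, selected, max_gap_bp = 1000, min_cpgs = 6) {
  if (nrow(selected) == 0) {
    return(structure(list(regions = data.frame(chrom = character(0),
                                               start = integer(0),
                                               end = integer(0),
                                               n_cpgs = integer(0)),
                          levels = matrix(0, 0, ncol(cpgs$meth))),
                     class = "VmrSet"))
  }
  o <- order(selected$chrom, selected$pos)
  sel <- selected[o, , drop = FALSE]
  new_grp <- c(TRUE, diff(sel$pos) > max_gap_bp |
                 sel$chrom[-1] != sel$chrom[-nrow(sel)])
  grp <- cumsum(new_grp)
  regions <- list()
  levels <- list()
  for (g in unique(grp)) {
    rows <- sel[grp == g, ]
    if (nrow(rows) < min_cpgs) next
    idx <- rows$index
    regions[[length(regions) + 1L]] <- data.frame(
      chrom = rows$chrom[1], start = min(rows$pos),
      end = max(rows$pos) + 1L, n_cpgs = nrow(rows))
    levels[[length(levels) + 1L]] <-
      colSums(cpgs$meth[idx, , drop = FALSE]) /
      pmax(colSums(cpgs$total[idx, , drop = FALSE]), 1e-12)
  }
  if (!length(regions)) {
    return(structure(list(regions = data.frame(chrom = character(0),
                                               start = integer(0),
                                               end = integer(0),
                                               n_cpgs = integer(0)),
                          levels = matrix(0, 0, ncol(cpgs$meth))),
                     class = "VmrSet"))
  }
  structure(list(regions = do.call(rbind, regions),
                 levels = do.call(rbind, levels)),
            class = "VmrSet")
}

#' Differentially methylated region model
#'
#' Linear model of each VMR's methylation level on an ancestry term (global
#' or local) plus sex, age and methylation PCs, with BH adjustment across
#' VMRs.
#'
#' @param vmrs a `VmrSet`.
#' @param ancestry per-sample global ancestry, or a VMR x sample matrix of
#'   local-ancestry scores.
#' @param age,sex per-sample covariates.
#' @param meth_pcs sample x PC score matrix (may be NULL).
#' @return data.frame per VMR: beta, se, t, p, fdr.
#' @export
fit_dmr <- function(vmrs, ancestry, age, sex, meth_pcs = NULL) {
  Y <- vmrs$levels
  n <- ncol(Y)
  base <- cbind(sex = sex, age = age, meth_pcs)
  local <- is.matrix(ancestry)
  out <- data.frame(beta = rep(NA_real_, nrow(Y)), se = NA_real_,
                    t = NA_real_, p = NA_real_)
  for (i in seq_len(nrow(Y))) {
    a <- if (local) ancestry[i, ] else ancestry
    X <- cbind(`(Intercept)` = 1, ancestry = a, base)
    fit <- .ols_rows(Y[i, , drop = FALSE], X, which = 2L)
    out$beta[i] <- fit$beta
    out$se[i] <- fit$se
  }
  out$t <- out$beta / out$se
  df <- n - 2L - ncol(base)
  out$p <- 2 * pt(-abs(out$t), df)
  out$fdr <- p.adjust(out$p, "BH")
  cbind(vmrs$regions, out)
}

#' Residualize VMR methylation levels on known factors
#'
#' Residuals of raw region methylation levels after regressing out local
#' ancestry, age, sex and the top methylation PCs — the environmental-proxy
#' covariates entering the adjusted P_ST model.
#'
#' @param vmrs a `VmrSet`.
#' @param local_ancestry VMR x sample local-ancestry matrix (or per-sample
#'   vector).
#' @param age,sex per-sample covariates.
#' @param meth_pcs sample x PC scores (may be NULL).
#' @return VMR x sample residual matrix.
#' @export
residualize_vmrs <- function(vmrs, local_ancestry, age, sex,
                             meth_pcs = NULL) {
  Y <- vmrs$levels
  out <- matrix(NA_real_, nrow(Y), ncol(Y))
  for (i in seq_len(nrow(Y))) {
    la <- if (is.matrix(local_ancestry)) local_ancestry[i, ]
          else local_ancestry
    X <- cbind(la = la, age = age, sex = sex, meth_pcs)
    out[i, ] <- .row_residuals(Y[i, , drop = FALSE], X)
  }
  out
}

#' P_ST: partial coefficient of determination of ancestry
#'
#' `(SSE(reduced) - SSE(full)) / SSE(reduced)` where the full model regresses
#' expression on ancestry plus covariates and the reduced model omits
#' ancestry. When `vmr_covariates` is supplied (residualized methylation of
#' the VMRs annotated to the gene), both models additionally include them,
#' yielding the VMR-adjusted statistic.
#'
#' @param gene_expr per-sample expression of one gene.
#' @param theta per-sample global ancestry.
#' @param covariates per-sample covariates (may be NULL).
#' @param vmr_covariates optional matrix of per-sample VMR residuals
#'   (samples in columns or a vector).
#' @return partial R-squared in `[0, 1]` (NA with a warning when the reduced
#'   model already fits exactly).
#' @export
pst <- function(gene_expr, theta, covariates = NULL,
                vmr_covariates = NULL) {
  n <- length(gene_expr)
  V <- if (is.null(vmr_covariates)) NULL else {
    v <- vmr_covariates
    if (is.vector(v)) v <- matrix(v, ncol = 1)
    if (nrow(v) != n) v <- t(v)
    v
  }
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  red <- cbind(rep(1, n), C, V)
  full <- cbind(red, theta)
  sse <- function(X) sum(qr.resid(qr(X), gene_expr)^2)
  sse_red <- sse(red)
  if (sse_red <= 1e-12) {
    warning("SSE(reduced) is zero; P_ST undefined")
    return(NA_real_)
  }
  max(0, (sse_red - sse(full)) / sse_red)
}

#' Relative drop in P_ST after VMR adjustment
#'
#' `(pst - pst_vmr) / pst`, the share of the ancestry-associated expression
#' variance attributable to the methylation-proxied environment. May be
#' negative when adjustment increases the ancestry signal; undefined when
#' `pst` is zero.
#'
#' @param pst,pst_vmr unadjusted and VMR-adjusted partial R-squared.
#' @return the fraction (NA when pst is 0 or NA).
#' @export
delta_pst <- function(pst, pst_vmr) {
  out <- (pst - pst_vmr) / pst
  out[!is.na(pst) & pst == 0] <- NA_real_
  out
}

#' Annotate VMRs to genes
#'
#' A VMR is annotated to a gene when it overlaps the gene body padded by
#' `promoter_pad_bp` on each side.
#'
#' @param vmrs a `VmrSet`.
#' @param features feature annotation (`feature_id`, `chrom`, `start`,
#'   `end`).
#' @param promoter_pad_bp pad (default 5000).
#' @return data.frame with `feature_id` and `vmr_index` pairs.
#' @export
annotate_vmrs <- function(vmrs, features, promoter_pad_bp = 5000) {
  reg <- vmrs$regions
  out <- list()
  for (j in seq_len(nrow(features))) {
    lo <- features$start[j] - promoter_pad_bp
    hi <- features$end[j] + promoter_pad_bp
    hit <- which(reg$chrom == features$chrom[j] &
                 reg$start < hi & reg$end > lo)
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(
        feature_id = features$feature_id[j], vmr_index = hit)
  }
  if (!length(out))
    return(data.frame(feature_id = character(0), vmr_index = integer(0)))
  do.call(rbind, out)
}
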