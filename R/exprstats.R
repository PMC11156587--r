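#' Effective feature length
#'
#' `length - mean_insert_size + 1`. Features whose effective length is one or
#' less carry no usable positions and are dropped by callers; junction-type
#' features use a fixed effective length of 100.
#'
#' @param length_bp feature length(s) in bp.
#' @param mean_insert_size mean sequenced-fragment insert size.
#' @param is_junction logical; junctions get effective length 100.
#' @return numeric effective lengths.
#' @export
effective_length <- function(length_bp, mean_insert_size,
                             is_junction = FALSE) {
  stopifnot(all(length_bp > 0))
  out <- length_bp - mean_insert_size + 1
  out[rep_len(is_junction, length(out))] <- 100
  out
}

#' TPM normalization
#'
#' `TPM = 1e6 * (count/efflen) / sum(count/efflen)` per sample. Columns sum
#' to 1e6; all-zero samples are returned as NA and flagged with a warning.
#'
#' @param counts feature x sample count matrix (or an `ExpressionSet`).
#' @param efflen effective length per feature.
#' @return TPM matrix.
#' @export
tpm_normalize <- function(counts, efflen) {
  if (inherits(counts, "ExpressionSet")) counts <- counts$counts
  stopifnot(nrow(counts) == length(efflen), all(efflen > 0))
  rate <- counts / efflen
  tot <- colSums(rate)
  bad <- tot == 0
  if (any(bad)) {
    warning(sum(bad), " all-zero sample(s); TPM undefined")
    tot[bad] <- NA_real_
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' Filter low-expressed features
#'
#' Retains features with TPM above `min_tpm` in at least `min_frac` of
#' samples and raw count at least `min_count` in at least `min_frac` of
#' samples.
#'
#' @param set an `ExpressionSet` (or plain count matrix).
#' @param tpm matching TPM matrix (from [tpm_normalize()]).
#' @param min_tpm TPM threshold (default 0.1).
#' @param min_frac sample fraction (default 0.2).
#' @param min_count count threshold (default 6).
#' @return The filtered set (same class as input).
#' @export
filter_low_expression <- function(set, tpm, min_tpm = 0.1, min_frac = 0.2,
                                  min_count = 6) {
  counts <- if (inherits(set, "ExpressionSet")) set$counts else set
  stopifnot(all(dim(counts) == dim(tpm)))
  n <- ncol(counts)
  keep <- rowMeans(tpm > min_tpm, na.rm = TRUE) >= min_frac &
    rowMeans(counts >= min_count) >= min_frac
  if (!any(keep))
    stop("no features pass the expression filter (TPM > ", min_tpm,
         " and count >= ", min_count, " in >= ", min_frac, " of samples)")
  if (inherits(set, "ExpressionSet")) {
    set$counts <- counts[keep, , drop = FALSE]
    if (!is.null(set$latent)) set$latent <- set$latent[keep, , drop = FALSE]
    set$features <- set$features[keep, , drop = FALSE]
    set$lib_size <- colSums(set$counts)
    set
  } else {
    counts[keep, , drop = FALSE]
  }
}

#' log2 counts-per-million
#'
#' @param counts feature x sample counts.
#' @param lib_size library sizes (default: column sums).
#' @param prior pseudo-count added to CPM before log2 (default 0.5).
#' @return log2-CPM matrix.
#' @export
log2_cpm <- function(counts, lib_size = colSums(counts), prior = 0.5) {
  log2(sweep(counts, 2, lib_size / 1e6, "/") + prior)
}

## OLS of every row of Y (features x samples) on design X (samples x p);
## returns coefficient, its se and residual df for column `which`
.ols_rows <- function(Y, X, which) {
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p) stop("more model parameters than samples (n <= p)")
  qx <- qr(X)
  if (qx$rank < p) {
    cols <- colnames(X)[setdiff(seq_len(p), qx$pivot[seq_len(qx$rank)])]
    stop("rank-deficient design; collinear column(s): ",
         paste(cols, collapse = ", "))
  }
  XtXi <- chol2inv(qr.R(qx))
  B <- XtXi %*% crossprod(X, t(Y))          # p x J
  res <- t(Y) - X %*% B
  sigma2 <- colSums(res^2) / (n - p)
  list(beta = B[which, ], se = sqrt(sigma2 * XtXi[which, which]),
       df = n - p, coefficients = B, residuals = res)
}

#' Ancestry differential expression for one region
#'
#' Ordinary least squares of log2-CPM on ancestry plus covariates, returning
#' the ancestry coefficient (log2 fold change per unit ancestry proportion),
#' its standard error and residual degrees of freedom per feature — the
#' effect/se pairs consumed by the multivariate shrinkage stage. With a
#' global-ancestry table the regressor is shared across features; with a
#' `LocalAncestryScore` each feature is fit against its own local score.
#'
#' @param set an `ExpressionSet` (counts are log2-CPM transformed) or a
#'   numeric feature x sample matrix used as-is.
#' @param ancestry an `AncestryTable`, a numeric vector of per-sample
#'   ancestry proportions, or a `LocalAncestryScore`.
#' @param covariates data.frame or matrix of per-sample covariates (may be
#'   NULL). Samples dropped listwise on missing ancestry.
#' @return list of class `EffectMatrix` with `beta`, `se` (feature x 1
#'   matrices here; combine regions with [combine_effects()]) and `df`.
#' @export
fit_ancestry_de <- function(set, ancestry, covariates = NULL) {
  Y <- if (inherits(set, "ExpressionSet")) log2_cpm(set$counts) else set
  n <- ncol(Y)
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)

  if (inherits(ancestry, "LocalAncestryScore")) {
    S <- ancestry$scores
    stopifnot(ncol(S) == n)
    common <- intersect(rownames(Y), rownames(S))
    beta <- se <- setNames(rep(NA_real_, nrow(Y)), rownames(Y))
    df <- NA_integer_
    for (f in common) {
      a <- S[f, ]
      ok <- !is.na(a)
      X <- cbind(`(Intercept)` = 1, ancestry = a[ok],
                 if (!is.null(C)) C[ok, , drop = FALSE])
      fit <- .ols_rows(Y[f, ok, drop = FALSE], X, which = 2L)
      beta[f] <- fit$beta
      se[f] <- fit$se
      df <- fit$df
    }
  } else {
    a <- if (inherits(ancestry, "AncestryTable")) ancestry$theta_hat
         else ancestry
    stopifnot(length(a) == n)
    ok <- !is.na(a)
    X <- cbind(`(Intercept)` = 1, ancestry = a[ok],
               if (!is.null(C)) C[ok, , drop = FALSE])
    fit <- .ols_rows(Y[, ok, drop = FALSE], X, which = 2L)
    beta <- fit$beta
    se <- fit$se
    df <- fit$df
  }
  structure(list(beta = cbind(beta), se = cbind(se), df = df),
            class = "EffectMatrix")
}

#' Combine one-region effect fits into a multi-region effect matrix
#'
#' @param fits named list of `EffectMatrix` objects (one per region).
#' @return `EffectMatrix` with feature x region `beta` and `se` and a vector
#'   of per-region residual df. Features are aligned by name (missing
#'   allowed, NA).
#' @export
combine_effects <- function(fits) {
  stopifnot(length(fits) >= 1)
  feats <- unique(unlist(lapply(fits, function(f) rownames(f$beta))))
  R <- length(fits)
  beta <- se <- matrix(NA_real_, length(feats), R,
                       dimnames = list(feats, names(fits)))
  for (r in seq_len(R)) {
    i <- match(rownames(fits[[r]]$beta), feats)
    beta[i, r] <- fits[[r]]$beta[, 1]
    se[i, r] <- fits[[r]]$se[, 1]
  }
  structure(list(beta = beta, se = se,
                 df = vapply(fits, function(f) f$df[1], 0)),
            class = "EffectMatrix")
}

#' Residualize expression on a null covariate model and z-score
#'
#' Regresses log2-CPM on the covariates (null model, excluding ancestry),
#' then standardizes each feature's residuals to mean 0, sd 1.
#' Zero-variance features are dropped with a warning.
#'
#' @param set an `ExpressionSet` or numeric feature x sample matrix.
#' @param covariates_null per-sample covariates of the null model.
#' @return residualized, z-scored feature x sample matrix.
#' @export
residualize <- function(set, covariates_null = NULL) {
  Y <- if (inherits(set, "ExpressionSet")) log2_cpm(set$counts) else set
  X <- cbind(`(Intercept)` = rep(1, ncol(Y)),
             if (!is.null(covariates_null)) as.matrix(covariates_null))
  fit <- .ols_rows(Y, X, which = 1L)
  res <- t(fit$residuals)
  s <- apply(res, 1, sd)
  zero <- s == 0 | !is.finite(s)
  if (any(zero)) {
    warning(sum(zero), " zero-variance feature(s) dropped")
    res <- res[!zero, , drop = FALSE]
    s <- s[!zero]
  }
  (res - rowMeans(res)) / s
}
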