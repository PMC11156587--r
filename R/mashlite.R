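#' Estimate the null correlation of effects across regions
#'
#' Correlation matrix of z-scores (beta/se) over features that look null in
#' every region (max |z| below `z_thresh`), used as the residual correlation
#' V of the shrinkage model. Falls back to the identity with a warning when
#' fewer than R+1 null-like features exist.
#'
#' @param effects an `EffectMatrix`.
#' @param z_thresh |z| threshold defining "null-like" (default 2).
#' @return R x R correlation matrix with unit diagonal.
#' @export
estimate_null_correlation <- function(effects, z_thresh = 2) {
  z <- effects$beta / effects$se
  R <- ncol(z)
  ok <- complete.cases(z)
  nullish <- ok & apply(abs(z), 1, max) < z_thresh
  if (sum(nullish) < R + 1) {
    warning("too few null-like features; returning identity")
    return(diag(R))
  }
  V <- cor(z[nullish, , drop = FALSE])
  V[!is.finite(V)] <- 0
  diag(V) <- 1
  (V + t(V)) / 2
}

#' Build the covariance dictionary
#'
#' Canonical matrices (identity, per-region singletons, equal effects,
#' heterogeneous with off-diagonal 0.25/0.5/0.75) plus data-driven matrices
#' from the top principal components of the strong-set z-scores (one rank-1
#' matrix per PC and their rank-`n_pcs` reconstruction), all scaled to unit
#' maximum diagonal, together with a geometric grid of scaling factors.
#'
#' @param effects_strong `EffectMatrix` restricted to the strong set.
#' @param n_pcs number of principal components (default 4); reduced with a
#'   warning when the strong set is smaller.
#' @param grid optional explicit grid of variance scales; by default
#'   geometric with ratio sqrt(2) from `(min se)^2 / 100` to
#'   `4 * max(beta^2)`.
#' @return list of class `CovarianceDictionary` with `matrices` (named list
#'   of R x R PSD matrices) and `grid`.
#' @export
build_covariances <- function(effects_strong, n_pcs = 4, grid = NULL) {
  beta <- effects_strong$beta
  se <- effects_strong$se
  ok <- complete.cases(beta) & complete.cases(se)
  beta <- beta[ok, , drop = FALSE]
  se <- se[ok, , drop = FALSE]
  stopifnot(nrow(beta) > 0)
  R <- ncol(beta)

  unit <- function(M) {
    d <- max(diag(M))
    if (d <= 0) M else M / d
  }
  mats <- list(identity = diag(R))
  if (R > 1) {
    for (r in seq_len(R)) {
      e <- matrix(0, R, R)
      e[r, r] <- 1
      mats[[paste0("singleton_", r)]] <- e
    }
    mats$equal_effects <- matrix(1, R, R)
    for (rho in c(0.25, 0.5, 0.75)) {
      H <- matrix(rho, R, R)
      diag(H) <- 1
      mats[[paste0("het_", rho)]] <- H
    }
    if (n_pcs > nrow(beta)) {
      warning("strong set smaller than n_pcs; reducing to ", nrow(beta))
      n_pcs <- nrow(beta)
    }
    n_pcs <- min(n_pcs, R)
    z <- beta / se
    sv <- svd(z, nu = 0, nv = n_pcs)
    for (p in seq_len(n_pcs)) {
      v <- sv$v[, p]
      mats[[paste0("pca_", p)]] <- unit(tcrossprod(v))
    }
    Vp <- sv$v[, seq_len(n_pcs), drop = FALSE]
    Dp <- diag(sv$d[seq_len(n_pcs)]^2 / nrow(z), n_pcs, n_pcs)
    mats[[paste0("rank_", n_pcs)]] <- unit(Vp %*% Dp %*% t(Vp))
  }
  mats <- lapply(mats, unit)

  if (is.null(grid)) {
    lo <- min(se[se > 0])^2 / 100
    hi <- max(4 * max(beta^2), lo * 2)
    n_g <- ceiling(log(hi / lo) / log(sqrt(2))) + 1
    grid <- lo * sqrt(2)^(seq_len(n_g) - 1)
  }
  stopifnot(all(diff(grid) > 0), all(grid > 0))
  structure(list(matrices = mats, grid = grid),
            class = "CovarianceDictionary")
}

## expand dictionary into the component cube (slice 1 = null point mass)
.dictionary_cube <- function(dictionary, R) {
  mats <- dictionary$matrices
  grid <- dictionary$grid
  M <- 1L + length(mats) * length(grid)
  U <- array(0, c(R, R, M))
  labels <- character(M)
  labels[1] <- "null"
  m <- 1L
  for (k in seq_along(mats)) {
    for (l in seq_along(grid)) {
      m <- m + 1L
      U[, , m] <- grid[l] * mats[[k]]
      labels[m] <- sprintf("%s;omega=%g", names(mats)[k], grid[l])
    }
  }
  list(U = U, labels = labels)
}

## log-sum-exp of loglik rows against mixture weights
.mix_loglik <- function(ll, pi_w) {
  lw <- sweep(ll, 2, log(pi_w + 1e-300), "+")
  mx <- apply(lw, 1, max)
  mx + log(rowSums(exp(lw - mx)))
}

#' Fit the mixture weights by EM
#'
#' Expectation-maximization over the mixture proportions of the (covariance,
#' scale) components plus the null point mass, with a Dirichlet penalty on
#' the null to keep it conservative. The fit can be run on a random subset
#' of features (the weights are then applied to all features in
#' [posterior_summaries()]).
#'
#' @param effects `EffectMatrix`.
#' @param dictionary a [build_covariances()] dictionary.
#' @param V null correlation matrix (default identity).
#' @param subset_frac fraction of features used for fitting (default 1;
#'   the conventional two-pass scheme uses 0.05).
#' @param null_penalty Dirichlet prior weight on the null component
#'   (default 10).
#' @param max_iter,tol EM controls.
#' @param seed seed for the random subset.
#' @return list of class `MashFit`: `pi` (named weights), `V`, `dictionary`,
#'   `loglik_trace` (penalized objective per iteration, non-decreasing),
#'   `converged`.
#' @export
fit_mixture_em <- function(effects, dictionary, V = NULL,
                           subset_frac = 1, null_penalty = 10,
                           max_iter = 500, tol = 1e-6, seed = 1L) {
  beta <- effects$beta
  se <- effects$se
  ok <- complete.cases(beta) & complete.cases(se)
  beta <- beta[ok, , drop = FALSE]
  se <- se[ok, , drop = FALSE]
  R <- ncol(beta)
  if (is.null(V)) V <- diag(R)

  if (subset_frac < 1) {
    set.seed(seed)
    idx <- sort(sample.int(nrow(beta), ceiling(subset_frac * nrow(beta))))
    beta <- beta[idx, , drop = FALSE]
    se <- se[idx, , drop = FALSE]
  }
  cube <- .dictionary_cube(dictionary, R)
  ll <- .mash_loglik_cpp(beta, se, V, cube$U)
  if (any(!is.finite(ll))) {
    bad <- which(!apply(is.finite(ll), 1, all))
    stop("non-finite likelihood for feature row(s): ",
         paste(head(bad, 5), collapse = ", "))
  }
  M <- ncol(ll)
  J <- nrow(ll)
  pi_w <- rep(1 / M, M)
  prior_extra <- c(null_penalty - 1, rep(0, M - 1))

  penalized <- function(pi_w)
    sum(.mix_loglik(ll, pi_w)) + (null_penalty - 1) * log(pi_w[1] + 1e-300)

  trace <- penalized(pi_w)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lw <- sweep(ll, 2, log(pi_w + 1e-300), "+")
    mx <- apply(lw, 1, max)
    g <- exp(lw - mx)
    g <- g / rowSums(g)
    counts <- colSums(g) + prior_extra
    pi_w <- counts / sum(counts)
    obj <- penalized(pi_w)
    trace <- c(trace, obj)
    if (obj - trace[length(trace) - 1] < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(pi = setNames(pi_w, cube$labels), V = V,
                 dictionary = dictionary, loglik_trace = trace,
                 converged = converged),
            class = "MashFit")
}

#' Posterior effects and local false sign rates
#'
#' Given fitted mixture weights, computes per-feature responsibilities and
#' the mixture of conditional posteriors: the null contributes a point mass
#' at zero, every other component a normal with mean
#' \eqn{U (U + S_j)^{-1} \hat b_j} and covariance
#' \eqn{U - U (U + S_j)^{-1} U}. The LFSR per region is
#' `min(P(b <= 0), P(b >= 0))` with the point mass counted in both tails.
#'
#' @param effects `EffectMatrix` (all features to summarize).
#' @param fit a `MashFit`.
#' @return list of class `MashPosterior`: `post_mean`, `post_sd`, `lfsr`
#'   (feature x region), row/col names preserved.
#' @export
posterior_summaries <- function(effects, fit) {
  beta <- effects$beta
  se <- effects$se
  ok <- complete.cases(beta) & complete.cases(se)
  R <- ncol(beta)
  cube <- .dictionary_cube(fit$dictionary, R)
  ll <- .mash_loglik_cpp(beta[ok, , drop = FALSE], se[ok, , drop = FALSE],
                         fit$V, cube$U)
  post <- .mash_posterior_cpp(beta[ok, , drop = FALSE],
                              se[ok, , drop = FALSE],
                              fit$V, cube$U, fit$pi, ll)
  shape <- function(m) {
    out <- matrix(NA_real_, nrow(beta), R, dimnames = dimnames(beta))
    out[ok, ] <- m
    out
  }
  neg <- post$neg_prob
  zero <- post$zero_prob
  pos <- pmax(1 - neg - zero, 0)
  lfsr <- pmin(pmax(zero + pmin(neg, pos), 0), 1)
  structure(list(post_mean = shape(post$post_mean),
                 post_sd = shape(post$post_sd),
                 lfsr = shape(lfsr)),
            class = "MashPosterior")
}

#' Threshold posterior significance
#'
#' @param posterior a `MashPosterior`.
#' @param lfsr_cut LFSR threshold (default 0.05).
#' @return list with per-region significant feature id sets, their `union`
#'   and `intersection`.
#' @export
significant_features <- function(posterior, lfsr_cut = 0.05) {
  lf <- posterior$lfsr
  per_region <- lapply(seq_len(ncol(lf)), function(r) {
    rownames(lf)[which(lf[, r] < lfsr_cut)]
  })
  names(per_region) <- colnames(lf)
  list(per_region = per_region,
       union = Reduce(union, per_region, character(0)),
       intersection = if (length(per_region))
         Reduce(intersect, per_region) else character(0))
}

#' Strong-set selection by per-region tests
#'
#' Features whose two-sided normal p-value (from beta/se) passes BH FDR
#' below `fdr` in at least one region — the condition-by-condition
#' definition of "strong" signals feeding the data-driven covariances.
#'
#' @param effects `EffectMatrix`.
#' @param fdr BH threshold (default 0.05).
#' @return logical vector over features.
#' @export
strong_set <- function(effects, fdr = 0.05) {
  z <- effects$beta / effects$se
  p <- 2 * pnorm(-abs(z))
  padj <- apply(p, 2, p.adjust, method = "BH")
  sel <- rowSums(padj < fdr, na.rm = TRUE) > 0
  sel & complete.cases(effects$beta) & complete.cases(effects$se)
}

#' One-call multivariate shrinkage
#'
#' Convenience pipeline: null correlation, strong set, covariance
#' dictionary, EM mixture fit (optionally on a random subset) and posterior
#' summaries for all features.
#'
#' @inheritParams fit_mixture_em
#' @param n_pcs PCs for the data-driven covariances.
#' @return list with `fit` (`MashFit`) and `posterior` (`MashPosterior`).
#' @export
mash_lite <- function(effects, subset_frac = 1, n_pcs = 4,
                      null_penalty = 10, max_iter = 500, tol = 1e-6,
                      seed = 1L) {
  V <- estimate_null_correlation(effects)
  sel <- strong_set(effects)
  eff_strong <- if (sum(sel) >= 2) {
    structure(list(beta = effects$beta[sel, , drop = FALSE],
                   se = effects$se[sel, , drop = FALSE],
                   df = effects$df), class = "EffectMatrix")
  } else {
    effects
  }
  dict <- build_covariances(eff_strong, n_pcs = n_pcs)
  fit <- fit_mixture_em(effects, dict, V = V, subset_frac = subset_frac,
                        null_penalty = null_penalty, max_iter = max_iter,
                        tol = tol, seed = seed)
  list(fit = fit, posterior = posterior_summaries(effects, fit))
}
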