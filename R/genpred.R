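#' Predicted expression from the top variant
#'
#' `prediction = posterior effect size x dosage` per sample.
#'
#' @param posterior_effect scalar effect of the feature's top variant.
#' @param dosage per-sample dosages of that variant (NA gives NA).
#' @return numeric predictions.
#' @export
predict_top_snp <- function(posterior_effect, dosage) {
  posterior_effect * dosage
}

#' Elastic-net expression imputation from cis genotypes
#'
#' Sparse linear model of residualized expression on cis dosages:
#' coordinate-descent elastic net over a grid of 20 alpha values (0.05 to 1
#' by 0.05) and a 100-value geometric lambda path, with cross-model
#' selection and averaging: per fold the path is fit on the training split,
#' the fold's lambda is chosen on its held-out split, and the final weights
#' are the mean of the per-fold models at the selected alpha. `cv_r` is the
#' mean across folds of the held-out Pearson correlation. Predictors are
#' standardized within training folds only; weights are back-transformed to
#' the dosage scale. Variants are pre-filtered at MAF >= `maf_min` and HWE
#' exact P >= `hwe_p_min`.
#'
#' @param y per-sample residualized expression of one feature.
#' @param dosage_matrix cis-window dosages (variants x samples).
#' @param alphas elastic-net mixing grid (default `seq(0.05, 1, 0.05)`).
#' @param k_folds cross-validation folds (default 5).
#' @param n_lambda lambda-path length (default 100).
#' @param maf_min,hwe_p_min variant pre-filters (defaults 0.01 and 1e-5).
#' @param seed integer seed for fold assignment (required).
#' @return list of class `PredictionModel`: `weights` (named, dosage
#'   scale), `intercept`, `alpha`, `lambda`, `cv_r`, `cv_pred` (cross-fitted
#'   per-sample predictions: each sample predicted by the fold model that
#'   did not see it, the prediction to use when relating predicted to
#'   observed effects within the same cohort), `model_kind`, `n_variants`;
#'   or a flagged empty model when all variants are filtered.
#' @export
fit_elastic_net <- function(y, dosage_matrix, alphas = seq(0.05, 1, 0.05),
                            k_folds = 5, n_lambda = 100,
                            maf_min = 0.01, hwe_p_min = 1e-5, seed) {
  if (missing(seed)) stop("seed is required")
  n <- length(y)
  stopifnot(ncol(dosage_matrix) == n, n > k_folds)

  f <- rowMeans(dosage_matrix) / 2
  maf <- pmin(f, 1 - f)
  hwe <- apply(dosage_matrix, 1, hwe_exact_test)
  keep <- maf >= maf_min & hwe >= hwe_p_min &
    apply(dosage_matrix, 1, sd) > 0
  if (!any(keep)) {
    return(structure(list(weights = numeric(0), intercept = NA_real_,
                          alpha = NA_real_, lambda = NA_real_,
                          cv_r = NA_real_, model_kind = "elastic_net",
                          n_variants = 0L, empty = TRUE),
                     class = "PredictionModel"))
  }
  X <- t(dosage_matrix[keep, , drop = FALSE])   # n x p
  p <- ncol(X)

  set.seed(seed)
  fold <- sample(rep_len(seq_len(k_folds), n))

  ## lambda path shared across folds: geometric from the smallest lambda
  ## zeroing all coefficients (at the smallest alpha it is largest)
  xs <- scale(X)
  ys <- y - mean(y)
  lmax_base <- max(abs(crossprod(xs, ys)) / n)

  fit_fold_path <- function(tr, alpha) {
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, sd)
    sdv[sdv == 0] <- 1
    Xs <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdv, "/")
    yc <- y[tr] - mean(y[tr])
    lmax <- max(abs(crossprod(Xs, yc)) / length(tr)) / alpha
    lam <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = n_lambda))
    path <- .elnet_path_cpp(Xs, yc, alpha, lam, 1000L, 1e-7)
    ## back-transform to raw dosage scale
    B <- path$beta / sdv
    a0 <- mean(y[tr]) - as.vector(mu %*% B)
    list(B = B, a0 = a0, lambda = lam)
  }

  best <- NULL
  for (alpha in alphas) {
    fold_w <- matrix(0, p, k_folds)
    fold_a0 <- numeric(k_folds)
    fold_r <- numeric(k_folds)
    fold_lam <- numeric(k_folds)
    cvp <- numeric(n)
    for (k in seq_len(k_folds)) {
      tr <- which(fold != k)
      te <- which(fold == k)
      fp <- fit_fold_path(tr, alpha)
      pred <- sweep(X[te, , drop = FALSE] %*% fp$B, 2, fp$a0, "+")
      mse <- colMeans((y[te] - pred)^2)
      l <- which.min(mse)
      fold_w[, k] <- fp$B[, l]
      fold_a0[k] <- fp$a0[l]
      fold_lam[k] <- fp$lambda[l]
      fold_r[k] <- if (sd(pred[, l]) > 0) cor(y[te], pred[, l]) else 0
      cvp[te] <- pred[, l]
    }
    cv_r <- mean(fold_r)
    if (is.null(best) || cv_r > best$cv_r) {
      best <- list(alpha = alpha, cv_r = cv_r,
                   weights = rowMeans(fold_w),
                   intercept = mean(fold_a0),
                   lambda = mean(fold_lam),
                   cv_pred = cvp)
    }
  }
  structure(list(weights = setNames(best$weights, colnames(X)),
                 intercept = best$intercept, alpha = best$alpha,
                 lambda = best$lambda, cv_r = best$cv_r,
                 cv_pred = best$cv_pred,
                 model_kind = "elastic_net",
                 n_variants = sum(best$weights != 0), empty = FALSE),
            class = "PredictionModel")
}

#' Predict expression from a fitted model
#'
#' @param model a `PredictionModel`.
#' @param dosage_matrix variants x samples dosages (rownames matched to
#'   weight names).
#' @return per-sample predictions.
#' @export
predict_expression <- function(model, dosage_matrix) {
  if (isTRUE(model$empty)) return(rep(NA_real_, ncol(dosage_matrix)))
  w <- model$weights
  G <- dosage_matrix[match(names(w), rownames(dosage_matrix)), ,
                     drop = FALSE]
  as.vector(crossprod(G, w)) + model$intercept
}

#' Variance of ancestry effects explained by genotype-predicted expression
#'
#' Applies the same ancestry differential-expression model to
#' genotype-predicted expression as was applied to observed expression, then
#' reports the squared correlation (and slope) between predicted and
#' observed ancestry effects across the supplied features — the share of
#' ancestry-associated expression differences attributable to cis genetic
#' variation.
#'
#' @param predicted_expr feature x sample matrix of predicted expression.
#' @param ancestry per-sample global ancestry proportions (or an
#'   `AncestryTable`).
#' @param covariates per-sample covariates as in the observed fit.
#' @param observed_effects per-feature observed ancestry effects (e.g. the
#'   posterior-mean column of a region from [posterior_summaries()]), named
#'   by feature.
#' @param region label stored in the result.
#' @return list of class `VarianceExplained`: `region`, `r2`, `slope`,
#'   `n_features`, plus the per-feature predicted effects.
#' @export
ancestry_effect_variance_explained <- function(predicted_expr, ancestry,
                                               covariates = NULL,
                                               observed_effects,
                                               region = "region") {
  common <- intersect(rownames(predicted_expr), names(observed_effects))
  if (length(common) < 10)
    stop("need at least 10 features with both predicted expression and ",
         "observed effects; got ", length(common))
  fit <- fit_ancestry_de(predicted_expr[common, , drop = FALSE],
                         ancestry, covariates)
  pred_eff <- fit$beta[common, 1]
  obs_eff <- observed_effects[common]
  sl <- coef(lm.fit(cbind(1, pred_eff), obs_eff))[2]
  structure(list(region = region, r2 = cor(pred_eff, obs_eff)^2,
                 slope = unname(sl), n_features = length(common),
                 predicted_effects = pred_eff),
            class = "VarianceExplained")
}
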