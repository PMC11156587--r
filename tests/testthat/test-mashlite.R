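## hand-built dictionary/fit helpers for oracle tests
manual_dict <- function(mats, grid = 1) {
  structure(list(matrices = mats, grid = grid),
            class = "CovarianceDictionary")
}
manual_fit <- function(pi_w, V, dict) {
  structure(list(pi = pi_w, V = V, dictionary = dict,
                 loglik_trace = 0, converged = TRUE), class = "MashFit")
}

test_that("null correlation approaches identity on independent nulls", {
  set.seed(41)
  J <- 3000
  se <- matrix(runif(J * 3, 0.5, 1.5), J)
  beta <- se * matrix(rnorm(J * 3), J)
  eff <- as_effects(beta, se)
  V <- estimate_null_correlation(eff)
  expect_equal(unname(diag(V)), rep(1, 3))
  expect_lt(max(abs(V - diag(3))), 0.05)
  expect_equal(V, t(V))
})

test_that("duplicated region columns give unit off-diagonal correlation", {
  set.seed(42)
  z <- rnorm(200)
  se <- matrix(1, 200, 2)
  eff <- as_effects(cbind(z, z), se)
  V <- estimate_null_correlation(eff)
  expect_equal(V[1, 2], 1, tolerance = 1e-12)
})

test_that("too few null-like features falls back to identity", {
  beta <- matrix(10, 5, 3)       # all strongly non-null
  se <- matrix(1, 5, 3)
  expect_warning(V <- estimate_null_correlation(as_effects(beta, se)),
                 "identity")
  expect_equal(V, diag(3))
})

test_that("covariance dictionary has PSD matrices and an increasing grid", {
  set.seed(43)
  eff <- as_effects(matrix(rnorm(60, 0, 3), 20), matrix(1, 20, 3))
  d <- build_covariances(eff)
  for (M in d$matrices) {
    expect_equal(M, t(M))
    expect_gte(min(eigen(M, symmetric = TRUE)$values), -1e-8)
    expect_lte(max(diag(M)), 1 + 1e-12)
  }
  expect_true(all(diff(d$grid) > 0))
  expect_setequal(
    c("identity", "equal_effects", "het_0.5", "pca_1", "rank_3"),
    intersect(names(d$matrices),
              c("identity", "equal_effects", "het_0.5", "pca_1", "rank_3")))
})

test_that("equal strong z-scores make the leading PC the equal-effects matrix", {
  z <- matrix(rep(rnorm(30, 0, 4), 3), 30)
  eff <- as_effects(z, matrix(1, 30, 3))
  d <- build_covariances(eff, n_pcs = 2)
  expect_lt(max(abs(d$matrices$pca_1 - d$matrices$equal_effects)), 1e-8)
})

test_that("data-driven PCs match a direct eigendecomposition oracle", {
  set.seed(44)
  z <- matrix(rnorm(150), 50, 3) %*% matrix(c(2, 1, 0, 0, 1, 1, 0, 0, 1), 3)
  eff <- as_effects(z, matrix(1, 50, 3))
  d <- build_covariances(eff, n_pcs = 2)
  ev <- eigen(crossprod(z), symmetric = TRUE)
  for (p in 1:2) {
    v <- ev$vectors[, p]
    oracle <- tcrossprod(v) / max(diag(tcrossprod(v)))
    expect_lt(max(abs(d$matrices[[paste0("pca_", p)]] - oracle)), 1e-8)
  }
})

test_that("single-region dictionary degenerates to scalar shrinkage", {
  set.seed(45)
  beta <- matrix(rnorm(100, 0, 2), 100, 1)
  se <- matrix(1, 100, 1)
  eff <- as_effects(beta, se)
  d <- build_covariances(eff)
  expect_named(d$matrices, "identity")
  fit <- fit_mixture_em(eff, d, null_penalty = 1)
  post <- posterior_summaries(eff, fit)
  ## oracle: univariate mixture of scaled-normal priors, closed form
  pi_w <- fit$pi
  grid <- c(0, d$grid)     # null first
  for (j in c(1, 10, 50)) {
    liks <- stats::dnorm(beta[j, 1], 0, sqrt(1 + grid))
    g <- pi_w * liks / sum(pi_w * liks)
    mean_or <- sum(g * grid / (grid + 1) * beta[j, 1])
    expect_equal(unname(post$post_mean[j, 1]), mean_or, tolerance = 1e-8)
  }
})

test_that("a null-only dictionary collapses to the null in one step", {
  set.seed(46)
  eff <- as_effects(matrix(rnorm(40), 20, 2), matrix(1, 20, 2))
  d <- manual_dict(list())
  fit <- fit_mixture_em(eff, d)
  expect_equal(unname(fit$pi[1]), 1)
  post <- posterior_summaries(eff, fit)
  expect_true(all(post$post_mean == 0))
  expect_true(all(post$lfsr == 1))
})

test_that("EM recovers a known 50/50 mixture against a grid-search oracle", {
  set.seed(47)
  J <- 2000
  R <- 2
  U <- matrix(c(4, 3.2, 3.2, 4), 2)
  se <- matrix(1, J, R)
  is_sig <- rep(c(FALSE, TRUE), length.out = J)
  beta <- matrix(rnorm(J * R), J, R)     # null part: N(0, I)
  L <- chol(U + diag(R))
  beta[is_sig, ] <- matrix(rnorm(sum(is_sig) * R), sum(is_sig)) %*% L
  eff <- as_effects(beta, se)
  d <- manual_dict(list(signal = U))
  fit <- fit_mixture_em(eff, d, null_penalty = 1, tol = 1e-10)
  expect_true(all(diff(fit$loglik_trace) > -1e-9))

  ## oracle: 1-D grid search over the binary mixture weight
  cube_ll <- admixdeconv:::.mash_loglik_cpp(beta, se, diag(R),
                              array(c(matrix(0, R, R), U), c(R, R, 2)))
  w_grid <- seq(0.001, 0.999, 0.001)
  tot <- vapply(w_grid, function(w) {
    mx <- pmax(cube_ll[, 1], cube_ll[, 2])
    sum(mx + log(w * exp(cube_ll[, 1] - mx) +
                 (1 - w) * exp(cube_ll[, 2] - mx)))
  }, 0)
  w_star <- w_grid[which.max(tot)]
  expect_lt(abs(unname(fit$pi[1]) - w_star), 0.05)
  expect_lt(abs(unname(fit$pi[1]) - 0.5), 0.05)
})

test_that("pure-null weights give zero posterior means and unit LFSR", {
  eff <- as_effects(matrix(c(1, -2, 0.5, 3), 2), matrix(1, 2, 2))
  d <- manual_dict(list(id = diag(2)))
  fit <- manual_fit(c(1, 0), diag(2), d)
  post <- posterior_summaries(eff, fit)
  expect_true(all(post$post_mean == 0))
  expect_true(all(post$lfsr == 1))
})

test_that("symmetric prior at beta = 0 gives LFSR 1/2 without a null mass", {
  eff <- as_effects(matrix(0, 1, 2), matrix(1, 1, 2))
  d <- manual_dict(list(id = diag(2), eq = matrix(c(1, 1, 1, 1), 2)))
  fit <- manual_fit(c(0, 0.5, 0.5), diag(2), d)
  post <- posterior_summaries(eff, fit)
  expect_equal(unname(post$lfsr[1, ]), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(unname(post$post_mean[1, ]), c(0, 0), tolerance = 1e-12)
})

test_that("posterior matches dense Bayes-rule quadrature on an R=2 toy", {
  U1 <- matrix(c(1, 0.9, 0.9, 1), 2)
  U2 <- diag(c(0.5, 0.1))
  V <- matrix(c(1, 0.3, 0.3, 1), 2)
  se <- c(0.4, 0.7)
  S <- diag(se) %*% V %*% diag(se)
  pi_w <- c(0.3, 0.4, 0.3)
  d <- manual_dict(list(u1 = U1, u2 = U2))
  fit <- manual_fit(pi_w, V, d)

  ## vectorized bivariate normal density over grid rows
  dmvn_rows <- function(X, Sig) {
    k <- ncol(X)
    Q <- rowSums((X %*% solve(Sig)) * X)
    exp(-0.5 * (k * log(2 * pi) +
                  as.numeric(determinant(Sig)$modulus) + Q))
  }
  grid1 <- seq(-8, 8, length.out = 401)
  gr <- as.matrix(expand.grid(b1 = grid1, b2 = grid1))
  h <- diff(grid1)[1]^2
  ## tail indicator with half weight on the b = 0 grid line (midpoint rule)
  wneg <- (gr < 0) + 0.5 * (gr == 0)
  wpos <- (gr > 0) + 0.5 * (gr == 0)

  for (bhat in list(c(1.2, 0.4), c(-0.5, 2), c(0, 0))) {
    eff <- as_effects(matrix(bhat, 1), matrix(se, 1))
    post <- posterior_summaries(eff, fit)

    lik_at_zero <- dmvn_rows(matrix(bhat, 1), S)
    prior1 <- dmvn_rows(gr, U1)
    prior2 <- dmvn_rows(gr, U2)
    lik <- dmvn_rows(sweep(gr, 2, bhat, "-"), S)
    dens <- (pi_w[2] * prior1 + pi_w[3] * prior2) * lik
    mass_cont <- sum(dens) * h
    mass_null <- pi_w[1] * lik_at_zero
    norm <- mass_cont + mass_null
    mean_or <- colSums(gr * dens) * h / norm
    expect_lt(max(abs(post$post_mean[1, ] - mean_or)), 1e-4)

    sd_or <- sqrt(colSums(gr^2 * dens) * h / norm - mean_or^2)
    expect_lt(max(abs(post$post_sd[1, ] - sd_or)), 1e-3)

    neg_or <- (colSums(wneg * dens) * h + mass_null) / norm
    pos_or <- (colSums(wpos * dens) * h + mass_null) / norm
    lfsr_or <- pmin(neg_or, pos_or)
    expect_lt(max(abs(post$lfsr[1, ] - lfsr_or)), 5e-3)
  }
})

test_that("shrinkage never inflates effects with small-scale dictionaries", {
  set.seed(48)
  eff <- as_effects(matrix(rnorm(200), 100, 2),
                    matrix(1, 100, 2))
  d <- manual_dict(list(id = diag(2)), grid = c(0.1, 0.5, 1))
  fit <- fit_mixture_em(eff, d)
  post <- posterior_summaries(eff, fit)
  expect_true(all(abs(post$post_mean) <= abs(eff$beta) + 1e-12))
})

test_that("posterior mean approaches beta as se -> 0 and 0 as se -> Inf", {
  beta <- matrix(c(2, -1), 1)
  d <- manual_dict(list(id = diag(2)), grid = c(1, 4))
  fit <- manual_fit(c(0.2, 0.4, 0.4), diag(2), d)
  post_small <- posterior_summaries(
    as_effects(beta, matrix(1e-4, 1, 2)), fit)
  expect_equal(unname(post_small$post_mean[1, ]), c(2, -1),
               tolerance = 1e-3)
  post_big <- posterior_summaries(
    as_effects(beta, matrix(1e4, 1, 2)), fit)
  expect_lt(max(abs(post_big$post_mean)), 1e-3)
})

test_that("LFSR is conservative on fully null effects", {
  set.seed(49)
  J <- 2000
  se <- matrix(runif(J * 4, 0.5, 1.5), J)
  beta <- se * matrix(rnorm(J * 4), J)
  eff <- as_effects(beta, se)
  m <- mash_lite(eff)
  expect_lte(mean(m$posterior$lfsr < 0.05), 0.05)
})

test_that("significance thresholding matches brute force", {
  lf <- matrix(c(0.01, 0.2, 0.8, 0.04, 0.06, 0.03), 3, 2,
               dimnames = list(paste0("f", 1:3), c("r1", "r2")))
  post <- structure(list(lfsr = lf), class = "MashPosterior")
  sig <- significant_features(post)
  expect_setequal(sig$per_region$r1, c("f1"))
  expect_setequal(sig$per_region$r2, c("f1", "f3"))
  expect_setequal(sig$union, c("f1", "f3"))
  expect_setequal(sig$intersection, "f1")
  expect_length(significant_features(
    structure(list(lfsr = lf * 0 + 1), class = "MashPosterior"))$union, 0)
})

test_that("subset fitting then full posterior stays consistent", {
  set.seed(50)
  J <- 3000
  se <- matrix(1, J, 2)
  beta <- matrix(rnorm(J * 2, 0, sqrt(2)), J)
  eff <- as_effects(beta, se)
  d <- manual_dict(list(id = diag(2)), grid = c(0.5, 1, 2))
  f_all <- fit_mixture_em(eff, d, subset_frac = 1)
  f_sub <- fit_mixture_em(eff, d, subset_frac = 0.5, seed = 3)
  expect_lt(max(abs(f_all$pi - f_sub$pi)), 0.1)
})
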