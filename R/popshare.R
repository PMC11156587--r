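#' Pairwise cross-region sharing of significant effects
#'
#' For each region pair, among features significant (LFSR below `lfsr_cut`)
#' in either region: `sign_match` is the fraction with concordant effect
#' sign, and `magnitude_share` the fraction with concordant sign and effect
#' ratio within `[factor, 1/factor]` (the "within a factor 0.5" rule).
#'
#' @param posterior a `MashPosterior`.
#' @param lfsr_cut significance threshold (default 0.05).
#' @param factor magnitude-sharing factor (default 0.5).
#' @return list of class `SharingSummary`: symmetric `sign_match` and
#'   `magnitude_share` matrices with unit diagonal, and overlap `counts`
#'   (unique / pairwise / per k-way sharing level).
#' @export
pairwise_sharing <- function(posterior, lfsr_cut = 0.05, factor = 0.5) {
  pm <- posterior$post_mean
  lf <- posterior$lfsr
  R <- ncol(pm)
  stopifnot(R >= 2)
  sig <- lf < lfsr_cut
  sign_match <- magnitude_share <- diag(1, R)
  dimnames(sign_match) <- dimnames(magnitude_share) <-
    list(colnames(pm), colnames(pm))
  flagged <- FALSE
  for (a in seq_len(R - 1)) {
    for (b in (a + 1):R) {
      i <- which(sig[, a] | sig[, b])
      if (!length(i)) {
        sign_match[a, b] <- sign_match[b, a] <- NA
        magnitude_share[a, b] <- magnitude_share[b, a] <- NA
        flagged <- TRUE
        next
      }
      same <- sign(pm[i, a]) == sign(pm[i, b]) & pm[i, a] != 0
      ratio <- pm[i, a] / pm[i, b]
      mag <- same & ratio >= factor & ratio <= 1 / factor
      sign_match[a, b] <- sign_match[b, a] <- mean(same)
      magnitude_share[a, b] <- magnitude_share[b, a] <- mean(mag)
    }
  }
  n_sig_regions <- rowSums(sig)
  counts <- table(factor(n_sig_regions[n_sig_regions > 0],
                         levels = seq_len(R)))
  structure(list(sign_match = sign_match,
                 magnitude_share = magnitude_share,
                 counts = counts, flagged = flagged),
            class = "SharingSummary")
}

#' Fisher exact enrichment with BH correction
#'
#' Two-sided exact hypergeometric test per gene list against a hit set
#' within a universe (summing all tables with probability at most the
#' observed one), BH correction across lists, and the sample odds ratio with
#' a Haldane 0.5 correction only when a zero cell exists.
#'
#' @param gene_lists named list of candidate gene-id vectors (each a subset
#'   of the universe).
#' @param hits character vector of "positive" genes (e.g. DEGs), a subset of
#'   the universe.
#' @param universe all tested gene ids.
#' @return data.frame of class `EnrichmentResult`: list_name, table cells
#'   (`n11` overlap, `n10`, `n01`, `n00`), odds_ratio, haldane flag, p, fdr.
#' @export
fisher_bh <- function(gene_lists, hits, universe) {
  stopifnot(is.list(gene_lists), length(gene_lists) > 0)
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  N <- length(universe)
  rows <- lapply(names(gene_lists), function(nm) {
    g <- gene_lists[[nm]]
    if (!all(g %in% universe))
      stop("list '", nm, "' is not a subset of the universe")
    n11 <- length(intersect(g, hits))
    n10 <- length(g) - n11
    n01 <- length(hits) - n11
    n00 <- N - n11 - n10 - n01
    p <- fisher_exact_p(n11, n10, n01, n00)
    hald <- any(c(n11, n10, n01, n00) == 0)
    or <- if (hald) ((n11 + 0.5) * (n00 + 0.5)) / ((n10 + 0.5) * (n01 + 0.5))
          else (n11 * n00) / (n10 * n01)
    data.frame(list_name = nm, n11 = n11, n10 = n10, n01 = n01, n00 = n00,
               odds_ratio = or, haldane = hald, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, "BH")
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Two-sided Fisher exact p for a 2x2 table
#'
#' Sums the hypergeometric probabilities of all tables (with the same
#' margins) whose probability does not exceed the observed table's.
#'
#' @param n11,n10,n01,n00 table cells.
#' @return exact two-sided p-value.
#' @export
fisher_exact_p <- function(n11, n10, n01, n00) {
  m <- n11 + n01          # hits
  nn <- n10 + n00         # non-hits
  k <- n11 + n10          # list size
  x <- 0:min(k, m)
  pr <- dhyper(x, m, nn, k)
  obs <- dhyper(n11, m, nn, k)
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

#' Monte-Carlo k-way overlap test
#'
#' Draws random sets of the observed sizes from the universe and reports
#' `empirical p = (1 + #{draws with overlap >= observed}) / (n_draws + 1)`
#' for the size of the k-way intersection.
#'
#' @param sig_sets list of significant-feature id sets (one per region).
#' @param universe all tested ids.
#' @param n_draws Monte-Carlo draws (default 1e5).
#' @param seed integer seed (required).
#' @return list with `observed` overlap, `empirical_p`, `n_draws`.
#' @export
monte_carlo_overlap <- function(sig_sets, universe, n_draws = 1e5, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(all(vapply(sig_sets, function(s) all(s %in% universe), TRUE)))
  observed <- length(Reduce(intersect, sig_sets))
  sizes <- lengths(sig_sets)
  N <- length(universe)
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_draws)) {
    inter <- sample.int(N, sizes[1])
    for (k in seq_along(sizes)[-1])
      inter <- intersect(inter, sample.int(N, sizes[k]))
    if (length(inter) >= observed) hits <- hits + 1L
  }
  list(observed = observed,
       empirical_p = (1 + hits) / (n_draws + 1),
       n_draws = n_draws)
}

#' Cell-type specificity markers
#'
#' The specificity score of gene g in cell type c is its mean TPM there
#' divided by its total mean TPM across cell types. Markers per cell type
#' are the top `top_frac` of genes by score among genes with at least
#' `min_tpm` in that cell type; genes with zero expression everywhere are
#' removed.
#'
#' @param mean_expr_by_celltype gene x cell-type matrix of mean TPM.
#' @param min_tpm expression floor within the cell type (default 1).
#' @param top_frac marker fraction (default 0.1).
#' @return list with `scores` (gene x cell type) and `markers` (list of
#'   gene-id vectors per cell type).
#' @export
specificity_markers <- function(mean_expr_by_celltype, min_tpm = 1,
                                top_frac = 0.1) {
  M <- as.matrix(mean_expr_by_celltype)
  tot <- rowSums(M)
  M <- M[tot > 0, , drop = FALSE]
  scores <- M / rowSums(M)
  markers <- lapply(seq_len(ncol(M)), function(c) {
    elig <- which(M[, c] >= min_tpm)
    if (!length(elig)) return(character(0))
    n_top <- max(1L, ceiling(top_frac * length(elig)))
    ord <- elig[order(scores[elig, c], decreasing = TRUE)]
    rownames(M)[ord[seq_len(n_top)]]
  })
  names(markers) <- colnames(M)
  list(scores = scores, markers = markers)
}

#' One-sided rank-sum comparison of allele-frequency differences
#'
#' Tests whether the first group (e.g. gene-level AFD of ancestry DEGs)
#' is stochastically greater than the second (non-DEGs): exact rank-sum for
#' up to 20 total observations without ties, normal approximation with tie
#' correction otherwise.
#'
#' @param deg_afd,nondeg_afd numeric AFD values per group.
#' @return list with `p`, `statistic` (Mann-Whitney U of group 1),
#'   `method`, `degenerate` flag (all values tied).
#' @export
compare_afd <- function(deg_afd, nondeg_afd) {
  stopifnot(length(deg_afd) > 0, length(nondeg_afd) > 0)
  x <- deg_afd[!is.na(deg_afd)]
  y <- nondeg_afd[!is.na(nondeg_afd)]
  if (length(unique(c(x, y))) == 1)
    return(list(p = 0.5, statistic = NA_real_, method = "degenerate",
                degenerate = TRUE))
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "greater", exact = exact,
                correct = FALSE))
  list(p = wt$p.value, statistic = unname(wt$statistic),
       method = if (exact) "exact" else "normal approximation",
       degenerate = FALSE)
}
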