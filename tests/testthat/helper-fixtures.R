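## small shared fixtures built in code

tiny_panel <- function(n = 60, seed = 42, length_bp = 2e6) {
  simulate_panel(n, chrom_length_bp = length_bp, seed = seed)
}

tiny_config <- function(...) {
  sim_config(n_samples = 60, n_regions = 2, n_features = 20,
             n_variants = 60, chrom_length_bp = 2e6,
             n_background_cpgs = 200, cpgs_per_cluster = 8, ...)
}

## reference-population dosage draws from panel frequencies
ref_pops <- function(panel, n_per_pop = 50, seed = 7) {
  set.seed(seed)
  m <- nrow(panel)
  list(
    AFR = matrix(rbinom(m * n_per_pop, 2, rep(panel$freq_afr, n_per_pop)),
                 m, dimnames = list(panel$variant_id, NULL)),
    EUR = matrix(rbinom(m * n_per_pop, 2, rep(panel$freq_eur, n_per_pop)),
                 m, dimnames = list(panel$variant_id, NULL)))
}

## an EffectMatrix from raw beta/se matrices
as_effects <- function(beta, se, df = 50) {
  if (is.null(rownames(beta)))
    rownames(beta) <- rownames(se) <- paste0("f", seq_len(nrow(beta)))
  if (is.null(colnames(beta)))
    colnames(beta) <- colnames(se) <- paste0("r", seq_len(ncol(beta)))
  structure(list(beta = beta, se = se, df = rep(df, ncol(beta))),
            class = "EffectMatrix")
}
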