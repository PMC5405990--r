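#' Single-locus null-cohort configuration
#'
#' A compact configuration for calibration experiments: one 12-kb locus
#' carrying `n_variants` low-frequency variants (target MAFs uniform on
#' `[0.01, 0.09]`) in AR(1) LD blocks, a cohort of `n` individuals, and a
#' phenotype generated from covariates plus Gaussian noise only (no causal
#' variants), so every set-association signal is a false positive.
#'
#' @param n Cohort size (default 110).
#' @param n_variants Variants in the locus (default 60).
#' @param rho Within-block AR(1) correlation (default 0.8).
#' @param block_size Variants per LD block (default 15).
#' @param seed Integer seed.
#' @return A [sim_config()].
#' @export
null_locus_config <- function(n = 110L, n_variants = 60L, rho = 0.8,
                              block_size = 15L, seed = 1L) {
  loci <- data.frame(name = "nullLocus", chrom = "chr3",
                     start_bp = 186440001L, end_bp = 186452000L,
                     n_variants = as.integer(n_variants))
  mafs <- local_rng(seed, "maf", stats::runif(n_variants, 0.01, 0.09))
  sim_config(n_individuals = n, loci = loci, maf = mafs,
             ld_blocks = rho, block_size = block_size,
             causal = NULL, seed = seed)
}

#' Family-wise error rate of the permutation set-test procedure
#'
#' Simulates `n_replicates` independent null cohorts with
#' [null_locus_config()], and for each builds the sliding 2-kb variant
#' sets over the sample-low-frequency variants, runs the kernel set test,
#' and applies min-p permutation adjustment with `B` permutations at level
#' `alpha`. The empirical FWER is the fraction of cohorts in which at
#' least one set is declared significant.
#'
#' @param n_replicates Number of simulated cohorts (default 100).
#' @param B Permutations per cohort (default 500).
#' @param alpha FWER level (default 0.05).
#' @param n,n_variants Cohort size and variant count per cohort.
#' @param seed Integer base seed; replicate `i` uses `seed * 1000 + i`.
#' @return List: `fwer` (fraction with any significant set),
#'   `n_replicates`, `mc_se` (binomial Monte-Carlo standard error at
#'   `alpha`), `any_significant` (logical per replicate).
#' @export
fwer_null_experiment <- function(n_replicates = 100L, B = 500L,
                                 alpha = 0.05, n = 110L, n_variants = 60L,
                                 seed = 1L) {
  any_sig <- vapply(seq_len(n_replicates), function(i) {
    si <- (seed %% 1000L) * 1000L + i
    cfg <- null_locus_config(n = n, n_variants = n_variants, seed = si)
    g <- simulate_genotypes(cfg)
    ph <- simulate_phenotype(g$genotypes, cfg)
    mafs <- apply(g$genotypes, 2L, compute_maf)
    lowf <- g$variants[mafs > 0 & mafs < 0.10, ]
    if (nrow(lowf) == 0) return(FALSE)
    w <- build_windows(lowf[, c("variant_id", "chrom", "pos")])
    pf <- permutation_fwer(ph$fxi_pct, ph[, c("age", "sex")],
                           g$genotypes, w, B = B, alpha = alpha, seed = si)
    any(pf$significant_fwer)
  }, logical(1))
  list(fwer = mean(any_sig), n_replicates = n_replicates,
       mc_se = sqrt(alpha * (1 - alpha) / n_replicates),
       any_significant = any_sig)
}

#' Power of the permutation set-test for a planted low-frequency signal
#'
#' Plants one large-effect low-frequency causal variant (per-allele effect
#' `effect_sd` residual standard deviations) in the single-locus
#' configuration and measures how often the window anchored at it is
#' FWER-significant.
#'
#' @param n_replicates Number of simulated cohorts.
#' @param effect_sd Causal effect in units of the residual SD (default 2).
#' @param B Permutations per cohort.
#' @param alpha FWER level.
#' @param n,n_variants Cohort size and variant count.
#' @param seed Integer base seed.
#' @return List: `power` (fraction of replicates in which a window
#'   containing the causal variant is significant), `hits` per replicate.
#' @export
power_experiment <- function(n_replicates = 50L, effect_sd = 2,
                             B = 500L, alpha = 0.05, n = 110L,
                             n_variants = 60L, seed = 1L) {
  hits <- vapply(seq_len(n_replicates), function(i) {
    si <- (seed %% 1000L) * 1000L + 500L + i
    cfg <- null_locus_config(n = n, n_variants = n_variants, seed = si)
    causal_idx <- n_variants %/% 2L
    cfg$causal <- stats::setNames(effect_sd * cfg$sigma, causal_idx)
    g <- simulate_genotypes(cfg)
    ph <- simulate_phenotype(g$genotypes, cfg)
    mafs <- apply(g$genotypes, 2L, compute_maf)
    lowf <- g$variants[mafs > 0 & mafs < 0.10, ]
    causal_id <- g$variants$variant_id[causal_idx]
    if (!causal_id %in% lowf$variant_id) return(FALSE)
    w <- build_windows(lowf[, c("variant_id", "chrom", "pos")])
    pf <- permutation_fwer(ph$fxi_pct, ph[, c("age", "sex")],
                           g$genotypes, w, B = B, alpha = alpha, seed = si)
    carries <- vapply(strsplit(pf$members, ",", fixed = TRUE),
                      function(mm) causal_id %in% mm, logical(1))
    any(pf$significant_fwer & carries)
  }, logical(1))
  list(power = mean(hits), hits = hits)
}
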