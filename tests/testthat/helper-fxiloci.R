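# Shared fixtures, all built in code.

# one small locus, explicit MAFs, optional LD
tiny_config <- function(n = 100, mafs = c(0.05, 0.2, 0.45), rho = 0,
                        seed = 1, block_size = length(mafs), ...) {
  loci <- data.frame(name = "L1", chrom = "chr3",
                     start_bp = 1000L, end_bp = 1000L + 50L * length(mafs),
                     n_variants = length(mafs))
  sim_config(n_individuals = n, loci = loci, maf = mafs,
             ld_blocks = rho, block_size = block_size, seed = seed, ...)
}

# dosage matrix of independent binomial variants, named columns
random_genotypes <- function(n, mafs, seed = 1) {
  set.seed(seed)
  g <- vapply(mafs, function(f) stats::rbinom(n, 2, f), numeric(n))
  colnames(g) <- sprintf("v%02d", seq_along(mafs))
  g
}

# brute-force OLS via the normal equations
ols_oracle <- function(y, X) {
  b <- solve(crossprod(X), crossprod(X, y))
  r <- y - X %*% b
  s2 <- sum(r^2) / (length(y) - ncol(X))
  se <- sqrt(diag(s2 * solve(crossprod(X))))
  list(beta = unname(drop(b)), se = unname(se))
}

# the five printed native/mutated splice-score pairs for the KNG1
# intronic candidate
splice_pairs_kng1 <- function() {
  data.frame(
    algorithm = c("SpliceSiteFinder", "MaxEntScan", "NNSplice",
                  "GeneSplicer", "HumanSplicingFinder"),
    native = c(88.56, 6.28, 0.66, 7.43, 91.23),
    mutated = c(85.25, 5.86, 0.57, 6.52, 89.98))
}
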