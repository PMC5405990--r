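#' Simulation configuration for a two-locus targeted-sequencing cohort
#'
#' Builds and validates the configuration driving [simulate_genotypes()] and
#' [simulate_phenotype()]. The defaults emulate a cohort of 110 unrelated
#' individuals sequenced over the KNG1 (chr3, 25,581 bp) and F11 (chr4,
#' 23,718 bp) loci: 504 + 258 biallelic variants, a mixed allele-frequency
#' spectrum in which about 41\% of variants are common (MAF >= 10\%),
#' block-wise linkage disequilibrium, and a Factor XI coagulant activity
#' phenotype on the \%-of-normal scale (clinical normal range 55--185\%)
#' with age and sex covariate effects plus a handful of causal variants.
#'
#' Genotypes are generated from a latent multivariate-normal copula:
#' haplotypes within an LD block follow an AR(1) correlation, thresholded
#' at the normal quantile of each variant's target MAF; two haplotypes are
#' paired per individual, so dosages are 0/1/2. The block parameter `rho`
#' is expressed on the allele-correlation scale: the latent correlation is
#' `sin(pi * rho / 2)` (the tetrachoric inverse, exact at MAF 0.5), so
#' adjacent same-MAF variants realize a dosage correlation close to `rho`,
#' attenuating somewhat for rarer alleles.
#'
#' @param n_individuals Number of diploid individuals.
#' @param loci Data frame with columns `name`, `chrom`, `start_bp`, `end_bp`
#'   (1-based inclusive) and `n_variants`.
#' @param maf Numeric vector of per-variant target minor-allele frequencies
#'   in `[0, 0.5]`, of length `sum(loci$n_variants)`, ordered by locus then
#'   position. `NULL` draws a default spectrum (see Details).
#' @param ld_blocks Either a single AR(1) correlation `rho` in `[0, 1)`
#'   applied within blocks of `block_size` consecutive variants, or a data
#'   frame with columns `first`, `last` (variant indices, 1-based, within
#'   the full variant list) and `rho`.
#' @param block_size Number of consecutive variants per LD block when
#'   `ld_blocks` is a scalar.
#' @param causal Named numeric vector: names are variant indices (into the
#'   full variant list), values are per-allele effects in phenotype units.
#' @param mu Phenotype intercept (\% activity).
#' @param beta_age Phenotype change per year of age.
#' @param beta_sex Phenotype difference for sex coded 1 versus 0.
#' @param sigma Residual standard deviation (\% activity), must be > 0.
#' @param age_range Uniform sampling range for age in years.
#' @param p_male Probability that sex is coded 1.
#' @param common_fraction When `maf` is `NULL`, fraction of variants drawn
#'   from the common (>= 10\%) part of the spectrum.
#' @param seed Integer seed; all draws derive from it through per-stage
#'   substreams so each stage is independently reproducible.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_individuals = 50, seed = 1)
#' cfg$loci
#' @export
sim_config <- function(n_individuals = 110,
                       loci = default_loci(),
                       maf = NULL,
                       ld_blocks = 0.8,
                       block_size = 25,
                       causal = NULL,
                       mu = 103,
                       beta_age = 0.3,
                       beta_sex = 5,
                       sigma = 45,
                       age_range = c(18, 80),
                       p_male = 0.5,
                       common_fraction = 0.41,
                       seed = 1L) {
  stopifnot(is.data.frame(loci),
            all(c("name", "chrom", "start_bp", "end_bp", "n_variants") %in%
                  names(loci)))
  if (n_individuals < 1) stop("n_individuals must be >= 1")
  if (any(loci$start_bp > loci$end_bp))
    stop("locus start_bp must be <= end_bp")
  if (any(loci$n_variants > loci$end_bp - loci$start_bp + 1))
    stop("more variants requested than positions available in a locus")
  if (sigma <= 0) stop("residual sigma must be > 0")
  m <- sum(loci$n_variants)

  if (is.null(maf)) {
    maf <- default_maf_spectrum(m, common_fraction, seed)
  }
  if (length(maf) != m)
    stop("maf must have one entry per variant (", m, ")")
  if (any(maf < 0 | maf > 0.5))
    stop("target MAFs must lie in [0, 0.5]")

  if (is.numeric(ld_blocks) && length(ld_blocks) == 1L) {
    rho <- ld_blocks
    if (rho < 0 || rho >= 1) stop("ld_blocks rho must be in [0, 1)")
    # block grid restarts at each locus boundary
    offset <- c(0L, cumsum(loci$n_variants))
    first <- unlist(lapply(seq_len(nrow(loci)), function(i)
      offset[i] + seq(1L, loci$n_variants[i], by = block_size)))
    last <- unlist(lapply(seq_len(nrow(loci)), function(i) {
      f <- seq(1L, loci$n_variants[i], by = block_size)
      offset[i] + pmin(f + block_size - 1L, loci$n_variants[i])
    }))
    ld_blocks <- data.frame(first = first, last = last, rho = rho)
  }
  stopifnot(all(c("first", "last", "rho") %in% names(ld_blocks)))
  if (any(ld_blocks$rho < 0 | ld_blocks$rho >= 1))
    stop("block rho must be in [0, 1)")
  # blocks never straddle locus boundaries
  bounds <- cumsum(loci$n_variants)
  for (b in seq_len(nrow(ld_blocks))) {
    lo <- findInterval(ld_blocks$first[b] - 1L, bounds)
    hi <- findInterval(ld_blocks$last[b] - 1L, bounds)
    if (lo != hi) stop("LD block ", b, " crosses a locus boundary")
  }

  if (is.null(causal)) causal <- numeric(0)
  if (length(causal)) {
    idx <- as.integer(names(causal))
    if (anyNA(idx) || any(idx < 1L | idx > m))
      stop("causal variant indices must name valid variants")
  }

  structure(list(n_individuals = as.integer(n_individuals),
                 loci = loci, maf = maf, ld_blocks = ld_blocks,
                 causal = causal, mu = mu, beta_age = beta_age,
                 beta_sex = beta_sex, sigma = sigma,
                 age_range = age_range, p_male = p_male,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default KNG1/F11 locus table (GRCh37 spans)
#'
#' @return Data frame of the two loci with their printed genomic spans and
#'   discovery-sample variant counts (504 and 258).
#' @export
default_loci <- function() {
  data.frame(name = c("KNG1", "F11"),
             chrom = c("chr3", "chr4"),
             start_bp = c(186435098L, 187187118L),
             end_bp = c(186460678L, 187210835L),
             n_variants = c(504L, 258L))
}

# MAF spectrum: `common_fraction` of variants uniform on [0.10, 0.50],
# the rest skewed toward rarity on (0, 0.10) -- matching a resequencing
# discovery sample where most variants are low-frequency.
default_maf_spectrum <- function(m, common_fraction, seed) {
  local_rng(seed, "maf", {
    n_common <- round(m * common_fraction)
    common <- stats::runif(n_common, 0.10, 0.50)
    low <- 0.10 * stats::rbeta(m - n_common, 0.6, 1.6)
    low <- pmax(low, 1 / 220)      # at least one expected carrier chromosome
    sample(c(common, low))
  })
}

#' Default causal-effect specification for a simulated cohort
#'
#' Picks one common variant (per-allele effect `beta_common`) and
#' `n_low` clustered low-frequency variants (effect `beta_low`) from a
#' generated variant list, mimicking a locus where both a common regulatory
#' signal and a cluster of low-frequency functional alleles shift FXI
#' levels.
#'
#' @param maf Vector of target MAFs from the configuration.
#' @param beta_common,beta_low Per-allele effects in phenotype units.
#' @param n_low Number of adjacent low-frequency causal variants.
#' @param seed Integer seed.
#' @return Named numeric vector suitable for `sim_config(causal = )`.
#' @export
default_causal <- function(maf, beta_common = 12, beta_low = 25,
                           n_low = 2, seed = 1L) {
  local_rng(seed, "causal", {
    common_idx <- which(maf >= 0.25)
    low_idx <- which(maf >= 0.01 & maf < 0.10)
    ci <- sample(common_idx, 1L)
    # a run of adjacent low-frequency variants so they share a 2-kb window
    li <- sort(low_idx)[seq_len(min(n_low, length(low_idx)))]
    stats::setNames(c(beta_common, rep(beta_low, length(li))),
                    c(ci, li))
  })
}

# Substream scheme: each named stage perturbs the global seed with a fixed
# offset, so stages are reproducible independently of call order.
stage_offsets <- c(maf = 11L, causal = 13L, positions = 17L,
                   haplotypes = 19L, covariates = 23L, noise = 29L,
                   tails = 31L, perm = 37L, cohort = 41L)

local_rng <- function(seed, stage, expr) {
  offset <- stage_offsets[[stage]]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((seed * 101L + offset) %% .Machine$integer.max)
  expr
}

#' Simulate genotype dosages with block-LD structure
#'
#' Draws haplotypes from the latent-Gaussian copula described in
#' [sim_config()] and pairs them into diploid dosages. Variant positions are
#' sampled uniformly without replacement within each locus span and sorted.
#'
#' @param config A [sim_config()] object.
#' @return A list with `genotypes` (an `n x m` integer matrix of dosages,
#'   rownames individual ids, colnames variant ids) and `variants` (a data
#'   frame of variant records: `variant_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `locus`, `target_maf`).
#' @examples
#' sim <- simulate_genotypes(sim_config(n_individuals = 20, seed = 7))
#' dim(sim$genotypes)
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  m <- length(config$maf)

  pos <- local_rng(config$seed, "positions", {
    unlist(lapply(seq_len(nrow(config$loci)), function(i) {
      with(config$loci[i, ],
           sort(sample(seq.int(start_bp, end_bp), n_variants)))
    }), use.names = FALSE)
  })
  locus <- rep(config$loci$name, config$loci$n_variants)
  chrom <- rep(config$loci$chrom, config$loci$n_variants)

  hap <- local_rng(config$seed, "haplotypes", {
    z <- matrix(stats::rnorm(2L * n * m), nrow = 2L * n)
    # AR(1) within each block: z_j = rho*z_{j-1} + sqrt(1-rho^2)*e_j.
    # The block parameter is calibrated to the realized allele correlation
    # through the arcsine (tetrachoric) identity rho_z = sin(pi*rho/2),
    # which is exact for median-threshold dichotomization (MAF 0.5) and
    # counteracts most of the attenuation at lower MAFs.
    for (b in seq_len(nrow(config$ld_blocks))) {
      rho <- sin(pi * config$ld_blocks$rho[b] / 2)
      if (rho == 0) next
      cols <- seq.int(config$ld_blocks$first[b], config$ld_blocks$last[b])
      for (k in seq_along(cols)[-1]) {
        z[, cols[k]] <- rho * z[, cols[k - 1L]] +
          sqrt(1 - rho^2) * z[, cols[k]]
      }
    }
    z
  })
  thresh <- stats::qnorm(config$maf)
  alleles <- sweep(hap, 2L, thresh, `<`)
  g <- alleles[seq_len(n), , drop = FALSE] +
    alleles[n + seq_len(n), , drop = FALSE]
  storage.mode(g) <- "integer"

  ids <- sprintf("ind%03d", seq_len(n))
  vids <- sprintf("%s_%d", chrom, pos)
  dimnames(g) <- list(ids, vids)
  variants <- data.frame(variant_id = vids, chrom = chrom, pos = pos,
                         ref = "A", alt = "G", locus = locus,
                         target_maf = config$maf)
  list(genotypes = g, variants = variants)
}

#' Simulate a quantitative phenotype with covariate and genetic effects
#'
#' Generates `y = mu + beta_age*age + beta_sex*sex + sum_j beta_j g_j + e`
#' with Gaussian residuals, on the \%-of-normal FXI activity scale.
#'
#' @param genotypes Dosage matrix from [simulate_genotypes()].
#' @param config The same [sim_config()] object.
#' @return Data frame with columns `id`, `fxi_pct`, `age`, `sex` (0/1).
#' @export
simulate_phenotype <- function(genotypes, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(genotypes)
  if (n != config$n_individuals)
    stop("genotype row count (", n, ") does not match n_individuals (",
         config$n_individuals, ")")
  cov <- local_rng(config$seed, "covariates", {
    data.frame(age = stats::runif(n, config$age_range[1], config$age_range[2]),
               sex = stats::rbinom(n, 1L, config$p_male))
  })
  gpart <- 0
  if (length(config$causal)) {
    idx <- as.integer(names(config$causal))
    gpart <- as.vector(genotypes[, idx, drop = FALSE] %*% config$causal)
  }
  eps <- local_rng(config$seed, "noise", stats::rnorm(n, 0, config$sigma))
  y <- config$mu + config$beta_age * cov$age + config$beta_sex * cov$sex +
    gpart + eps
  data.frame(id = rownames(genotypes), fxi_pct = y,
             age = cov$age, sex = cov$sex)
}

#' Simulate a cohort assembled around a tail-sampling design
#'
#' Emulates a study in which the sequenced cohort is drawn from a much
#' larger family-project pool and deliberately includes both phenotype
#' tails: a pool of `pool_size` individuals is simulated under `config`,
#' the `n_low + n_high` tail individuals are selected with
#' [select_tails()], and the cohort is filled to `config$n_individuals`
#' with a random draw from the remaining pool. The returned cohort
#' therefore always satisfies the tail design, at the cost of mild
#' enrichment of causal-allele frequencies relative to their targets --
#' exactly as in a real tail-enriched resequencing cohort.
#'
#' @param config A [sim_config()]; `n_individuals` is the cohort size.
#' @param design A [tail_design()] satisfiable within the pool.
#' @param pool_size Size of the simulated source pool (default 935).
#' @return List: `genotypes`, `phenotypes`, `variants`, `tail_ids`.
#' @export
simulate_cohort <- function(config, design = tail_design(),
                            pool_size = 935L) {
  stopifnot(inherits(config, "sim_config"), inherits(design, "tail_design"))
  if (design$n_low + design$n_high > config$n_individuals)
    stop("tail design larger than the cohort")
  pool_cfg <- config
  pool_cfg$n_individuals <- as.integer(pool_size)
  sim <- simulate_genotypes(pool_cfg)
  pheno <- simulate_phenotype(sim$genotypes, pool_cfg)
  tail_ids <- select_tails(pheno, design, seed = config$seed)
  rest <- setdiff(pheno$id, tail_ids)
  fill <- local_rng(config$seed, "cohort", {
    sample(rest, config$n_individuals - length(tail_ids))
  })
  ids <- c(tail_ids, fill)
  keep <- match(ids, pheno$id)
  list(genotypes = sim$genotypes[keep, , drop = FALSE],
       phenotypes = pheno[keep, , drop = FALSE],
       variants = sim$variants, tail_ids = tail_ids)
}

#' Tail-sampling design for a discovery subsample
#'
#' @param n_low,n_high Number of individuals to draw from each tail.
#' @param low_range,high_range Phenotype ranges (\% activity), inclusive,
#'   non-overlapping.
#' @return A `tail_design` list.
#' @examples
#' tail_design()  # the 20-low (36-80%) / 20-high (158-250%) design
#' @export
tail_design <- function(n_low = 20L, low_range = c(36, 80),
                        n_high = 20L, high_range = c(158, 250)) {
  stopifnot(length(low_range) == 2, length(high_range) == 2)
  if (low_range[1] > low_range[2] || high_range[1] > high_range[2])
    stop("ranges must be ordered (min, max)")
  if (low_range[2] >= high_range[1] && high_range[2] >= low_range[1])
    stop("low and high ranges must not overlap")
  structure(list(n_low = as.integer(n_low), low_range = low_range,
                 n_high = as.integer(n_high), high_range = high_range),
            class = "tail_design")
}

#' Select a tail-sampled discovery subsample
#'
#' Draws `n_low` individuals whose phenotype falls inside the low range and
#' `n_high` inside the high range, uniformly at random among those eligible.
#'
#' @param phenotypes Data frame with columns `id` and `fxi_pct`.
#' @param design A [tail_design()].
#' @param seed Integer seed; the same seed always returns the same ids.
#' @return Character vector of `n_low + n_high` individual ids.
#' @export
select_tails <- function(phenotypes, design = tail_design(), seed = 1L) {
  stopifnot(inherits(design, "tail_design"),
            all(c("id", "fxi_pct") %in% names(phenotypes)))
  in_rng <- function(r) phenotypes$fxi_pct >= r[1] & phenotypes$fxi_pct <= r[2]
  low_ids <- phenotypes$id[in_rng(design$low_range)]
  high_ids <- phenotypes$id[in_rng(design$high_range)]
  if (length(low_ids) < design$n_low)
    stop("tail shortfall: ", design$n_low, " low-tail individuals requested, ",
         length(low_ids), " available in [", design$low_range[1], ", ",
         design$low_range[2], "]")
  if (length(high_ids) < design$n_high)
    stop("tail shortfall: ", design$n_high, " high-tail individuals requested, ",
         length(high_ids), " available in [", design$high_range[1], ", ",
         design$high_range[2], "]")
  local_rng(seed, "tails", {
    c(sample(low_ids, design$n_low), sample(high_ids, design$n_high))
  })
}

#' Probability that a variant is seen in a discovery sample
#'
#' For a variant with minor-allele frequency `maf`, the probability that at
#' least one copy of the minor allele appears among the `2n` chromosomes of
#' `n` diploid individuals: `1 - (1 - maf)^(2n)`. With `n = 40` and
#' `maf = 0.05` this exceeds 0.98, the detection power quoted for the
#' 40-individual tail discovery sample.
#'
#' @param maf Minor-allele frequency in `[0, 0.5]`.
#' @param n Number of diploid individuals, >= 1.
#' @return Detection probability in `[0, 1]`.
#' @examples
#' detection_power(0.05, 40)  # 0.9835...
#' @export
detection_power <- function(maf, n) {
  if (any(maf < 0 | maf > 0.5)) stop("maf must lie in [0, 0.5]")
  if (any(n < 1)) stop("n must be >= 1")
  1 - (1 - maf)^(2 * n)
}

#' Write genotypes to a VCF 4.2 file
#'
#' Serializes a dosage matrix and variant table as biallelic VCF records
#' with unphased GT fields; missing dosages become `./.`. Reading the file
#' back with [read_vcf()] recovers the dosage matrix and positions exactly.
#'
#' @param genotypes `n x m` dosage matrix (individuals x variants).
#' @param variants Variant data frame with `chrom`, `pos`, `ref`, `alt` and
#'   optionally `dbsnp_id`.
#' @param path Output file path (plain text; use a `.gz` suffix for gzip).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, variants, path) {
  if (nrow(variants) > 0 && ncol(genotypes) != nrow(variants))
    stop("genotype columns (", ncol(genotypes),
         ") must match variant rows (", nrow(variants), ")")
  header <- c("##fileformat=VCFv4.2",
              "##source=fxiloci",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(genotypes)), collapse = "\t"))
  body <- character(0)
  if (nrow(variants) > 0) {
    gt <- matrix(c("0/0", "0/1", "1/1")[genotypes + 1L], nrow = nrow(genotypes))
    gt[is.na(gt)] <- "./."
    ids <- if ("dbsnp_id" %in% names(variants)) {
      ifelse(is.na(variants$dbsnp_id) | variants$dbsnp_id == "",
             ".", variants$dbsnp_id)
    } else "."
    body <- paste(variants$chrom, variants$pos, ids, variants$ref,
                  variants$alt, ".", ".", ".", "GT",
                  apply(gt, 2L, paste, collapse = "\t"), sep = "\t")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}
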