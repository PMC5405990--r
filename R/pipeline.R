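#' Configuration for a full pipeline run
#'
#' Exactly one of `sim` (a [sim_config()] simulation block) or `inputs`
#' (paths to a VCF, a phenotype TSV with columns `id`, `fxi_pct`, `age`,
#' `sex`, and optionally an annotation TSV) must be given.
#'
#' @param sim A [sim_config()], or `NULL`.
#' @param inputs List with `vcf`, `phenotypes` and optionally
#'   `annotations`, or `NULL`.
#' @param outdir Output directory (created if absent).
#' @param freq_threshold Common/low-frequency MAF cut (default 0.10).
#' @param prune A [prune_params()].
#' @param clump A [clump_params()].
#' @param window_bp Set width for the collapsing arm (default 2000).
#' @param B Permutations for FWER control (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param screen A [screen_criteria()].
#' @param tails A [tail_design()], or `NULL` to skip the discovery step.
#' @param seed Integer seed for all stochastic stages.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = NULL, inputs = NULL, outdir = tempfile("fxirun"),
                       freq_threshold = 0.10, prune = prune_params(),
                       clump = clump_params(), window_bp = 2000,
                       B = 1000L, alpha = 0.05,
                       screen = screen_criteria(), tails = tail_design(),
                       seed = 1L) {
  if (is.null(sim) == is.null(inputs))
    stop("exactly one of 'sim' and 'inputs' must be supplied")
  if (!is.null(inputs) && !all(c("vcf", "phenotypes") %in% names(inputs)))
    stop("inputs must name 'vcf' and 'phenotypes'")
  structure(list(sim = sim, inputs = inputs, outdir = outdir,
                 freq_threshold = freq_threshold, prune = prune,
                 clump = clump, window_bp = window_bp, B = as.integer(B),
                 alpha = alpha, screen = screen, tails = tails,
                 seed = as.integer(seed)),
            class = "run_config")
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full association pipeline
#'
#' Stages, in order: data acquisition (simulation or file ingestion),
#' phenotype normality check, optional tail-sampled discovery subsetting
#' (variants monomorphic in the discovery subsample are dropped from
#' downstream analysis, mirroring a design where only variants seen in the
#' sequenced tails are genotyped in the full cohort), MAF computation and
#' frequency stratification, per-stratum VIF pruning, single-variant
#' association with six multiple-testing corrections and LD clumping for
#' common variants, sliding-window kernel set tests with permutation FWER
#' control and region merging for low-frequency variants, and the
#' pathogenic-candidate screen (when annotations are available). Every
#' stage writes a TSV/BED/JSON artifact into `config$outdir` and a manifest
#' records parameters, seed and per-stage row counts.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of all stage results plus `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("fxiloci")),
                   seed = config$seed, alpha = config$alpha,
                   B = config$B, window_bp = config$window_bp,
                   freq_threshold = config$freq_threshold,
                   weights = "beta(1,25)", stages = list())
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, n_in, n_out) {
    manifest$stages[[name]] <<- list(
      n_in = n_in, n_out = n_out,
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
  }

  # -- data -----------------------------------------------------------
  if (!is.null(config$sim)) {
    if (!is.null(config$tails)) {
      # cohort assembled from a larger pool so the tail design is met
      sim <- simulate_cohort(config$sim, config$tails)
      geno <- sim$genotypes
      pheno <- sim$phenotypes
    } else {
      sim <- simulate_genotypes(config$sim)
      geno <- sim$genotypes
      pheno <- simulate_phenotype(geno, config$sim)
    }
    variants <- sim$variants
    write_vcf(geno, variants, file.path(config$outdir, "genotypes.vcf"))
    write_tsv(pheno, file.path(config$outdir, "phenotypes.tsv"))
  } else {
    vc <- read_vcf(config$inputs$vcf)
    geno <- vc$genotypes
    variants <- vc$variants
    pheno <- utils::read.delim(config$inputs$phenotypes)
    if (!all(c("id", "fxi_pct", "age", "sex") %in% names(pheno)))
      stop("phenotype table must have columns id, fxi_pct, age, sex")
    pheno <- pheno[match(rownames(geno), pheno$id), ]
    if (anyNA(pheno$id)) stop("phenotype table missing VCF individuals")
    if (!is.null(config$inputs$annotations)) {
      ann <- utils::read.delim(config$inputs$annotations)
      variants <- merge(variants, ann,
                        by = intersect(c("chrom", "pos"), names(ann)),
                        all.x = TRUE, sort = FALSE)
      variants <- variants[order(variants$chrom, variants$pos), ]
    }
  }
  stage("data", nrow(geno), ncol(geno))

  # -- normality ------------------------------------------------------
  norm <- test_normality(pheno$fxi_pct)
  write_tsv(norm, file.path(config$outdir, "normality.tsv"))
  stage("normality", nrow(pheno), 1L)

  # -- tail discovery -------------------------------------------------
  discovery_ids <- NULL
  if (!is.null(config$tails)) {
    discovery_ids <- select_tails(pheno, config$tails, seed = config$seed)
    writeLines(discovery_ids, file.path(config$outdir, "discovery_ids.txt"))
    disc_poly <- apply(geno[discovery_ids, , drop = FALSE], 2L,
                       function(col) {
                         u <- unique(col[!is.na(col)])
                         length(u) > 1
                       })
    n_before <- ncol(geno)
    geno <- geno[, disc_poly, drop = FALSE]
    variants <- variants[variants$variant_id %in% colnames(geno), ]
    stage("discovery", n_before, ncol(geno))
  }

  # -- MAF + stratification ------------------------------------------
  variants$maf <- apply(geno[, variants$variant_id, drop = FALSE], 2L,
                        compute_maf)
  variants$freq_class <- classify_frequency(variants$maf,
                                            config$freq_threshold)
  write_tsv(variants, file.path(config$outdir, "variants.tsv"))
  stage("stratify", nrow(variants), sum(variants$freq_class == "common"))

  covar <- pheno[, c("age", "sex")]
  y <- pheno$fxi_pct
  results <- list(normality = norm, variants = variants,
                  discovery_ids = discovery_ids)

  # -- common arm: prune, associate, clump ---------------------------
  common <- variants[variants$freq_class == "common" & variants$maf > 0, ]
  assoc <- NULL; clumps <- NULL
  if (nrow(common) >= 2) {
    pruned <- list(); mtot <- 0L
    for (chr in unique(common$chrom)) {
      ids <- common$variant_id[common$chrom == chr]
      ids <- ids[order(common$pos[common$chrom == chr])]
      pruned[[chr]] <- vif_prune(geno, ids, config$prune)$kept
    }
    kept_common <- unlist(pruned, use.names = FALSE)
    write_tsv(data.frame(variant_id = common$variant_id,
                         kept = common$variant_id %in% kept_common),
              file.path(config$outdir, "prune_common.tsv"))
    assoc <- associate_common(y, geno, covar, kept_common,
                              variants = variants)
    write_tsv(assoc, file.path(config$outdir, "assoc_common.tsv"))
    sig <- assoc[assoc$p < config$alpha,
                 c("variant_id", "pos", "p"), drop = FALSE]
    clumps <- clump(sig, geno, config$clump)
    write_tsv(clumps, file.path(config$outdir, "clumps.tsv"))
    stage("common_arm", nrow(common), nrow(assoc))
  }
  results$assoc_common <- assoc
  results$clumps <- clumps

  # -- low-frequency arm: windows, kernel test, permutation, regions --
  lowf <- variants[variants$freq_class == "low_frequency" & variants$maf > 0, ]
  windows <- NULL; regions_nominal <- NULL; regions_fwer <- NULL
  if (nrow(lowf) >= 1) {
    lowids <- list()
    for (chr in unique(lowf$chrom)) {
      ids <- lowf$variant_id[lowf$chrom == chr]
      ids <- ids[order(lowf$pos[lowf$chrom == chr])]
      lowids[[chr]] <- vif_prune(geno, ids, config$prune)$kept
    }
    kept_low <- unlist(lowids, use.names = FALSE)
    lowkept <- lowf[lowf$variant_id %in% kept_low, ]
    windows <- build_windows(lowkept[, c("variant_id", "chrom", "pos")],
                             width_bp = config$window_bp)
    null <- fit_null_model(y, covar)
    windows <- skat_windows(null, geno, windows)
    windows <- permutation_fwer(y, covar, geno, windows,
                                B = config$B, alpha = config$alpha,
                                seed = config$seed)
    write_tsv(windows, file.path(config$outdir, "set_results.tsv"))
    regions_nominal <- merge_regions(windows, config$alpha, "nominal")
    regions_fwer <- merge_regions(windows, config$alpha, "fwer")
    regions <- rbind(regions_nominal, regions_fwer)
    # BED: 0-based half-open, converted from 1-based inclusive
    bed <- data.frame(chrom = regions$chrom, start = regions$start - 1L,
                      end = regions$end, name = regions$tier)
    con <- file(file.path(config$outdir, "regions.bed"), "w")
    writeLines("# 0-based half-open; converted from 1-based inclusive spans",
               con)
    utils::write.table(bed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
    stage("lowfreq_arm", nrow(lowf), nrow(windows))
  }
  results$windows <- windows
  results$regions_nominal <- regions_nominal
  results$regions_fwer <- regions_fwer

  # -- screen ---------------------------------------------------------
  if ("feature_location" %in% names(variants)) {
    smafs <- stats::setNames(variants$maf, variants$variant_id)
    screen <- filter_candidates(variants, smafs, config$screen)
    write_tsv(screen, file.path(config$outdir, "screen.tsv"))
    results$screen <- screen
    stage("screen", nrow(variants), sum(screen$candidate))
  }

  # -- summary + manifest --------------------------------------------
  results$summary <- summarize_variants(
    if ("locus" %in% names(variants)) variants else
      transform(variants, locus = chrom))
  write_tsv(results$summary, file.path(config$outdir, "variant_summary.tsv"))
  results$manifest <- manifest
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

#' Render a human-readable report from pipeline outputs
#'
#' Reads the stage artifacts in an output directory and prints an
#' association table, the set/region tables, the variant summary and the
#' screen audit. Every number is read from the stage artifacts; nothing is
#' recomputed. Missing artifacts are listed as absent.
#'
#' @param outdir Directory written by [run_pipeline()].
#' @return The report, a character vector of lines, invisibly; also printed.
#' @export
make_report <- function(outdir) {
  lines <- c("== fxiloci run report ==", paste("output dir:", outdir), "")
  grab <- function(f) {
    p <- file.path(outdir, f)
    if (file.exists(p)) utils::read.delim(p) else NULL
  }
  sect <- function(title, d, fmt) {
    if (is.null(d)) return(paste0("[absent] ", title))
    c(paste0("-- ", title, " --"), fmt(d), "")
  }
  norm <- grab("normality.tsv")
  lines <- c(lines, sect("phenotype normality", norm, function(d)
    sprintf("Shapiro-Wilk W = %.5f, p = %.4g (n = %d)", d$W, d$p, d$n)))
  assoc <- grab("assoc_common.tsv")
  lines <- c(lines, sect("common-variant association", assoc, function(d) {
    top <- utils::head(d[order(d$p), ], 10)
    c(sprintf("%d common variants tested; %d with p < 0.05",
              nrow(d), sum(d$p < 0.05)),
      sprintf("%-22s beta=%7.2f  p=%.3g  bonferroni=%.3g",
              top$variant_id, top$beta, top$p, top$p_bonferroni))
  }))
  clumps <- grab("clumps.tsv")
  lines <- c(lines, sect("independent signals (clumps)", clumps, function(d)
    sprintf("%d independent signal(s); largest clump has %d member(s)",
            nrow(d), if (nrow(d)) max(d$n_members) else 0L)))
  sets <- grab("set_results.tsv")
  lines <- c(lines, sect("low-frequency variant sets", sets, function(d)
    c(sprintf("%d sliding sets; %d nominally significant; %d FWER-significant",
              nrow(d), sum(d$p < 0.05, na.rm = TRUE),
              sum(d$significant_fwer)),
      if (any(d$significant_fwer))
        sprintf("  %s:%d-%d empirical_p=%.4g", d$chrom[d$significant_fwer],
                d$window_start[d$significant_fwer],
                d$window_end[d$significant_fwer],
                d$empirical_p[d$significant_fwer])
      else "  no set survives permutation FWER control")))
  summ <- grab("variant_summary.tsv")
  lines <- c(lines, sect("variant summary", summ, function(d)
    sprintf("%-8s n=%4d  indel%%=%s  dbSNP%%=%s", d$locus, d$n_total,
            format(d$pct_indel), format(d$pct_dbsnp))))
  screen <- grab("screen.tsv")
  lines <- c(lines, sect("pathogenic-candidate screen", screen, function(d)
    sprintf("%d of %d variants pass all screening rules",
            sum(d$candidate), nrow(d))))
  if (is.null(assoc) && is.null(sets))
    lines <- c(lines, "no significant findings: no association artifacts present")
  cat(lines, sep = "\n")
  invisible(lines)
}
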