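#' Read a VCF file into a dosage matrix and variant table
#'
#' Loads biallelic records from a VCF 4.2 file via \pkg{vcfR}. Multiallelic
#' records are excluded with a logged count; positions stay 1-based.
#'
#' @param path VCF file (plain or gzipped).
#' @return List with `genotypes` (individuals x variants dosage matrix,
#'   `NA` = missing), `variants` (data frame: `variant_id`, `chrom`, `pos`,
#'   `ref`, `alt`, `dbsnp_id`, `is_indel`) and `n_multiallelic_excluded`.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (n_rec == 0) {
    return(list(genotypes = matrix(NA_integer_, 0, 0),
                variants = empty_variant_table(),
                n_multiallelic_excluded = 0L))
  }
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"])
  n_multi <- sum(multi)
  if (n_multi > 0)
    message(n_multi, " multiallelic record(s) excluded")
  if (all(multi)) {
    return(list(genotypes = matrix(NA_integer_, 0, 0),
                variants = empty_variant_table(),
                n_multiallelic_excluded = n_multi))
  }
  gt_char <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt_char)))
    gt_char <- matrix(gt_char, nrow = n_rec)
  keep <- which(!multi)
  gt_char <- gt_char[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  # dosage = count of ALT alleles, phase-insensitive
  dose <- matrix(NA_integer_, nrow = nrow(gt_char), ncol = ncol(gt_char))
  clean <- gsub("\\|", "/", gt_char)
  dose[clean %in% c("0/0")] <- 0L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean %in% c("1/1")] <- 2L
  g <- t(dose)
  vids <- paste0(fix[, "CHROM"], "_", fix[, "POS"])
  dimnames(g) <- list(colnames(v@gt)[-1], vids)
  variants <- data.frame(
    variant_id = vids,
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    dbsnp_id = ifelse(fix[, "ID"] %in% c(".", NA), NA_character_, fix[, "ID"]),
    is_indel = nchar(fix[, "REF"]) != 1L | nchar(fix[, "ALT"]) != 1L,
    row.names = NULL)
  list(genotypes = g, variants = variants,
       n_multiallelic_excluded = n_multi)
}

empty_variant_table <- function() {
  data.frame(variant_id = character(0), chrom = character(0),
             pos = integer(0), ref = character(0), alt = character(0),
             dbsnp_id = character(0), is_indel = logical(0))
}

#' Minor-allele frequency of a dosage vector
#'
#' `min(f, 1 - f)` where `f` is the alternate-allele frequency computed
#' over non-missing genotypes: `sum(dosage) / (2 * n_non_missing)`.
#' Missing genotypes are excluded from the denominator, not imputed.
#'
#' @param dosages Integer vector with values 0, 1, 2 or `NA`.
#' @return MAF in `[0, 0.5]`.
#' @examples
#' compute_maf(c(0, 0, 1, 2))  # 0.375
#' @export
compute_maf <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) stop("all dosages missing: MAF undefined")
  if (any(!dosages[ok] %in% 0:2)) stop("dosages must be 0, 1 or 2")
  f <- sum(dosages[ok]) / (2 * sum(ok))
  min(f, 1 - f)
}

#' Classify a variant as common or low-frequency
#'
#' Common variants are those with sample MAF at or above the threshold
#' (default 10\%); everything below is low-frequency. The boundary is
#' inclusive on the common side.
#'
#' @param maf MAF in `[0, 0.5]` (vectorized).
#' @param threshold Frequency threshold, default 0.10.
#' @return Character vector, `"common"` or `"low_frequency"`.
#' @examples
#' classify_frequency(c(0.472, 0.10, 0.0999))
#' @export
classify_frequency <- function(maf, threshold = 0.10) {
  if (any(maf < 0 | maf > 0.5)) stop("maf must lie in [0, 0.5]")
  ifelse(maf >= threshold, "common", "low_frequency")
}

#' Length of a locus from a 1-based inclusive genomic span
#'
#' @param start_bp,end_bp 1-based inclusive coordinates, `start_bp <= end_bp`.
#' @return `end_bp - start_bp + 1`.
#' @examples
#' locus_length(186435098, 186460678)  # 25581 (KNG1)
#' locus_length(187187118, 187210835)  # 23718 (F11)
#' @export
locus_length <- function(start_bp, end_bp) {
  if (any(start_bp > end_bp)) stop("start_bp must be <= end_bp")
  end_bp - start_bp + 1
}

#' Round half-up to a given number of decimals
#'
#' Plain-arithmetic rounding where `.5` always rounds away from zero,
#' matching how descriptive percentages are conventionally printed
#' (40/504 -> 7.9).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Per-locus descriptive summary of a variant table
#'
#' Tabulates, per locus and overall, the counts and percentages of indels,
#' exonic variants, variants with a dbSNP annotation, and variants with a
#' reference-panel allele frequency above 1\%. Percentages are
#' `100 * count / total`, rounded half-up to one decimal.
#'
#' @param variants Data frame with a `locus` column and optionally
#'   `is_indel` (logical), `feature_location` (character; exonic variants
#'   match `"exon"`), `dbsnp_id`, and one or more reference-panel AF
#'   columns named in `af_columns`.
#' @param af_columns Character vector of allele-frequency column names; a
#'   variant counts as panel-common if any of them exceeds
#'   `panel_af_threshold`.
#' @param panel_af_threshold Default 0.01.
#' @return Data frame, one row per locus plus an `"all"` row, with `n_*`
#'   counts and `pct_*` percentages (`NA` for an empty locus).
#' @export
summarize_variants <- function(variants, af_columns = character(0),
                               panel_af_threshold = 0.01) {
  if (!"locus" %in% names(variants))
    stop("variants must carry a 'locus' column")
  if (anyNA(variants$locus))
    stop("variant(s) outside all loci: rows ",
         paste(which(is.na(variants$locus)), collapse = ", "))
  groups <- c(split(variants, variants$locus), list(all = variants))
  rows <- lapply(names(groups), function(nm) {
    d <- groups[[nm]]
    total <- nrow(d)
    cnt <- function(x) sum(x, na.rm = TRUE)
    n_indel <- if ("is_indel" %in% names(d)) cnt(d$is_indel) else NA_integer_
    n_exonic <- if ("feature_location" %in% names(d))
      cnt(grepl("exon", d$feature_location)) else NA_integer_
    n_dbsnp <- if ("dbsnp_id" %in% names(d))
      cnt(!is.na(d$dbsnp_id) & d$dbsnp_id != "") else NA_integer_
    n_panel <- if (length(af_columns)) {
      afs <- as.matrix(d[, af_columns, drop = FALSE])
      cnt(apply(afs, 1L, function(r) any(!is.na(r) & r > panel_af_threshold)))
    } else NA_integer_
    pct <- function(k) if (total == 0 || is.na(k)) NA_real_ else
      round_half_up(100 * k / total, 1)
    data.frame(locus = nm, n_total = total,
               n_indel = n_indel, pct_indel = pct(n_indel),
               n_exonic = n_exonic, pct_exonic = pct(n_exonic),
               n_dbsnp = n_dbsnp, pct_dbsnp = pct(n_dbsnp),
               n_not_dbsnp = if (is.na(n_dbsnp)) NA_integer_ else total - n_dbsnp,
               pct_not_dbsnp = if (is.na(n_dbsnp)) NA_real_ else
                 pct(total - n_dbsnp),
               n_panel_af_gt1pct = n_panel,
               pct_panel_af_gt1pct = pct(n_panel))
  })
  do.call(rbind, rows)
}
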