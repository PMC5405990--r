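#' Criteria for the putative-pathogenic-mutation screen
#'
#' Three rules: (a) the variant is rare -- every available reference-panel
#' allele frequency below `rare_af_threshold` (absence from a panel counts
#' as rare in that panel); (b) location -- intronic variants more than
#' `intronic_distance_max_bp` into the intron from the nearest exon
#' boundary are rejected; (c) for variants absent from the primary
#' reference panel, sample MAF below `unannotated_sample_maf_threshold`.
#'
#' @param rare_af_threshold Default 0.01 (1\%).
#' @param intronic_distance_max_bp Default 30 bp.
#' @param unannotated_sample_maf_threshold Default 0.05 (5\%).
#' @return A `screen_criteria` list.
#' @export
screen_criteria <- function(rare_af_threshold = 0.01,
                            intronic_distance_max_bp = 30L,
                            unannotated_sample_maf_threshold = 0.05) {
  stopifnot(rare_af_threshold > 0, rare_af_threshold < 1,
            intronic_distance_max_bp > 0,
            unannotated_sample_maf_threshold > 0,
            unannotated_sample_maf_threshold < 1)
  structure(list(rare_af_threshold = rare_af_threshold,
                 intronic_distance_max_bp = as.integer(intronic_distance_max_bp),
                 unannotated_sample_maf_threshold =
                   unannotated_sample_maf_threshold),
            class = "screen_criteria")
}

#' Rule-based screen for putative pathogenic mutations
#'
#' Evaluates all three [screen_criteria()] rules for every variant and
#' returns the complete pass/fail trail; a variant is a candidate iff all
#' applicable rules pass. Every rule is evaluated regardless of earlier
#' failures so the audit trail is complete.
#'
#' @param variants Data frame with `variant_id`, `feature_location`,
#'   `exon_distance_bp` (required for intronic variants), and zero or more
#'   reference-panel AF columns named in `af_columns` (`NA` = not annotated
#'   in that panel).
#' @param sample_mafs Named numeric vector of sample MAFs (names =
#'   `variant_id`); required for variants absent from the primary panel.
#' @param criteria A [screen_criteria()].
#' @param af_columns Reference-panel AF column names; the first is the
#'   primary panel used by rule (c).
#' @return Data frame per variant: `pass_rare`, `pass_location`,
#'   `pass_sample_maf`, `candidate`, `reason` (first failing rule or
#'   `"candidate"`).
#' @export
filter_candidates <- function(variants, sample_mafs,
                              criteria = screen_criteria(),
                              af_columns = grep("^af_", names(variants),
                                                value = TRUE)) {
  stopifnot(inherits(criteria, "screen_criteria"),
            "variant_id" %in% names(variants))
  n <- nrow(variants)
  afs <- if (length(af_columns))
    as.matrix(variants[, af_columns, drop = FALSE]) else
    matrix(NA_real_, n, 0)

  # (a) rare in every panel where an AF is available
  pass_rare <- apply(afs, 1L, function(r)
    all(is.na(r) | r < criteria$rare_af_threshold))
  if (ncol(afs) == 0) pass_rare <- rep(TRUE, n)

  # (b) reject deep-intronic variants
  intronic <- grepl("intron", variants$feature_location)
  dist <- if ("exon_distance_bp" %in% names(variants))
    variants$exon_distance_bp else rep(NA_integer_, n)
  if (any(intronic & is.na(dist)))
    stop("intronic variant(s) missing exon_distance_bp: ",
         paste(variants$variant_id[intronic & is.na(dist)], collapse = ", "))
  pass_location <- !(intronic & dist > criteria$intronic_distance_max_bp)

  # (c) sample-MAF fallback for variants absent from the primary panel
  in_primary <- if (ncol(afs) >= 1) !is.na(afs[, 1]) else rep(FALSE, n)
  smaf <- sample_mafs[variants$variant_id]
  needs_c <- !in_primary
  if (any(needs_c & is.na(smaf)))
    stop("sample MAF required for unannotated variant(s): ",
         paste(variants$variant_id[needs_c & is.na(smaf)], collapse = ", "))
  pass_sample_maf <- !needs_c |
    smaf < criteria$unannotated_sample_maf_threshold

  candidate <- pass_rare & pass_location & pass_sample_maf
  reason <- ifelse(candidate, "candidate",
            ifelse(!pass_location, "deep_intronic",
            ifelse(!pass_rare, "panel_af_not_rare", "sample_maf_too_high")))
  data.frame(variant_id = variants$variant_id,
             pass_rare = pass_rare, pass_location = pass_location,
             pass_sample_maf = unname(pass_sample_maf),
             candidate = candidate, reason = reason)
}

#' Percent change between native and mutated splice scores
#'
#' `100 * (mutated - native) / native`; the reported value is rounded
#' half-up to one decimal, the unrounded value is kept for consensus
#' counting.
#'
#' @param native,mutated Scores on the algorithm's own scale; `native`
#'   must be positive.
#' @return List with `delta_pct` (unrounded) and `delta_pct_reported`.
#' @examples
#' splice_delta(88.56, 85.25)$delta_pct_reported  # -3.7
#' @export
splice_delta <- function(native, mutated) {
  if (any(native <= 0)) stop("native score must be > 0")
  d <- 100 * (mutated - native) / native
  list(delta_pct = d, delta_pct_reported = round_half_up(d, 1))
}

#' Consensus over splice-prediction score changes
#'
#' Counts the algorithms whose unrounded percent change exceeds the
#' magnitude threshold, and flags the variant when at least
#' `min_algorithms` do.
#'
#' @param pairs Data frame with columns `algorithm`, `native`, `mutated`.
#' @param magnitude_threshold_pct Default 10.
#' @param min_algorithms Default 2.
#' @return List: `deltas` (per-algorithm unrounded percent changes),
#'   `count_exceeding`, `flagged`.
#' @export
splice_consensus <- function(pairs, magnitude_threshold_pct = 10,
                             min_algorithms = 2L) {
  stopifnot(nrow(pairs) >= 1,
            all(c("algorithm", "native", "mutated") %in% names(pairs)))
  d <- splice_delta(pairs$native, pairs$mutated)$delta_pct
  names(d) <- pairs$algorithm
  count <- sum(abs(d) > magnitude_threshold_pct)
  list(deltas = d, count_exceeding = count,
       flagged = count >= min_algorithms)
}
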