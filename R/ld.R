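#' Squared Pearson correlation between two dosage vectors
#'
#' Computed over individuals non-missing in both vectors; this is the
#' pairwise special case of the multiple correlation used in the VIF.
#'
#' @param g_i,g_j Dosage vectors of equal length.
#' @return r-squared in `[0, 1]`.
#' @export
genotype_r2 <- function(g_i, g_j) {
  stopifnot(length(g_i) == length(g_j))
  ok <- !is.na(g_i) & !is.na(g_j)
  if (sum(ok) < 3) stop("need >= 3 shared non-missing individuals")
  x <- g_i[ok]; y <- g_j[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("r2 undefined for a constant dosage vector")
  min(stats::cor(x, y)^2, 1)
}

#' Parameters for windowed VIF pruning
#'
#' @param window_size Number of variants per window (default 30).
#' @param shift Number of variants the window advances each step (default 3).
#' @param vif_threshold Maximum tolerated variance inflation factor
#'   (default 2, i.e. multiple R-squared 0.5).
#' @return A `prune_params` list.
#' @export
prune_params <- function(window_size = 30L, shift = 3L, vif_threshold = 2) {
  if (shift > window_size) stop("shift must be <= window_size")
  if (shift < 1L) stop("shift must be >= 1")
  if (vif_threshold <= 1) stop("vif_threshold must be > 1")
  structure(list(window_size = as.integer(window_size),
                 shift = as.integer(shift),
                 vif_threshold = vif_threshold),
            class = "prune_params")
}

# VIF of every column of a (mean-imputed, possibly constant) dosage window:
# diag of the inverse correlation matrix, which equals 1/(1 - R^2) of each
# column regressed on all the others. Constant columns get VIF 1 (nothing
# predicts or is predicted by them). On a singular correlation matrix the
# per-column least-squares R^2 is used, capping VIF at 1e12.
window_vifs <- function(Gw) {
  m <- ncol(Gw)
  if (m < 2) return(rep(1, m))
  sds <- apply(Gw, 2L, stats::sd)
  vifs <- rep(1, m)
  act <- which(sds > 0)
  if (length(act) < 2) return(vifs)
  R <- stats::cor(Gw[, act, drop = FALSE])
  inv <- tryCatch(solve(R), error = function(e) NULL)
  if (!is.null(inv) && all(diag(inv) > 0)) {
    vifs[act] <- diag(inv)
  } else {
    Z <- scale(Gw[, act, drop = FALSE])
    for (k in seq_along(act)) {
      fit <- stats::lm.fit(cbind(1, Z[, -k, drop = FALSE]), Z[, k])
      r2 <- 1 - sum(fit$residuals^2) / sum(Z[, k]^2)
      vifs[act[k]] <- 1 / max(1 - r2, 1e-12)
    }
  }
  vifs
}

#' Windowed variance-inflation-factor LD pruning
#'
#' Slides a window of `window_size` variants along the position-sorted
#' variant list, advancing `shift` variants per step. Within a window the
#' VIF of every variant -- `1/(1 - R^2)`, `R^2` the multiple correlation of
#' its dosages on all other variants in the window -- is computed
#' repeatedly, and while the largest VIF exceeds the threshold that variant
#' is removed (ties broken toward keeping the higher-MAF, earlier-position
#' variant). Windows are taken over the currently retained sequence and
#' full passes repeat until no variant is removed, so the result is stable:
#' pruning the output again removes nothing, and re-auditing any window of
#' the output finds all VIFs at or below the threshold.
#'
#' Missing dosages are mean-imputed within the window for the regression
#' (set `impute = FALSE` for complete-case columns).
#'
#' @param genotypes Dosage matrix (individuals x variants) with column names.
#' @param order Character vector of variant ids in position order; defaults
#'   to the matrix column order.
#' @param params A [prune_params()].
#' @param impute Mean-impute missing dosages within each window (default).
#' @return List with `kept` (retained ids, position order) and `removed`
#'   (data frame: `variant_id`, `window_first`, `vif_at_removal`).
#' @export
vif_prune <- function(genotypes, order = colnames(genotypes),
                      params = prune_params(), impute = TRUE) {
  stopifnot(inherits(params, "prune_params"))
  if (length(order) < 2)
    return(list(kept = order,
                removed = data.frame(variant_id = character(0),
                                     window_first = integer(0),
                                     vif_at_removal = numeric(0))))
  if (!all(order %in% colnames(genotypes)))
    stop("order contains unknown variant ids")
  mafs <- apply(genotypes[, order, drop = FALSE], 2L, compute_maf)
  pos_rank <- stats::setNames(seq_along(order), order)
  kept <- order
  removed <- list()

  repeat {
    removed_this_pass <- FALSE
    start <- 1L
    repeat {
      if (start > length(kept)) break
      idx <- seq.int(start, min(start + params$window_size - 1L, length(kept)))
      if (length(idx) >= 2) {
        repeat {
          win <- kept[idx]
          Gw <- genotypes[, win, drop = FALSE]
          if (impute && anyNA(Gw)) {
            Gw <- apply(Gw, 2L, function(col) {
              col[is.na(col)] <- mean(col, na.rm = TRUE); col
            })
          }
          vifs <- window_vifs(Gw)
          if (max(vifs) <= params$vif_threshold) break
          worst <- which(vifs == max(vifs))
          if (length(worst) > 1) {   # drop lowest MAF, then latest position
            worst <- worst[order(mafs[win[worst]], -pos_rank[win[worst]])][1]
          }
          removed[[length(removed) + 1L]] <-
            data.frame(variant_id = win[worst], window_first = start,
                       vif_at_removal = max(vifs))
          kept <- kept[-idx[worst]]
          removed_this_pass <- TRUE
          idx <- seq.int(start, min(start + params$window_size - 1L, length(kept)))
          if (length(idx) < 2) break
        }
      }
      if (start + params$window_size - 1L >= length(kept)) break
      start <- start + params$shift
    }
    if (!removed_this_pass) break
  }
  list(kept = kept,
       removed = if (length(removed)) do.call(rbind, removed) else
         data.frame(variant_id = character(0), window_first = integer(0),
                    vif_at_removal = numeric(0)))
}

#' Parameters for LD clumping of association signals
#'
#' @param index_p_threshold Maximum p-value for a variant to seed a clump
#'   (default 0.05, so every nominally significant variant can head its own
#'   signal).
#' @param member_p_threshold Maximum p-value for absorption into a clump.
#' @param r2_threshold Minimum r-squared with the index (default 0.5).
#' @param distance_kb Maximum distance from the index in kb (default 250).
#' @return A `clump_params` list.
#' @export
clump_params <- function(index_p_threshold = 0.05,
                         member_p_threshold = 0.05,
                         r2_threshold = 0.5, distance_kb = 250) {
  if (index_p_threshold > member_p_threshold)
    stop("index_p_threshold must be <= member_p_threshold")
  structure(list(index_p_threshold = index_p_threshold,
                 member_p_threshold = member_p_threshold,
                 r2_threshold = r2_threshold,
                 distance_kb = distance_kb),
            class = "clump_params")
}

#' Greedy LD clumping of single-variant association results
#'
#' Repeatedly takes the unassigned variant with the smallest p-value at or
#' below the index threshold as a clump index, then absorbs every
#' unassigned variant with p-value at or below the member threshold,
#' r-squared with the index at or above `r2_threshold`, and position within
#' `distance_kb` of the index. Each variant belongs to at most one clump.
#'
#' @param assoc Data frame with columns `variant_id`, `pos`, `p`.
#' @param genotypes Dosage matrix with the assoc variants as columns.
#' @param params A [clump_params()].
#' @return Data frame, one row per clump: `index`, `index_p`, `n_members`,
#'   `members` (comma-separated, index first), `r2_to_index`
#'   (comma-separated, aligned with `members`).
#' @export
clump <- function(assoc, genotypes, params = clump_params()) {
  stopifnot(inherits(params, "clump_params"),
            all(c("variant_id", "pos", "p") %in% names(assoc)))
  if (any(assoc$p < 0 | assoc$p > 1)) stop("p-values must lie in [0, 1]")
  unassigned <- assoc[order(assoc$p), ]
  clumps <- list()
  while (nrow(unassigned) > 0 &&
         unassigned$p[1] <= params$index_p_threshold) {
    index <- unassigned[1, ]
    rest <- unassigned[-1, , drop = FALSE]
    take <- logical(nrow(rest))
    r2s <- rep(NA_real_, nrow(rest))
    for (k in seq_len(nrow(rest))) {
      if (rest$p[k] > params$member_p_threshold) next
      if (abs(rest$pos[k] - index$pos) > params$distance_kb * 1000) next
      r2 <- tryCatch(genotype_r2(genotypes[, index$variant_id],
                                 genotypes[, rest$variant_id[k]]),
                     error = function(e) NA_real_)
      if (!is.na(r2) && r2 >= params$r2_threshold) {
        take[k] <- TRUE; r2s[k] <- r2
      }
    }
    clumps[[length(clumps) + 1L]] <- data.frame(
      index = index$variant_id, index_p = index$p,
      n_members = 1L + sum(take),
      members = paste(c(index$variant_id, rest$variant_id[take]),
                      collapse = ","),
      r2_to_index = paste(c(1, round(r2s[take], 4)), collapse = ","))
    unassigned <- rest[!take, , drop = FALSE]
  }
  if (!length(clumps))
    return(data.frame(index = character(0), index_p = numeric(0),
                      n_members = integer(0), members = character(0),
                      r2_to_index = character(0)))
  do.call(rbind, clumps)
}
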