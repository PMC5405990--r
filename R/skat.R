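#' Sliding 2-kb variant sets over low-frequency variants
#'
#' One window per low-frequency variant: anchored at the variant's
#' position, the window spans `[pos, pos + width_bp]` (1-based inclusive at
#' both ends) and contains every low-frequency variant inside that span.
#' Successive windows advance by one anchor variant, reproducing windows
#' whose printed endpoints differ by exactly the inter-anchor shifts.
#'
#' @param variants Data frame of low-frequency variants with `variant_id`
#'   and `pos`, sorted by position (sorted internally if not).
#' @param width_bp Window width in bp (default 2000).
#' @return Data frame, one row per window: `window_start`, `window_end`,
#'   `anchor`, `n_members`, `members` (comma-separated ids).
#' @export
build_windows <- function(variants, width_bp = 2000) {
  if (nrow(variants) == 0)
    return(data.frame(chrom = character(0), window_start = integer(0),
                      window_end = integer(0), anchor = character(0),
                      n_members = integer(0), members = character(0)))
  has_chrom <- "chrom" %in% names(variants)
  if (!has_chrom) variants$chrom <- "."
  v <- variants[order(variants$chrom, variants$pos), ]
  rows <- lapply(seq_len(nrow(v)), function(i) {
    lo <- v$pos[i]; hi <- v$pos[i] + width_bp
    inside <- v$chrom == v$chrom[i] & v$pos >= lo & v$pos <= hi
    data.frame(chrom = v$chrom[i], window_start = lo, window_end = hi,
               anchor = v$variant_id[i], n_members = sum(inside),
               members = paste(v$variant_id[inside], collapse = ","))
  })
  do.call(rbind, rows)
}

#' Null model for the kernel score test
#'
#' OLS of the phenotype on the covariates (intercept, age, sex by
#' default). Stores the residuals, the residual variance
#' `sigma2 = r'r / (n - rank(X))` and the QR decomposition used to project
#' onto the residual space of the covariates.
#'
#' @param y Phenotype vector, no missing values.
#' @param covariates Data frame/matrix of covariates (an intercept is
#'   added), or `NULL` for intercept-only.
#' @return A `null_model` list: `coefficients`, `residuals`, `sigma2`,
#'   `qr` (of the covariate design), `n`, `rank`.
#' @export
fit_null_model <- function(y, covariates = NULL) {
  if (anyNA(y)) stop("phenotype must be complete for the null model")
  X <- if (is.null(covariates)) matrix(1, length(y), 1)
       else cbind(1, as.matrix(covariates))
  if (anyNA(X)) stop("covariates must be complete")
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient covariate design")
  r <- qr.resid(qx, y)
  structure(list(coefficients = qr.coef(qx, y), residuals = r,
                 sigma2 = sum(r^2) / (length(y) - qx$rank),
                 qr = qx, n = length(y), rank = qx$rank),
            class = "null_model")
}

#' Beta-density variant weights
#'
#' `w(maf) = dbeta(maf, a, b)`, the conventional up-weighting of rarer
#' variants in kernel association tests; the default Beta(1, 25) gives
#' weight 25 as MAF approaches 0 and ~1.99 at MAF 0.1. `a = b = 1` is a
#' flat weight.
#'
#' @param maf MAF vector in `[0, 0.5]`.
#' @param a,b Beta shape parameters.
#' @return Non-negative weights.
#' @export
weights_beta <- function(maf, a = 1, b = 25) {
  if (any(maf < 0 | maf > 0.5)) stop("maf must lie in [0, 0.5]")
  stats::dbeta(maf, a, b)
}

# Imhof-type numerical inversion for P(sum_k lambda_k chi2_1 > q):
# p = 1/2 + (1/pi) Int_0^inf sin(theta(u)) / (u rho(u)) du with
# theta(u) = (1/2) sum arctan(lambda_k u) - qu/2 and
# rho(u) = prod (1 + lambda_k^2 u^2)^(1/4). Eigenvalues are rescaled by
# their maximum (the tail probability is scale-invariant) and a single
# eigenvalue reduces to the exact chi-square tail. Returns NA when the
# adaptive quadrature fails or leaves [0, 1]; the caller then falls back
# to the Liu approximation.
davies_pvalue <- function(q, lambda) {
  lambda <- lambda[lambda > 1e-12 * max(lambda, 1)]
  if (!length(lambda)) return(if (q <= 0) 1 else 0)
  if (length(lambda) == 1)
    return(stats::pchisq(q / lambda, df = 1, lower.tail = FALSE))
  s <- max(lambda); lambda <- lambda / s; q <- q / s
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(theta) / (u * rho)
  }
  val <- tryCatch(
    stats::integrate(integrand, 0, Inf, rel.tol = 1e-4,
                     subdivisions = 10000L, stop.on.error = TRUE)$value,
    error = function(e) NA_real_)
  if (is.na(val)) return(NA_real_)
  p <- 0.5 + val / pi
  if (p < -1e-4 || p > 1 + 1e-4) return(NA_real_)  # inversion unreliable
  min(max(p, 0), 1)
}

# Liu-Tang-Zhang moment-matching approximation to the same tail
# probability; cheap enough for permutation use. Vectorized over q.
liu_pvalue <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  if (c2 <= 0) return(ifelse(q <= c1, 1, 0))
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    df <- a^2 - 2 * delta
  } else {
    delta <- 0
    df <- 1 / s2
  }
  mu_q <- c1; sigma_q <- sqrt(2 * c2)
  mu_x <- df + delta; sigma_x <- sqrt(2 * (df + 2 * delta))
  tstar <- (q - mu_q) / sigma_q
  stats::pchisq(tstar * sigma_x + mu_x, df = df, ncp = delta,
                lower.tail = FALSE)
}

#' Variance-component kernel score test for a variant set
#'
#' The score statistic is `Q = r' G W^2 G' r` with `r` the null-model
#' residuals, `G` the set's dosage submatrix and `W = diag(weights)`.
#' Under the null `Q` follows a mixture `sum_k lambda_k chi2_1`, where the
#' `lambda_k` are the eigenvalues of `sigma2 * W G' P0 G W` and `P0`
#' projects onto the residual space of the covariates. The tail probability
#' is evaluated by numerical inversion of the characteristic function
#' (Imhof/Davies form), falling back to the Liu moment-matching
#' approximation when inversion does not converge (`method = "liu"` forces
#' the fallback).
#'
#' @param null A [fit_null_model()] object.
#' @param G_set Dosage submatrix, individuals x set members; missing
#'   dosages are mean-imputed per variant.
#' @param weights Per-member weights (default Beta(1, 25) on sample MAF).
#' @param method `"davies"` (default, with fallback) or `"liu"`.
#' @return List: `Q`, `lambda` (eigenvalue mixture weights), `p`,
#'   `monomorphic` flag (all members constant: `Q = 0`, `p = 1`),
#'   `used_fallback` flag.
#' @export
skat_test <- function(null, G_set, weights = NULL, method = c("davies", "liu")) {
  method <- match.arg(method)
  stopifnot(inherits(null, "null_model"))
  G_set <- as.matrix(G_set)
  if (nrow(G_set) != null$n) stop("genotype rows must match the null model")
  if (ncol(G_set) == 0) stop("empty variant set")
  if (anyNA(G_set)) {
    G_set <- apply(G_set, 2L, function(col) {
      col[is.na(col)] <- mean(col, na.rm = TRUE); col
    })
  }
  if (is.null(weights))
    weights <- weights_beta(apply(G_set, 2L, compute_maf))
  if (length(weights) != ncol(G_set))
    stop("one weight per set member required")
  poly <- apply(G_set, 2L, function(col) stats::var(col) > 0)
  if (!any(poly)) {
    return(list(Q = 0, lambda = numeric(0), p = 1,
                monomorphic = TRUE, used_fallback = FALSE))
  }
  A <- sweep(G_set, 2L, weights, `*`)          # G W
  Q <- sum(crossprod(A, null$residuals)^2)
  PA <- qr.resid(null$qr, A)                   # P0 G W
  lambda <- eigen(crossprod(PA), symmetric = TRUE, only.values = TRUE)$values
  lambda <- null$sigma2 * lambda[lambda > 1e-10 * max(lambda)]
  used_fallback <- FALSE
  p <- if (method == "davies") davies_pvalue(Q, lambda) else NA_real_
  if (is.na(p)) {
    p <- liu_pvalue(Q, lambda)
    used_fallback <- method == "davies"
  }
  list(Q = Q, lambda = lambda, p = min(max(p, 0), 1),
       monomorphic = FALSE, used_fallback = used_fallback)
}

#' Kernel set tests for every sliding window
#'
#' @param null A [fit_null_model()].
#' @param genotypes Dosage matrix.
#' @param windows Output of [build_windows()].
#' @param weights_fn Function MAF-vector -> weights (default
#'   [weights_beta()]).
#' @param method Tail-probability method, see [skat_test()].
#' @return `windows` with `Q`, `p`, `monomorphic`, `used_fallback` columns.
#' @export
skat_windows <- function(null, genotypes, windows,
                         weights_fn = weights_beta,
                         method = "davies") {
  res <- lapply(seq_len(nrow(windows)), function(i) {
    ids <- strsplit(windows$members[i], ",", fixed = TRUE)[[1]]
    G <- genotypes[, ids, drop = FALSE]
    mafs <- apply(G, 2L, compute_maf)
    skat_test(null, G, weights_fn(mafs), method = method)
  })
  windows$Q <- vapply(res, `[[`, numeric(1), "Q")
  windows$p <- vapply(res, `[[`, numeric(1), "p")
  windows$monomorphic <- vapply(res, `[[`, logical(1), "monomorphic")
  windows$used_fallback <- vapply(res, `[[`, logical(1), "used_fallback")
  windows
}

#' Min-p permutation control of the family-wise error rate
#'
#' Westfall--Young-style resampling: for each of `B` permutations the
#' phenotype vector is shuffled across individuals (genotypes and the
#' covariate-to-individual pairing stay fixed, preserving the correlation
#' structure among variants), the null model is refit, and every set's
#' p-value is recomputed; the minimum p over sets is recorded. The
#' empirical p-value of set `s` is `(1 + #\{b : min_b <= p_s\}) / (B + 1)`,
#' and a set is FWER-significant when that is at or below `alpha`.
#'
#' Both the observed and permuted set p-values entering the comparison are
#' computed with the fast moment-matching tail approximation so that the
#' comparison is internally consistent; the analytic p-values reported by
#' [skat_windows()] are unaffected.
#'
#' @param y Phenotype vector.
#' @param covariates Covariate data frame (age, sex).
#' @param genotypes Dosage matrix.
#' @param windows Output of [build_windows()] (optionally already carrying
#'   analytic p-values).
#' @param B Number of permutations (default 1000).
#' @param alpha FWER level (default 0.05).
#' @param seed Integer seed.
#' @param scheme `"phenotype"` permutes raw phenotype values (default);
#'   `"residual"` permutes null-model residuals (Freedman--Lane style),
#'   keeping fitted covariate effects attached to individuals.
#' @return `windows` with columns `p_comparison` (the p used in the min-p
#'   comparison), `empirical_p` and `significant_fwer`.
#' @export
permutation_fwer <- function(y, covariates, genotypes, windows,
                             B = 1000L, alpha = 0.05, seed = 1L,
                             scheme = c("phenotype", "residual")) {
  scheme <- match.arg(scheme)
  if (B < 1) stop("B must be >= 1")
  n <- length(y)
  null <- fit_null_model(y, covariates)
  member_ids <- strsplit(windows$members, ",", fixed = TRUE)
  # Stack every set's weighted dosage columns once: Q_s = ||A_s' r||^2.
  Acols <- list(); set_of_col <- integer(0)
  lambda0 <- vector("list", nrow(windows))   # eigenvalues / sigma2
  for (s in seq_len(nrow(windows))) {
    G <- as.matrix(genotypes[, member_ids[[s]], drop = FALSE])
    if (anyNA(G)) {
      G <- apply(G, 2L, function(col) {
        col[is.na(col)] <- mean(col, na.rm = TRUE); col
      })
    }
    mafs <- apply(G, 2L, compute_maf)
    A <- sweep(G, 2L, weights_beta(mafs), `*`)
    PA <- qr.resid(null$qr, A)
    ev <- eigen(crossprod(PA), symmetric = TRUE, only.values = TRUE)$values
    lambda0[[s]] <- ev[ev > 1e-10 * max(ev, 1)]
    Acols[[s]] <- A
    set_of_col <- c(set_of_col, rep(s, ncol(A)))
  }
  Astack <- do.call(cbind, Acols)
  n_sets <- nrow(windows)

  set_pvals <- function(r, sigma2) {
    z2 <- as.vector(crossprod(Astack, r))^2
    Qs <- rowsum(z2, set_of_col, reorder = TRUE)[, 1]
    vapply(seq_len(n_sets), function(s) {
      if (!length(lambda0[[s]])) return(1)
      liu_pvalue(Qs[s] / sigma2, lambda0[[s]])
    }, numeric(1))
  }

  p_obs <- set_pvals(null$residuals, null$sigma2)
  base <- if (scheme == "phenotype") y else null$residuals
  minp <- local_rng(seed, "perm", {
    vapply(seq_len(B), function(b) {
      yb <- base[sample.int(n)]
      rb <- qr.resid(null$qr, yb)
      s2b <- sum(rb^2) / (n - null$rank)
      min(set_pvals(rb, s2b))
    }, numeric(1))
  })
  emp <- vapply(p_obs, function(p) (1 + sum(minp <= p)) / (B + 1), numeric(1))
  windows$p_comparison <- p_obs
  windows$empirical_p <- emp
  windows$significant_fwer <- emp <= alpha
  windows
}

#' Merge overlapping significant variant sets into regions
#'
#' Unions the genomic intervals of the selected sets (`tier = "nominal"`:
#' analytic `p < alpha`; `tier = "fwer"`: the `significant_fwer` flag) into
#' maximal disjoint intervals by a position sweep.
#'
#' @param windows Set table carrying `window_start`, `window_end` and the
#'   relevant significance column.
#' @param alpha Nominal significance level (tier `"nominal"`).
#' @param tier `"nominal"` or `"fwer"`.
#' @return Data frame of disjoint regions: `start`, `end`, `tier`,
#'   `n_sets`, sorted by start.
#' @export
merge_regions <- function(windows, alpha = 0.05, tier = c("nominal", "fwer")) {
  tier <- match.arg(tier)
  sel <- if (tier == "nominal") {
    if (!"p" %in% names(windows)) stop("windows must carry analytic p-values")
    !is.na(windows$p) & windows$p < alpha
  } else {
    if (!"significant_fwer" %in% names(windows))
      stop("windows must carry significance flags; run permutation_fwer first")
    windows$significant_fwer
  }
  w <- windows[sel, , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), tier = character(0),
                      n_sets = integer(0))
  if (nrow(w) == 0) return(empty)
  if (!"chrom" %in% names(w)) w$chrom <- "."
  out <- lapply(split(w, w$chrom), function(wc) {
    wc <- wc[order(wc$window_start, wc$window_end), ]
    starts <- wc$window_start[1]; ends <- wc$window_end[1]; counts <- 1L
    if (nrow(wc) > 1) for (i in 2:nrow(wc)) {
      k <- length(starts)
      if (wc$window_start[i] <= ends[k]) {
        ends[k] <- max(ends[k], wc$window_end[i])
        counts[k] <- counts[k] + 1L
      } else {
        starts <- c(starts, wc$window_start[i])
        ends <- c(ends, wc$window_end[i])
        counts <- c(counts, 1L)
      }
    }
    data.frame(chrom = wc$chrom[1], start = starts, end = ends,
               tier = tier, n_sets = counts)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}
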