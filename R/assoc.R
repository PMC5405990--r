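#' Covariate-adjusted single-variant linear association
#'
#' Ordinary least squares of the phenotype on `[1, g, age, sex]`, with the
#' dosage recoded so the tested allele is the sample minor allele (if the
#' alternate allele is the major one, `g` becomes `2 - g` and the tested
#' allele label switches to the reference). Individuals missing the
#' phenotype, a covariate or this variant's dosage are dropped for this
#' variant only. The p-value is the two-sided t-test on the dosage
#' coefficient.
#'
#' @param y Phenotype vector.
#' @param g Dosage vector (0/1/2, `NA` = missing).
#' @param covariates Data frame or matrix with columns `age` and `sex`.
#' @param ref,alt Allele labels used to name the tested allele.
#' @param tested `"minor"` (default) recodes the dosage so the coefficient
#'   is per copy of the sample minor allele; `"alt"` keeps the ALT-allele
#'   dosage as given, in which case recoding `g -> 2 - g` flips the sign
#'   of `beta` and leaves `p` unchanged.
#' @return One-row data frame: `tested_allele`, `maf`, `beta`, `se`,
#'   `t_stat`, `p`, `n`.
#' @export
fit_linear <- function(y, g, covariates, ref = "REF", alt = "ALT",
                       tested = c("minor", "alt")) {
  tested <- match.arg(tested)
  covariates <- as.data.frame(covariates)
  stopifnot(all(c("age", "sex") %in% names(covariates)),
            length(y) == length(g), length(y) == nrow(covariates))
  ok <- !is.na(y) & !is.na(g) & !is.na(covariates$age) & !is.na(covariates$sex)
  y <- y[ok]; g <- g[ok]
  age <- covariates$age[ok]; sex <- covariates$sex[ok]
  if (length(unique(g)) < 2)
    stop("monomorphic variant: dosage is constant after missing-data exclusion")
  if (length(y) < 5)
    stop("too few complete observations for a 4-parameter fit")
  f <- mean(g) / 2                    # alternate-allele frequency
  allele <- alt
  if (tested == "minor" && f > 0.5) { g <- 2 - g; allele <- ref }
  X <- cbind(1, g = g, age = age, sex = sex)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  df <- length(y) - ncol(X)
  sigma2 <- rss / df
  XtXinv <- solve(crossprod(X))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  beta <- unname(fit$coefficients["g"])
  t_stat <- beta / se
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  data.frame(tested_allele = allele, maf = min(f, 1 - f),
             beta = beta, se = se, t_stat = t_stat, p = p, n = length(y))
}

#' Multiple-testing adjustment of p-values
#'
#' Six methods: Bonferroni single-step, Holm step-down, Sidak single-step
#' (`1 - (1 - p)^m`), Sidak step-down, Benjamini--Hochberg FDR and
#' Benjamini--Yekutieli FDR. Bonferroni, Holm, BH and BY delegate to
#' [stats::p.adjust()]; the two Sidak variants are computed directly.
#' Output order matches input order.
#'
#' @param pvals Numeric vector of raw p-values in `[0, 1]`.
#' @param method One of `"bonferroni"`, `"holm"`, `"sidak_single_step"`,
#'   `"sidak_step_down"`, `"bh"`, `"by"`.
#' @param m Number of tests; defaults to `length(pvals)` but may be larger
#'   when the tested variants are a subset of the testing family (e.g. the
#'   count of common variants retained after LD pruning).
#' @return Adjusted p-values in `[0, 1]`, same order as input.
#' @examples
#' adjust_pvalues(0.00008, "bonferroni", m = 125)  # 0.010
#' @export
adjust_pvalues <- function(pvals,
                           method = c("bonferroni", "holm",
                                      "sidak_single_step", "sidak_step_down",
                                      "bh", "by"),
                           m = length(pvals)) {
  method <- match.arg(method)
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  if (m < length(pvals)) stop("m must be >= length(pvals)")
  switch(method,
    bonferroni = stats::p.adjust(pvals, "bonferroni", n = m),
    holm = stats::p.adjust(pvals, "holm", n = m),
    bh = stats::p.adjust(pvals, "BH", n = m),
    by = stats::p.adjust(pvals, "BY", n = m),
    sidak_single_step = 1 - (1 - pvals)^m,
    sidak_step_down = {
      k <- length(pvals)
      o <- order(pvals)
      adj <- 1 - (1 - pvals[o])^(m - seq_len(k) + 1L)
      adj <- cummax(adj)                 # enforce step-down monotonicity
      out <- numeric(k); out[o] <- pmin(adj, 1)
      out
    })
}

#' Shapiro--Wilk normality check of a phenotype vector
#'
#' @param y Numeric vector, `3 <= length(y) <= 5000` after removing `NA`.
#' @return One-row data frame with `W`, `p` and `n`.
#' @export
test_normality <- function(y) {
  y <- y[!is.na(y)]
  if (length(y) < 3 || length(y) > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  sw <- stats::shapiro.test(y)
  data.frame(W = unname(sw$statistic), p = sw$p.value, n = length(y))
}

#' Association table for a set of common variants
#'
#' Runs [fit_linear()] per variant and attaches all six adjusted p-values.
#'
#' @param y Phenotype vector.
#' @param genotypes Dosage matrix (individuals x variants).
#' @param covariates Data frame with `age` and `sex`.
#' @param variant_ids Columns of `genotypes` to test.
#' @param variants Optional variant table (`variant_id`, `pos`, `ref`,
#'   `alt`, ...) merged into the output.
#' @param m Size of the testing family for the adjustments; defaults to
#'   `length(variant_ids)`.
#' @return Data frame, one row per variant, raw and adjusted p-values.
#' @export
associate_common <- function(y, genotypes, covariates, variant_ids,
                             variants = NULL, m = length(variant_ids)) {
  rows <- lapply(variant_ids, function(v) {
    ra <- c("REF", "ALT")
    if (!is.null(variants) && all(c("ref", "alt") %in% names(variants))) {
      hit <- match(v, variants$variant_id)
      if (!is.na(hit)) ra <- c(variants$ref[hit], variants$alt[hit])
    }
    res <- fit_linear(y, genotypes[, v], covariates, ref = ra[1], alt = ra[2])
    cbind(data.frame(variant_id = v), res)
  })
  out <- do.call(rbind, rows)
  for (meth in c("bonferroni", "holm", "sidak_single_step",
                 "sidak_step_down", "bh", "by")) {
    out[[paste0("p_", meth)]] <- adjust_pvalues(out$p, meth, m = m)
  }
  if (!is.null(variants)) {
    keep <- setdiff(names(variants), setdiff(names(out), "variant_id"))
    out <- merge(variants[, keep, drop = FALSE], out, by = "variant_id",
                 sort = FALSE)
    out <- out[order(out$p), ]
  }
  rownames(out) <- NULL
  out
}
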