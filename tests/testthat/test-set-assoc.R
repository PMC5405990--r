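test_that("sliding 2-kb windows are anchored at each low-frequency variant", {
  v <- data.frame(variant_id = c("a", "b", "c"), pos = c(100, 600, 2300))
  w <- build_windows(v, width_bp = 2000)
  expect_identical(nrow(w), 3L)
  expect_identical(w$members, c("a,b", "b,c", "c"))
  expect_true(all(w$window_end - w$window_start == 2000))

  w1 <- build_windows(v[1, ])
  expect_identical(w1$members, "a")
  expect_identical(nrow(build_windows(v[0, ])), 0L)

  # windows never span chromosomes
  v2 <- data.frame(variant_id = c("a", "b"), chrom = c("chr3", "chr4"),
                   pos = c(100, 600))
  w2 <- build_windows(v2)
  expect_true(all(w2$n_members == 1L))
})

test_that("the null model residualizes covariates exactly", {
  set.seed(50)
  n <- 80
  cov <- data.frame(age = runif(n, 18, 80), sex = rbinom(n, 1, 0.5))
  # phenotype inside the covariate span: zero residuals
  y <- 3 + 0.5 * cov$age - 2 * cov$sex
  nm <- fit_null_model(y, cov)
  expect_lt(max(abs(nm$residuals)), 1e-10)

  # intercept-only: residuals are the centered phenotype
  y2 <- rnorm(n, 50, 10)
  nm2 <- fit_null_model(y2, NULL)
  expect_equal(nm2$residuals, y2 - mean(y2), tolerance = 1e-12)

  # residuals orthogonal to every covariate column
  y3 <- rnorm(n, 100, 30)
  nm3 <- fit_null_model(y3, cov)
  X <- cbind(1, cov$age, cov$sex)
  expect_lt(max(abs(crossprod(X, nm3$residuals))), 1e-8)

  expect_error(fit_null_model(y3, cbind(cov, dup = cov$age)), "rank")
})

test_that("beta-density weights follow the closed form", {
  expect_equal(weights_beta(c(0.05, 0.2, 0.5), a = 1, b = 1), rep(1, 3))
  expect_equal(weights_beta(0, a = 1, b = 25), 25)
  expect_equal(weights_beta(0.1, a = 1, b = 25), 25 * 0.9^24)
  expect_error(weights_beta(0.7), "maf")
})

test_that("kernel score statistic and p-value behave at the boundaries", {
  set.seed(51)
  n <- 60
  cov <- data.frame(age = runif(n, 18, 80), sex = rbinom(n, 1, 0.5))
  null <- fit_null_model(rnorm(n, 100, 20), cov)

  # all-monomorphic set: defined no-test result
  st0 <- skat_test(null, matrix(0L, n, 3))
  expect_identical(st0$Q, 0)
  expect_identical(st0$p, 1)
  expect_true(st0$monomorphic)

  # Q >= 0 and invariant under member permutation
  G <- random_genotypes(n, c(0.05, 0.08, 0.03, 0.06), seed = 52)
  st <- skat_test(null, G)
  expect_gte(st$Q, 0)
  st_perm <- skat_test(null, G[, c(3, 1, 4, 2)])
  expect_equal(st_perm$Q, st$Q, tolerance = 1e-10)
  expect_equal(st_perm$p, st$p, tolerance = 1e-8)
})

test_that("a single-variant set agrees with the linear score test", {
  set.seed(53)
  concordant <- 0L; total <- 0L
  for (i in 1:10) {
    n <- 150
    g <- rbinom(n, 2, 0.15)
    if (var(g) == 0) next
    cov <- data.frame(age = runif(n, 18, 80), sex = rbinom(n, 1, 0.5))
    y <- 100 + 0.2 * cov$age + rnorm(n, 0, 20) + 3 * g
    null <- fit_null_model(y, cov)
    st <- skat_test(null, matrix(g, ncol = 1), weights = 1)
    pf <- fit_linear(y, g, cov)$p
    total <- total + 1L
    if (abs(st$p - pf) / pf < 0.10) concordant <- concordant + 1L
  }
  expect_gte(concordant / total, 0.9)
})

test_that("mixture tail probabilities match a Monte-Carlo oracle", {
  set.seed(54)
  draws <- matrix(rchisq(6 * 1e5, df = 1), nrow = 6)
  for (i in 1:8) {
    lambda <- rexp(sample(2:6, 1)) + 0.05
    k <- length(lambda)
    mc <- colSums(lambda * draws[seq_len(k), , drop = FALSE])
    q <- quantile(mc, probs = runif(1, 0.5, 0.999))
    p_mc <- mean(mc > q)
    if (p_mc < 1e-4) next
    p_davies <- fxiloci:::davies_pvalue(q, lambda)
    expect_lt(abs(p_davies - p_mc) / p_mc, 0.15)
    # the moment-matching fallback is in the same neighbourhood
    p_liu <- fxiloci:::liu_pvalue(q, lambda)
    expect_lt(abs(p_liu - p_mc) / max(p_mc, 0.01), 0.5)
  }
})

test_that("set-test p-values are uniform under the global null", {
  set.seed(55)
  n <- 110
  reps <- 1000
  pvals <- vapply(seq_len(reps), function(i) {
    G <- vapply(runif(5, 0.02, 0.09), function(f) rbinom(n, 2, f), numeric(n))
    if (all(apply(G, 2, var) == 0)) return(NA_real_)
    cov <- data.frame(age = runif(n, 18, 80), sex = rbinom(n, 1, 0.5))
    y <- 100 + 0.3 * cov$age + 5 * cov$sex + rnorm(n, 0, 30)
    skat_test(fit_null_model(y, cov), G)$p
  }, numeric(1))
  pvals <- pvals[!is.na(pvals)]
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  t1 <- mean(pvals < 0.05)
  expect_lt(abs(t1 - 0.05), 0.02)
})

test_that("permutation adjustment is bounded, monotone and reproducible", {
  cfg <- null_locus_config(n = 110, n_variants = 40, seed = 56)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(g$genotypes, cfg)
  mafs <- apply(g$genotypes, 2, compute_maf)
  lowf <- g$variants[mafs > 0 & mafs < 0.10, ]
  w <- build_windows(lowf[, c("variant_id", "chrom", "pos")])
  B <- 200
  pf <- permutation_fwer(ph$fxi_pct, ph[, c("age", "sex")], g$genotypes,
                         w, B = B, seed = 57)
  expect_true(all(pf$empirical_p >= 1 / (B + 1)))
  expect_true(all(pf$empirical_p <= 1))
  # monotone in the comparison p across sets of the same run
  o <- order(pf$p_comparison)
  expect_true(all(diff(pf$empirical_p[o]) >= 0))
  # same seed, same result
  pf2 <- permutation_fwer(ph$fxi_pct, ph[, c("age", "sex")], g$genotypes,
                          w, B = B, seed = 57)
  expect_identical(pf$empirical_p, pf2$empirical_p)
  expect_error(permutation_fwer(ph$fxi_pct, ph[, c("age", "sex")],
                                g$genotypes, w, B = 0), "B")
})

test_that("a planted large low-frequency effect is detected after permutation", {
  pw <- power_experiment(n_replicates = 10, effect_sd = 2, B = 300,
                         seed = 58)
  expect_gte(pw$power, 0.5)
})

test_that("overlapping significant windows merge into maximal regions", {
  # the five FWER-significant printed windows collapse to one region
  anchors <- c(186448468, 186448470, 186448478, 186448482, 186448484)
  w <- data.frame(chrom = "chr3", window_start = anchors,
                  window_end = anchors + 2000,
                  significant_fwer = TRUE)
  r <- merge_regions(w, tier = "fwer")
  expect_identical(nrow(r), 1L)
  expect_identical(r$start, 186448468)
  expect_identical(r$end, 186450484)
  expect_identical(r$n_sets, 5L)

  # disjoint windows pass through; nested windows give the outer interval
  w2 <- data.frame(chrom = "chr3", window_start = c(100, 5000),
                   window_end = c(2100, 7000), p = c(0.01, 0.02))
  r2 <- merge_regions(w2, tier = "nominal")
  expect_identical(nrow(r2), 2L)
  w3 <- data.frame(chrom = "chr3", window_start = c(100, 300),
                   window_end = c(5000, 800), p = c(0.01, 0.02))
  r3 <- merge_regions(w3, tier = "nominal")
  expect_identical(nrow(r3), 1L)
  expect_identical(c(r3$start, r3$end), c(100, 5000))

  # idempotent and order-independent
  shuffled <- w[sample(nrow(w)), ]
  expect_identical(merge_regions(shuffled, tier = "fwer")[, c("start", "end")],
                   r[, c("start", "end")])
  rr <- data.frame(chrom = r$chrom, window_start = r$start,
                   window_end = r$end, significant_fwer = TRUE)
  expect_identical(merge_regions(rr, tier = "fwer")[, c("start", "end")],
                   r[, c("start", "end")])

  # non-significant windows produce no regions
  w4 <- data.frame(chrom = "chr3", window_start = 1, window_end = 2001,
                   p = 0.5)
  expect_identical(nrow(merge_regions(w4, tier = "nominal")), 0L)
})
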