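test_that("single-variant fit matches the normal-equations oracle", {
  set.seed(40)
  n <- 200
  g <- rbinom(n, 2, 0.3)
  cov <- data.frame(age = runif(n, 18, 80), sex = rbinom(n, 1, 0.5))
  y <- 100 + 15 * g + 0.4 * cov$age + 6 * cov$sex + rnorm(n, 0, 25)
  fit <- fit_linear(y, g, cov)
  oracle <- ols_oracle(y, cbind(1, g, cov$age, cov$sex))
  expect_equal(fit$beta, oracle$beta[2], tolerance = 1e-8)
  expect_equal(fit$se, oracle$se[2], tolerance = 1e-8)
  expect_lt(abs(fit$beta - 15), 3 * fit$se)

  # exact linear relation: beta recovered, p at numerical zero
  y2 <- 2 * g
  fit2 <- fit_linear(y2, g, cov)
  expect_equal(fit2$beta, 2, tolerance = 1e-10)
  expect_lt(fit2$p, 1e-100)

  expect_error(fit_linear(y, rep(1, n), cov), "monomorphic")
})

test_that("the tested allele is the sample minor allele", {
  set.seed(41)
  n <- 300
  g <- rbinom(n, 2, 0.8)              # ALT is the major allele
  cov <- data.frame(age = runif(n, 20, 70), sex = rbinom(n, 1, 0.5))
  y <- 100 + 10 * g + rnorm(n, 0, 10)
  fit <- fit_linear(y, g, cov, ref = "A", alt = "G")
  expect_identical(fit$tested_allele, "A")
  expect_equal(fit$beta, -10, tolerance = 1)      # per minor (REF) allele
  # under minor-allele testing, recoding d -> 2 - d is a no-op on beta
  # (the same physical allele is tested); p is unchanged
  fit_rec <- fit_linear(y, 2 - g, cov, ref = "A", alt = "G")
  expect_equal(fit_rec$beta, fit$beta, tolerance = 1e-10)
  expect_equal(fit_rec$p, fit$p, tolerance = 1e-12)
  # testing the ALT dosage as given, the recode flips the sign and keeps p
  f1 <- fit_linear(y, g, cov, tested = "alt")
  f2 <- fit_linear(y, 2 - g, cov, tested = "alt")
  expect_equal(f2$beta, -f1$beta, tolerance = 1e-10)
  expect_equal(f2$p, f1$p, tolerance = 1e-12)
})

test_that("the six adjustment methods reproduce hand-computed values", {
  # printed worked example: p = 0.00008 over m = 125 tests
  expect_equal(round(adjust_pvalues(0.00008, "bonferroni", m = 125), 3), 0.010)
  # m = 1 leaves any method unchanged
  for (meth in c("bonferroni", "holm", "sidak_single_step",
                 "sidak_step_down", "bh", "by"))
    expect_equal(adjust_pvalues(0.03, meth), 0.03)
  # hand step-down / step-up
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.04), "holm"),
               c(0.03, 0.04, 0.04))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bh"),
               c(0.03, 0.03, 0.03))
  # Sidak single-step closed form
  expect_equal(adjust_pvalues(c(0.01, 0.2), "sidak_single_step"),
               1 - (1 - c(0.01, 0.2))^2)
  # Sidak step-down by hand: ordered (0.01, 0.03): 1-(1-.01)^2, then
  # running max with 1-(1-.03)^1
  expect_equal(adjust_pvalues(c(0.03, 0.01), "sidak_step_down"),
               c(max(1 - 0.99^2, 0.03), 1 - 0.99^2))
  expect_error(adjust_pvalues(c(0.1, 1.2), "holm"), "\\[0, 1\\]")
})

test_that("adjustments are monotone, bounded and correctly ordered", {
  set.seed(42)
  methods <- c("bonferroni", "holm", "sidak_single_step",
               "sidak_step_down", "bh", "by")
  for (i in 1:10) {
    p <- runif(20)
    adj <- sapply(methods, function(m) adjust_pvalues(p, m))
    expect_true(all(adj >= 0 & adj <= 1))
    # FWER methods never fall below the raw p
    expect_true(all(adj[, c("bonferroni", "holm", "sidak_single_step",
                            "sidak_step_down")] >= matrix(p, 20, 4) - 1e-12))
    # method orderings, elementwise
    expect_true(all(adj[, "holm"] <= adj[, "bonferroni"] + 1e-12))
    expect_true(all(adj[, "sidak_single_step"] <= adj[, "bonferroni"] + 1e-12))
    expect_true(all(adj[, "bh"] <= adj[, "by"] + 1e-12))
    # raising one raw p never lowers any adjusted p
    j <- sample(20, 1)
    p2 <- p; p2[j] <- min(1, p2[j] + runif(1, 0, 1 - p2[j]))
    for (m in methods)
      expect_true(all(adjust_pvalues(p2, m) >= adjust_pvalues(p, m) - 1e-12))
  }
})

test_that("Bonferroni keeps the family-wise error rate under the global null", {
  set.seed(43)
  n <- 100; m <- 20; reps <- 60
  any_sig <- replicate(reps, {
    g <- random_genotypes(n, rep(0.3, m), seed = sample.int(1e6, 1))
    cov <- data.frame(age = runif(n, 18, 80), sex = rbinom(n, 1, 0.5))
    y <- rnorm(n, 100, 20)
    p <- vapply(seq_len(m),
                function(j) fit_linear(y, g[, j], cov)$p, numeric(1))
    any(adjust_pvalues(p, "bonferroni") < 0.05)
  })
  # binomial tolerance: 0.05 + 2*sqrt(.05*.95/reps)
  expect_lte(mean(any_sig), 0.05 + 2 * sqrt(0.05 * 0.95 / reps))
})

test_that("Shapiro-Wilk wrapper is calibrated and powered", {
  out <- test_normality(rnorm(200))
  expect_true(out$W > 0 && out$W <= 1)
  expect_error(test_normality(c(1, 2)), "3 <= n")

  set.seed(44)
  null_ok <- mean(replicate(100, test_normality(rnorm(500))$p > 0.05))
  expect_gte(null_ok, 0.9)
  alt_ok <- mean(replicate(100, test_normality(rexp(500))$p < 0.05))
  expect_gte(alt_ok, 0.9)
})

test_that("the common-variant association table carries all six adjustments", {
  set.seed(45)
  n <- 150
  g <- random_genotypes(n, c(0.3, 0.4, 0.2), seed = 46)
  cov <- data.frame(age = runif(n, 18, 80), sex = rbinom(n, 1, 0.5))
  y <- 100 + 12 * g[, 1] + rnorm(n, 0, 15)
  out <- associate_common(y, g, cov, colnames(g))
  expect_identical(nrow(out), 3L)
  expect_true(all(c("p_bonferroni", "p_holm", "p_sidak_single_step",
                    "p_sidak_step_down", "p_bh", "p_by") %in% names(out)))
  expect_equal(out$p_bonferroni, pmin(1, out$p * 3))
})
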