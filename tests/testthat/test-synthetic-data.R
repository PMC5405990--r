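test_that("simulated dosages track their target MAFs", {
  # a zero-MAF variant is monomorphic reference
  cfg0 <- tiny_config(n = 200, mafs = c(0, 0.3), seed = 2)
  g0 <- simulate_genotypes(cfg0)$genotypes
  expect_true(all(g0[, 1] == 0))

  # law of large numbers: realized allele-count MAF within +/- 0.02 at n=5000
  cfg <- tiny_config(n = 5000, mafs = c(0.05, 0.20, 0.45), rho = 0, seed = 3)
  g <- simulate_genotypes(cfg)$genotypes
  realized <- colSums(g) / (2 * nrow(g))
  expect_true(all(abs(realized - c(0.05, 0.20, 0.45)) < 0.02))
})

test_that("block LD produces correlated dosages", {
  cfg <- tiny_config(n = 5000, mafs = c(0.3, 0.3), rho = 0.9, seed = 4)
  g <- simulate_genotypes(cfg)$genotypes
  expect_gt(cor(g[, 1], g[, 2])^2, 0.5)
  # at MAF 0.5 the dosage correlation is calibrated to rho itself
  cfg2 <- tiny_config(n = 5000, mafs = c(0.5, 0.5), rho = 0.9, seed = 4)
  g2 <- simulate_genotypes(cfg2)$genotypes
  expect_lt(abs(cor(g2[, 1], g2[, 2]) - 0.9), 0.05)
})

test_that("MAF convergence tightens with sample size", {
  target <- c(0.08, 0.25, 0.4)
  err <- sapply(c(200, 2000, 20000), function(n) {
    g <- simulate_genotypes(tiny_config(n = n, mafs = target, seed = 11))$genotypes
    max(abs(colSums(g) / (2 * n) - target))
  })
  expect_lt(err[3], err[1])
  expect_lt(err[3], 0.01)
})

test_that("phenotype follows the additive covariate + genetic model", {
  # beta = 0, sigma -> 0: phenotype is exactly the covariate surface
  cfg <- tiny_config(n = 120, seed = 5, sigma = 1e-9, mu = 120,
                     beta_age = 0.5, beta_sex = 8)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(g$genotypes, cfg)
  expect_equal(ph$fxi_pct, 120 + 0.5 * ph$age + 8 * ph$sex, tolerance = 1e-6)

  # planted effect recovered by the normal-equations oracle
  cfg2 <- tiny_config(n = 5000, mafs = c(0.05, 0.2, 0.45), seed = 6,
                      causal = c("2" = 15))
  g2 <- simulate_genotypes(cfg2)
  ph2 <- simulate_phenotype(g2$genotypes, cfg2)
  fit <- ols_oracle(ph2$fxi_pct,
                    cbind(1, g2$genotypes[, 2], ph2$age, ph2$sex))
  expect_lt(abs(fit$beta[2] - 15), 1.5)

  # CLT: sample mean near mu when covariate effects are off
  cfg3 <- tiny_config(n = 5000, seed = 7, mu = 120, sigma = 30,
                      beta_age = 0, beta_sex = 0)
  g3 <- simulate_genotypes(cfg3)
  ph3 <- simulate_phenotype(g3$genotypes, cfg3)
  expect_lt(abs(mean(ph3$fxi_pct) - 120), 2)
})

test_that("phenotype residuals are Gaussian once the linear predictor is removed", {
  ok <- vapply(1:10, function(s) {
    cfg <- tiny_config(n = 5000, seed = s, causal = c("1" = 10))
    g <- simulate_genotypes(cfg)
    ph <- simulate_phenotype(g$genotypes, cfg)
    res <- ph$fxi_pct - (cfg$mu + cfg$beta_age * ph$age +
                           cfg$beta_sex * ph$sex + 10 * g$genotypes[, 1])
    stats::shapiro.test(res)$p.value > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("simulation is reproducible and validates its configuration", {
  cfg <- tiny_config(seed = 8)
  expect_identical(simulate_genotypes(cfg)$genotypes,
                   simulate_genotypes(cfg)$genotypes)
  expect_error(tiny_config(mafs = c(0.6, 0.1)), "MAF")
  expect_error(tiny_config(rho = 1), "rho")
  expect_error(tiny_config(sigma = 0), "sigma")
  expect_error(simulate_phenotype(matrix(0, 5, 3), tiny_config(n = 10)),
               "match")
})

test_that("tail selection respects ranges, counts and seed", {
  ph <- data.frame(id = sprintf("i%03d", 1:300),
                   fxi_pct = seq(30, 260, length.out = 300))
  des <- tail_design()
  ids <- select_tails(ph, des, seed = 9)
  expect_length(ids, 40)
  vals <- ph$fxi_pct[match(ids, ph$id)]
  expect_true(all((vals >= 36 & vals <= 80) | (vals >= 158 & vals <= 250)))
  expect_identical(sum(vals <= 80), 20L)
  expect_identical(ids, select_tails(ph, des, seed = 9))

  # shortfall is an explicit error
  few <- data.frame(id = c("a", "b", "c"), fxi_pct = c(50, 60, 200))
  expect_error(select_tails(few, tail_design(n_low = 3, n_high = 1)),
               "shortfall")

  # property: never an id outside the configured ranges
  for (s in 1:5) {
    ids <- select_tails(ph, des, seed = s)
    vals <- ph$fxi_pct[match(ids, ph$id)]
    expect_true(all((vals >= 36 & vals <= 80) | (vals >= 158 & vals <= 250)))
  }
})

test_that("cohort assembly from a pool always satisfies the tail design", {
  cfg <- sim_config(n_individuals = 110, seed = 12)
  co <- simulate_cohort(cfg, tail_design(), pool_size = 935)
  expect_identical(nrow(co$genotypes), 110L)
  ph <- co$phenotypes
  expect_gte(sum(ph$fxi_pct >= 36 & ph$fxi_pct <= 80), 20)
  expect_gte(sum(ph$fxi_pct >= 158 & ph$fxi_pct <= 250), 20)
})

test_that("discovery detection power follows 1 - (1 - maf)^(2n)", {
  expect_equal(detection_power(0.05, 40), 1 - 0.95^80)
  expect_gt(detection_power(0.05, 40), 0.98)
  expect_identical(detection_power(0, 40), 0)
  expect_equal(detection_power(0.5, 1), 0.75)
  expect_error(detection_power(0.7, 40), "maf")
  expect_error(detection_power(0.05, 0), "n")
})

test_that("VCF round trip preserves dosages, positions and missingness", {
  set.seed(10)
  g <- matrix(sample(c(0:2, NA), 50, replace = TRUE), nrow = 5,
              dimnames = list(sprintf("s%d", 1:5), NULL))
  variants <- data.frame(variant_id = sprintf("chr3_%d", 1:10 * 100),
                         chrom = "chr3", pos = as.integer(1:10 * 100),
                         ref = "A", alt = "G",
                         dbsnp_id = c("rs1", rep(NA, 9)))
  colnames(g) <- variants$variant_id
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g, variants, path)
  back <- read_vcf(path)
  expect_identical(unname(back$genotypes), unname(g))
  expect_identical(back$variants$pos, variants$pos)
  expect_identical(back$variants$dbsnp_id[1], "rs1")
  expect_true(is.na(back$variants$dbsnp_id[2]))

  # header-only VCF for an empty variant list
  p2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g[, 0, drop = FALSE], variants[0, ], p2)
  expect_identical(sum(!startsWith(readLines(p2), "#")), 0L)
})
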