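---
title: "Methods: tail-sampled association analysis of FXI-level loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tail-sampled association analysis of FXI-level loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fxiloci)
```

## The analysis problem

Plasma coagulation Factor XI (FXI) activity is a heritable quantitative
trait — an *intermediate phenotype* correlated with venous-thrombosis
liability and statistically closer to gene action than the disease state
itself. `fxiloci` implements a complete targeted-resequencing dissection of
two FXI-level loci, KNG1 (chr3, 25,581 bp) and F11 (chr4, 23,718 bp), for a
cohort of unrelated individuals:

1. a **tail-sampled discovery design**: a 40-individual subsample taken
   from the phenotype extremes (20 with FXI activity 36–80%, 20 with
   158–250%, against a clinical normal range of 55–185%) defines the
   "variants of interest"; with 80 chromosomes the probability of seeing at
   least one copy of an allele with MAF $f$ is $1-(1-f)^{80}$, which
   exceeds 0.98 at $f = 0.05$ (`detection_power()`);
2. **frequency stratification** at sample MAF 10% (inclusive on the common
   side), because single-variant tests are well powered for common
   variants while low-frequency variants need set-based collapsing;
3. **VIF-based LD pruning** within each stratum, windows of 30 variants
   advancing by 3, removing variants whose variance inflation factor
   $\mathrm{VIF} = 1/(1-R^2)$ exceeds 2 (i.e. multiple $R^2 > 0.5$);
4. a **covariate-adjusted single-variant linear model** for common
   variants, $y = \alpha_0 + \beta g + \alpha_1 \mathrm{age} + \alpha_2
   \mathrm{sex} + \varepsilon$, with six family-wise/FDR corrections and
   LD **clumping** of nominally significant hits into independent signals;
5. a **variance-component kernel (SKAT-style) score test** on sliding 2-kb
   sets of low-frequency variants, with min-p **permutation FWER control**
   and merging of overlapping significant sets into regions;
6. a **rule-based screen** for putative pathogenic mutations plus the
   percent-change consensus arithmetic over external splice-prediction
   scores.

Because no individual-level data are deposited for this design, the package
ships a first-class synthetic-data module; every downstream stage is
exercised end-to-end on generated cohorts.

## The synthetic cohort generator

`simulate_genotypes()` draws haplotypes from a latent Gaussian copula.
Within an LD block the latent variables follow an AR(1) process; each is
thresholded at the normal quantile of the variant's target MAF and two
haplotypes are paired per individual. The block correlation parameter
$\rho$ is expressed on the allele-correlation scale: the latent correlation
used is $\sin(\pi\rho/2)$, the tetrachoric inverse, which is exact for
median-split variants (MAF 0.5) and counteracts most of the dichotomization
attenuation at lower MAFs. Positions are drawn uniformly without
replacement within each locus span; a single global seed drives all draws
through fixed per-stage substreams, so each stage is independently
reproducible.

Default study conditions: $n = 110$ unrelated individuals; 504 + 258 = 762
biallelic variants across the two printed GRCh37 locus spans; 41% of
variants drawn from the common part of the MAF spectrum (uniform on
[0.10, 0.50]) and the rest skewed toward rarity (scaled Beta(0.6, 1.6) on
(0, 0.10), floored at one expected carrier chromosome); AR(1) blocks of 25
variants with $\rho = 0.8$.

The phenotype is additive:
$y_i = \mu + \beta_{\mathrm{age}}\,\mathrm{age}_i +
\beta_{\mathrm{sex}}\,\mathrm{sex}_i + \sum_j \beta_j g_{ij} +
\varepsilon_i$, $\varepsilon \sim N(0, \sigma^2)$. The generative
parameters are not fixed by any published table, so they were chosen once
on clinical grounds and not revisited: $\mu = 103$% with age drawn
uniformly on [18, 80] years ($\beta_{\mathrm{age}} = 0.3$ %/year) and sex
Bernoulli(0.5) ($\beta_{\mathrm{sex}} = 5$%) centres the cohort near 120%,
the midpoint of the 55–185% clinical normal range; the residual SD
$\sigma = 45$% is deliberately wide because the emulated cohort is drawn
from thrombophilia families enriched for phenotype extremes, not from a
general population. The default causal configuration
(`default_causal()`) plants one common variant at 12% activity per allele
— comparable to the large common-variant effects reported at these loci —
and two adjacent low-frequency variants at 25% per allele, so that both
analysis arms have signal to find.

A plain normal cohort of 110 cannot reliably contain 20 individuals in
each tail window, for any residual SD — the windows are bounded on both
sides and their normal mass peaks below 18%. The study design itself
solves this: the sequenced cohort was assembled from a much larger family
project. `simulate_cohort()` reproduces that step — it simulates a pool
(default 935 individuals), selects the 20 + 20 tails, and fills the cohort
to 110 with a random draw from the rest. The tail design is then always
satisfiable, at the cost of mild enrichment of causal-allele frequencies
relative to their targets, exactly as in a real tail-enriched
resequencing cohort.

What the generator does **not** emulate: read-level sequencing error,
genotype missingness patterns (missingness is supported in all consumers
but not generated by default), family structure, mutation-age/frequency
coupling beyond the chosen MAF spectrum, and recombination-distance decay
of LD (blocks are exchangeable AR(1), not genetic-map based). Passing
tests therefore demonstrate the statistical machinery under a controlled
LD/MAF regime, not robustness to real-data artefacts.

## VIF pruning and clumping

Pruning windows are defined in variant counts (30/3), matching the printed
parameters. Within a window the VIF of every variant is read off the
diagonal of the inverse correlation matrix — equivalent to regressing each
variant on all others — and the worst variant is removed while any VIF
exceeds 2. Two choices were genuinely open:

* **Removal order**: the largest-VIF variant is removed first, ties broken
  toward keeping the higher-MAF, earlier-position variant, which keeps the
  most informative variant of a redundant pair.
* **Window bookkeeping**: windows are taken over the *currently retained*
  sequence and full passes repeat until a fixpoint. A single pass over the
  original indices can leave retained pairs that were never jointly
  windowed; the fixpoint construction guarantees the post-hoc audit (every
  window of the output has max VIF ≤ 2 + ε) and idempotence.

Multiple-regression $R^2$ uses mean-imputed missing dosages within the
window (`impute = FALSE` switches to complete-case columns).

Clumping greedily picks the most significant unassigned variant as an
index and absorbs variants with $r^2 \ge 0.5$ within 250 kb. Both p-value
thresholds default to 0.05 so that every nominally significant variant can
either join a clump or head its own independent signal; with a
stricter index threshold the weaker signals would be reported as
"unclumped" rather than as independent signals, which is not how the
signal count is quoted in this design.

## Single-variant association

`fit_linear()` is OLS of phenotype on `[1, g, age, sex]`, complete-case
per variant, with the dosage recoded so the reported $\beta$ is per copy
of the *sample minor allele* (a `tested = "alt"` mode keeps the ALT dosage
as given; in that mode recoding $g \to 2-g$ flips the sign of $\beta$ and
leaves $p$ unchanged). The adjustment family size `m` defaults to the
number of variants actually tested — the post-pruning common set — and is
exposed because the printed worked example (raw $p = 8\times10^{-5}$
adjusting to 0.010) corresponds to $m = 125$.

Six corrections are provided: Bonferroni, Holm, Šidák single-step
($1-(1-p)^m$), Šidák step-down, Benjamini–Hochberg and
Benjamini–Yekutieli. Bonferroni/Holm/BH/BY delegate to `stats::p.adjust`;
the two Šidák variants are computed directly since `p.adjust` does not
offer them.

## The kernel set test

For a set with dosage matrix $G$ and weight matrix $W =
\mathrm{diag}(w_j)$, the score statistic is
$$Q = r^\top G W^2 G^\top r,$$
where $r$ are the OLS residuals of the covariate-only null model. Under
the null, $Q \sim \sum_k \lambda_k \chi^2_1$ with $\lambda_k$ the
eigenvalues of $\hat\sigma^2\, W G^\top P_0 G W$, $P_0$ the projection
onto the covariate residual space. Weights default to the conventional
Beta(1, 25) density on sample MAF (weight 25 at MAF → 0, ≈ 1.99 at 0.1);
flat weights are available, and the choice is recorded in the run
manifest because it is a genuine free parameter of the method.

The mixture tail probability is evaluated by numerical inversion of the
characteristic function (the Imhof integral), computed with adaptive
quadrature after rescaling the eigenvalues by their maximum; a single
eigenvalue reduces to the exact $\chi^2_1$ tail. When the quadrature
fails to converge or leaves $[0,1]$ — which happens in the far tail,
roughly $p < 10^{-6}$ — the Liu moment-matching approximation
(chi-square with matched skewness/kurtosis) is used instead and the
fallback is flagged in the output. Monte-Carlo checks in the test suite
hold the inversion to within 15% relative error of a 100,000-draw oracle
for $p \ge 10^{-4}$.

Degenerate inputs are defined, not errors: an all-monomorphic set returns
$Q = 0$, $p = 1$ with a `monomorphic` flag; constant columns contribute
zero eigenvalues, which are trimmed at a relative tolerance of $10^{-10}$.

### Sliding 2-kb windows

One window per low-frequency variant, spanning `[pos, pos + 2000]`
(1-based, inclusive at both edges — the membership rule at the right edge
is not dictated by anything printed, so the inclusive convention was
chosen and is stated here). Anchoring windows at variants rather than
sliding by base pairs reproduces printed windows whose endpoints differ by
exactly the inter-anchor spacings. Windows never span chromosomes.

### Permutation FWER control

Westfall–Young single-step min-p: the phenotype vector is shuffled across
individuals `B` times (default 1,000; genotypes and the
covariate-to-individual pairing stay fixed, preserving the LD structure
among variants), the null model is refit per permutation, every set's
p-value is recomputed, and the per-permutation minimum is recorded. The
empirical p-value of set $s$ is $(1 + \#\{b: \min_b \le p_s\})/(B+1)$ —
never exactly zero — and a set is FWER-significant at `alpha` when that is
≤ `alpha`. The minimum is taken across all sets of the run (both loci
jointly). A residual-permutation (Freedman–Lane) variant is available via
`scheme = "residual"` for designs with strong covariate effects.

One computational design choice matters here: inside the permutation
comparison, both the observed and the permuted set p-values are computed
with the Liu approximation. The comparison only requires a common monotone
transform of the set statistics, and the adaptive-quadrature inversion is
three orders of magnitude more expensive — prohibitive at
`sets × B` evaluations. The analytic p-values reported per set are
unaffected (still Imhof-with-fallback), and the `p_comparison` column
records exactly what the permutation procedure compared. Simulation under
a global null (100 cohorts of $n = 110$ with ~60 low-frequency variants
in strong LD) puts the realized FWER at ≈ 0.04–0.09 for a level of 0.05,
within two binomial standard errors of the level.

### Region merging

Significant windows (nominal tier: analytic $p < \alpha$; FWER tier: the
permutation flag) are unioned into maximal disjoint intervals per
chromosome by a position sweep. The operation is idempotent and
order-independent; BED exports convert the internal 1-based inclusive
intervals to 0-based half-open.

## Pathogenic-candidate screen

Three rules, all evaluated for every variant so the audit trail is
complete: (a) *rarity* — every supplied reference-panel AF < 1%, with
absence from a panel counting as rare in that panel (an unannotated
variant cannot be declared common by a panel that has never seen it);
(b) *location* — intronic variants more than 30 bp from the nearest exon
boundary are rejected; (c) *fallback* — variants absent from the primary
panel must have sample MAF < 5%. Tightening any threshold can only shrink
the candidate set (tested as a monotonicity property).

Splice-score consensus uses the unrounded percent change
$100(\mathrm{mut}-\mathrm{nat})/\mathrm{nat}$ per algorithm and flags a
variant when the magnitude exceeds 10% for at least two algorithms.
Reported deltas are rounded half-up to one decimal; counting uses the
unrounded values, since printed one-decimal scores can recompute a tenth
off. External predictor scores are consumed as inputs only — the package
implements no splice or missense predictor.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations to run on
a single CPU in minutes: null-calibration uses 1,000 single-set
replicates at $n = 110$; FWER calibration uses 100 cohorts of one 12-kb
locus with ~60 low-frequency variants and `B = 500`; power checks use 50
cohorts with one planted low-frequency variant at 2 residual SD per
allele (detected after permutation in well over half of replicates).
Tolerances: eigenvalues trimmed at $10^{-10}$ relative; VIF audit at
$+10^{-8}$; OLS agreement with the normal-equations oracle at $10^{-8}$;
quadrature at relative tolerance $10^{-4}$ with the fallback path
logged.

## Known limitations

* The permutation comparison p-value is the Liu approximation; in regimes
  where Liu's ordering of extreme sets differs from the exact mixture
  tail, the min-p ranking could shift marginally.
* Single-step min-p is used (not the step-down variant), matching the
  single reported adjustment; it is slightly conservative for
  non-extreme sets.
* The latent-copula LD model produces exchangeable block correlation, not
  map-distance decay; realized $r^2$ attenuates below the nominal $\rho$
  for rare variants.
* The screen carries missense predictor verdicts as annotations only and
  performs no co-segregation analysis.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_individuals = 110, seed = 1)
cfg$causal <- default_causal(cfg$maf, seed = 1)
rc <- run_config(sim = cfg, outdir = "fxiloci_demo", B = 1000L, seed = 1)
res <- run_pipeline(rc)
make_report("fxiloci_demo")
```
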