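---
title: "Clinically guided gene-based association: models, weights, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clinically guided gene-based association: models, weights, and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skatpipe)
```

## The problem and the pipeline

Rare-variant association studies face a dimensionality problem: cohorts of
tens to hundreds of clinically characterized patients are genotyped at
hundreds of thousands of sites, and variant-by-variant testing at that scale
has essentially no power for rare alleles. skatpipe implements a four-stage
strategy for this setting:

1. **Clinical screen** (`functional_analysis()`): every variant is tested
   one at a time against the clinical outcome — Fisher's exact or Pearson
   chi-square allelic tests, the Cochran–Armitage trend test, logistic or
   linear regression with covariates, or log-rank / Cox models for survival
   outcomes — under an additive, dominant or recessive genetic coding.
   Variants with `p < threshold` (default 0.05) form the clinically
   relevant subset carried forward. This is deliberately a liberal filter:
   its purpose is dimension reduction toward clinically associated sites,
   not genome-wide discovery.
2. **Annotation** (`map_snps_to_genes()`, `ora_test()`): the retained
   variants are mapped to every gene whose interval contains them
   (optionally padded by `flank_bp`), and the mapped gene list is tested
   for gene-set over-representation with the upper-tail hypergeometric
   test, Benjamini–Hochberg adjustment, and a Storey q-value.
3. **Collapsing weights** (`get_logistic_weights()`): each variant receives
   a weight from its minor allele frequency in an external reference
   population, rather than from the study sample itself. The logistic
   weight is
   $$w(\mathrm{MAF}) = \frac{e^{-x}}{1+e^{-x}}, \qquad
     x = (\mathrm{MAF} - W_1)\,W_2,$$
   with defaults $W_1 = 0.07$, $W_2 = 150$: a smooth switch that is 0.5 at
   MAF = 7%, above 0.99 below ~3.7% and below 0.01 above ~10.3%. Using an
   external panel avoids the selection bias (and type-I inflation) of
   estimating rarity from the same data being tested. The
   Beta(1, 25)-density weighting conventional in kernel association tests
   is available as an alternative (`beta_weight()`).
4. **Gene-level kernel test** (`skat_assoc()`): per gene unit, the sequence
   kernel association test. With null-model residuals
   $r = y - \hat\mu$ (logistic or linear fit on covariates only), genotype
   submatrix $G$ and weights $W = \mathrm{diag}(w_j)$, the score statistic
   is $Q = r^\top G W^2 G^\top r$ (divided by $\hat\sigma^2$ for continuous
   outcomes). Under the null, $Q$ is distributed as a weighted mixture
   $\sum_j \lambda_j \chi^2_{1,j}$, where the $\lambda_j$ are eigenvalues
   of $W G^\top P_0 G W$ with $P_0$ the variance/projection matrix of the
   null model ($V - VX(X^\top V X)^{-1}X^\top V$ with
   $V = \mathrm{diag}(\hat\mu_i(1-\hat\mu_i))$ for a dichotomous outcome;
   $I - X(X^\top X)^{-1}X^\top$ for a continuous one).

`run_pipeline()` chains the four stages from one YAML config and records a
manifest of counts, the seed, and any approximation fallbacks.

## Parameters that matter

| parameter | default | units / meaning |
|---|---|---|
| `threshold` (stage 1) | 0.05 | per-variant p-value cutoff for the clinical screen |
| `model` | `"add"` | genetic coding: 0/1/2 copies, carrier, or homozygote |
| `flank_bp` (stage 2) | 0 | bp added to each gene interval before overlap |
| `w1`, `w2` (stage 3) | 0.07, 150 | logistic weight midpoint (MAF units) and slope |
| `fallback` (stage 3) | `sample_maf` | policy for variants absent from the reference panel |
| `out_type` (stage 4) | `"D"` | dichotomous (logistic null) vs continuous (OLS null) |
| `sig_val`, `geno_val` | 3, 5 | plot threshold lines, in −log10(p) units |

The weight-function defaults place the rare/common transition at 7% MAF;
changing `w1` moves the midpoint, `w2` controls how sharp the switch is
(the weight is exactly 0.5 at `w1` for any `w2`, and
`w(w1+d) + w(w1-d) = 1`). SKAT p-values are invariant to rescaling all
weights by a constant, so only the *shape* of the weight function matters.

Allele orientation between user genotypes and external MAF panels is
reconciled by exact (chrom, pos, ref, alt) lookup, then a retry with
ref/alt swapped (the stored frequency is already folded to the minor
allele, so no re-folding is needed). Variants still unmatched follow the
`fallback` policy; the default substitutes the in-sample MAF with a
warning, because silently dropping variants would change the marker counts
of downstream gene units.

## Mixture-of-chi-square tail probabilities

`quadform_tail()` exposes three engines for
$p = P(\sum_j \lambda_j \chi^2_{1,j} > q)$:

* **davies** (default): numerical inversion of the characteristic function
  in Imhof form,
  $p = \tfrac12 + \tfrac1\pi \int_0^\infty
  \frac{\sin\theta(u)}{u\,\rho(u)}\,du$. The envelope decays like
  $u^{-(1+m/2)}$, which defeats infinite-range quadrature when only two or
  three eigenvalues dominate, so the integral is evaluated on a finite
  interval $[0, U]$ with an analytic first-order integration-by-parts
  correction for the tail; $U$ is grown until the second-order remainder
  bound falls below tolerance. Degenerate mixtures (one distinct
  eigenvalue) reduce to exact chi-square tails. For $p < 10^{-7}$, where
  an absolute quadrature tolerance limits *relative* accuracy, the exact
  Ruben representation — $Q/\beta$ as a mixture of central
  $\chi^2_{m+2k}$ variables with nonnegative weights summing to one — is
  used instead whenever its series converges within 3000 terms (the
  truncation error is bounded by the unassigned mixture weight).
* **liu**: the four-moment noncentral chi-square match. It is fast and has
  accurate far tails, but at mid-range p-values it can deviate from the
  exact inversion by up to ~0.02 for skewed spectra regardless of the
  number of eigenvalues; it is therefore only a recorded fallback (the
  `method` column of `skat_assoc()` output says when it was used).
* **montecarlo**: direct simulation of the mixture, used as an independent
  oracle in the test suite, never in analysis paths.

## The null model, QC, and missing data

The null model is fit once per phenotype (logistic IRLS or OLS on
covariates only); each gene reuses its residuals and variance structure.
Within a gene, missing dosages are mean-imputed to twice the in-sample MAF
(complete-case analysis is available by flag), and variants monomorphic
after imputation are dropped — `N.Marker.All` counts the unit's variants
present in the genotype data, `N.Marker.Test` the post-QC survivors. In
stage 1, missingness is handled per variant by complete-case analysis, and
`NMISS` reports the non-missing sample count actually used, following the
convention of mainstream GWAS tooling. The missing-genotype sentinel is an
explicit `NA` throughout; no test ever sees missingness coded as a value.

Further numerical choices: allelic 2×2 tests treat each non-missing
genotype as two independent alleles (a Hardy–Weinberg assumption,
matching standard GWAS allelic tests); the chi-square test applies no
continuity correction by default; Fisher's two-sided p uses the
point-probability rule; odds ratios for tables with an empty cell are
reported with the Haldane–Anscombe +0.5 correction while p-values are left
untouched; negative numerical eigenvalues below `1e-10 × max` are clipped
to zero; ties in minor-allele determination (MAF exactly 0.5) keep the
input file's counted allele.

## What the synthetic cohorts do and do not emulate

`sim_spec()` / `make_fixture_suite()` generate the complete input bundle —
PLINK trio, matching VCF, phenotype CSV, gene BED, GMT sets, SetID, and a
reference MAF table. Genotypes are independent Hardy–Weinberg draws
(`dosage ~ Binomial(2, MAF)`), optionally with block-LD via Markov allele
copying so that LD heatmaps have structure; phenotypes follow a logistic,
linear, or exponential-survival model on the genotypes plus sex and age
covariates. Reference MAF tables are the generating MAFs perturbed by
binomial resampling at a configurable panel size, emulating an imperfect
external population.

Defaults were fixed once: 500 samples with ~50% cases (mirroring a
severity-split clinical cohort), MAF uniform on (0.005, 0.35), 2% missing
dosages, and for the full fixture 5000 variants in 100 genes. What the
generator does **not** emulate: realistic coalescent LD and allele-frequency
spectra, population stratification, genotyping batch effects, or
imputation-quality artifacts. Passing calibration on these fixtures
therefore demonstrates correctness of the statistics under their stated
assumptions, not robustness to confounding in real cohorts.

The test suite's problem sizes — 1000–10,000 null variants at n = 500 for
scan calibration, 2000 null genes for kernel-test calibration, 50
replicates per effect size for the power ordering — were chosen as the
smallest sizes at which the binomial/KS acceptance bands are informative.

## Design decisions on open points

* **Filter-then-test is the method, selection bias included.** Stage 4
  tests gene units built from variants already selected on the same
  outcome. The power-ordering simulation shows the expected gain from the
  pre-filter, and under the null it equally shows the inflation such
  double use of the data produces. The package makes no calibration claim
  for the filtered route; the external-panel weights exist precisely so
  that at least the *weighting* introduces no such bias.
* **Permutation vs analytic p-values.** For a continuous outcome the
  permutation distribution of Q matches the eigenvalue mixture closely and
  the two agree within permutation sampling error. For a dichotomous
  outcome with rare variants the exact permutation null has discrete atoms
  that a continuous mixture cannot reproduce near p ≈ 1; disagreements
  there (observed up to ~0.06 at p ≈ 0.97) are a property of the
  asymptotic approximation, in its conservative region, not an
  implementation error.
* **Allelic-orientation reconciliation** between genotypes and MAF panels
  (the swap-and-fold retry) is this package's policy; upstream conventions
  differ and no single rule is universal.
* **The trend test** is exposed as `method = "trend"` although the
  four-stage menu traditionally lists only fisher/chisq/lm/glm/
  survfit/coxph.
* **Multi-allelic VCF records** are rejected by default (split them
  upstream, or pass `allow_multi = TRUE` to treat any non-reference allele
  as the alternate).
* **q-values** use Storey's estimator with a λ grid 0.05–0.95 and a
  smoothing spline for π₀; q-values from other implementations will differ
  slightly in π₀ and are not an exactness target.
* **out_type** follows the SKAT convention: `"D"` = dichotomous
  (logistic null), `"C"` = continuous (linear null).

## Known limitations

No SKAT-O style burden/kernel combination; no small-sample moment
adjustment for very small cohorts (n ≲ 100 dichotomous analyses will be
conservative); no related-sample or mixed models; no phased/dosage
genotype support; BGEN/PGEN formats are out of scope. Gene annotation and
gene sets come from user-supplied BED/GTF/GMT files — there is no built-in
genome annotation, and results inherit whatever identifier scheme those
files use.
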