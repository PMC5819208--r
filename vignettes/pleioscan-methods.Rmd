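---
title: "Methods: multi-trait pleiotropy scanning with pleioscan"
author: "pleioscan maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-trait pleiotropy scanning with pleioscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Alzheimer's disease neuropathology is measured on autopsied brains as
several correlated but distinct quantities: neuritic plaque burden (NP,
a 4-level CERAD grade), neurofibrillary tangle distribution (NFT, a
4-level Braak stage), and presence of cerebral amyloid angiopathy (CAA, a
binary finding). A variant that shifts two of these traits jointly may be
detectable even when each univariate genome-wide scan falls short of
significance. `pleioscan` implements a joint-testing pipeline over
per-trait GWAS summary statistics: no individual-level genotypes are
needed for the scan itself, only per-SNP effect estimates and standard
errors per trait, plus a reference genotype panel for the gene-based
stage.

## The combined statistic

For one SNP, let $z = (z_1, \dots, z_K)'$ be the signed Wald statistics
($z_k = \beta_k / \mathrm{se}_k$) for the $K$ traits in a subset. Under
the global null of no association with any trait, $z \sim N(0, \Sigma)$
where $\Sigma$ captures the correlation of the test statistics induced by
phenotypic correlation on (partially) shared samples. The O'Brien
combined statistic with generalized-least-squares weights is

$$ T \;=\; \frac{\mathbf{1}'\Sigma^{-1} z}{\sqrt{\mathbf{1}'\Sigma^{-1}\mathbf{1}}}, $$

standard normal under the null; the equal-weights variant is
$T = \mathbf{1}'z / \sqrt{\mathbf{1}'\Sigma\mathbf{1}}$. Both are
implemented and the two coincide exactly whenever $\Sigma$ is
equicorrelated, which is the common case for a small set of traits
measured on one cohort — reporting both makes any discrepancy a
diagnostic rather than a silent choice. GLS is the default.

$\Sigma$ is estimated as the sample covariance of the aligned $M \times K$
Z matrix over all SNPs. Because the overwhelming majority of genome-wide
SNPs are null, this estimate is dominated by the null distribution; a
truncated mode restricted to rows with every $|z| < 2$ is exposed for
signal-dense inputs. The covariance — not the correlation — is used: the
per-trait null variances are close to, but not exactly, one, and dividing
them out would mis-calibrate the test. One algebraic caveat is worth
stating: $T$ computed from $c\Sigma$ equals $T(\Sigma)/\sqrt{c}$, so the
statistic is *not* invariant to rescaling $\Sigma$ in isolation; it is
equivariant in the self-consistent sense $T(\sqrt{c}\,z, c\Sigma) =
T(z, \Sigma)$, which is what makes the overall scale immaterial when
$\Sigma$ is estimated from the same Z matrix the scan runs on. For a
single-trait subset the scan short-circuits to $T = z$ so the joint
p-value reduces exactly to the univariate one.

P-values are computed and stored in log10 space
(`pnorm(..., log.p = TRUE)`), so statistics as large as $|z| = 40$ retain
a finite, accurate $-\log_{10} p \approx 349.4$ where the natural-scale
number underflows double precision.

## The pleiotropy declaration rule

A SNP is declared pleiotropic for a trait subset when

1. $p_\text{joint} \le p_{\text{univ},k} / 10$ for **every** member trait
   $k$ (the joint evidence is at least one order of magnitude stronger
   than each univariate result), and
2. every $p_{\text{univ},k} < 0.05$ (each trait is at least nominally
   associated).

It is genome-wide-significant pleiotropic when additionally
$p_\text{joint} < 5\times 10^{-8}$. The magnitude comparison is
non-strict ($\le$) and the factor (10), nominal level, and GWS threshold
are all arguments. Comparisons run in log10 space. The bundled
worked-example table (`workedExampleLoci()`) exercises every branch of
this rule on published results for two loci; exactly two of the six
(SNP, pair) combinations come out genome-wide-significant pleiotropic.
This rule is deliberately strict: when the two univariate statistics are
unequal — the typical case under noise — the joint p rarely beats the
*stronger* univariate p by a full order of magnitude unless the shared
signal is substantial.

## Diagnostics

`genomicLambda()` is the classic genomic-control factor: the median
association $\chi^2_1$ divided by its null median ($\approx 0.4549$).
An optional exclusion window exists for dominant loci; the default
coordinates offered by `apoeRegion()` are chr19:44.4–46.5 Mb (GRCh37),
a deliberate over-cover of the APOE locus since only the region, not
exact coordinates, is conventionally specified. `qqTable()` pairs sorted
observed p-values with uniform $i/(n+1)$ expected quantiles on the
$-\log_{10}$ scale.

## Gene-based testing

The VEGAS-style gene test assigns to each gene every SNP within 30 kb of
the transcript span (inclusive bounds, 1-based inclusive coordinates
throughout; BED input is converted on read). The observed statistic is
$Q = \sum_j F^{-1}_{\chi^2_1}(1 - p_j)$ over the gene's SNPs, and its
null distribution is simulated as $Q^* = \sum_j z_j^{*2}$ with
$z^* \sim N(0, R)$, $R$ the Pearson correlation of reference-panel
dosages (0–2 scale; $r$, not $r^2$ or $D'$, is what parameterizes the
multivariate normal). $R$ is shrunk linearly toward the identity by the
smallest intensity that lifts its minimum eigenvalue to $10^{-8}$, so
near-duplicate SNPs never break the factorization.

The empirical p-value is the never-zero estimator
$(b + 1)/(N + 1)$, where $b$ counts simulated $Q^* \ge Q$. Simulation
escalates through stages (default $10^3, 10^4, 10^6$) and stops as soon
as 10 exceedances have accumulated — small p-values get the full
$10^6$-simulation ceiling, where zero exceedances floor the p-value at
$\approx 1.0\times 10^{-6}$, while unremarkable genes cost almost
nothing. The staging rule is this package's declared behaviour (the
classical tool's internal stopping rule is not documented); per-gene
seeds are derived deterministically from the run seed, so results are
exactly reproducible. Significance across genes uses Bonferroni
(0.05/18,500 genes $\approx 2.7\times10^{-6}$ at genome scale).

## Expression models

`dgeLm()` is ordinary least squares of (already-normalized) expression on
AD status plus a named covariate set; negative coefficients mean lower
expression in cases. Two presets mirror common brain-expression designs:
`"mayo_rnaseq"` (age at death, sex, RIN, tissue source, flow cell) and
`"geo_microarray"` (RIN, PMI, batch, preservation, pH, age, sex), each
optionally augmented with five CNS cell-type markers (ENO2, GFAP, CD68,
OLIG2, CD34) to absorb disease-driven shifts in cell composition.
`eqtlLm()` regresses expression on SNP dosage with the eQTL covariate set
(status, APOE-ε4 dosage, age, sex, plate, RIN, adjusted RIN), dropping
the status covariate inside case or control strata. Normalization (CQN,
array pipelines) is upstream of this package by contract: the inputs are
normalized matrices.

The "adjusted RIN" covariate is printed in the source design as
"RIN − RINmean²", which is ambiguous; the default here is the centered
quadratic $(\mathrm{RIN} - \overline{\mathrm{RIN}})^2$ — a standard way
to let RIN act curvilinearly — with the verbatim reading
$\mathrm{RIN} - \overline{\mathrm{RIN}}^2$ selectable. Missing covariates
are handled by listwise deletion with `n_used` reported; rank-deficient
designs error and name the collinear columns rather than silently
dropping them.

## The synthetic-data generator

The generator exists so every stage can be tested end to end with known
truth; its defaults are the study conditions the tests run under.

**Genotypes.** Haplotypes are thresholded latent Gaussians: AR(1)
correlation `rhoWithin` (default 0.8) inside blocks of 50 SNPs,
independent across blocks, MAF drawn uniformly on (0.01, 0.5). An allele
is carried when the latent exceeds the MAF quantile; dosage is the sum of
two independent haplotypes, hence Hardy–Weinberg at the drawn MAF.
Thresholding attenuates the latent correlation (most strongly for
asymmetric MAF pairs), which is why dosage LD is always measured, never
assumed, in the tests.

**Traits.** A liability-threshold model: per-trait liability is
standardized-dosage causal effects plus a trivariate Gaussian residual.
NP and NFT are cut at the quartile thresholds into levels 0–3; CAA is
dichotomized at 0 (prevalence 0.5 — a round value typical of AD-enriched
autopsy series, chosen once; the source design reports no CAA
prevalence). The latent residual correlations are *calibrated* — via
bivariate-normal rectangle probabilities computed by one-dimensional
quadrature and root-finding — so the realized Pearson correlations of
the categorized scores hit the targets 0.68 (NP–NFT), 0.56 (NP–CAA) and
0.40 (NFT–CAA); without calibration, categorization attenuation would
leave the realized correlations ~10% short. AD/control status labels a
fraction 0.87 of subjects as cases by thresholding a noisy composite of
the three liabilities, mimicking a case-enriched autopsy series. The
Pearson-on-scores estimand is an interpretation choice: the targets are
treated as correlations of the realized grades.

**Per-SNP fits.** Summary statistics come from a cumulative-logit
(proportional-odds) regression for the ordinal traits and a logistic
regression for CAA, one SNP at a time. These fits use an in-package
Newton–Raphson with analytic gradient and Hessian (warm-started at the
marginal cutpoints): it matches `MASS::polr` to ~6 decimal places in the
tests but runs an order of magnitude faster, which is what makes a
20,000-SNP × 3-trait study take ~3 minutes on one core instead of ~30.
Separation and non-convergence drop the SNP with a report rather than
crashing. No population structure is simulated, so no principal
components enter the fits (a documented divergence from real-cohort
practice, where ancestry PCs are standard).

**Causal architecture.** The default study plants 10 dual-effect SNPs
(liability effect 0.18 SD on both NP and NFT) and 10 matched single-trait
SNPs (0.18·√2 on NP alone — the same total squared effect), each in a
distinct LD block with MAF ≥ 0.1. The 0.18 figure comes from a design
power analysis: it puts univariate |z| near 5–7 at n = 2000, the regime
where the order-of-magnitude rule can fire for shared effects while
single-trait SNPs — whose second-trait z is pure noise — essentially
never qualify. Ground truth (SNP, per-trait effects, type) is stored in
the study object and serialized by `writeStudy()`, so any downstream
result can be joined to truth.

**What the generator does not emulate.** Real LD from a haplotype
reference, imputation uncertainty beyond a dosage-variance column,
population structure, age-of-onset processes, and between-study
heterogeneity of a meta-analysis. Passing tests therefore demonstrate
internal statistical correctness and calibration of the methods, not
robustness to those real-data features.

## Numerical choices

* Covariance estimates and LD matrices are symmetrized and, when needed,
  regularized by minimal diagonal inflation (eigenvalue floor
  $10^{-8}$ relative) or minimal shrinkage toward the identity.
* Cholesky is attempted first for multivariate-normal draws, with an
  eigendecomposition fallback for exactly singular (e.g. rank-1) LD.
* Harmonization keys SNPs by (chromosome, position); rsIDs are carried as
  annotation only. Swapped alleles flip the sign and complement the EAF;
  irreconcilable allele pairs and duplicated positions (multi-allelic
  sites) are dropped with counts. Strand-ambiguous A/T and C/G SNPs are
  kept and matched by letters by default (`dropAmbiguous = TRUE` to
  drop), since synthetic and harmonized modern data are strand-consistent.
* QC boundaries are inclusive exclusions: MAF ≤ 0.01, imputation
  R² ≤ 0.4, dosage variance ≤ 0.02 each remove the SNP; a missing
  optional QC column passes that rule (those filters are then assumed
  applied upstream).
* Input p-values are ignored and recomputed from β/SE so univariate and
  joint p-values share one convention.

## Problem sizes used by the tests

The suite runs null-calibration checks at $M = 10^5$ direct Z draws,
LD/MAF recovery at n = 5,000 subjects, the full end-to-end recovery study
at n = 2,000 × M = 20,000 with a reduced GWS threshold of $10^{-4}$
(appropriate to 20,000 rather than millions of SNPs), and expression
checks at 400 samples — sizes where every Monte-Carlo tolerance is set
from binomial or Kolmogorov sampling theory at 3-SE (or 0.1%-level)
bounds.

## Known limitations

* The scan tests association jointly; it does not estimate a joint
  effect size, and no colocalization or conditional analysis is
  attempted.
* The declaration rule inherits its strictness from the
  order-of-magnitude comparison against *every* member trait: power is
  concentrated on variants with comparably strong evidence in all traits.
* Gene-based results depend on the reference panel matching the scanned
  population's LD; the package takes the panel as given.
* `correctMultiple()` is plain Bonferroni, matching the downstream
  analyses it mirrors; no FDR option is provided.
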