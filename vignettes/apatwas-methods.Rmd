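---
title: "Models and methods behind apatwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind apatwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apatwas)
```

Alternative polyadenylation (APA) lets one gene produce transcripts with
shorter or longer 3'UTRs, and the choice is partly genetic. `apatwas`
implements the full chain of analyses that connects that choice to disease:
quantifying 3'UTR usage from RNA-seq coverage, mapping the cis variants
that regulate it, building genetic predictors of usage, testing those
predictors against GWAS summary statistics, and asking whether the
molecular and disease signals share a causal variant. This vignette
explains each model, its assumptions, the tunable parameters, and the
choices made where the design was genuinely open.

## Quantifying 3'UTR usage (PDUI)

The observable is per-base read depth across a gene's 3'UTR. Under a
two-site APA model the expected depth is a step function: all transcripts
cover the region upstream of the proximal poly(A) site, and only the
distal (long-3'UTR) fraction covers the region downstream. The *percentage
of distal usage index* (PDUI) is that fraction — 1 means fully long, 0
fully short.

`fit_two_segment()` scans candidate breakpoints $P$ on a grid and models
each segment of each sample's profile as a normal with free mean and
variance. The fitted breakpoint maximises the summed profile
log-likelihood

$$\sum_{\text{samples}} \left[-\tfrac{n_1}{2}\log(\mathrm{RSS}_1/n_1)
  -\tfrac{n_2}{2}\log(\mathrm{RSS}_2/n_2)\right],$$

so one $P$ is shared by all samples while segment means and variances are
per-sample — the joint multi-sample design that makes low-coverage samples
borrow strength from the rest. Per-sample PDUI is
$\min(1, \max(0, \mu_{\text{dist}}/\mu_{\text{prox}}))$, a ratio of means
and therefore invariant to any per-sample depth rescaling.

Numerical choices worth knowing:

* **Variance floor** (`var_floor = 1e-8`): an exactly constant segment has
  zero RSS; flooring the per-base variance keeps the objective finite and
  makes the noiseless case exact — the true breakpoint is the unique grid
  point where *both* segments hit the floor.
* **Grid** (`step = 1`, `min_seg = 100`): UTRs are short enough that
  exhaustive 1-nt search is cheap; `min_seg` keeps both segments long
  enough for stable means. Ties in the objective break to the smallest
  $P$, so the fit is deterministic.
* **Coverage gates**: samples with mean region depth below `min_mean_cov`
  (default 20) get a missing PDUI and do not contribute to the fit; rows
  with fewer than `min_sample_fraction` (default 0.5) non-missing samples
  are dropped. Public per-sample coverage cutoffs for this family of
  methods are not standardised; both gates are exposed as configuration.
* A pure least-squares objective (`objective = "lss"`) is available; it
  differs only when per-segment variances differ strongly.

Coordinates follow one fixed convention: BED/bedGraph are 0-based
half-open, VCF positions 1-based, and coverage profiles are always
transcript-oriented (position 0 is the UTR 5' end; minus-strand profiles
are reversed genomic slices).

## Phenotype preparation

PDUI is bounded in $[0,1]$ and often skewed, so each transcript is
rank-based inverse-normal transformed ($\Phi^{-1}(r/(n+1))$, average ranks
on ties) — a choice that depends only on ranks and is therefore robust to
the bounded support. The covariate model is applied in a fixed, logged
order: residualize on known covariates plus genotype principal
components; estimate hidden factors on those residuals; residualize on the
hidden factors.

Hidden confounders are estimated by truncated SVD of the gene-standardised
residual matrix. This captures the broad structure (batches, technical
drift) that Bayesian hidden-confounder estimators such as PEER capture in
QTL pipelines, at a fraction of the cost; it will not reproduce PEER's
shrinkage of weak factors. The default factor count follows the
sample-size schedule commonly used in large expression-QTL studies
(15 below 150 samples, 30 to 249, 35 to 349, 60 from 350), exposed as
`hidden_k`. Genotype PCs use standardised dosages
($(g-2f)/\sqrt{2f(1-f)}$, mean-imputed) with PC signs fixed by the
largest-magnitude loading so results do not depend on the LAPACK build.
Missing PDUI cells are mean-imputed *only* inside the factor
decomposition; they stay missing for all inference.

## cis-3'aQTL mapping

Each transcript is tested against every variant within 1 Mbp of its 3'UTR
(closed interval) by simple linear regression on the residualized
phenotype — the two-stage design used by Matrix-eQTL-style mappers, which
lets 1000 permutation rounds reuse the residuals instead of refitting
covariates. The gene-level statistic is the minimum nominal p across cis
variants; permutations shuffle the phenotype, and the empirical p is
$(1+\#\{\text{perm} \le \text{obs}\})/(n_{\text{perm}}+1)$, which can
never be zero. No beta-approximation of the permutation null is applied:
the empirical p is reported as is. FDR control uses Storey q-values with
$\hat\pi_0$ estimated at a single $\lambda = 0.5$ (no spline smoothing —
robust at the gene counts used here), or Benjamini–Hochberg; with
$\hat\pi_0 = 1$ the two are identical. FDR is applied per run, and the
scope is recorded in the output metadata.

Two GWAS-overlap diagnostics are included. `annotate_qq()` plots the GWAS
p-value distribution of annotated SNP subsets with genomic inflation
$\lambda = \mathrm{median}(\chi^2)/0.4549$. `enrichment_or()` is a
deliberately *simplified* enrichment test — a Mantel–Haenszel odds ratio
across MAF strata on an LD-pruned background with a bootstrap CI — in
place of the full LD/distance-matched permutation machinery of dedicated
enrichment tools; its output is labelled `simplified-garfield`.

## Prediction models and the 3'aTWAS scan

For each transcript, cis heritability is estimated under the
single-component mixed model $y \sim N(0, \sigma^2_g K + \sigma^2_e I)$
with $K = XX'/m$ from standardised cis dosages. The likelihood is profiled
on the spectral decomposition of $K$, leaving a 1-D search over
$h^2 \in [0, 1-10^{-6}]$; the test against $h^2 = 0$ uses the boundary
mixture $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$. Transcripts failing the
gate (p ≥ 0.05) are not trained. The gate is nominal by default; a
Bonferroni mode (`gate_n_tests`) is provided because both conventions are
in circulation for this family of pipelines, and the package does not
adjudicate between them.

Three weight vectors are trained on standardised genotypes: BLUP/ridge
with the heritability-implied penalty $\lambda = m(1-h^2)/h^2$, LASSO, and
Elastic Net (mixing 0.5). One seeded k-fold split (default 5) is shared by
all methods: `cv.glmnet` selects each penalty on it and returns
out-of-fold predictions at the selected penalty, and BLUP is folded
manually on the same split — the standard TWAS weight-training design, in
which penalty selection and accuracy estimation share one split. CV
$R^2$ is the squared out-of-fold correlation, signed so anti-predictive
models count as failures; the best method wins with the deterministic tie
order BLUP > Elastic Net > LASSO, and a transcript whose best CV $R^2$
is not positive is gated out.

The association with a GWAS trait needs only summary statistics:
$$Z = \frac{w^\top z}{\sqrt{w^\top \Sigma w}},$$
with $w$ the selected weights, $z$ the harmonized GWAS z-scores and
$\Sigma$ the LD of the model variants in an *explicit* reference panel
(the LD source is a required argument; in-sample panels are typical).
Harmonization drops strand-ambiguous (A/T, C/G) variants, indels, and
panel MAF ≤ 0.01; flips $z$ where alleles are swapped; and restricts to
the variant overlap — no summary-statistic imputation of missing GWAS
variants is attempted, and the overlap is reported. $\Sigma$ is shrunk as
$(1-\theta)\Sigma + \theta I$ with $\theta = 0.1$ by default, which keeps
the denominator positive definite with finite panels; $Z$ is invariant to
rescaling $w$.

Two follow-up tests probe a significant association. Conditioning removes
the predicted-phenotype component from each SNP,
$z_j^{(c)} = (z_j - c_j Z)/\sqrt{1-c_j^2}$ with $c = \Sigma w / \sqrt{w^\top
\Sigma w}$ (variance floored at $10^{-6}$): if usage mediates the locus,
the conditioned regional signal collapses. The weight-shuffling
permutation test (default 100,000 rounds) re-assigns weights to variants
and recomputes $|Z|$; when one weight dominates, the attainable p is about
$1/m$, so the test is informative only for models with enough variants.

## Colocalization

Per-variant evidence is Wakefield's approximate Bayes factor from $(z, V,
W)$, with $V = se^2$ or $1/(2nf(1-f))$ for quantitative traits summarised
by z and n, and prior effect SD $W = 0.15$ (0.2 on the log-odds scale for
case-control). Under the single-causal-variant assumption the five
hypotheses (no association / trait 1 only / trait 2 only / two distinct
variants / one shared variant) have posterior weights assembled from
per-variant priors $p_1 = p_2 = 10^{-4}$, $p_{12} = 10^{-5}$ — the
conventional defaults, all exposed as configuration. All accumulation is
in log space with log-sum-exp, and the distinct-variant cross-term uses a
stable complement ($\log(e^{a} - e^{b}) = a + \log(1-e^{b-a})$), so loci
with thousands of variants and large z-scores cannot overflow. A locus is
called colocalized when $PP_4 \ge 0.5$, boundary inclusive. With a single
variant the distinct-variant hypothesis has no configuration and $PP_3 =
0$ by convention. Both $(\beta, se)$ and $(z, n)$ entry points exist and
the mode used is recorded in the result.

## The synthetic-data generator

Every stage is validated on data the package generates itself, because the
cohorts this class of analysis runs on are controlled-access.

* **Genotypes**: haplotypes from a first-order Markov copying model — each
  site's latent uniform is copied from its neighbour with probability
  `ld_rho`, else redrawn, then thresholded at the site's allele frequency.
  With a shared allele frequency the adjacent-haplotype correlation equals
  `ld_rho` exactly; with frequencies drawn from a range, Frechet bounds cap
  it below `ld_rho` (the parameter-recovery test therefore fixes a common
  frequency). Monomorphic columns are repaired with a single heterozygote
  so downstream standardisation is always defined.
* **PDUI phenotypes**: baseline + per-variant additive effects + Gaussian
  noise, clipped to $[0,1]$ after noise — clipping is what makes the
  generator honest about the bounded support, and it slightly attenuates
  effects near the boundaries.
* **Coverage**: negative binomial around the two-segment expectation with
  $\mathrm{Var} = \mu + \phi\mu^2$; `dispersion = 0` returns the exact
  expectation (not a Poisson draw), giving machine-precision fixtures for
  the breakpoint tests.
* **GWAS summary statistics**: $z \sim N(\sqrt{n}\,\Sigma\gamma, \Sigma)$,
  the standard summary-statistic model. In mediated mode $\gamma =
  \alpha w$ with $w$ on the standardised-genotype scale, which makes the
  positive control internally consistent with the TWAS estimand.

What the generator does **not** emulate: population stratification,
related individuals, read-level artefacts (mapping bias, duplicates),
more than two poly(A) sites per UTR, intronic APA, and LD beyond
first-order neighbour structure. Passing tests therefore demonstrate the
statistical machinery, not robustness to those real-data complications.

## Reference study conditions

The package's validation suite runs fixed, deliberately desk-scale
conditions: 50-gene coverage panels (20 samples, 50x depth, dispersion
0.05, 600-nt UTRs); 200 null genes at n = 300 with 1000 permutations for
calibration; heritability recovery at $h^2 = 0.3$ (n = 500, m = 200, 50
replicates); a 5000-sample panel for the summary-vs-individual-level
equivalence; 20-variant loci at n = 5000 per trait for coloc
discrimination; and an end-to-end positive control with one mediated gene
among 49 nulls (reference panel n = 500, GWAS n = 50,000 summary-level,
30 cis variants per gene, causal effect 0.08 PDUI units per allele,
mediation $\alpha = 0.1$, 20 replicates). Effect sizes were chosen once to
represent a clearly powered locus of the kind the method is meant to
detect; they are conditions of the simulation, not tuning knobs.

## Known limitations

* The breakpoint model fits exactly one proximal site; UTRs with three or
  more used sites are summarised by the best two-segment approximation.
* The heritability optimizer assumes a single variance component; shared
  environment or relatedness inflates $\hat h^2$.
* The coloc module inherits the single-causal-variant assumption; loci
  with multiple independent signals dilute $PP_4$.
* The enrichment test is a simplified stand-in for full LD/distance
  matched enrichment machinery and is labelled as such in its output.
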