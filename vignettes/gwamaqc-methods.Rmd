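---
title: "Across-cohort QC for GWAMA summary statistics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Across-cohort QC for GWAMA summary statistics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwamaqc)
```

Genome-wide association meta-analyses (GWAMAs) pool per-SNP summary
statistics — effect sizes, standard errors, allele frequencies, sample
sizes — from tens to hundreds of cohorts. Standard QC pipelines operate
cohort by cohort; they do not ask whether the *collection* of uploaded
files is mutually consistent: are the reported frequencies compatible with
the declared ancestry? Do two files secretly share samples, which inflates
meta-analysis test statistics and produces false positives? This package
implements four across-cohort metrics that answer these questions from
summary-level data alone, plus a simulator that generates multi-cohort
experiments with known truth so each metric can be validated end to end.

## Fst profiles and the F_PC cartographer

For a cohort that reports allele frequencies, its genetic distance to a
reference population is estimated with a Hudson-type Fst: per SNP the
numerator is $(p_1-p_2)^2 - \frac{p_1(1-p_1)}{2n_1-1} -
\frac{p_2(1-p_2)}{2n_2-1}$ and the denominator $p_1(1-p_2)+p_2(1-p_1)$,
combined across SNPs as a ratio of averages. The correction terms remove
the sampling contribution to the squared frequency difference, so a
population compared with itself gives a slightly negative raw value
(reported as 0 after clamping) rather than a spuriously positive distance.
Per-SNP numerators are deliberately left unclamped — only the final ratio
is — because clamping each SNP would bias the ratio-of-averages upward.
This estimator needs only frequencies and sample sizes, exactly what a
summary-statistics file carries. Against two Balding–Nichols populations
simulated at $F$, it recovers $F$ (the tests assert within 10% at
30\,000 SNPs, $n = 100$ per population).

The *cartographer* turns three reference distances into map-like
coordinates. The convention, consistent with the known relationship
between Fst and genotype principal components, is that **squared**
Euclidean distance in F$_{PC}$ space is proportional to Fst. The three
reference populations are embedded by classical metric MDS of their
pairwise Fst matrix (double-centering, top-2 eigenpairs, negative
eigenvalues clipped); each cohort is then placed by least-squares
trilateration of its three Fst values, via the standard linearization that
subtracts the first anchor's sphere equation. With three anchors in two
dimensions the linearized system is exactly determined; the residual
misfit of the three sphere equations is reported per cohort so that
inconsistent distance triples are visible. Collinear anchors (second MDS
eigenvalue numerically zero) are rejected rather than projected onto a
line, and more than three anchors are rejected rather than silently
generalized — the three-reference design is the use case, and the
two-dimensional geometry is what makes the output interpretable as a map.
When an exact solution exists the linearized solution is also the
minimizer of the symmetric objective
$\sum_k (|x-v_k|^2 - F_{st,k})^2$; the tests verify this against a dense
grid search and verify that forward-simulating distances from planted
coordinates recovers the configuration to Procrustes RMSD $< 10^{-8}$.

Cohorts more differentiated than `flag_threshold` from a pooled reference
are flagged by `outlier_scan()`. The default 0.005 reflects typical
within-continental-ancestry differentiation: cohorts below it are
unremarkable, while known isolates sit several-fold higher.

## Meta-PCA

`run_meta_pca()` is conventional PCA with each *cohort* as one
observation and its reported allele frequencies as features. Columns are
centered; the default `center_scale` mode also divides each column by
$\sqrt{\bar p(1-\bar p)}$, the frequency analogue of genotype
standardization. Whether the original formulation scaled columns is not
determinable from its description ("the same as the conventional PCA"),
so both modes are exposed; on well-separated populations the partition is
the same either way, and `center_scale` prevents common SNPs from
dominating purely through their larger frequency variance. Coordinates
are left singular vectors scaled by singular values, with each
component's sign fixed so its largest-magnitude loading is positive —
an arbitrary but deterministic convention that makes results reproducible
across BLAS implementations. Like any PCA, the projection depends on
which cohorts (and reference populations) are included; the tests
therefore assert determinism and partition recovery, not coordinate
stability under context changes.

## lambda_meta

For a harmonized cohort pair, each SNP yields
$T_i = (b_{1i}-b_{2i})^2/(\sigma_{1i}^2+\sigma_{2i}^2)$. If the cohorts
are independent and estimate the same effects, $T \sim \chi^2_1$, and

$$\lambda_{meta} = \frac{\mathrm{median}(T)}{\mathrm{median}(\chi^2_1)}$$

has expectation 1. Overlapping samples correlate $b_1$ and $b_2$, shrink
the differences, and deflate $\lambda_{meta}$ below 1; heterogeneous true
effects inflate it. The median (rather than mean) makes the statistic
robust to the handful of genuinely associated SNPs: under polygenic
heritability with shared effects the bulk of the $T$ distribution is
untouched. The $\chi^2_1$ median is computed from the inverse CDF
(0.4549364...) rather than the rounded 0.455 that is fine for prose but
not for a denominator used in thousands of pair tests.

The null standard error comes from the asymptotic variance of a sample
median, $SE(\lambda) = \frac{1}{q}\sqrt{1/(4mf(q)^2)}$ with $q$ the
$\chi^2_1$ median and $f$ its density; at $m = 30\,000$ markers this is
0.0135. `pairwise_scan()` reports a $z$-test against this theoretical SE
and a second one against the empirical across-pair mean and SD, which is
the more honest yardstick when mild study-wide heterogeneity shifts the
whole $\lambda$ distribution; flags are Bonferroni-corrected over the
number of pairs. If input SEs were genomic-control adjusted, a user flag
annotates the result ($\lambda_{meta}$ is then deflated); no automatic
un-correction is attempted.

Markers should be approximately independent. Lacking genotype data for LD
pruning, `prune_independent()` thins by physical distance (default gap
$10^5$ bp) and randomly subsamples to the target count (default 30\,000)
under a seed. This is a deliberate stand-in for LD-based pruning: distance
thinning removes the bulk of short-range LD, and the statistic only needs
approximate independence for its median-based SE to apply.

### From lambda to an overlap count

With overlap, $\mathrm{Var}(b_1-b_2) = \sigma_1^2+\sigma_2^2 -
2\gamma\sigma_1\sigma_2$ where $\gamma$ is the correlation of the two
estimates. Since $\sigma^2 \propto 1/n$,
$E[\lambda] \approx 1 - \gamma\,2\sqrt{n_1n_2}/(n_1+n_2)$, inverted by
`gamma_from_lambda()`:
$\hat\gamma = (1-\lambda)(n_1+n_2)/(2\sqrt{n_1n_2})$, and because pure
overlap of $n_o$ individuals gives $\gamma = n_o/\sqrt{n_1n_2}$, the
effective overlap count is $\hat n_o = (1-\lambda)(n_1+n_2)/2$. This
transformation is reconstructed from the variance model; its validity is
anchored by recovering the planted correlations of simulated cohort pairs
across heritabilities and sample-size ratios (see the acceptance tests).
Two consequences of the algebra are worth noting. First, for a *fixed
correlation* $\gamma$ the deflation $|E[\lambda]-1| =
\gamma\,2\sqrt{n_1n_2}/(n_1+n_2)$ is maximal at $n_1 = n_2$: equal-sized
pairs give the best detection of a given correlation, and the tests
assert this. Second, for a fixed *count* $n_o$ the deflation reduces to
$2n_o/(n_1+n_2)$, independent of the split — the sample-size ratio
matters through $\gamma$, not beside it. The transform is valid for
quantitative traits; for case-control designs the case/control ratio
breaks the $n_o$ interpretation, which is one motivation for PPSR below.
A frequency-only variant (`lambda_af()`) replaces effect differences with
allele-frequency differences and their binomial variances, usable when
betas are absent; monomorphic SNPs carry no information and are excluded.

The naive alternative — directly correlating the two cohorts' effect
estimates — is confounded by genetic architecture: with $h^2 > 0$ both
cohorts partly estimate the *same* true effects, so the correlation is
inflated far beyond the overlap contribution (two orders of magnitude in
the simulated $n_o = 1$ design), while $\hat\gamma$ from
$\lambda_{meta}$ is not. This contrast is reproduced quantitatively by
the acceptance suite.

## Pseudo profile score regression

PPSR pinpoints *which* individuals overlap without moving genotypes. The
hub draws $K$ weight vectors $s_k \sim N(0, I_M)$ over $M$ agreed,
non-palindromic SNPs and fixes standardization frequencies; each cohort
returns per individual the scores
$PPS_k = \sum_m \frac{(g_m - 2p_m)w_{mk}}{\sqrt{2p_m(1-p_m)}\sqrt{M}}$.
Hub-supplied (not per-cohort) frequencies are essential: they put every
cohort's scores on one scale so cross-cohort coefficients estimate
relatedness rather than frequency differences. Standardized (not raw)
genotypes are used so that the coefficient lives on the GRM scale where
duplicates sit at 1 and first-degree relatives near 0.5. Missing
genotypes become 0 after centering (mean imputation), which keeps
duplicate pairs detectable under the percent-level missingness that
defeats exact-hash matching. The $1/\sqrt{M}$ scaling makes coefficient
magnitudes comparable across choices of $M$.

Regressing individual $j$'s $K$ scores on individual $i$'s gives
$b_{ij} = \widehat{\mathrm{cov}}/\widehat{\mathrm{var}}$, computable for
all $n_i \times n_j$ pairs as one matrix product of row-centered score
matrices (the tests verify exact agreement with an explicit loop of
regressions). Conditional on genotypes the scores are Gaussian, so
$b_{ij}$ is unbiased for the relationship of $i$ and $j$ normalized by
$i$'s realized self-relatedness; duplicates give $b = 1$ exactly. A pair
is classified on $\max(b_{ij}, b_{ji})$ — robust to one-sided
missingness deflating one row's score variance — as duplicate at
$b \ge 0.95$ or first-degree at $b \ge 0.45$.

### How many scores?

Under the null the coefficient has variance $1/K$; under the alternative
of true coefficient $\rho$, variance $(1-\rho^2)/K$. A one-sided test at
Bonferroni per-test level $\alpha = \alpha_{exp}/n_{tests}$ with power
$1-\beta$ requires

$$K = \left\lceil \left(\frac{z_{1-\alpha} +
z_{1-\beta}\sqrt{1-\rho^2}}{\rho}\right)^2 \right\rceil,$$

which gives $K = 57$ for duplicate detection ($\rho = 0.95$) at
experiment-wise $\alpha = 0.01$, power 0.95, across 488\,587\,090 pair
tests. Two caveats the package is explicit about. The normal
approximation is optimistic in the extreme tail: the slope's
$t$-distributed tails make the nominal $z$-boundary anticonservative at
per-test levels of $10^{-8}$, so in practice false-positive control comes
from the operational threshold itself — $b \ge 0.95$ lies about seven
null SDs out at $K = 57$, and the tests observe zero false positives
among hundreds of thousands of null pairs, with the power side of the
design formula verified by simulation. Second, at the first-degree
cutoff the alternative is diffuse: a parent-offspring pair's realized
relatedness over $M = 500$ SNPs fluctuates around 0.5 with SD about
0.05, so even at $K = 286$ an individual true pair clears the 0.45 cutoff
with probability near 0.8, not 1; the tests assert recall above 0.6 over
40 pairs and a mean coefficient near 0.5 rather than perfect recall.

### What the scores leak

An analyst holding both $S$ and the scores can least-squares invert the
linear map: exactly when $K \ge M$, and onto a random $K$-dimensional
subspace when $K < M$, so per-SNP reconstruction $R^2$ scales with
$K/M$. `decode_risk()` quantifies this, optionally against true
genotypes, per MAF bin. The practical reading: keep $K/M$ small (the
default design, 57 scores over 500 SNPs, has $K/M \approx 0.11$), and
the tests confirm recovery is near-perfect at $K \ge M$, near zero for
decoupled scores, monotone in $K$ at fixed $M$, and decreasing in $M$ at
fixed $K$.

## The simulator

`sim_pair_study()` / `sim_study()` generate the study conditions the
metrics assume: ancestral frequencies uniform on 0.05–0.95,
Balding–Nichols population frequencies
$\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$, unlinked $\mathrm{Binomial}(2,p)$
genotypes, and a polygenic trait with normal effects on `n_qtl` randomly
chosen SNPs (1000 by default), rescaled so the realized genetic variance
is exactly $h^2$ of a unit total. Overlapping individuals are copied —
genotype *and* phenotype — into the partner cohort; first-degree
relatives are gene-dropped parent-offspring pairs (one transmitted
allele, one population allele). Per-SNP least-squares GWAS is vectorized
in column chunks and tested against an `lm()` loop at $10^{-10}$.
Simulated markers are spaced $10^5$ bp apart across 22 chromosomes so
the default thinning gap treats them all as independent — which they
are, by construction.

What the generator deliberately does *not* model: linkage
disequilibrium, imputation error, genotyping-platform artifacts,
case-control ascertainment of effect sizes, and population structure
within a cohort. Passing tests therefore demonstrate the statistical
machinery under the metrics' own assumptions; on real data, LD reduces
the effective number of independent markers (hence the distance-thinning
step), and platform artifacts can move $\lambda_{meta}$ without any
sample sharing — which is precisely why the empirical across-pair SD is
reported alongside the theoretical one.

Within one `sim_study()` population all cohorts share a single trait
model (one QTL set, one $h^2$): overlapping individuals must carry
identical phenotypes in both cohorts, which a per-cohort trait model
would violate.

## Problem sizes and numerical choices

The validation experiments mirror the reference simulation design at its
original scale — 30\,000 unlinked markers, 1000 QTLs, cohort sizes from
1000 to 10\,000, ten replicates per configuration, twenty for the
independent-cohort null — sizes chosen so each configuration completes
in minutes on a single core while the replicate means sit well inside
the reference $\pm 3$ SD bands. Property suites (PPSR recovery, decode
risk, cluster agreement) run at a few hundred markers and individuals,
where their guarantees are already sharp. Degenerate inputs are handled
explicitly rather than propagated: zero-SE records are rejected on load,
monomorphic SNPs get missing effect estimates and are excluded
downstream, zero-variance score rows are skipped with a flag,
all-monomorphic Fst input and zero-variance frequency matrices are
errors, and ties in the thinning step are broken by the seeded random
visit order. Seeds are mandatory-with-default (2016) on every stochastic
path and are echoed into output headers, so any number in any output
file can be regenerated from its own provenance line.
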