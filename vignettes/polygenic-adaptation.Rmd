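---
title: "Detecting polygenic adaptation with polyadapt: models and methods"
author: "polyadapt authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting polygenic adaptation with polyadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyadapt)
```

# The problem

A genome-wide association study (GWAS) for a quantitative trait yields a set
of L trait-associated SNPs with additive effect sizes. Given the frequencies
of those alleles in M populations, the population mean *genetic value*

$$Z_m = 2 \sum_{l=1}^{L} \alpha_l\, p_{lm}$$

summarizes the additive contribution of the mapped loci in population $m$
(the factor 2 counts diploid allele copies; alleles are labelled so that
$\alpha_l \ge 0$, i.e. the stored allele is the trait-increasing one).
Populations differ in their genetic values even under pure neutrality,
because drift and shared history move allele frequencies. The question this
package answers is whether the observed dispersion of genetic values — or
their correlation with an environmental variable — exceeds what neutral
divergence can explain, which is the signature of *polygenic adaptation*:
many small, coordinated allele-frequency shifts at trait-increasing alleles.

# The drift null

The null model treats the vector of standardized allele-frequency
deviations at a neutral locus as multivariate normal with covariance
$\epsilon(1-\epsilon)\,F$, where $\epsilon$ is the ancestral (grand mean)
frequency and $F$ is an among-population covariance matrix summarizing
drift, shared branches and gene flow. Genetic values, as sums over many
loci, inherit this structure (by the central limit theorem even when
per-locus normality is doubtful): $Z \sim \mathrm{MVN}(\mu \mathbf{1},\,
2 V_A F)$, where $V_A = 2\sum_l \alpha_l^2 \bar\epsilon_l (1 -
\bar\epsilon_l)$ is the additive variance the loci would contribute at the
grand-mean frequencies $\bar\epsilon_l$ (the mean of each locus across the
M populations; the package resolves an ambiguity here by always using the
GWAS loci's own mean frequencies).

Because the ancestral mean is estimated by the sample mean, one degree of
freedom is lost: every vector is mean-centered and one population's
coordinate is dropped (`centerProjection()`). Which population is dropped
is arbitrary; `qx()` and the no-intercept slope are exactly invariant to
the choice (a test asserts this at $10^{-8}$), while rank- and
centered-correlation statistics depend on the basis only weakly, and their
empirical nulls absorb the dependence because null draws pass through the
same basis.

`estimateF()` estimates $F$ from genome-wide null SNPs: per SNP,
standardize by $\sqrt{\bar\epsilon(1-\bar\epsilon)}$ with the *unweighted*
mean $\bar\epsilon$ across populations (no weighting is stated for the
centering, so none is applied), project, and take the sample covariance
with divisor $K-1$ (the conventional unbiased choice; the same estimator is
applied to null and observed data, so the choice cannot affect test
calibration). Because sample rather than population frequencies enter the
estimate, binomial sampling inflates the diagonal by terms of order
$1/n_m$; the GWAS loci carry the same sampling noise, so no correction is
applied — the null is matched by construction. A covariance that fails its
Cholesky factorization (duplicate populations, K too small) receives one
ridge of $10^{-10}\,\mathrm{tr}(F)/(M-1)$ with a warning before failing
hard; silent regularization would distort p-values.

Whitening (`whiten()`) maps genetic values to
$x' = C^{-1} T Z / \sqrt{2 V_A}$ with $C$ the lower Cholesky factor of
$F$: under the null the $M-1$ coordinates are independent standard
normals. Environmental variables pass through the same projection and
solve but keep their own units (`whitenEnvironment()`).

# Test statistics

**Excess variance.** $Q_X = \sum_m x_m'^2$, a $Q_{ST}$–$F_{ST}$-style
quadratic form that is approximately $\chi^2_{M-1}$ under neutrality.
Upper-tail values mean more among-population variance in genetic values
than drift explains. The test is upper-tailed by default; a two-sided
option exists because a *deficit* of variance (widespread stabilizing
selection) is also interpretable, though hard to detect with GWAS panels
that miss rare large-effect alleles.

**Variance/covariance decomposition.** Writing the whitened genetic values
as effect-weighted sums of transformed per-locus frequencies
(`transformedFrequencies()`), $Q_X$ splits exactly
(`qxDecomposition()`, additivity asserted at $10^{-8}$) into an
$F_{ST}$-like sum of per-locus variance terms and an LD-like sum of
cross-locus covariance terms. Neutrally drifting unlinked loci covary in
no preferred direction, so the LD-like term has expectation zero;
directional selection moves like-effect alleles together and drives it
positive. This term carries most of the power when many loci underlie the
trait.

**Environmental correlations.** `envRegression()` regresses whitened
genetic values on the whitened environment *without an intercept* — both
vectors are constructed mean-free, and an intercept would spend a spurious
degree of freedom — and reports the slope, the squared Pearson correlation
and the Spearman rank correlation (average ranks on ties; robust to
outlying populations). The slope and rank correlation are tested
two-sided. $r^2$ is unsigned, so it is tested upper-tail, which under a
symmetric null is equivalent to a two-sided test of the signed
correlation; the direction of an association is read off the slope's sign,
and the two are reported separately rather than as a "signed $r^2$".
`perLocusRegression()` gives the per-locus view: under a shared-slope
model the stacked maximum-likelihood slope is an effect-size-weighted
combination of per-locus slopes, exactly proportional to the genetic-value
slope via $\sqrt{2V_A}/\sum_l (2\alpha_l)^2$ (asserted at $10^{-8}$).

# Empirical nulls from matched SNPs

Parametric $\chi^2$ or normal references are reported, but significance
comes from an *empirical* genome-wide null: sample sets of null SNPs
matched to the GWAS loci, carry over the effect sizes positionally, and
recompute every statistic on the resulting null genetic values
(`sampleNullSets()`, `nullGeneticValues()`). Matching uses a
$25 \times 2 \times 10$ contingency table — minor allele frequency in the
ascertainment population in bins of 0.02, imputation status, and
background-selection B value in bins of 0.1 — so that subtle ascertainment
effects on the frequency distribution are reproduced in the null. The same
matching supplies the SNPs from which $F$ is estimated
(`fitMatchedModel()`), so the covariance describes SNPs with the GWAS
ascertainment profile. For an admixed ascertainment population without a
direct reference panel, `admixedAscertainmentFreq()` builds the binning
frequency as an admixture-weighted mean of two reference populations,
folded to a MAF.

Design choices the source procedure leaves open, resolved here: within one
set, loci sharing a cell receive *distinct* null SNPs (without
replacement), while sets are independent; an empty cell widens its MAF bin
by ±1 then ±2 at the same imputation and B bins (and a cell shared by g
loci widens until it holds g candidates) before failing with the offending
loci named — refusing outright would make modest pools unusable, and every
widening is counted in the returned object. Empirical p-values use the
add-one rule $p = (r+1)/(K+1)$ so that p is never zero; with $K = 99$ null
sets, rejecting at $p \le 0.05$ is an exact 5% test under exchangeability.

# Localizing signals: conditional MVN outliers

Given a partition into a tested group and a conditioning group (at least
two populations), the covariance is re-estimated centered on the
conditioning group's mean (`recenterF()`) — divergence from a subgroup
mean exceeds divergence from the global mean even under neutrality, and
the null must reflect that. Standard multivariate-normal conditioning
(`conditionalDistribution()`) then yields the expected mean and covariance
of the tested group given the observed values elsewhere; the group-2 block
is singular by construction (rank $M_2 - 1$), so its inverse is a
pseudo-inverse restricted to the rank support. `groupZscore()` standardizes
the discrepancy between the tested group's mean genetic value and its
conditional expectation; under the null Z is standard normal, and a
two-sided Gaussian p-value is reported because departures in both
directions are of interest. The additive-variance scale is reused from the
global fit: it is a property of the loci, not of the partition. A
significant Z localizes a signal but does not attribute causation —
selection in a closely related conditioning population produces the same
discrepancy, so interpretation needs external demographic and ecological
context.

Conditional operators are verified against an independent
precision-matrix oracle on random positive-definite covariances at
$10^{-8}$, and the calibration of Z (mean 0, variance 1) is checked on
10,000 neutral replicates.

# Power simulations

Rather than forward-simulating selection, the package perturbs *neutral*
frequency sets — drift and shared history are then already present — with
a deterministic shift

$$p'_{lm} = p_{lm} + s\, \alpha_l\, Y_m\, p_{lm}(1-p_{lm}),$$

clipped to $[0,1]$ with the clipped count logged. The exact functional
form is a package choice: it is the minimal additive form with the three
qualitative properties a directional-selection response must have (shifts
grow with the environmental value, the effect size, and heterozygosity),
and `applyShift()` accepts a pluggable `shift_fun` for alternatives.
Variants: `pleiotropicEffects()` replaces the acting effects by draws from
the conditional of a mean-zero bivariate normal with equal variance and
correlation $\rho$ — the marginal variance is the *second moment about
zero* of the measured effects, since the all-positive orientation of
$\alpha$ must not shrink the acting effects, and this keeps
$E[\gamma^2]$ (hence per-locus shift magnitudes) invariant in $\rho$;
`downsampleLoci()` subsamples loci uniformly, optionally rescaling effect
sizes to hold $V_A$ fixed; `targetedShift()` uses a raw 0/1 indicator
environment to confine the shift to one population or region (the
indicator is deliberately not mean-centered; centering would only rescale
$s$).

`powerExperiment()` reports, per scenario and statistic, the fraction of
perturbed replicates beyond the 5% critical value established from the
*same* replicates left unshifted — critical values come from the s = 0
simulations, not from the asymptotic references — with a fresh
pleiotropic draw per replicate so power averages over the acting-effect
distribution. Comparators include naive variants computed on raw
mean-centered values without whitening, and a single-locus enrichment
test.

**The enrichment comparator** counts loci whose per-locus
transformed-frequency correlation with the environment is an outlier
against the per-locus empirical null and refers the count to
Binomial(L, 0.05). Two design points matter. First, the outlier tail is
*sign-agnostic* (beyond the 2.5%/97.5% null quantiles): a locus counts
however its allele moves with the environment, which is what makes this
comparator's power insensitive to the genetic correlation between the
measured and the selected trait. Second, a deterministic binomial tail
cannot attain a 5% level at L = 161 (the exact tail's attained size is
about 3.2%, the mid-p tail's about 6.1%); `enrichmentTest()` reports the
deterministic mid-p tail by default for data analysis, while the
calibration and power machinery uses the randomized p-value
$P(X > k) + U\,P(X = k)$, which is exactly uniform under the null, so the
comparator is held to precisely the same level as the continuous
statistics it is compared with. The per-locus null cutoffs are taken from
the exact matched mixture — the pooled correlations of every pool SNP in
each locus's contingency cell — rather than from a finite resample of
null sets, removing one layer of Monte Carlo noise.

# The synthetic fixture generator

`makeDataset()` draws everything the pipeline consumes. Its defaults are
the study conditions used throughout the tests: 52 populations, 161 GWAS
loci, a 20,000-SNP null pool — the scale of a height-GWAS analysis against
a worldwide human diversity panel. Per SNP: ancestral frequency uniform on
[0.05, 0.95]; population frequencies MVN with covariance
$\epsilon(1-\epsilon)F$ truncated to $[0,1]$; binomial sampling with 50
chromosomes per population, so the $1/n_m$ diagonal inflation that real
sample frequencies carry is present in fixtures too. The star-tree drift
parameter defaults to $c = 0.02$ per branch: large enough that drift
dominates over pure sampling noise, small enough that the Gaussian
approximation to drift holds and the truncation rate stays below 1% (it is
recorded in the panel's metadata; truncation rather than reflection keeps
the generator simple and makes the approximation error visible).
Balanced-clade trees and explicit covariances are available for
structured-history scenarios. Effect sizes are half-normal with scale 0.1
trait units; the environmental variable is latitude-like (uniform on
[0, 60]); B values and imputation flags are drawn independently of
frequency, because only the matching *mechanics* — not a mechanistic model
of background selection — need exercising. MAF metadata is the folded
sample frequency in the first population, mimicking ascertainment in a
single reference population.

What the fixtures deliberately do not emulate: linkage disequilibrium
between test loci (the framework assumes unlinked loci), ascertainment
biases that correlate effect-size estimates with frequency deviations
(the false-positive mode of structured-GWAS effect estimates), non-MVN
drift under strong differentiation, and any dependence of B value on
frequency. Passing calibration on fixtures therefore demonstrates the
statistical machinery is correct under the model's own assumptions, not
that those assumptions hold for any particular empirical dataset.

# Problem sizes and determinism

The test suite runs the null calibration of $Q_X$ against
$\chi^2_{51}$ on 10,000 matched sets; type-I error on 1,000 neutral
replicates with 99 matched null sets each; conditional-Z calibration on
10,000 fresh neutral replicates; and power sweeps at 200 replicates per
scenario point, with selection gradients spanning from calibration
($s = 0$) to saturation — sizes chosen so the whole suite completes in a
few minutes on one core while leaving Monte Carlo error well inside the
asserted bands. Every stochastic step takes an explicit integer seed, and
identical seeds reproduce results bit-for-bit.

# Known limitations

- The MVN drift approximation degrades with substantial drift
  ($F$ entries approaching 0.1 and beyond) and near frequency boundaries;
  the genetic-value-level CLT softens but does not remove this.
- Conditional Z-scores condition on populations that may themselves be
  selected; the Z localizes, it does not attribute.
- Strand-ambiguous (A/T, C/G) SNP harmonization between the GWAS and the
  frequency panel is assumed done upstream; the loaders only resolve
  trait-increasing orientation.
- The empirical null inherits the pool's finite size: with few pool SNPs
  per contingency cell the null distribution is granular, which first
  shows up in the two-sided environmental tests. Several hundred pool
  SNPs per occupied cell are advisable.
- Multiple-trait and multiple-environment testing is not penalized; users
  scanning many combinations should apply their own error-rate control.
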