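---
title: "Methods: episignature discovery, drug-correction calling and screen statistics"
author: "episig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: episignature discovery, drug-correction calling and screen statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the statistical models it
implements, the assumptions behind them, the parameters that matter,
and the design decisions taken where more than one defensible choice
existed. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The discovery model

Each CpG's methylation is summarised as a beta value
$\beta \in [0,1]$, the fraction of methylated signal. For modelling,
betas are mapped to M-values, $M = \log_2\{\beta/(1-\beta)\}$, after
clipping to $[\varepsilon, 1-\varepsilon]$ with $\varepsilon = 0.001$
(matching the generator clamp, so the transform is finite). Per CpG $g$
we fit ordinary least squares

$$ y_g = X\gamma_g + e_g, \qquad e_g \sim N(0, \sigma_g^2 I), $$

with a shared design $X$: intercept, case status, age (years), and the
estimated neutrophil and monocyte fractions. The residual variance
$s_g^2$ on $d_g = n - \mathrm{rank}(X)$ degrees of freedom is shrunk by
empirical Bayes toward a common prior: with prior
$\sigma_g^{-2} \sim \chi^2_{d_0}/(d_0 s_0^2)$,

$$ \tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},
   \qquad \tilde t_g = \frac{\hat\gamma_g}{\tilde s_g\,u},
$$

referred to a t distribution on $d_0 + d_g$ degrees of freedom ($u$ is
the unscaled standard deviation of the tested coefficient). The
hyperparameters $(d_0, s_0^2)$ are estimated by matching the first two
moments of $\log s_g^2$ to the scaled-F prior predictive: with
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$,

$$ \mathrm{E}\,e = \log s_0^2 + \psi(d_0/2) - \log(d_0/2),
   \qquad \mathrm{Var}\,e - \psi'(d_g/2) = \psi'(d_0/2), $$

and the trigamma equation is solved by a monotone Newton iteration.
When the observed spread of $\log s_g^2$ does not exceed its chi-square
sampling noise the trigamma equation has no finite root; the documented
fallback is $d_0 = \infty$ with every posterior variance equal to
$s_0^2$. Two sub-cases matter numerically: if the variances genuinely
vary, the consistent scale estimate is the digamma-corrected
$\exp(\bar e)$; if they are exactly equal (a degenerate input), that
correction would move them, so the common value is returned unchanged
and the moderated t then equals the ordinary t. Zero-variance CpGs are
flagged, excluded from the prior fit, and still receive a prior-driven
statistic.

**Modelling scale.** Both beta- and M-scale fits are supported; the
default is the M scale. On array-like data whose replicate noise is
approximately Gaussian on the logit scale, beta-scale residuals are
non-Gaussian and strongly heteroscedastic (the fitted prior df drops to
single digits), which visibly inflates the far tail of the null; on the
M scale the same data are homoscedastic and the model is close to
exact. Effect sizes are **always** reported as the difference in group
mean beta ("methylation difference", fraction units), independent of
the modelling scale, because that is how the field quotes episignature
effects.

**Workflow order.** Blood cell proportions are estimated first
(section 2) and joined to the sample sheet; the age screen (simple
per-CpG regression on age, moderated, BH at FDR 0.05) then removes
age-associated CpGs **before** the case/control model, so age-driven
variation cannot enter the signature; finally the case/control model is
fitted to the surviving CpGs and DMPs are selected at nominal
p < 0.005 **and** |methylation difference| > 0.05, both strict
inequalities (the mouse analysis states its effect criterion as
"> 5%", and the same reading is applied here).

**Covariates.** Only the neutrophil and monocyte estimates are used as
covariates. In whole blood the lymphocyte subsets co-vary (inversely)
with the dominant neutrophil fraction, so a neutrophil term captures
most composition variation; this association is also what the
synthetic generator reproduces (section 5). Passing all six estimated
fractions would make the design nearly collinear with the intercept.

## 2. Cell-type deconvolution

Proportions are estimated per sample by nonnegative least squares of
the observed betas on the reference profiles (Lawson–Hanson active
set, tolerance 1e-8, via `pracma::lsqnonneg`), using the CpGs shared
between sample and reference with pairwise deletion of missing values.
The raw solution and its sum-to-one renormalisation are both returned;
the residual norm is reported on the raw solution, which keeps it
interpretable. When the unconstrained least-squares solution is already
nonnegative the constrained solution equals it exactly — a property the
test suite asserts. `select_discriminating_cpgs` ranks CpGs per cell
type by the difference between that type's beta and the mean of the
others and keeps the most extreme `k` (half hyper-, half
hypomethylated where available); the union conditions the design far
better than a random subset of equal size (checked via condition
numbers).

The normalised fractions are used as covariates. Whether to
re-normalise before use is not a settled convention; normalising makes
the covariate invariant to per-sample intensity scale, which is the
behaviour wanted here.

## 3. The drug-correction caller

The mouse study crosses genotype (WT/KO) with treatment
(vehicle/drug). Per CpG a two-factor linear model with interaction is
fitted (moderated as in section 1; the interaction coefficient is
tested) and three beta-scale group-mean effects are computed:

- genotype effect: mean(KO-vehicle) − mean(WT-vehicle);
- drug effect: mean(KO-vehicle) − mean(KO-drug);
- residual effect: mean(KO-drug) − mean(WT-vehicle).

The identity (genotype) − (drug) = (residual) holds exactly by
construction and is asserted to 1e-12. A CpG is called drug-corrected
iff the interaction p is below threshold, |genotype| and |drug| effects
exceed 5%, and the |residual| effect is below 5% — i.e. the treated
knockout has returned to within tolerance of the wild-type baseline.
The default p threshold is 0.01; 0.05 is also in circulation for this
analysis and is available as an argument — the package defaults to the
stricter value and exposes the laxer one rather than asserting either
as canonical. A sign-consistent mode (drug effect must oppose the
genotype effect) exists but is off by default, since the residual
criterion already enforces return-toward-baseline. Note that relabeling
vehicle/drug flips the sign of the drug effect but also changes which
cell anchors the genotype effect; only the former is a clean symmetry.

## 4. Count-based differential methylation

RRBS-style data give methylated/coverage counts per CpG and sample.
CpGs with any sample below 10x coverage (configurable) are skipped and
reported. The two-group test statistic is the score (Pearson)
chi-square of the pooled 2×2 table — equivalent to the score test of
the group coefficient in a grouped binomial logistic regression, and
equal to the classic $n(ad-bc)^2$ closed form. Extra-binomial variation
is estimated per CpG as $\hat\varphi = X^2/(N-2)$ from the Pearson
residuals of the fitted two-proportion model.

Two refinements stabilise the correction at realistic sample sizes:

1. **Dispersion squeezing.** At $n = 3$ vs 3 a per-CpG dispersion sits
   on 4 degrees of freedom; dividing by it and referring to
   $\chi^2_1$ behaves like an F(1,4) ratio and is badly anticonservative.
   The per-CpG estimates are therefore squeezed across CpGs with the
   same log-moment empirical-Bayes fit used for variance moderation
   (default on). When the true dispersion is common, the squeezed
   estimate converges on it and the corrected statistic is calibrated.
2. **Coverage weighting.** The pooled statistic weights reads, so its
   variance inflation under clustered counts is
   $1 + \rho(\tilde c - 1)$ with $\tilde c = \sum c_i^2 / \sum c_i$
   per group, whereas $\hat\varphi$ reflects the per-sample average
   coverage. The estimate is converted to an intraclass correlation
   $\hat\rho = (\hat\varphi - 1)/(\bar c - 1)$ and re-applied with the
   read-weighted coverage. With equal coverage this reduces exactly to
   dividing by $\max(\hat\varphi, 1)$, and for $\hat\varphi \le 1$ the
   corrected and uncorrected statistics are identical.

Multiplicity is controlled by Benjamini–Hochberg; where the source
field says "q value" this package reports BH q-values (a documented
deviation from SLIM-style q-values, which differ slightly). DMPs are
called at q < 0.05 and |pooled proportion difference| > 0.10 — the
higher effect cutoff guards against effect-size inflation at low read
depth. The effect is the count-weighted pooled proportion difference
(not the mean of per-sample proportions), matching the count-weighted
behaviour of grouped tests.

**Annotation.** Each CpG receives exactly one label by precedence
Promoter > 5UTR > 3UTR > Exon > Intron > Downstream > Distal
Intergenic, with the promoter a ±3000 bp window around the strand-aware
TSS and Downstream a 3000 bp window past the strand-aware gene end.
Interval queries go through GenomicRanges; the precedence and gene-id
attachment are this package's. CpGs on chromosomes absent from the
annotation fall to Distal Intergenic with a warning.

## 5. The synthetic-data generators

The generators produce data with the statistical structure each
analysis assumes, plus a truth manifest, so recovery and calibration
are measurable.

- **Cohorts** (`simulate_cohort`): per-sample expected betas are
  cell-reference mixtures plus an age slope at a subset of CpGs plus a
  signed planted delta at signature CpGs in cases; logit-normal noise
  (Gaussian on the logit scale, sd `noise_sd`, back-transformed) is
  applied and values clamped to [0.001, 0.999]. Defaults: 12 cases vs
  21 controls (test cohort 7 cases, 4 controls, 5 disease controls that
  carry an unrelated perturbation at non-signature CpGs), 20,000 CpGs,
  416 signature CpGs with |delta| drawn uniformly in
  [`delta`, 2`delta`] and random sign (the real effect-size
  distribution is unknown; this default is configurable, not a claim),
  logit noise sd 0.1 (~2.5% beta-scale sd at beta 0.5, a typical array
  replicate noise), 3% of CpGs with an age slope of 0.004/yr over ages
  0–60 (the planted fraction matches the ratio of age-removed to
  analysed sites in a typical blood EPIC cohort of this design).
- **Cell mixing**: blood-like rather than symmetric — the neutrophil
  fraction is a Beta(0.55·40, 0.45·40) draw and the remainder is split
  by a concentrated Dirichlet over a realistic minor-type composition,
  so minor-type fractions co-vary inversely with neutrophils. This is
  deliberate: the two-covariate adjustment of section 1 presumes
  exactly this association; with independent symmetric mixing the four
  uncovaried cell types confound their own marker CpGs and no
  two-covariate model can be calibrated there. A case-specific
  neutrophil mean is available as a confound stressor.
- **Mouse arrays**: four-cell design; planted genotype DMPs shift KO
  by `delta` (default 0.08), a `frac_corrected` subset returns the
  KO-drug cell exactly to the WT baseline.
- **RRBS counts**: coverage is `1 + NB(mu = mean_coverage − 1, size =
  5)` (mean exact, support ≥ 1); methylated counts are beta-binomial
  with intraclass correlation `rho = (phi − 1)/(mean_coverage − 1)`, so
  the dispersion factor at the mean coverage equals `phi` and `phi = 1`
  is exactly binomial.
- **Ordinal screens**: per-chemical categorical distributions over the
  4-point severity scale obtained by proportional-odds shifts of a
  severity-skewed baseline (negative shift = suppressor). The default
  baseline (0.10/0.15/0.25/0.50) reflects an untreated mutant clutch.
- **DEG lists**: two gene sets with an exact requested overlap.

All generators are deterministic given `seed` (R's default
Mersenne-Twister; identical seeds give byte-identical output).

What the generators do **not** emulate: probe cross-hybridisation and
SNP artifacts, batch/surrogate-variable structure, IDAT-level
normalisation, spatially correlated CpGs, and real effect-size
distributions. Passing tests therefore demonstrate the statistical
machinery under the stated noise model, not performance on raw array
data.

## 6. Validation and classification

PCA is computed on per-CpG mean-centered (unscaled) values over all
supplied samples jointly; component signs are fixed by making the
largest-magnitude loading positive, so the decomposition is
deterministic. Hierarchical clustering uses Euclidean distance on
per-CpG scaled and mean-centered values (the heatmap convention) with
average linkage — the linkage is a package decision, configurable,
since only the distance is conventionally fixed. The tree is cut into
two clusters; the cluster holding the majority of known discovery
cases is labelled case-like, with an exact tie going to cluster 1.
Rows and columns are sorted by id before clustering, making the result
invariant to input order. The two-cluster majority rule is this
package's operationalisation of "correctly clustered"; visual
assessments in the literature do not define one.

Nearest-centroid classification compares each query sample's Euclidean
distance to the case and control discovery centroids over the
signature CpGs, with pairwise deletion of missing CpGs (distances
renormalised by the CpG count used; one sample's missingness never
affects another) and a minimum 90% signature coverage. Margins within
1e-12 of zero are reported as ambiguous.

## 7. Screen statistics

`kruskal_wallis_dunn` computes the tie-corrected H (ties are the rule
on a 4-level scale). For pooled n ≤ 10 the p-value is exact by full
enumeration of group assignments, P(H ≥ observed); otherwise the
chi-square approximation is used. If all pooled observations are equal
the contract is H = 0, p = 1. Dunn's pairwise z uses the pooled
midranks with tie-corrected variance and Bonferroni adjustment (the
convention of the usual post-test implementations).

Fingerprints: within each enhancer block, all scores are ranked
jointly, the mean rank per suppressor is divided by the vehicle's mean
rank (the vehicle entry is exactly 1), and columns are then z-scored —
the transformation is unspecified in the source field, and per-column
z-scoring was chosen so clustering reflects the rescue *pattern*
rather than per-enhancer severity (log2 and identity transforms are
available). Rows are clustered with centered-correlation distance
(1 − Pearson) and average linkage, the classic Cluster-3.0-style
convention; pairs with undefined correlation (constant rows) fall back
to their Euclidean distance. A caveat follows from the transform:
enhancer columns carrying no signal are z-scored to full amplitude, so
with very few enhancers noise columns can dominate row correlations —
fingerprints should span enough informative enhancers.

The chemical–genetic interaction contrast is
(mut,treated − WT,treated) − (mut,vehicle − WT,vehicle), with a
seeded percentile bootstrap CI resampling within cells (default 10,000
replicates); a single-observation cell flags the CI as unstable.
Percent input is $100 \cdot 2^{(Ct_{input} - \log_2(1/f)) - Ct_{IP}}$
with input fraction $f$; the SAM:SAH ratio is the elementwise quotient.

## 8. Problem sizes, calibration checks and known limitations

The test suite and acceptance script use: 20,000-CpG cohorts (12 vs 21
discovery, 7/4/5 test), 2,000-CpG cell references with 100 markers per
type, 2,500-CpG RRBS simulations at 3 vs 3 samples and 30x mean
coverage, 20,000-CpG mouse arrays with 160 planted DMPs at 4 per cell,
and screens of 30–100 larvae per chemical — sizes chosen to mirror the
assays they emulate while keeping a full run in seconds.

Null calibration of the discovery model is measured on a fully null
generation (no planted signature or age effects): a type-I-error
measurement requires every tested null to be true, and planted age
CpGs are non-null inputs whose detection is the age screen's power
check. A small residual excess (a few percent of the nominal rate)
remains at cell-type marker CpGs, whose minor-type mixture variation is
Beta-distributed and only partially captured by the two-covariate
adjustment — a faithful property of that design choice, shared with its
real-data counterpart, not an implementation artifact.

Known limitations: no surrogate-variable or batch correction; no
DMR/tiling analysis; single-transcript gene models in the annotation;
BH in place of SLIM q-values; the beta-scale modelling option is
retained for comparability but is not calibrated as tightly in the far
tail; and the fingerprint clustering inherits the noise-column caveat
above.
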