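---
title: "Meta-analysis of variability and magnitude in case-control metabolite studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-analysis of variability and magnitude in case-control metabolite studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glumeta)
```

## The scientific question

Case-control studies of brain metabolite concentrations measured by proton
magnetic resonance spectroscopy (1H-MRS) almost always ask whether the
*mean* concentration differs between patients and controls.  A complementary
question is whether patients are more *variable* than controls: greater
inter-individual spread in a patient group is what one expects if the
underlying pathology differs in kind or degree between patients, and a
frankly bimodal distribution of individual values would suggest discrete
patient subgroups.  `glumeta` implements the full analysis chain for both
questions from study-level summary data (per-arm mean, SD and n for each
study x brain region x metabolite), plus a modality analysis for
individual-level data where available.

## Effect sizes

**Variability.**  SDs in many natural systems scale with means, so a naive
SD ratio confounds variability differences with mean differences.  The
primary variability measure is therefore the log coefficient of variation
ratio,

$$\mathrm{lnCVR} = \ln\!\frac{S_p/\bar x_p}{S_c/\bar x_c}
  + \frac{1}{2(n_p-1)} - \frac{1}{2(n_c-1)},$$

whose last two terms remove the leading small-sample bias of the log SD
estimates.  The mean-unadjusted log variability ratio
$\mathrm{lnVR} = \ln(S_p/S_c) + \tfrac{1}{2(n_p-1)} - \tfrac{1}{2(n_c-1)}$
is provided for sensitivity analyses; the two coincide exactly when the
group means are equal, and their difference is always
$\ln(\bar x_c/\bar x_p)$.  Whether CV-scaling is appropriate for a given
data set can be checked with `weighted_pearson()` on the per-arm means and
SDs (weighted by arm sample sizes): a strongly positive correlation
indicates mean-scaling of the SDs.

The sampling variance of lnCVR is not part of the estimator's definition
and must be chosen.  We use the standard independent-groups approximation

$$v = \frac{S_p^2}{n_p \bar x_p^2} + \frac{1}{2(n_p-1)}
    + \frac{S_c^2}{n_c \bar x_c^2} + \frac{1}{2(n_c-1)},$$

without a mean-SD correlation term; this choice is recorded in the pipeline
output metadata as an assumption.  For lnVR,
$v = \tfrac{1}{2(n_p-1)} + \tfrac{1}{2(n_c-1)}$.

**Magnitude.**  Mean differences use Hedges' g: Cohen's d standardised by
the pooled SD and shrunk by $J = 1 - 3/(4\,df - 1)$, $df = n_p + n_c - 2$.
We use this standard approximation of the correction factor (not the exact
gamma-ratio form) and the large-sample variance
$J^2[(n_p+n_c)/(n_p n_c) + d^2/(2(n_p+n_c))]$, with an exact-df
alternative (`g_variance = "UB"`) behind a flag.  The variance formula is
validated against simulation (10,000 replicates at $n = 20+20$ agree within
5%).

**Shared controls.**  When several clinical cohorts in one study are
compared against a single control group, the control n is divided by the
number of cohorts so controls are not double-counted.  The quotient is kept
fractional by default — the bias and variance terms are continuous in n, so
rounding would only add error — with a round-half-down integer mode behind a
flag.  Effective control sizes below 2 make the bias term undefined and the
record is flagged unusable.

## Random-effects pooling

Per-study effect sizes are combined under the normal-normal model
$y_i \sim N(x_i'\beta, v_i + \tau^2)$.  The between-study variance
$\tau^2$ is estimated by restricted maximum likelihood.  The iteration is
Fisher scoring on the REML score
$\tfrac{1}{2}(y'PPy - \mathrm{tr}\,P)$ with expected information
$\tfrac{1}{2}\mathrm{tr}(PP)$, where
$P = W - WX(X'WX)^{-1}X'W$ and $W = \mathrm{diag}\{1/(v_i+\tau^2)\}$.
Plain scoring is not reliable here: on stress tests the expected
information sometimes under-estimates the curvature (the iteration
oscillates around the optimum) and sometimes over-estimates it by orders of
magnitude (the iteration creeps).  Because the problem is one-dimensional
and the score changes sign exactly once, every score evaluation tightens a
bracket around the optimum; scoring steps are accepted only inside the open
bracket and every third iteration bisects it outright, which guarantees
geometric convergence.  Tolerance is $10^{-10}$ on $\tau^2$, at most 200
iterations, with projection to zero at the boundary.  On thousands of
random instances the estimate agrees with both a $10^{-5}$-step grid search
of the restricted likelihood and an independent implementation to
$\sim\!10^{-10}$.

DerSimonian-Laird (`method = "DL"`, intercept-only) and fixed-effect
(`method = "FE"`) estimators are available for sensitivity analyses.
Coefficient tests and 95% confidence intervals use plain Wald normal
quantiles (1.959964) without a Knapp-Hartung adjustment, matching the usual
z/p reporting style of this literature.  Heterogeneity is reported as
$\tau^2$ and, for pooled fits, as
$I^2 = 100\,\hat\tau^2/(\hat\tau^2 + s^2)$ with the typical within-study
variance $s^2 = (k-1)\sum w_i/[(\sum w_i)^2 - \sum w_i^2]$, $w_i = 1/v_i$;
$I^2$ is invariant to a common rescaling of all variances.

**Subgroups and moderators.**  Antipsychotic-naive and medicated subsets
are pooled separately (each with its own $\tau^2$) and compared with a Wald
test $z = (a-b)/\sqrt{se_a^2+se_b^2}$; the comparison refuses overlapping
study sets.  Meta-regressions add one moderator at a time to the fixed
part; the reported slope is per unit of the moderator.  Records missing a
moderator drop out of that regression only, never out of pooling.  The
default minimum of 5 studies per meta-regression can be lowered, with a
warning, for exploratory use.

**Multiplicity.**  P-values are corrected per outcome measure x metabolite
*across the six brain regions* with the Benjamini-Hochberg step-up rule at
a false discovery rate of 10%.  The family definition is configurable; the
default treats regions as the multiplicity dimension because region
categories are the repeated test within each measure.

## The modality analysis

Hartigan's dip statistic is the sup-norm distance from the empirical CDF to
the nearest unimodal CDF.  For tie-free samples it is computed by the
iterative greatest-convex-minorant / least-concave-majorant algorithm: the
GCM runs through the lower corners of the ecdf jumps, the LCM through the
upper corners; each pass finds the largest gap between the hulls, shrinks
the candidate modal interval to its location, and accumulates the ecdf's
deviation from the hulls over the excluded flanks; the best unimodal fit
splits every deviation in half, giving $D$ as the accumulated maximum over
$2n$.  For tied samples the nearest unimodal *distribution function* may
place an atom at the mode, which bridges that one jump for free; corner
accounting is then no longer valid and the dip is found instead by
bisection on $d$, testing whether a convex-then-concave df (atom at the
mode allowed) fits inside the ecdf tube of half-width $d$.  Both routes are
exact: they agree with each other on continuous data and with a brute-force
minimisation over unimodal CDFs on small samples to $10^{-9}$.  Counts are
first reduced by their greatest common divisor, so duplicated samples give
exactly the dip of one copy.  Constant samples return the classical floor
$1/(2n)$.

P-values are Monte-Carlo: $p = (1 + \#\{D^{null} \ge D\})/(n_{sim}+1)$
against null samples of the same size from Uniform(0,1) — the
asymptotically least favourable unimodal distribution, and the null from
which the classical tables were built.  The default is
$n_{sim} = 2000$ and a seed is required, making every p-value reproducible;
the caller's RNG state is preserved.  Under its own uniform null the test
holds the 5% level (measured 0.043 over 1000 replicates at $n = 100$,
$n_{sim} = 999$).  For data that are genuinely normal the test is
conservative — measured type-I error 0.002 under the same settings —
which is inherent to calibrating against the least favourable null, not an
implementation artefact; dip rejections are therefore trustworthy while
non-rejections of mildly non-uniform unimodal data are expected.

`pool_and_test()` applies the test per study and to the concatenation of
normalised studies.  The default normalisation divides by the study mean
(mean-scaling), which harmonises studies quantified on different
concentration scales; mean-centring (`subtract_mean`) is also available,
but note that it does not align the component separation of studies on
different scales, so genuinely bimodal structure can be washed out of the
pooled sample under centring.  Both schemes are reported when individual
data are supplied to the pipeline, and reference schemes (creatine-scaled
vs CSF-corrected) are kept as separate strata throughout.

## The synthetic-data generator

`gen_study_level()` and `gen_individual()` emulate the statistical
structure the estimators assume, with known ground truth.  Per study $i$,
true effects are drawn as
$\theta_i = \delta\ (\mathrm{or}\ \varphi) + \sum_m \beta_m m_i + N(0,\tau^2)$,
normal per-arm samples are simulated with the implied means and CVs, and
the *sample* moments are emitted in the ingest schema (so emitted summaries
are exactly the moments of the stored samples).  The defaults describe a
realistic study base for this literature: 60 studies per cell, arm sizes
uniform on 15-80, control CV 15% around 10 institutional units, mean age
31 +/- 6 years, two-thirds male, PANSS total 70 +/- 15, chlorpromazine
equivalents 400 +/- 150 mg/day, between-study heterogeneity
$\tau = 0.05$ on both effect scales, and a 0.4 SD of the log control mean
across studies.  That last parameter emulates scanner and quantification
scale differences between sites; it is what makes SDs track means across
studies (the weighted mean-SD correlation in synthetic runs is ~0.9) while
leaving the scale-free measures untouched.  Individual-level patient values
come from a one- or two-component Gaussian mixture with components
`separation` control-SDs apart and the overall mean preserved, so the
mixing proportion's limit at zero reduces exactly to the single-component
generator.

A single integer seed governs a run, with per-study substreams derived by a
fixed counter scheme — extending `k_studies` never perturbs earlier
studies.  Moderators are drawn independently; a correlated-moderator mode
is deliberately out of scope.

What passing recovery tests show is that the estimators recover the
parameters of data generated under their own assumptions (normal arms,
study-level heterogeneity, linear moderator effects).  They do not show
robustness to skewed metabolite distributions, reporting or publication
bias, correlated moderators, or heteroscedastic measurement error across
scanners — none of which the generator emulates.

## Validation problem sizes

The shipped checks use: 50 random instances ($k \le 8$) for
REML-vs-grid-search agreement within $10^{-4}$ and 50 samples ($n \le 8$)
for dip-vs-brute-force agreement within $10^{-9}$; 200 replicates at
$k = 60$ for recovery of $\varphi = 0.15$ (median within 0.03) and of an
injected age slope of $-0.03$/year (sign recovery and CI coverage); 2000
replicates at $k = 20$ for the pooled z-test's type-I error and 1000
replicates at $n = 100$, $n_{sim} = 999$ for the dip test's, both required
to sit in $0.05 \pm 0.02$ under their respective nulls.  These sizes give
Monte-Carlo standard errors comfortably below the tolerances they are
checked against.

## Known limitations

* The lnCVR/lnVR variance formulas are approximations that ignore any
  within-study mean-SD correlation.
* Meta-regressions are study-level and one moderator at a time; they cannot
  see within-study variation and are vulnerable to ecological confounding.
* The subgroup Wald test treats subgroup estimates as independent, which is
  what disjoint study sets justify; overlap is refused rather than
  modelled.
* The dip test is conservative for unimodal data less flat than the
  uniform; with small samples it has little power against subtle mixtures.
* Longitudinal deduplication beyond first-timepoint filtering (e.g.
  choosing the largest of partially overlapping samples) is a curation
  decision left to the input table.
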