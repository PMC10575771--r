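# glumeta

Meta-analysis of **variability** and **magnitude** in case-control brain
metabolite studies.

Proton magnetic resonance spectroscopy (1H-MRS) studies of conditions such
as schizophrenia report per-group means and SDs of glutamate, glutamine or
Glx concentrations for a brain region.  Beyond the usual question — do
*mean* levels differ between patients and controls? — lies a second one: are
patients more *variable* than controls, and if so, does the individual-level
distribution look like a continuum or like discrete subgroups?  `glumeta`
implements the full analysis chain for both questions from study-level
summary tables, for meta-analysts working with this kind of literature.

## What it computes

For each study, with patient/control means $\bar x_p, \bar x_c$, reported
SDs $S_p, S_c$ and sizes $n_p, n_c$:

* **log coefficient of variation ratio** (primary variability measure;
  positive = patients relatively more variable):

$$\mathrm{lnCVR} = \ln\!\frac{S_p/\bar x_p}{S_c/\bar x_c}
  + \frac{1}{2(n_p-1)} - \frac{1}{2(n_c-1)}$$

* **log variability ratio** $\ln(S_p/S_c)$ with the same bias correction
  (mean-unadjusted sensitivity measure);
* **Hedges' g** standardised mean difference with the small-sample
  correction $J = 1 - 3/(4\,df-1)$.

Per-study effects are pooled with a **random-effects model**
$y_i \sim N(\mu, v_i + \tau^2)$, $\tau^2$ by REML (DerSimonian-Laird and
fixed-effect variants available), with Wald z tests, 95% CIs and $I^2$;
antipsychotic-naive and medicated subsets are compared by Wald tests;
moderator **meta-regressions** (age, proportion male, symptom scores,
antipsychotic dose) run per region x metabolite; **Benjamini-Hochberg FDR**
(q = 10%) corrects across brain regions per measure x metabolite.
Individual-level data are tested for unimodality with **Hartigan's dip
statistic** (exact GCM/LCM computation, Monte-Carlo calibration against the
uniform null), per study and pooled after mean-scaling.

A synthetic-data generator with known ground truth (`gen_study_level()`,
`gen_individual()`) makes every stage testable end to end.

## Worked example

```r
library(glumeta)

# a synthetic study base: 20 studies, true lnCVR 0.15, true g -0.15
sim <- gen_study_level(synth_config(k_studies = 20, seed = 42))

es  <- effect_sizes(sim$table, measure = "lnCVR")
fit <- remeta(es$yi, es$vi)
fit
#> Random-effects pooling (k = 20, REML)
#> tau^2 = 0, I^2 = 0%
#>           estimate     se      z p  ci.lb  ci.ub
#> intercept   0.1963 0.0361 5.4384 0 0.1256 0.2671
```

The pooled lnCVR of 0.196 (95% CI 0.126-0.267) recovers the generating
value 0.15 to within sampling error of a 20-study set; $\hat\tau^2 = 0$
says the per-study sampling variances already explain the between-study
spread.  The full pipeline runs every measure, subset, meta-regression and
FDR family at once:

```r
res <- run_full_analysis(sim$table)
res
#> glumeta analysis: 20 records
#> Pooled results (subset = all):
#>  measure region metabolite  k estimate ci_low ci_high p i2
#>    lnCVR    MFC  glutamate 20    0.196  0.126   0.267 0  0
#>     lnVR    MFC  glutamate 20    0.153  0.084   0.222 0  0
#>      SMD    MFC  glutamate 20   -0.273 -0.368  -0.177 0  0
#> Weighted mean-SD correlation: 0.92
#> 8 meta-regressions ( 0 with p < 0.05 )
```

The weighted mean-SD correlation of 0.92 across study arms confirms that
SDs scale with means here, which is exactly why the CV-based measure is the
right variability outcome.  Individual-level data go through the dip test;
with a deliberately bimodal generator (two components six control-SDs
apart):

```r
ind <- gen_individual(synth_config(k_studies = 5, seed = 42,
         mixture = list(components = 2L, separation = 6, mixing = 0.5)))
pool_and_test(ind[ind$group == "patient", ], n_sim = 2000, seed = 7)
#> Pooled dip test over 5 studies ( divide_by_mean ):
#> Hartigan's dip test (Monte-Carlo, n_sim = 2000)
#> D = 0.07, n = 248, p = 5e-04  [bimodal_evidence]
#> Per-study verdicts: 1 unimodal-compatible, 4 with bimodality evidence
```

Real tables enter through `read_study_table()` (schema in
`study_table_schema()`; free-text voxel labels are harmonised via
`assign_region()`, J-edited/EPSI records rescaled, shared control groups
adjusted, and invalid rows collected with reasons).  A thin command-line
front end with `validate` / `analyze` / `simulate` / `dip` / `export` verbs
ships at `inst/cli/glumeta.R`.

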