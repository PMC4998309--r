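# nodalstage

Comparing lymph-node staging systems for gastric cancer — the number-based
pN stage, the node ratio rN, and the log odds of positive nodes (LODDS) —
with survival-based cutpoint derivation, composite TNM/TRM/TLM stage
groups, and a synthetic-cohort simulator for studying stage migration.

## The problem

After curative gastrectomy, prognosis is driven by nodal involvement, but
the pN stage (the count of metastatic nodes) depends on how many nodes were
examined: shallow lymphadenectomy under-counts positives and down-stages
patients (the "Will Rogers" stage-migration phenomenon). Two sample-size-
aware alternatives are

```
rN    = pnod / tnod
LODDS = ln((pnod + 0.5) / (tnod - pnod + 0.5))
```

where `pnod` and `tnod` are the positive and total retrieved node counts.
LODDS separates even node-negative patients (for `pnod = 0` it equals
`-ln(2 * tnod + 1)`, decreasing in retrieval depth), which is exactly what
the ratio cannot do.

The package implements:

* score computation and classification for all three axes, including the
  conventional schemes (rN cut at 0.1/0.2/0.3 with rN0 = exact zero;
  LODDS cut at −4/−2.5/−2/−0.5) under the `(lower, upper]` convention;
* composite stage grouping: TNM, and its TRM / TLM analogues that replace
  the pN axis by the rN or LODDS class, via the 7th-edition table;
* data-driven cutpoint derivation: scan a score at a fixed interval,
  tabulate per-bin 5-year survival, merge adjacent bins with similar
  prognosis (largest pairwise log-rank p) down to a target class count;
* a self-contained survival toolkit — Kaplan–Meier, k-group log-rank, Cox
  proportional hazards (Breslow/Efron ties) — cross-checked in the tests
  against brute-force oracles and the `survival` package;
* the evaluation battery: cross-stratified 5-year survival tables,
  Spearman correlation of each axis with retrieval count, correlated
  ROC-AUC contrasts (paired DeLong), composite-system discrimination and
  within-stage reclassification;
* a synthetic cohort generator (latent involvement, binomial nodal
  sampling, Weibull proportional hazards on true nodal burden) with a
  paired migration-scenario generator.

## Worked example

```r
library(nodalstage)

co  <- simulate_cohort(simulation_config(n_patients = 2000, seed = 42))
st  <- stage_cohort(co)
st[1:3, c("id", "rn_score", "lodds_score", "pn_class", "rn_class",
          "lodds_class", "tnm_group", "tlm_group")]
#>       id rn_score lodds_score pn_class rn_class lodds_class tnm_group tlm_group
#> 1 P00001    0.000   -4.418841      pN0      rN0      LODDS1        IA        IA
#> 2 P00002    0.075   -2.371578      pN2      rN1      LODDS3       IIA       IIA
#> 3 P00003    0.000   -4.595120      pN0      rN0      LODDS1        IA        IA
```

Patient `P00002` has 3 of 40 nodes positive: by count pN2, by ratio only
rN1, and LODDS lands in the middle class — the three axes
genuinely disagree, which is why the comparison needs survival data.

```r
fit <- cox_fit(co$time, co$event, cbind(lodds = co$true_lodds))
fit
#> Cox proportional-hazards fit (breslow ties), n = 2000, events = 516
#>            coef         se       HR  lower95  upper95        z             p
#> lodds 0.7048075 0.02416989 2.023457 1.929835 2.121621 29.16056 6.138113e-187
```

The generator's true log-hazard per LODDS unit is 0.7; the fit recovers
0.705 (hazard ratio 2.02 per unit) well within one standard error.

```r
rep <- evaluate_cohort(co, st)
rep$roc$auc[1:3, c("axis", "auc", "ci_lower", "ci_upper")]
#>          axis   auc ci_lower ci_upper
#> 1        pnod 0.873    0.851    0.895
#> 2    rn_score 0.874    0.852    0.896
#> 3 lodds_score 0.871    0.847    0.895
```

AUCs against death within 60 months are statistically indistinguishable
across axes (pairwise DeLong tests in `rep$roc$pairwise`), while the
stratified tables and the stage-IA reclassification (`rep$subgroup_ia`)
show where LODDS separates patients the other axes cannot.

## The analysis workflow

The `analysis/` scripts run the study end to end, writing tables to
`results/`:

1. `01_simulate.R` — the working cohort and its summary statistics;
2. `02_stage.R` — staging on all axes, class distributions;
3. `03_cutpoints.R` — survival-derived rN and LODDS schemes with merge
   traces, plus planted-boundary recovery on a benchmark;
4. `04_evaluate.R` — the comparative battery (stratified survival,
   correlations, ROC, composite systems, stage-IA subgroup);
5. `05_migration.R` — paired shallow-vs-deep lymphadenectomy cohorts: pN
   misclassification against exhaustive-dissection reference staging and
   the discrimination cost for TNM vs TLM.

Run them in order with `Rscript analysis/01_simulate.R`, etc.

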