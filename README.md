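# pedri — indirect pediatric reference intervals

`pedri` establishes age- and sex-specific pediatric reference intervals
(RIs) for blood trace elements (Cu, Zn, Ca, Mg, Fe, Pb) from routine
laboratory data by the **indirect method**: instead of recruiting
healthy children, it statistically isolates the non-pathological
component of mixed outpatient data. It is aimed at clinical-laboratory
scientists and biostatisticians who want every step of such a pipeline
— cleaning, partitioning, estimation — as tested, auditable code.

The pipeline:

1. **Outlier cleaning** — Tukey fences (`Q1 − 1.5·IQR`,
   `Q3 + 1.5·IQR`) applied per analyte × sex × whole-year age cell and
   repeated to a fixed point.
2. **Age partitioning** — a depth-2 regression tree proposes candidate
   age cuts; every adjacent pair of bins is then validated with the
   Harris–Boyd z test

   z = (X̄₁ − X̄₂) / √(s₁²/n₁ + s₂²/n₂),  z* = 3·√((n₁+n₂)/240),

   the SD-ratio rule (max(s₁,s₂)/min(s₁,s₂) > 1.5 supports a split),
   and the Lahti proportionality criterion (any subgroup proportion
   outside the pooled 2.5th/97.5th limits ≥ 4.1% or ≤ 0.9% supports a
   split). Pairs no criterion keeps apart are merged; surviving bins
   are re-examined for further subdivision until stable.
3. **RI estimation** — an inverse model search: for each Box-Cox power
   λ on a grid, the transformed data's central region is compared with
   the normal model implied by its robust location/scale (median and
   IQR/1.349); the best-explaining model yields lower/median/upper
   limits at μ ± 1.959964·σ, back-transformed. 95% CIs come from a
   200-replicate percentile bootstrap with full refits.

Because no patient-level data are distributable, the package ships a
synthetic-cohort generator (`default_config()`, `generate_cohort()`)
whose healthy component is Box-Cox-normal with realistic age trends and
whose closed-form quantiles (`true_reference_limits()`) act as a
recovery oracle for everything downstream.

## Worked example

Simulate a cohort (19.2% pathological contamination, shifted +3 SD) and
run the full pipeline for magnesium, whose true age trend is flat:

```r
library(pedri)
cfg    <- default_config(n_subjects = 1500)
cohort <- generate_cohort(cfg, seed = 11)
mg     <- cohort[cohort$analyte == "Mg", ]
run_pipeline(mg, B = 200, seed = 11)
#>  Analyte Sex Age     n   Median            Lower             Upper
#>  Mg      F   0 mths– 629 1.53 (1.52, 1.54) 1.28 (1.20, 1.31) 1.90 (1.81, 1.99)
#>  Mg      M   0 mths– 752 1.54 (1.53, 1.56) 1.34 (1.28, 1.36) 1.87 (1.77, 1.89)

true_reference_limits(cfg, "Mg", "M", 48)
#> lower median  upper
#>  1.29   1.53   1.77
```

Reading the output: the validation loop correctly collapsed magnesium
to a single age bin per sex ("0 mths–" is open-ended); each bin shows
the fitted median and 2.5th/97.5th limits with bootstrap 95% CIs. The
estimated male limits (1.34, 1.87) sit close to the generating healthy
percentiles (1.29, 1.77); the upper limit leans a few percent high —
the residual footprint of the one-sided contamination that the
estimator suppresses but cannot erase. Analytes with real age trends
(e.g. zinc) instead come back partitioned into several age bins, each
flagged `n<120` where a bin falls below the conventional minimum
subgroup size.

The result object also carries `$partitions` — the complete
merge/split audit (z, z*, SD ratio, the four Lahti percentages and the
action taken for every decision) — and `$removed`, the outliers dropped
during cleaning.

## The analysis workflow

The `analysis/` scripts run the study end to end on the simulated
cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R   # cohort.csv: 3,933 records/analyte
Rscript analysis/02_clean.R             # iterated Tukey cleaning + sidecar
Rscript analysis/03_partition.R         # per-stratum partitions + audit
Rscript analysis/04_reference_intervals.R  # report.csv/txt + truth scoring
```

Step 4 also scores every bin against the generator's closed-form
percentiles — the check a real study cannot perform.

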