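---
title: "Indirect pediatric reference intervals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indirect pediatric reference intervals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedri)
```

## The problem

A reference interval (RI) is the central 95% of results in a
non-pathological population, bounded by the 2.5th and 97.5th
percentiles. Recruiting healthy children per subgroup — the *direct*
method — is expensive and rarely done, so pediatric RIs are often
borrowed from kit inserts. The *indirect* alternative mines routine
laboratory data, which mix a dominant non-pathological majority with a
minority of pathological results, and isolates the non-pathological
component statistically. `pedri` implements such a pipeline for blood
trace elements (Cu, Zn, Ca, Mg, Fe, Pb) in children, where analyte
levels shift strongly with age and somewhat with sex, so the population
must first be partitioned before a common interval makes sense.

The pipeline has four stages, each exported on its own:

1. **Cleaning** — iterated Tukey fences per analyte × sex × whole-year
   cell (`iterative_tukey_clean()`, `clean_cohort()`).
2. **Partition proposal** — a depth-limited regression tree on age
   (`fit_age_tree()`).
3. **Partition validation** — Harris–Boyd and Lahti criteria with a
   merge/re-split refinement loop (`harris_boyd()`, `lahti()`,
   `refine_partition()`).
4. **Estimation** — an inverse Box-Cox model search for the
   non-pathological component, with percentile-bootstrap CIs
   (`fit_indirect_model()`, `reference_interval()`, `bootstrap_ci()`).

`run_pipeline()` chains all four; the numbered scripts under
`analysis/` drive them step by step on a simulated cohort.

## The estimation model

The non-pathological component of one subgroup is modelled as
Box-Cox-normal: there is a power $\lambda$ such that

$$ z = \begin{cases} (x^\lambda - 1)/\lambda & \lambda \neq 0 \\
\log x & \lambda = 0 \end{cases} $$

is Gaussian with location $\mu$ and scale $\sigma$. Pathological
results are assumed to sit mainly in the tails. Rather than trimming
tails, the estimator works *inversely*: for each $\lambda$ on a grid
($-2$ to $2$ in steps of $0.1$) it transforms the data, estimates
$\mu$ as the transformed median and $\sigma$ from the central
inter-quantile spread ($(q_{0.75}-q_{0.25})/1.349$, the
normal-consistent scaling), and scores how well the implied
$\mathcal N(\mu, \sigma)$ explains the *central region*
$[\mu - 1.28\sigma,\ \mu + 1.28\sigma]$ with a chi-square-type
histogram cost over 20 equal-width bins:

$$ \mathrm{cost}(\lambda) = \sum_{j=1}^{20}
   \frac{(O_j - E_j)^2}{\max(E_j, 1)}, $$

where $E_j$ is the model's bin probability renormalised over the
central region times the number of observations in that region.
Renormalising makes the expected counts sum to the observed total, so
the cost compares *shape* inside the central region and ignores how
much mass sits outside it — which is exactly what keeps tail
contamination from steering the fit. The winning $\lambda$ (ties go to
the smaller $|\lambda|$) yields the limits

$$ \widehat{L}, \widehat{M}, \widehat{U} =
   g^{-1}_{\lambda}(\mu \mp 1.959964\,\sigma),\
   g^{-1}_{\lambda}(\mu). $$

Because $\mu$ and $\sigma$ come from quantiles at probabilities 0.25,
0.5 and 0.75 — all inside the default 20th–80th-percentile central
window — no observation outside that window influences the point
estimates.

Confidence intervals are nonparametric percentile bootstrap: $B = 200$
resamples with replacement, a full refit (including the $\lambda$
search) per resample, and the 2.5th/97.5th percentiles of each
replicate limit. Replicate failures are dropped and counted; more than
10% aborts.

### What the estimator can and cannot do

Simulation (the acceptance suite) characterises the estimator's
operating range:

- On a pure component the fitted interval captures the central 95% of
  the sample almost exactly, and under tail contamination of 5–20%
  shifted $+2.5$ to $+4$ SD the indirect upper limit is substantially
  closer to the generating 97.5th percentile than the naive empirical
  percentile of the mixed sample — the property the method exists for.
  The residual bias is upward, because the 75th percentile used for
  $\sigma$ is itself mildly inflated by heavy upper-tail mixing.
- $\lambda$ is only weakly identified when the component's coefficient
  of variation is small: the central 60% of a narrow distribution looks
  Gaussian under any nearby power. This is benign — when $\lambda$ is
  unidentifiable the limits are also insensitive to it — except at
  intermediate CV (around 0.2, e.g. the copper component), where
  grid-selection noise puts roughly ±3–8% of wobble on the lower limit
  at $n = 2000$.
- For very wide components (the lead component has log-scale SD 0.85,
  an upper limit 5.3× the median) the *sampling* noise of any
  quantile-based estimate of the 97.5th percentile at $n = 2000$
  exceeds 5% relative; tighter claims would need more data, not a
  better estimator.

## Partition validation

Adjacent age subgroups are compared with three criteria:

- **Harris–Boyd z test**: $z = (\bar X_1 - \bar X_2) /
  \sqrt{s_1^2/n_1 + s_2^2/n_2}$ against the size-scaled critical value
  $z^* = 3\sqrt{(n_1 + n_2)/240}$ (exactly 3 when the pooled size is
  240). Exceeding $z^*$ supports separate intervals.
- **SD-ratio rule**: a larger-to-smaller SD ratio above 1.5 supports a
  split regardless of means, because a common interval would mis-cover
  the tighter subgroup.
- **Lahti proportionality**: pool both subgroups, take the pooled
  2.5th/97.5th percentiles as common limits, and count the percentage
  of each subgroup strictly outside each limit; any of the four
  percentages $\geq 4.1$% or $\leq 0.9$% supports a split.

`refine_partition()` starts from the tree's candidate cuts, merges any
adjacent pair that *no* criterion keeps apart (greedy left-to-right,
repeated to stability), then re-runs the tree inside each surviving bin
and accepts a proposed cut only when the same criteria validate it,
looping up to 20 passes. Every decision — statistics, verdicts, action
— is recorded in an audit table that ships with the result.

Two design choices here deserve their rationale:

- **Removed cuts are never re-proposed.** The pair a cut is tested
  against changes as its neighbours merge, so a cut can be "unreasonable"
  in one configuration and "reasonable" in another; re-admitting removed
  cuts lets the loop cycle between configurations indefinitely.
  Blocking them guarantees termination and resolves oscillating cuts in
  favour of merging, the conservative direction for a partition.
- **Lahti needs 120 observations per subgroup.** The proportions are
  observed counts with resolution $100/n$ percentage points; below
  $n = 112$ a proportion in $(0, 0.9]$% is not even representable, so
  the low-proportion rule collapses to "zero tail observations", which
  identically distributed subgroups hit routinely by chance. 120 is
  both the smallest round size above that bound and the conventional
  minimum reference-subgroup size. Pairs below it fall back to the
  Harris–Boyd criteria alone.

Even above the floor, counted tail proportions remain noisy: for
subgroups of 120–400 the false-split rate per homogeneous pair is of
order 10–20%, so refined partitions of strongly trending (or
contaminated) data tend to be finer than a human reviewer would draw.
The audit table exists precisely so such splits can be inspected, and
each reported bin carries an `n<120` flag where the CLSI minimum is not
met.

## The synthetic cohort

No patient-level data ship with the package; `default_config()` defines
a generative stand-in with the structure the analysis assumes:

- **Healthy component**: per analyte and sex, Box-Cox-normal with a
  piecewise-linear age trend in the transformed location and constant
  scale. The simplest family matching the estimator's model class, so
  recovery can be tested against closed forms
  (`true_reference_limits()`).
- **Defaults**: cohort median-age medians of 19.74 (Cu, µmol/L), 74.80
  (Zn, µmol/L), 1.60 (Ca, mmol/L), 1.52 (Mg, mmol/L), 7.84 (Fe,
  mmol/L), 126.09 (Pb); Cu, Ca and Pb decline with age, Zn and Fe
  rise, Mg is flat, Pb turns upward after 15 years; age profile with
  mode at 1–<2 years (17.75%) and sparse beyond 14 years; 56.32%
  male, females offset slightly lower for Zn/Ca/Mg/Fe. Scales are
  calibrated so per-bin interval widths are realistic for each
  analyte. Unit strings are opaque labels.
- **Contamination**: a single Gaussian on the transformed scale,
  shifted $+3$ healthy SDs and 1.5× wider, mixed at 19.2% — the
  excluded-abnormal fraction typical of unscreened outpatient data,
  modelling one-sided deficiency/excess referral. It stresses the upper
  limit, the harder tail for indirect estimation.

```{r example}
cfg <- default_config(n_subjects = 500)
cohort <- generate_cohort(cfg, seed = 1)
head(cohort, 3)
true_reference_limits(cfg, "Cu", "M", age_months = 48)
```

What the generator does **not** emulate: analytical imprecision and
batch effects between centres, age-varying dispersion, correlated
multi-analyte panels per child, two-sided pathology, and rounding of
reported values. Tests passing on this cohort therefore demonstrate
that the pipeline recovers the structure it models — not that real
trace-element data satisfy that structure.

## Numerical conventions

- **Quantiles**: one convention everywhere — sort, $h = (n-1)p + 1$,
  linear interpolation between bracketing order statistics
  (`compute_quantile()`, the mode-7 rule).
- **Tukey fences**: multiplier 1.5; *strictly* outside flags an
  outlier, so boundary values survive; cells under 8 observations pass
  through uncleaned; the fence pass repeats until a fixed point.
- **Tree**: candidate thresholds are midpoints between consecutive
  distinct ages; gain ties within $10^{-12}$ relative resolve to the
  youngest age; a node with no achievable gain does not split; both
  children must hold `min_leaf` (default 50) observations.
- **Half-open bins**: ages are integer months, bins $[lo, hi)$;
  non-integer tree thresholds round up to the first month of the
  right-hand bin; "1 to <2 years" is $[12, 24)$.
- **Degenerate inputs**: zero-IQR samples refuse to fit ("no spread");
  zero-variance subgroup pairs with equal means give $z = 0$, with
  unequal means an infinite $z$ (logged); back-transforms outside the
  Box-Cox domain error with the model context rather than returning
  `NaN`.
- **Determinism**: every stochastic entry point takes an explicit
  seed; identical inputs and seeds give bit-identical outputs,
  including the bootstrap.

## Problem sizes in the test suite

The packaged tests run the estimator checks at $n$ = 2,000–10,000 with
50-seed repetition where rates are asserted, the partition-recovery
checks at $n$ = 1,000–2,000 over 8–20 seeds, and the Monte-Carlo
generator checks at $n$ = 50,000–100,000 single draws — sizes chosen so
the full suite completes in a few minutes on one core while keeping
every assertion's sampling margin wide.

## Known limitations

- The estimator is a deliberately simplified member of the inverse
  family: one global Box-Cox power, robust quantile matching, a single
  central-region cost. It does not reproduce any published
  implementation's multi-region search or information-criterion model
  selection.
- Quantile-based $\sigma$ retains an upward bias under heavy one-sided
  contamination (the 75th percentile of the mixture is shifted), so
  upper limits on heavily contaminated bins lean high even though they
  beat naive percentiles.
- Counted Lahti proportions make the refinement loop split-happy on
  large, strongly trending strata; treat fine partitions as candidates
  for review, not verdicts.
- Continuous age trends have no "true" partition: piecewise-constant
  bins approximate the trend, and more data legitimately support more
  bins. Comparisons with published partitions are therefore
  qualitative.
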