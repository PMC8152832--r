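---
title: "Models and methods behind inhibmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind inhibmet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inhibmet)
```

This vignette is the package's own account of its science: the race model
behind the simulator, the behavioral estimators, the MRS tissue correction,
the statistical chain, and the design decisions taken where the procedures in
common use are typically under-specified.

## The independent race model

Each trial of the anticipated-response stop-signal task is modelled as a race
between two processes:

* a **go process**: the planned finger-lift time `T ~ Normal(mu + delta_c,
  sigma)`, where `mu` is the subject's intended lift time (the task rewards
  lifts near the 800-ms target crossing), `sigma` the trial-to-trial timing
  noise, and `delta_c` an additive proactive-slowing shift for the block
  context `c` (0 in pure-go blocks, `delta_20` and `delta_40` in blocks with
  20% and 40% stop-signal probability);
* a **stop process** of fixed latency `ssrt_true`, triggered when the
  indicator halts at the stop-signal delay (SSD).

The stop wins — the lift is cancelled — iff `T >= SSD + ssrt_true`. On a
failed stop the response escapes and the observed RT is `T` itself, which is
why failed-stop RTs are stochastically faster than go RTs drawn from the
same parameters: escaping requires an early draw. The two processes are
independent by assumption; this is the model under which the integration
estimator of SSRT is consistent, which is precisely why the simulator adopts
it. Context-dependent stop latencies and trigger failures are deliberately
out of scope.

The **staircase** is one-up-one-down with a fixed 33-ms step: the SSD rises
after each successful stop and falls after each failure, clamped to
`[33, 767]` ms so the indicator always halts before the 800-ms crossing.
A one-up-one-down rule converges to the 50% point of the underlying
inhibition function, so long runs must show `P(inhibit) ~ 0.5` regardless of
the subject's parameters — the package's acceptance script recomputes exactly
this calibration. The starting SSD defaults to 550 ms: steady-state SSDs for
a subject aiming at 800 ms with a ~200-ms stop latency sit near 600 ms, and
starting slightly below costs only a short burn-in. Because published
descriptions typically report a single mean SSD, one staircase is shared
across the 20% and 40% conditions by default (`per_condition_staircase`
switches to separate tracking), and the staircase carries over between the
two assessment sessions by default (`reset_staircase = TRUE` restarts it;
the choice is exposed rather than asserted because either protocol is
plausible and the carried-over variant merely shortens the session-2
burn-in).

Go trials are contaminated at configurable rates by **early responses**
(anticipatory lifts, drawn uniform on [150, 400) ms) and **omissions** (no
lift before the 1280-ms display cutoff, recorded as missing). Both default
to 1%, a typical order of magnitude for practiced adults on this task.

## Behavioral measures

Per session and subject:

* `go_rt` — mean go RT in the 0% SSP block, after removing go trials with
  RT < 400 ms or missing/late RT (> 1280 ms). The filter applies to go
  trials only; failed-stop RTs enter `rt_sf` unfiltered, a literal reading
  of the filtering rule, which names go trials alone.
* `go_rt_20`, `go_rt_40` — the same for the two stop-signal-probability
  contexts; `proactive_slowing = go_rt_40 - go_rt_20`.
* `ssrt` — integration method over the **pooled** 20% + 40% blocks: the
  valid go RTs are rank-ordered, `n = N * P(inhibit)` is rounded half-up and
  clamped to `[1, N]`, and the mean SSD over all stop trials is subtracted
  from the `n`-th go RT. Rounding half-up is symmetric and matches the
  estimator's quantile interpretation; the pooling follows the convention of
  computing a single SSRT across both stop contexts. Omitted go trials are
  removed before the rank step (the consensus alternative of imputing the
  maximum RT is intentionally not used, for fidelity to the filtering rule
  above).
* `mean_ssd`, `p_inhibit`, `rt_sf` — mean SSD over stop trials, fraction of
  successful stops, mean RT over failed stops.

Measures are computed per session and then averaged, so a session lost to a
degenerate `P(inhibit)` (0 or 1, where the rank rule is undefined) drops out
of the SSRT average with a warning instead of poisoning it. Proactive slowing
is differenced from the session-averaged `go_rt_40` and `go_rt_20` by
default; `proactive_by_session = TRUE` differences within sessions first.
The two orders coincide for balanced designs, which is why the default is a
matter of convention rather than substance.

## MRS quantification

Water-referenced metabolite signal ratios are converted to concentrations
with the standard compartmental water-scaling correction:

$$C = S \cdot C_{H_2O} \cdot \frac{\sum_k f'_k R_k}{(1 - f'_{CSF})\,A_{met}},
\qquad R_k = \left(1 - e^{-TR/T1_k}\right) e^{-TE/T2_k},$$

where `S` is the metabolite-to-water amplitude ratio, `C_H2O = 55510` mM,
`f'_k` are the water-content-weighted volume fractions (GM 0.78, WM 0.65,
CSF 0.97) and `R_k` the compartment water relaxation attenuations. The
shipped relaxation times (T1 1331/832/3817 ms, T2 110/79/503 ms for
GM/WM/CSF at TR 2000 ms, TE 68 ms) are the canonical compartment **water**
constants at 3 T. They are treated as water constants inside the correction
— not as metabolite relaxation times — because that is the only reading
under which the formula is internally consistent; any metabolite relaxation
correction is exposed separately as `metabolite_attenuation`, defaulting to
1 (no correction), since whether one should be applied is acquisition- and
fitting-dependent.

Quality control admits a spectrum only with linewidth strictly below 10 Hz
and SNR strictly above 5; failures carry a reason code and their
concentrations are set missing, which then propagates through ratios,
pairwise-deleted correlations and listwise-deleted regressions. Tissue
fractions that mis-sum by rounding (up to 1e-3) are renormalized with a
warning — segmentation outputs routinely mis-sum — while larger departures
are rejected. The correction is linear in the signal and strictly increasing
in the CSF fraction (a shrinking `1 - f'_CSF` divisor), two properties the
test suite checks directly.

The NAA/mIns concentration ratio is appended to the corrected panel as a
pseudo-metabolite per region so it flows through the same screening and
regression machinery as the single metabolites.

## The synthetic cohort

`simulate_cohort()` emulates a two-group aging cohort (defaults: 25 young,
26 older). Group-level race parameters place the young group at a ~193-ms
true SSRT and the older group at ~206 ms with slightly later planned lifts
and a slightly larger 40%-context shift, i.e. a selective reactive-inhibition
deficit; between-subject SDs (planned lift 9/20 ms, SSRT 12/17 ms for
young/older) are chosen so the simulated group summary tables land in the
range reported for cohorts of this design. Metabolite reference levels
(NAA 12, Glx 10, Cr 8, Cho 2, mIns 6 mM-equivalent, SDs 8–12% of the mean)
are typical of water-referenced 3 T quantification. The older group's means
are shifted by the canonical aging pattern (NAA −0.6 SD, mIns +0.7 SD,
Cho +0.6 SD, Glx and Cr stable), applied as within-group constants so they
never disturb within-group correlations.

**Planted effects.** Each requested effect (group, region, metabolite,
behavioral measure, target `r`) is planted so that the *sample* correlation
between the metabolite level and the subject's **measured** behavioral
statistic equals the target exactly: the behavior vector is standardized,
fresh noise is residualized against it and standardized, and the two are
mixed with weights `(r, sqrt(1 - r^2))`. The exact-sample construction —
rather than drawing from a population with correlation `r` — makes the
planted effect a fixed property of the generated dataset, so downstream
recovery rates measure the pipeline (QC losses, pairwise deletion, screen
thresholds, collinearity in the regression) rather than the generator's own
sampling error. Ratio effects (e.g. preSMA NAA/mIns vs SSRT) are planted on
the ratio itself, with the numerator rebuilt as ratio × denominator.
Planting against the measured statistic, not the latent subject parameter,
avoids attenuating the target by behavioral measurement error.

Voxel fractions are drawn Dirichlet-style around (GM, WM, CSF) =
(0.50, 0.40, 0.10) with mild variation; metabolite levels are stored as
water-referenced signal ratios obtained by **inverting** the tissue
correction at each voxel's own fractions, so correcting the panel with the
shipped constants returns the planted concentrations and the planted
correlations survive the correction stage. A configurable fraction of
spectra (default 4%, matching the exclusion rate typical of these studies)
is forced to violate one QC rule.

**What the generator does not emulate**, and what passing tests therefore do
not establish about real data: violations of race-model independence,
context-dependent or variable stop latencies, trigger failures, RT
distribution skew (planned lifts are Gaussian by construction), regional
covariance of metabolite levels within subject, acquisition drift, and any
nonlinearity between metabolite levels and behavior. Recovery results say
the *pipeline* is correct under the stated model, not that the model is
true.

## Statistical chain

* **Group comparisons** use the pooled-variance Student's t (df =
  n1 + n2 − 2), computable from summary statistics alone so printed tables
  can be re-tested; a Welch variant sits behind `var_equal = FALSE`. The
  pooled default is the variant consistent with df = 49 reported for a
  25 + 26 comparison. Zero pooled variance with unequal means yields a
  signed infinite t with a warning rather than an error.
* **FDR control** is Benjamini–Hochberg step-up at q = 0.05 across the full
  family of region × metabolite (and ratio) group comparisons in one run —
  the placement of FDR alongside the group t-tests, with the family taken as
  everything tested together. The reported *critical p* is the largest raw p
  among the rejected tests.
* **Screening** computes Pearson correlations of every region × metabolite
  cell (ratios included) against each behavioral measure within each group,
  with pairwise deletion of QC-failed values, flagging candidates at
  uncorrected two-tailed p < 0.05. The screen is deliberately uncorrected:
  it selects predictors, and the follow-up regression quantifies them.
* **Regression** is OLS with listwise deletion, reporting R², adjusted R²,
  the overall F, raw B (SE), standardized β (SE; both response and
  predictors z-scored — full standardization, matching the dual β/B
  reporting convention) and the **R² change** per predictor: the drop in R²
  when that predictor is removed, equal to its squared semipartial
  correlation. Because predictors correlate, the R² changes need not sum to
  R²; the unattributed remainder is shared variance. When screening admits
  more candidates than a small sample supports, the largest-|r| candidates
  are kept up to `n - 3` predictors. A documented two-step refit drops
  predictors whose R² change falls below 1% and refits, reporting both
  models — an explicit, reproducible version of the "negligible
  contributors removed" reduction that published model summaries often
  apply without stating a criterion.
* **Fisher r-to-z** compares two independent correlations via
  `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-tailed.

All tests are two-tailed throughout.

## Numerical choices and degenerate inputs

* SSRT rank: `n = round_half_up(N * P(inhibit))`, clamped to `[1, N]`;
  `P(inhibit)` of exactly 0 or 1 is an estimation error (the quantile is
  undefined at the boundary for this estimator).
* Staircase SSDs are clamped to `[33, 767]` ms.
* Tissue-fraction renormalization tolerance: warn and renormalize up to
  1e-3 mis-sum, reject beyond; a pure-CSF voxel (`f_csf = 1`) is an error
  (division by zero in the correction).
* Rank-deficient regression designs raise an error naming the offending
  predictors rather than silently dropping them.
* All randomness flows from a single master seed through named per-stage
  substreams (`run_pipeline`) or a single stream (`simulate_cohort`), so
  identical seeds give bit-identical tables.

## Problem sizes used in the checks

The test-suite and acceptance checks run at sizes chosen to make their
statistical bounds sharp while remaining desk-scale: staircase convergence
uses 20 replicates of 400 stop trials (burn-in 50); SSRT recovery uses 5000
go and 2000 staircased stop trials; proactive-slowing recovery uses 10⁴ go
trials per context; the end-to-end screen-plus-regression recovery uses 200
replicate cohorts at the default 25 + 26 subjects with the bilateral
striatal Glx pattern (r = −0.57 and +0.52 against go RT) planted in the
young group, requiring correct-sign recovery in at least 90% of replicates.

## Known limitations

The simulator's Gaussian go process cannot produce the right-skewed RT
distributions of real data, so integration-method biases that arise from
skew are invisible here. Metabolite levels are independent across regions
within subject, which understates the multiplicity burden a real correlation
screen faces. The FDR family is configurable but defaults to the group
comparisons only; screening is uncorrected by design. No mixed models,
trigger-failure correction, or parametric SSRT estimation are provided —
they are different methods, not refinements of these.
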