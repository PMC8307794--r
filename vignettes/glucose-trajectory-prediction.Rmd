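---
title: "Predicting post-meal blood glucose trajectories from dietary and insulin logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting post-meal blood glucose trajectories from dietary and insulin logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucopred)
```

## The prediction problem

Insulin-dependent patients must judge, meal by meal, how their blood glucose
level (BGL) will evolve until the next meal. glucopred predicts the full
post-meal BGL trajectory at the 2-minute resolution of a continuous glucose
monitor (CGM), over horizons of 60, 90, 120 and 180 minutes, from nothing but
a lifestyle log: meal compositions, bolus and basal insulin events, and a
fingertip baseline reading before the meal. Models are trained and evaluated
patient by patient — glycemic response is too individual for pooled models at
this data scale — and the training data a patient must collect amount to
roughly two weeks of CGM wear.

The package has five working parts: a glucose **absorption model** that turns
a meal's composition into a glucose infusion rate curve; a **feature
extractor** that reduces that curve, plus the insulin context, to five scaled
network inputs; a small **feed-forward network** regressing the whole target
trajectory at once; a **pipeline** for per-patient training, hybrid
prediction and evaluation; and a **virtual-patient simulator** that
generates complete cohorts with known ground truth, so every stage is
testable without clinical data.

## The absorption model

The absorption stage estimates the rate (g/min) at which a meal's digestible
carbohydrate reaches the blood. It is a deliberately small two-compartment
stomach-to-gut cascade, written so that the qualitative behaviour the
downstream features rely on is honest: fat, protein and fiber slow gastric
emptying; the glycemic index (GI) scales starch digestion; and essentially
all digestible carbohydrate is eventually absorbed.

With stomach pools $S_m$ (monosaccharide) and $S_s$ (starch), gut pools
$Q_s$ (starch) and $Q$ (glucose):

$$
\begin{aligned}
k_e &= \frac{k_{e0}}{1 + \alpha_p P + \alpha_l L + \alpha_f F}, \qquad
k_d = k_{d,\mathrm{ref}} \frac{GI}{GI_{\mathrm{ref}}},\\
S_m' &= -k_e S_m, \quad S_s' = -k_e S_s, \quad
Q_s' = k_e S_s - k_d Q_s, \quad
Q' = k_e S_m + k_d Q_s - k_{abs} Q,
\end{aligned}
$$

and the reported curve is $r(t) = k_{abs} Q(t)$. Dietary sugars other than
pure monosaccharide are mapped onto the monosaccharide pool at load time.
The defaults ($k_{e0} = 0.046$/min, $k_{abs} = 0.056$/min,
$k_{d,\mathrm{ref}} = 0.023$/min at $GI_{\mathrm{ref}} = 100$,
$\alpha_p = 0.02$, $\alpha_l = 0.035$, $\alpha_f = 0.06$ per gram) give
time-to-peak values around 20 min for pure sugar and 60–120 min for mixed
meals, in the physiologically expected range. All constants live in
`absorption_params()` and a YAML file can override them, so a different
absorption implementation can stand behind the same contract.

Integration is classical fixed-step RK4 (1-minute step by default; the inner
loop is compiled). A fixed-step explicit scheme was chosen over an adaptive
integrator deliberately: runs are bit-reproducible, grid points align with
the CGM clock, and at these rate constants the step-halving error is below
$10^{-6}$ g/min. The integration stops when the running trapezoid integral
of the emitted curve reaches `completeness` (default 99.5%) of the
digestible carbohydrate — the stop watches the *trapezoid* integral rather
than the internal ODE state so that the returned curve itself satisfies the
conservation contract (area within 0.5% of the carbohydrate mass). A
zero-carbohydrate meal returns a flagged empty curve; callers must filter
such meals before asking for curve parameters.

## From curve to features

`curve_parameters()` reduces a curve to four dynamics parameters: time to
peak (TPeak), time to 50% of the peak (T50), maximal absorption rate
(MaxCH) and area under the whole curve (AuC). T50 is taken on the *rising*
edge (first crossing, linearly interpolated between grid points); ties for
the maximum go to the earliest time. Together with the bolus dose (BI), the
pre-meal baseline BGL (SBGL) and the delay since the last basal injection
(DfB), these form the input pools of four 5-input strategies:

| Strategy  | Inputs (in order)            | Intent                      |
|-----------|------------------------------|-----------------------------|
| `ABS`     | BI, SBGL, MaxCH, TPeak, T50  | short-term (≤ 60 min)       |
| `AUC`     | BI, SBGL, MaxCH, AuC, TPeak  | mid-term, no basal timing   |
| `DFB`     | BI, SBGL, MaxCH, TPeak, DfB  | mid-term, no total mass     |
| `AUC_DFB` | BI, SBGL, MaxCH, AuC, DfB    | mid-term, proposed default  |

Five inputs is a hard design limit: with only a few dozen training meals per
patient, wider input layers stall convergence. Only two inputs are rescaled
— BI to pmol/1000 and DfB to min/100 — which is enough to bring all five
into a common numeric range; TPeak and T50 stay in raw minutes.

The rationale for `AUC_DFB` is that mid-term accuracy needs information
about the whole absorption process (AuC) and about the slowly varying basal
insulin background: a basal injection's effect builds up, plateaus and
decays gradually over the day, so the same bolus dose acts differently at
noon than in the evening. DfB is the cheapest observable proxy for where on
that curve a meal falls.

## The network and its training regime

The regressor is a fully connected network, 5 inputs → 20 tanh units → 60
tanh units → linear output layer, with one output per 2-minute step of the
horizon (30/45/60/90 outputs). The output layer is linear rather than tanh
because targets are BGL values in mmol/L, outside tanh's range; the
alternative (tanh output with target scaling) is not the default because it
adds a coupling between target units and activation saturation with no
observed benefit.

Training minimizes the mean squared error over all samples and output
positions with BFGS, using Brent's derivative-free line minimizer on the
step interval $[0, 10]$ at tolerance $10^{-6}$; the inverse-Hessian
approximation is reset to the identity whenever the curvature condition
$s^\top y > 0$ fails, and a bisection fallback guarantees the recorded
training error never increases. Training stops after 118 iteration cycles —
more invites overfitting at these sample sizes; the cap is the
regularizer — or when the error drops below $10^{-15}$. Weight
initialization is uniform symmetric, scaled by $1/\sqrt{\mathrm{fan~in}}$,
and fully determined by an integer seed that is part of the training
configuration; `(seed, samples, config)` determine the trained network
bit-for-bit. Gradients from saturated tanh units are flushed to zero at the
hardware level during training: below $10^{-308}$ they carry no usable
curvature information but make dense BFGS updates crawl.

Batch BFGS is the default mode. A `sequential` mode also exists, training
each sample in chronological order for up to the full iteration budget from
the previous sample's final weights. The sequential narrative is the more
literal reading of incremental training descriptions, but it cannot
guarantee overall descent of the full-set error (each sub-problem only sees
one sample), so the batch interpretation — the iteration cap read as total
epochs — is the reproducible default.

## Per-patient pipeline and evaluation conventions

`clean_meals()` turns raw logs into analyzable meal episodes. A meal is
excluded when no bolus falls within the 30 minutes up to the meal time (the
"insulin before the meal" window is not standardized anywhere; 30 min is
this package's configurable default), when total carbohydrate is below 5 g,
when another meal follows within 60 min, when no basal injection precedes it
in the log, or when the CGM series has a gap inside a requested horizon
window. SBGL comes from the latest fingertip reading at most 60 min old,
falling back to the CGM sample at meal time — fingertip baselines are logged
before meals, but not guaranteed for every meal. Targets are raw CGM values;
a 180-minute window may legitimately contain the next meal (only sub-60-min
successors are excluded), which keeps the task honest.

The train/validation split is chronological: the first $\lfloor 2n/3
\rfloor$ episodes train, the rest validate (43 episodes split 28/15, 26
split 17/9). Threefold cross-validation uses three contiguous chronological
blocks for the same reason: shuffling would leak future context into
training. `limited_subsample()` equalizes per-patient sample sizes (26
meals) for size-bias experiments.

Metrics pool the per-point errors of all episodes in scope before computing
RMSE and MAE ("all datasets" means concatenating all patients' validation
errors, not averaging per-patient metrics). Windowed metrics use half-open
intervals $(lo, hi]$ in minutes, so the 60-minute point belongs to the short
model: window (60, 120] covers trajectory indices 31–60, (120, 180] covers
61–90. The hybrid predictor copies outputs 1–30 from the patient's
`ABS`/60-min model and the rest from the `AUC_DFB` mid-term model, with no
smoothing at the seam — the seam is visible and that is intentional; the
two models are already each other's fallback.

The paired t-test compares two strategies on per-validation-episode RMSE
values pooled across patients. The episode is the pairing unit because it is
the natural quasi-independent draw; pairing per time point would fabricate
sample size out of autocorrelated residuals. Identical error sequences give
a degenerate-variance error rather than a p-value.

## The virtual-patient simulator

Clinical CGM data cannot ship with a package, so `generate_cohort()`
produces cohorts whose statistical structure matches what the method
assumes: per-patient meal schedules with varying composition, one basal
injection per day at a fixed clock time, a bolus 0–15 min before each main
meal with dose proportional to carbohydrate (90 pmol/g), occasional
un-bolused snacks (so the cleaning filters have work to do), fingertip
readings at meal times, and a gapless 2-min CGM trace. Noiseless BGL
follows

$$B' = c_g\, g(t) - s_i\,\big(a_{bolus}(t) + a_{basal}(t)\big) - k_r (B - B_0),$$

where $g$ is the summed absorption rate of all meals (using the same
absorption model, run essentially to exhaustion), $a_{bolus}$ is a
gamma-shaped action profile $(u/\tau^2) e^{-u/\tau}$ with unit integral and
peak at $\tau = 55$ min, and $a_{basal}$ is a difference of two logistic
ramps — gradual rise (midpoint 120 min), plateau, gradual decay (fall
midpoint at plateau + decay) — anchored to zero at the injection instant.
CGM and fingertip observations add iid Gaussian noise (σ = 0.4 mmol/L by
default, within the error range of real devices) and clamp to (2, 30)
mmol/L; if more than 20% of samples clamp, the generator warns that the
parameter set is implausible. Defaults ($c_g = 0.25$ mmol/L per g,
$s_i = 1.6$ mmol/L per 1000 pmol, $k_r = 0.008$/min toward 7.5 mmol/L)
produce fasting values near 6–7 mmol/L and post-meal excursions of 2–5
mmol/L.

The default test cohort is 5 patients × 12 days (≈ 36 retained meals per
patient, matching the scale of a realistic two-week diary), seed 42. The
simulator is integrated with RK4 at a 1-minute step against forcings
sampled every 15 s; the quarter-minute forcing record is kept in the ground
truth so a half-step re-integration reproduces the stored trajectories to
below $10^{-6}$ mmol/L, and meal times are generated on the 2-minute CGM
grid with whole-minute bolus leads so that every forcing kink lands on an
integrator step boundary.

What the simulator does *not* emulate matters for interpreting green tests:
there is no endogenous glucose production, no exercise, stress, dawn
phenomenon, sensor drift or calibration error, and the absorption curves
driving the truth are the same model family the features are extracted
from. Passing the recovery tests therefore shows the pipeline can learn the
mapping it assumes, with honest noise — it does not certify clinical
accuracy, which can only be measured on real logs.

## Numerical and design choices, in one place

* Fixed-step RK4 everywhere; no adaptive steps, for bit-reproducibility.
* Completeness stop watches the emitted trapezoid integral (conservation by
  construction); duration cap 600 min.
* T50 on the rising edge; peak ties to the earliest grid time.
* Output activation linear; `tanh` + target scaling available behind
  `network_layout()`-level re-wiring but not a supported default.
* Line search bracket $[0,10]$, Brent tolerance $10^{-6}$, BFGS reset on
  curvature failure; denormal gradients flushed during training.
* Timestamps are timezone-naive local clock times (stored as UTC);
  days are defined by local midnight.
* Split fraction applied as $\lfloor n \cdot 2/3 + 10^{-9}\rfloor$ to keep
  exact-multiple counts stable against floating-point representation.
* Model files are versioned JSON with 17-significant-digit numbers, which
  round-trip to bit-identical doubles.

## Problem sizes used by the shipped tests

The test suite trains real models, so sizes are chosen to make a full run a
matter of minutes: the recovery and strategy-comparison checks use the
5 × 12 default cohort and 3 × 12 cohorts over three seeds, training 60–180
min models per patient at the full 118-iteration budget; absorption
conservation is checked over 1000 randomized meals; metric and t-test
oracles use 100 randomized cases each. The acceptance script
(`scripts/acceptance.R`) regenerates the default cohort from its `--seed`
and retrains every model from scratch on each run.

## Known limitations

* The absorption stand-in is structurally faithful but not numerically
  identical to any published gastric-emptying model; absolute feature values
  (e.g. mean time-to-peak) shift with its constants.
* Sequential training mode is provided for completeness; its full-set error
  is not monotone and it is not used by the evaluation pipeline.
* With ~25 training meals per patient the network is heavily
  over-parameterized; the iteration cap is the only regularizer, exactly as
  configured, and validation error is accordingly noisy across seeds.
* The t-test treats episodes as independent; overlapping 180-min windows of
  meals on the same day weaken that assumption.
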