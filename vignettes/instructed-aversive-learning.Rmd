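---
title: "Modeling instructed and feedback-driven aversive reversal learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling instructed and feedback-driven aversive reversal learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pavlovr)
```

## The paradigm and what the package computes

`pavlovr` models a Pavlovian aversive reversal-learning task: two face cues,
one of which (the CS+) is paired with a mild electric shock on a third of
its presentations while the other (the CS-) is never reinforced. Roles
reverse three times, yielding four blocks of twenty trials. An *instructed*
group is told about the initial contingencies and about each reversal
(instructions occupy a 10-s epoch between blocks); an *uninstructed* group
learns everything from reinforcement. The conditioned response is the skin
conductance response (SCR) at cue onset, assumed proportional to the
learner's shock expectation.

The package provides the whole analysis chain — task generation, synthetic
SCR cohorts, waveform scoring, model fitting, two-level behavioral
statistics, and fMRI design construction — so that each estimator can be
validated against data with known generating parameters.

## The learning model

Expected value updates by the Rescorla-Wagner rule: on trial $n$ with
presented cue $x_n$ and outcome $r_n \in \{0, 1\}$,

$$\delta_n = r_n - V_n(x_n), \qquad V_{n+1}(x_n) = V_n(x_n) + \alpha\,\delta_n,$$

with constant learning rate $\alpha \in [0, 1]$. Only the presented cue
updates; the other cue's value is carried forward. When an instruction is
delivered (immediately after trials 20, 40 and 60), both cues update
jointly by the instructed-reversal weight $\rho \in [0, 1]$:

$$V(x_a) \leftarrow \rho V(x_b) + (1-\rho) V(x_a), \qquad
  V(x_b) \leftarrow \rho V(x_a) + (1-\rho) V(x_b).$$

The mixing conserves $V(x_a) + V(x_b)$ for every $\rho$; $\rho = 0$ makes
the instructed model collapse exactly onto the feedback-driven model, and
$\rho = 1$ exchanges the two values completely. The swap is applied after
the final pre-instruction trial's feedback update and before the next
trial's onset value is read. Prediction error is attributed to cue offset
(where the outcome occurs) and expected value to cue onset; this matters
only for the fMRI design, where EV modulates the onset event and shock/PE
modulate the offset event.

Initial values: the feedback variant starts both cues at $V_0 = 0.5$ (no
prior knowledge). The instructed variant starts the initially announced
CS+ at 0.75 and the CS- at 0.25, reflecting partial trust in the initial
instruction; both are overridable, and matched-$V_0$ fits are used whenever
the two variants are compared as nested models. Whether the asymmetric
start should interact differently with the very first instruction is not
determined by anything we model; we apply the same $\rho$-mixing at every
instruction event.

## Task generation

`generate_trial_sequence()` draws pseudorandom orders satisfying the
design's constraint set: per block, exactly 12 CS+ presentations (4
reinforced — a 33% rate; the degenerate all-unreinforced configuration is
also supported) and 8 CS- presentations; no US on a CS- trial; no two US
trials adjacent; no cue repeated more than twice in a row ("condition" is
interpreted as cue identity); and after each instruction, at least two
unreinforced presentations of each cue before the new block's first US.
Sampling is two-phase rejection per block — first a cue arrangement
satisfying the run-length constraint, then a US placement satisfying the
remaining constraints — with a shared retry budget of 10,000 draws, after
which generation aborts naming the failing constraint. This is simple and
auditable, and the constraint set is loose enough for typical per-block
acceptance within a few hundred draws. Trial $k$ starts at
$(k-1)(4\,\mathrm{s} + 12\,\mathrm{s})$, shifted by one 10-s epoch per
preceding instruction. Two canonical orders (seeds 1 and 2) play the role
of the experiment's two fixed orders and are also shipped as TSV fixtures
in `inst/extdata/`.

## The synthetic-data generator

`simulate_cohort()` is the generative inverse of the analysis assumptions.
Subject $s$'s trial-$n$ amplitude (in microsiemens) is

$$A_{s,n} = \max\!\big(0,\; a_s + b_s V_n(x_n) + h\,n + \varepsilon_{s,n}\big),
  \qquad \varepsilon_{s,n} \sim N(0, \sigma^2),$$

with subject intercept $a_s \sim N(0.3, 0.1^2)$, EV slope
$b_s \sim N(0.25, 0.05^2)$, linear habituation $h = -0.002$ uS/trial, trial
noise $\sigma = 0.1$ uS, and an independent US-evoked amplitude
$\sim N(1, 0.2^2)$ (truncated at zero) on reinforced trials. With
probability 0.3 a subject is a non-learner whose slope is drawn near zero,
mirroring the roughly one-third of participants who show no conditioning
signal in this paradigm. Instructed cohorts use the instructed EV trace,
uninstructed cohorts the feedback trace. The defaults were chosen once so
that, after the square-root transform and US-normalization, differential
CS+/CS- effects land in the 0.04–0.10 range typical of normalized SCR
betas in this literature; they are configuration, not empirical claims. No
published noise magnitudes exist for this paradigm, so these values are
calibrated only to qualitative effect sizes.

What the generator deliberately does *not* emulate: non-Gaussian amplitude
distributions (real SCR is right-skewed; here skew enters only through the
zero floor), autocorrelated tonic drift, movement artifacts, and any
dependence of the US response on learning. Passing recovery tests therefore
shows the estimators are correct *under the model's own assumptions*, not
that real data satisfy them.

The optional waveform path (`simulate_waveform()`) renders amplitudes as
canonical SCR impulses — a difference of exponentials with ~0.75-s rise and
~2-s decay time constants, unit peak — at latencies drawn uniformly from
0.5–4.5 s after cue onset (0.5–1.5 s after US delivery), on a tonic
baseline, sampled at 200 Hz. It exists to exercise the scoring module end
to end; the amplitude-level path is the primary test path because the
models operate on scored amplitudes.

## SCR scoring

`preprocess_waveform()` applies a 25-Hz low-pass FIR filter (windowed-sinc,
order 64, Hamming window, normalized to exact unit DC gain, run
forward-backward for zero phase with edge-replication padding) and then a
10-sample Gaussian smoothing kernel (SD 2.5 samples). `score_trial()`
implements an explicit stand-in for the human scorer: the response onset is
the first local minimum in the 0.5–4.5-s latency window followed by a
monotone rise of at least 0.01 uS/s sustained for 0.25 s; the peak is the
next local maximum; the score is peak minus base, floored to zero below
0.02 uS. Every parameter of this rule is configurable via
`scoring_config()`, since the original criterion was human judgment and any
algorithmic translation is a choice. US trials are scored relative to US
delivery; their CS-onset scores are recorded but CS-level analyses use
unreinforced trials only.

`transform_normalize()` square-root transforms amplitudes and divides by
the subject's mean square-root US response. Division (rather than
subtraction) is used because normalized conditioned responses are then
interpretable as fractions of the unconditioned response, matching how
normalized betas in this literature are read; zeros stay zero, and a
subject with no scoreable US response is rejected as unanalyzable.
`classify_learner()` labels a subject a learner if mean normalized SCR on
unreinforced CS+ trials exceeds the CS- mean in trials 11–20 (late
acquisition), a strict inequality with ties resolving to non-learner and no
significance requirement.

## Model fitting

The across-subjects fit treats $(\alpha, \rho)$ as fixed within a cohort
while every subject keeps a free intercept and EV slope: for each candidate
parameter set, the EV regressor is generated on each subject's trial order,
per-subject ordinary least squares produces predicted responses, and the
concatenated residual sum of squares is the objective. This two-stage
construction (per-subject regression inside a shared learning-parameter
search) avoids treating all observations as one pooled subject. The
within-subject fit is the same machinery with one participant.

The two-parameter search is Nelder-Mead simplex on
logistic-transformed coordinates — the search itself is unconstrained but
estimates respect $[0, 1]$ — restarted from 10 dispersed starting points
(a fixed grid by default; uniformly drawn in the transformed space when a
restart seed is supplied, which is how restart robustness is tested). The
one-parameter feedback fit uses bounded golden-section search instead,
which is also derivative-free and more reliable than a 1-D simplex.
Goodness of fit is reported both as raw SSE and as the Gaussian deviance
$N \log(2\pi\,\mathrm{SSE}/N) + N$ (the $-2$ log-likelihood at the ML
variance); the deviance convention is stated explicitly because more than
one is in circulation, and SSE is always reported alongside so either can
be compared. An SSE of exactly zero (noiseless self-fits) is flagged
degenerate rather than mapped to $-\infty$. Subjects with all-zero
responses are excluded with a warning. `compare_rho_groups()` is a pooled
two-sample t-test on within-subject $\hat\rho$, df $= n_1 + n_2 - 2$.

### Recovery harness

Estimator validation uses a fixed harness: cohorts of 20 subjects per cell,
trial noise equal to half the mean EV slope ($\sigma = 0.125$ with
$b = 0.25$), subject heterogeneity in intercept and slope on, habituation
and the non-learner mixture off, fit on the amplitude scale. The last three
choices isolate the stated noise condition: the fitted first-level model is
intercept + EV with no time term, so a habituation trend is unmodeled
structure (and, empirically, a linear trend is absorbed by the
near-zero-$\alpha$ EV shape, dragging $\hat\alpha$ to the boundary), while
the square-root transform is a deliberate nonlinearity that breaks exact
self-consistency. The test suite runs 100 replicates per generating
$\rho^* \in \{0, 0.5, 1\}$ for recovery bias/precision, 100 replicates of
20-vs-20 group discrimination at $\rho^* = 0.9$ vs $0$, and noiseless
self-fits checked to $10^{-3}$. The full-pipeline acceptance script uses
the same harness conditions for its fitted quantities.

## Two-level behavioral analysis

Each subject's unreinforced-trial normalized SCR is regressed on an
intercept, Stimulus (original CS+ vs CS-, coded $\pm\tfrac12$), Reversal
(original vs reversed contingencies, $\pm\tfrac12$), their interaction, and
a per-subject standardized linear Time regressor for habituation. The
interaction column is coded $\pm\tfrac12$ for the *current* CS+ vs CS-
(twice the raw product of the centered main-effect codes) so that its beta
equals the mean differential response — the quantity the literature reports.
Reversal boundaries are group-specific: instruction delivery for the
instructed group, the first shock on the previous CS- for the uninstructed
group. Second level: each beta is tested across subjects; with two groups,
the within-subject effect controlling for group is the intercept of a
regression on centered group and the group difference is its slope.
Subjects with rank-deficient designs are flagged and excluded per effect.
`mixed_model_check()` refits the same design jointly with random intercepts
via lme4 as an independent cross-check; on balanced noiseless data the
two-stage estimates equal pooled OLS exactly. Analysis subsets mirror the
standard reporting splits: all trials, post-first-reversal, and the second
half of each run (runs are the spans between group-specific boundaries).

`instructed_reversal_contrast()` is the model-free test of immediate
instructed updating: per subject, the differential response (current CS+
minus current CS-, "current" meaning post-reversal roles throughout)
in the post-instruction pre-reinforcement window minus the cue-matched
differential just before the instruction, averaged over the three
reversals, tested with a one-sample t (df $= n - 1$).

## fMRI design construction

`gamma_hrf()` is a difference of gamma densities with unit rate and modes
at 6 s (response) and 16 s (undershoot, weighted 1/6), normalized to unit
peak on a fine internal grid so kernel values are independent of the
sampling step. `build_fmri_design()` builds regressors at 16 microtime bins
per TR (TR = 2 s by default): cue onset (a 4-s epoch by default, a stick
optionally — the event shape is configurable because either modeling choice
is defensible), cue offset (stick), EV parametric modulators on onset,
optional shock and prediction-error modulators on offset, and a 10-s
instruction boxcar; everything is convolved with the HRF and sampled at the
TR grid. Modulators are mean-centered before convolution by default (the
dominant software convention), with an off switch. Orthogonalization is
*off* by default so that two EV modulators entering one design keep their
shared variance without prioritizing either; when on, successive modulator
columns are residualized against all earlier columns in declared order.
`collinearity_report()` returns pairwise correlations and VIFs of the
design columns and the rank of the trial-level modulator block, flagging
the exact dependence PE = shock − EV that makes a single-trace EV + shock
+ PE design unestimable. No voxel data are fitted; design construction and
its diagnostics are the deliverable.

## Numerical choices and degenerate inputs

- Optimizer: simplex `reltol` $10^{-10}$, 500 iteration cap, 10 restarts;
  golden-section tolerance $10^{-10}$ on $[10^{-6}, 1 - 10^{-6}]$.
- A candidate EV regressor with zero variance (e.g. $\alpha = 0$ in the
  feedback model) is an error in the exported objective; inside the
  optimizer the logistic transform keeps parameters strictly interior, and
  a numerically flat regressor falls back to an intercept-only subject fit.
- Scoring tolerances: slope threshold 0.01 uS/s over 0.25 s, non-response
  floor 0.02 uS; ties in learner classification resolve to non-learner.
- Sequence generation aborts after 10,000 rejected draws naming the
  violated constraint; validation (`validate_sequence()`) never raises.
- All randomness flows through explicit seeds (`withr::with_seed`), with
  per-subject and per-stage seeds derived from a master seed, so every
  pipeline artifact is bit-reproducible.

## Problem sizes used by the test suite

Module tests run on the two canonical 80-trial orders with cohorts of 2–8
subjects; recovery suites use 100 replicates per cell at 20 subjects (bias
and precision of $\hat\rho$; group discrimination), 200 replicates for
second-level unbiasedness and 500 null replicates for the type-I error
check at 12 subjects; the waveform round trip scores one full 80-trial
recording at 200 Hz. These sizes were chosen so that Monte-Carlo error is
small relative to the tolerances being asserted while the whole suite stays
comfortably runnable on a laptop.

## Known limitations

- The hybrid model with a dynamic associability-modulated learning rate is
  deliberately out of scope: its equations are not fully specified in the
  source literature for this paradigm, and guessing them would not be
  testable. The ρ-modified Rescorla-Wagner model is the implemented
  contribution.
- Fitted $\rho$ on square-root-normalized responses is compressed toward
  the interior relative to the amplitude-scale generating value — the
  monotone transform changes the regression geometry. Recovery guarantees
  are stated on the amplitude scale; normalized-scale fits are the applied
  path and their two cohorts remain clearly discriminable.
- Within-subject $\hat\rho$ from 80 trials is noisy and, being bounded,
  biased toward the interior under weak identification; group comparisons
  should rely on the distributional test, not individual point estimates.
- The scoring rule is an explicit algorithmic stand-in for trained human
  scorers; on overlapping responses (a late CS response running into a US
  response) it can attribute amplitude to the wrong event. Median, not
  worst-case, round-trip accuracy is guaranteed.
- Voxelwise fMRI statistics, robust regression group maps, and
  brain-behavior correlation maps require imaging data and are not part of
  the package.
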