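---
title: "Modelling letter-speech-sound learning with a reinforcement-learning drift-diffusion model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling letter-speech-sound learning with a reinforcement-learning drift-diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlddm)
```

## The model

`rlddm` models feedback-driven learning of audiovisual associations — the
kind of task in which a child repeatedly chooses which of two unfamiliar
characters matches a spoken sound and receives deterministic feedback. Two
traditions are combined:

* a **delta-rule learning model**: each pairing $i$ carries an associative
  strength $AS_i \in [0,1]$, initialized at 0.5 when the pairing is new.
  After feedback $o \in \{0,1\}$ on a trial presenting pairing $i$,
  $$AS_i \leftarrow AS_i + \eta\,(o - AS_i),$$
  where the prediction error $PE = o - AS_i$ and $\eta \in (0,1)$ is the
  learning rate. Two-rate model variants use $\eta^+$ after positive and
  $\eta^-$ after negative prediction errors.

* a **drift-diffusion decision model** (diffusion coefficient fixed at 1,
  accuracy coding: the upper boundary is the correct response): the trial's
  drift magnitude is
  $$\hat v_t = v_{mod}\cdot\frac{AS_{\mathrm{target}} + AS_{\mathrm{foil}}}{2},$$
  the mean of the associative strengths of the two characters on screen
  scaled by the drift-rate modifier $v_{mod}$. Choice and RT follow the
  Wiener first-passage-time (WFPT) distribution with trial-wise boundary
  separation $a_t$, relative starting point $z$ and nondecision time
  $\tau$; RTs exceeding the 2.5 s response deadline are missed trials.

The decision boundary may change over the course of a run. Three mappings
define, together with the one- vs two-rate choice, the six model variants:

| variants | learning rates | boundary |
|---|---|---|
| 1, 4 | 2, 1 | exponential: $a_t = a_{base}\, t^{a_{mod}}$ |
| 2, 5 | 2, 1 | linear: $a_t = a_{base} + a_{mod}(t-1)$ |
| 3, 6 | 2, 1 | static: $a_t = a_{base}$ |

with $t$ the 1-based within-run trial index. For $a_{mod}\in(0,1)$ the
power law grows logarithmically in appearance: strictly increasing with
strictly shrinking increments. Associative strengths (and the trial index
driving $a_t$) reset at run boundaries because each run introduces new
pairings.

### Design choices in the deterministic core

Several aspects of this model family are genuinely open; the package fixes
them as follows.

* **Initialization.** Every pairing starts at $AS = 0.5$ (no prior
  association), each run.
* **Outcome coding.** Feedback is coded $\{0,1\}$, which keeps $AS$ and
  $|PE|$ inside the unit interval for any feedback sequence.
* **Update scope.** Only the pairing presented on the trial is updated;
  missed trials trigger no update (no feedback is shown).
* **The foil's associative strength.** The drift averages two strengths.
  The target's is unambiguous. For the foil — the character from another
  pairing shown as the distractor — the package uses that pairing's own
  learned strength, which the task generator records per trial
  (`foil_pair_id`). Under this reading the drift roughly doubles over a
  run as all pairings are learned, which reproduces the rising accuracy
  *and falling RT* that characterize learning in this task. The
  alternative reading (the foil-sound combination as a never-reinforced
  association resting at 0.5) caps drift growth so severely that, at the
  reference parameter values below, mean RT would *rise* slightly across
  bins as the boundary grows — qualitatively wrong. When a trial table has
  no foil column the package falls back to the resting-value reading.
* **Sign convention.** `compute_drift()` returns the unsigned magnitude;
  the sign (toward the correct or error boundary) is attached at
  likelihood evaluation or simulation.

## The likelihood

`wfpt_log_density()` evaluates the WFPT log density with the standard
small-time/large-time series pair, choosing per trial whichever expansion
needs fewer terms for a truncation error below $10^{-7}$. The small-time
series is summed in log space, keeping the density finite for decision
times down to $10^{-4}$ s. The error-response density uses the reflection
identity $f_{lower}(t; v, z) = f_{upper}(t; -v, 1-z)$.
`upper_probability()` provides the closed-form absorption probability
$(1-e^{-2vza})/(1-e^{-2va})$, used throughout the tests as an analytic
oracle.

`trial_sequence_loglik()` replays the delta-rule recursion in presentation
order and evaluates the density at each responded trial's derived drift
and boundary.

**Missed trials.** The descriptive performance summaries treat misses as
their own response category. Inside the likelihood the package offers two
treatments: excluding missed trials entirely, or censoring them with the
survival term $\log P(T > \text{deadline} - \tau)$, computed from the
term-by-term integral of the large-time series. `fit_hierarchical()`
censors by default. The choice matters: at the reference parameter values
the generative process misses ~15% of trials, and a likelihood that simply
drops them sees an RT distribution truncated at the deadline. On synthetic
cohorts this pulls the fit toward a spuriously fast-and-furious regime
(drift modifier near 2.5 instead of 1, starting point near 0.6 instead of
0.75) that outscores the generating parameters by over a hundred log
units. With censoring the likelihood matches the generative process and
the generating values are recovered. `trial_sequence_loglik()` keeps
exclusion as its default for direct likelihood inspection; fitting uses
censoring.

## Hierarchical estimation

Subject parameters live on unconstrained scales — $\log$ for $a_{base}$,
$\tau$, $v_{mod}$; $\mathrm{logit}$ for $\eta$, $z$, $a_{mod}$ — with
Normal group distributions $x_j \sim N(\mu, \sigma)$. Priors are weakly
informative and standard for hierarchical sequential-sampling models:
$\mu \sim N(0, 1.5)$, $\sigma \sim \text{Half-Normal}(0.5)$. Nondecision
admissibility ($\tau$ below every observed RT) is enforced through the
likelihood, whose log is floored at $-700$ inside the sampler so
exploration never hits $-\infty$.

The sampler is an adaptive Markov chain Monte Carlo scheme built for this
posterior's two known pathologies:

1. **Correlated ridges.** The drift modifier, boundary, bias and
   nondecision time trade off against each other, and $a_{base}$ with
   $a_{mod}$. Axis-aligned proposals mix poorly along such ridges, so each
   sweep adds a joint Metropolis move per subject along the empirical
   posterior covariance estimated during warm-up, plus a *group shift*
   move that translates the group mean and all subjects together along the
   pooled covariance (scaled by $1/n$).
2. **The funnel at small spreads.** Several generating spreads are tiny
   (e.g. the starting point's), and centered updates of $(\mu_k,
   \sigma_k)$ given pinned subjects stall. Each sweep therefore also makes
   interweaving moves: subjects are re-expressed by their standardized
   offsets, and $(\mu_k, \log\sigma_k)$ — alternately $\log\sigma_k$
   alone — is re-proposed with the offsets held fixed and accepted by
   Metropolis. The joint and shift moves are repeated several times per
   sweep; they cost one likelihood evaluation per subject, an order of
   magnitude less than the component sweep, and carry most of the ridge
   and funnel mixing.

Component-wise proposal scales adapt toward 44% acceptance and the joint
moves toward 25%, in Robbins–Monro batches during warm-up; group means are
redrawn by exact Gibbs and spreads by slice sampling each sweep. Two
presets are provided: the *desk* preset (2 chains, 1,000 retained draws
each, 2,500 warm-up sweeps, thinning 6) and the *paper* preset (4 chains,
10,000 iterations, 4,000 warm-up, thinning 2). Convergence is summarized
by rank-normalized split $\widehat R$ with a warning threshold of 1.01,
plus effective sample sizes; at the desk preset on reference cohorts the
worst-parameter effective sample size is several hundred and every
$\widehat R$ falls below 1.01.

Pointwise log densities of responded trials are stored per retained draw,
so WAIC ($\mathrm{lppd} - p_{WAIC}$ on the deviance scale, with the
$n-1$ variance convention) can rank the six variants; ties break by lower
$p_{WAIC}$, then lower variant id. WAIC is computed over responded trials
for every variant, keeping comparisons aligned with a common data set.

`extract_trialwise_series()` replays the recursion at posterior draws and
averages, yielding per-trial associative strength, prediction error,
drift and boundary — the series used as parametric modulators (stimulus
onsets: AS; feedback onsets: PE) in model-based fMRI pipelines.

## The synthetic cohort generator

The generator emulates the study design: 2 runs of 40 trials; 4 pairings
per run learned deterministically over 10 randomized repetitions; correct
side balanced within pairing; 2.5 s deadline. Layout, parameter draws and
behavioral noise use independent substreams of the master seed, so the
task layout is invariant to the behavioral seed and whole cohorts are
bit-for-bit reproducible.

Diffusion paths are simulated by Euler–Maruyama with step $dt = 1$ ms.
Discretely monitored paths miss within-step boundary crossings, so the
barriers are pulled in by the standard continuity correction
$0.5826\sqrt{dt}$; the residual bias is below Monte-Carlo noise at $10^5$
draws (Kolmogorov–Smirnov distance to the density-implied CDF ≈ 0.007,
vs ≈ 0.02 uncorrected). An exact sampler (closed-form choice probability
plus numerical CDF inversion for the passage time) is available as an
opt-in backend. Misses arise only from the deadline; there is no separate
lapse process, which is one reason simulated miss rates (~15% at the
reference values) exceed the ~4–5% typical of real cohorts — see the
limitations below.

### Reference generating values

The package ships reference group-level values for a whole-sample
condition and two reading-skill groups (typical readers, TR; poor
readers, PR), drawn from the fitted single-rate exponential-boundary
model of the child cohort that motivated this package: nondecision time
0.73 ± 0.13 s (TR 0.70, PR 0.77), learning rate 0.19 ± 0.002, drift
modifier 0.97 ± 0.32, starting point 0.75 ± 0.01. Two quantities are not
reported directly and are derived once from reported summaries:

* $a_{mod}$ from the log-log slope of the bin-wise boundary trajectory
  (bins at roughly 3.05/3.24/3.33/3.40 for TR, 3.02/3.21/3.29/3.35 for
  PR), giving ≈ 0.053 (TR), 0.049 (PR), 0.052 (pooled);
* $a_{base}$ by dividing the reported trial-averaged boundary (3.17) by
  the mean power-law growth factor
  $\overline{t^{a_{mod}}} \approx 1.155$, giving ≈ 2.746. (Treating 3.17
  as the first-trial baseline instead would contradict the bin means,
  which never exceed 3.40.)

Natural-scale means map to the unconstrained scale through the transform;
SDs by the delta method. The Jensen gap between the transform of the mean
and the mean of the transform is below 2% at these spreads.

## What the recovery experiments do and do not show

The acceptance experiments simulate cohorts at the reference values, re-fit
them, and compare posterior group means to the generating values (within
±15% or the central 95% interval, with all $\widehat R < 1.01$). At the
desk preset with 20 subjects × 80 trials, nondecision time, starting
point and drift modifier recover to within a few percent.

At 20 subjects the cohort's own sample mean is a noisy estimate of the
group mean (the drift modifier's between-subject SD of 0.32 puts ±0.07
of standard error on the cohort mean alone), and a fit can only recover
the cohort it saw. The recovery experiments therefore draw subject
parameters by stratified inverse-CDF sampling (`balanced = TRUE` in
`cohort_spec()`): normal quantile midpoints in randomly permuted order,
independently per parameter. The marginals are unchanged, but the
cohort's unconstrained-scale sample mean equals the group mean exactly,
so the comparison isolates what it is meant to measure — estimation
error of the fitting machinery. Ordinary independent draws remain the
default for general simulation use.

The learning rate deserves honesty: its likelihood is nearly flat between
about 0.15 and 0.4 (the associative strengths saturate within a few
repetitions either way), so its posterior is wide, covers the generating
value, and has a mean pulled toward the prior's center — typically
0.3–0.4 rather than 0.19. This is a property of the design (80
deterministic-feedback trials), not of the sampler; sharpening it would
require more early-learning trials or probabilistic feedback, both outside
the task being modelled.

Passing these tests shows self-consistency of simulator and fitter under
the model's own assumptions. Real data differ in ways the generator does
not emulate: no lapses or attention drift, no RT contaminants, no
fatigue, deterministic feedback only, and exchangeable runs.

One qualitative property deserves a caveat. Simulated accuracy rises
monotonically across the four 10-trial bins at the reference values, as
in real cohorts. Mean correct RT, however, is nearly flat with a small
hump in bin 2: the power-law boundary grows fastest over the first bin
(its own bin-wise trajectory, taken from the reported marginal means,
rises ~6% from bin 1 to bin 2) while the drift, capped at
$v_{mod} \le \approx 1$ by the averaging formula, cannot outgrow it
early. Learning curves with a clearly *falling* RT would require trial
drifts well above 1 — which is what the reported bin-wise drift means
(> 1.2) suggest the original fit produced, and which the printed
averaging formula cannot reach with $v_{mod} \approx 0.97$. The package
implements the printed formula; the corresponding monotone-RT check is
therefore expected to fail at the reference values, and the test suite
keeps it as an honest record of that tension rather than relaxing it.

## Problem sizes and runtimes

The shipped experiments are sized for a single CPU: recovery fits use 20
subjects × 80 trials at the desk preset (a few minutes); the
model-recovery comparison fits all six variants on 15 subjects with
shortened chains; the simulator-vs-density comparison uses $10^5$ Euler
passages. The paper-scale sampler preset is provided behind a flag for
full-scale reanalyses.

## Known limitations

* The learning rate is weakly identified at this task length (above).
* WAIC is computed on responded trials; censored misses inform the
  posterior but not the comparison criterion.
* The group-difference workflow is post hoc (Welch tests on subject-level
  posterior means via `group_contrast()`); group effects are not modelled
  inside the hierarchy.
* Inter-trial variability parameters of the full Ratcliff model (sv, st,
  sz) and within-trial collapsing boundaries are out of scope.
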