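---
title: "Models and methods behind rskit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind rskit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rskit)
```

# The paradigm

The Random Soldier Kinematogram (RSK) is a crowd-of-agents variant of the
classical random-dot kinematogram. A crowd of 100 agents ("soldiers" wearing
khaki or white uniforms) moves inside an 18-degree square arena at 5 deg/s.
Two signal dimensions are parametrized independently:

* **motion coherence** — the fraction of agents translating in a common
  horizontal direction (leftward or rightward); the remainder move on fixed
  random linear paths;
* **color coherence** — the fraction of agents bearing the majority uniform
  color (0.5 to 1).

Because both dimensions map onto the same left/right response keys, a
bivalent RSK affords a response under either task rule: *motion* (report the
coherent direction; spatially compatible mapping) or *color* (report the
majority uniform; arbitrary mapping, counterbalanced across participants).
The task-irrelevant dimension then acts as a Stroop-like distractor, and a
cued task-switching context makes switch costs, mixing costs, preparation
effects and switch-cost asymmetries measurable with psychophysically
controllable signal-to-noise ratios.

`rskit` implements four components: the stimulus simulator, exact generators
for the standard experimental designs, a synthetic drift-diffusion observer,
and the full statistical pipeline.

# Stimulus simulator

The simulator works on a 2-D arena in degrees of visual angle rather than a
rendered 3-D scene: every behaviourally relevant parameter (speed, size,
coherence) is defined in visual degrees, and rendering is presentation-layer.
Positions use an origin at the bottom-left corner, x increasing rightward;
leftward motion is heading $\pi$, rightward heading $0$.

Choices the stimulus definition leaves open, and what the package does:

* **Noise agents** keep a heading drawn once per trial, uniform on
  $[0, 2\pi)$ — linear paths, no per-frame direction resampling.
* **Boundary rule**: toroidal wrap along the path (agents are re-drawn on the
  opposite side with identity, color and heading preserved), which conserves
  crowd density exactly; no perpendicular jitter is added on re-entry.
* **Counts**: exactly `round(coherence * n_agents)` agents are coherent /
  majority-colored, with round-half-up; for the standard grids (multiples of
  5% at $n = 100$) the products are integers and rounding never fires.
* **Independence**: the color assignment is an independent random permutation
  relative to motion-group membership (the two dimensions are crossed
  factorially in the orthogonal design, so correlating them would confound
  congruence with coherence).
* **Initial positions** are i.i.d. uniform; no minimum-separation or
  collision handling (visual overlap is a rendering concern).

A stimulus is fully determined by its seed. `measure_motion_coherence()` and
`measure_agent_speed()` are self-check oracles that re-estimate the nominal
parameters from wrap-corrected frame-to-frame displacements; "exactly
horizontal" uses a $10^{-9}$-degree tolerance on the vertical component
because `sin(pi)` is not exactly zero in floating point, while continuous
noise headings are horizontal with probability zero.

```{r stimulus}
frames <- simulate_stimulus(stimulus_spec(0.75, "leftward", 0.75, "white",
                                          seed = 1))
measure_motion_coherence(frames)
measure_agent_speed(frames)
```

# Design generators

Four generators return one tibble row per planned trial and are deterministic
given `(seed, flags)`:

* **`build_exp1a_design()`** — univalent motion psychometrics: 10 motion
  levels (5–95% in 10% steps) × 2 uniform colors at 100% color coherence ×
  6 replicates = 120 trials in two blocks of 60, directions balanced.
* **`build_exp1b_design()`** — univalent color psychometrics at 0% motion
  coherence: 5 color levels (55–95%) × 2 majority colors × 6 replicates =
  60 trials.
* **`build_exp2_design()`** — the orthogonal target/distractor design: 100
  unique bivalent stimuli (10 motion levels × 10 color conditions) × 4
  replicates per task = 400 trials per task in blocks of 50, run as two
  single-task series.
* **`build_exp3_design()`** — cued task switching at fixed 75/75 coherence:
  a sandwich of two single-task blocks, eight mixed blocks, and two closing
  single-task blocks (64 trials each), totalling 256 single-task, 256 repeat
  and 256 switch trials.

Sequencing uses rejection sampling: shuffle, check the constraints (at most
four consecutive trials with the same response key, and in mixed blocks the
same sequence type), retry up to a cap, fail loudly with a diagnostic. The
constraints are mild, so rejection is fast and auditable; `validate_plan()`
re-checks every constraint after the fact and is swept over seeds in the test
suite.

Decisions taken where the design description is silent:

* **Direction assignment in the orthogonal design.** The quadrant counts
  (25 unique stimuli per majority-color × direction cell) pin down the
  marginals but not the assignment; the generator uses the parity of
  (motion-level index + color-level index) within each majority color, which
  reproduces all four quadrant counts exactly and yields a 1:1
  congruent:incongruent split under either color mapping.
* **First trial of a mixed block** is typed (switch/repeat) relative to the
  previous block's final trial, which is what makes the nominal totals
  256/256 come out; the cleaning step discards block-first trials from all
  analyses regardless, so the nominal type never contaminates estimates.
* **CSI assignment**: the cue–stimulus interval (200 or 800 ms) is constant
  within a block; the eight mixed blocks follow an ABBA pattern by default
  (configurable), and the four single-task blocks are laid out so each
  task × CSI cell holds exactly 64 single-task trials. Single-task blocks
  carry a cue too — the cost analyses cross single-task trials with the CSI
  factor, so they need a CSI.
* **Interleaving**: the two uniform colors of the motion-psychometric design
  are interleaved within its two blocks rather than blocked.
* **Timing**: a cued trial runs blank (1000 − CSI), fixation (1000 ms), cue
  (CSI), stimulus (to response or 2000 ms). The blank varies inversely with
  the CSI so the response–stimulus interval is exactly 2000 ms at both CSIs,
  holding task-set decay constant; `trial_timeline()` exposes this and the
  uncued (fixation + stimulus) variant.
* **Congruency at near-chance color levels** is classified from the labeled
  majority color regardless of discriminability.
* The univalent designs (1a/1b) have an undefined congruent flag: a 100%
  uniform color with no competing response dimension is not treated as a
  distractor.

# The synthetic observer

No generative behavioural model is part of the paradigm definition; the
package supplies the simplest mechanism that produces every qualitative
regularity the analysis pipeline is meant to detect, so the pipeline can be
exercised end-to-end and injected parameters can be recovered.

Each trial is a single-stage drift-diffusion: evidence $X_t$ starts at 0 and
accumulates with drift

$$v = k_{\text{task}}\, s_{\text{target}} + k_{\text{distractor}}\,
s_{\text{distractor}},$$

where $s$ are signed coherences (positive when the corresponding feature
maps to the right key) and diffusion coefficient `noise_sd`; the first
passage through $\pm$`boundary` (Euler step, 1 ms) gives the decision time
and response side. Reaction time adds a non-decision time `t0_ms` and
additive penalties:

| parameter | default | unit | role |
|---|---|---|---|
| `k_target_motion` | 10 | 1/s | motion-task drift gain |
| `k_target_color` | 7 | 1/s | color-task drift gain (weaker task) |
| `k_distractor_in_color_task` | 1.5 | 1/s | motion interferes with color |
| `k_distractor_in_motion_task` | 0 | 1/s | color does not interfere (dominance) |
| `boundary` | 1 | evidence | decision threshold |
| `noise_sd` | 1 | evidence/$\sqrt{s}$ | diffusion coefficient |
| `t0_ms` | 300 | ms | non-decision time |
| `mixed_block_penalty_ms` | 90 | ms | sustained maintenance (mixing cost) |
| `switch_penalty_ms` | 40 | ms | reconfiguration (switch cost) |
| `inertia_penalty_ms` | 35 | ms | switching to motion after incongruent trials |
| `csi_benefit_ms` | 60 | ms | preparation at the long CSI, repeat and switch alike |
| `lapse_rate` | 0.02 | — | baseline coin-flip responses |
| `switch_lapse_rate` | 0.06 | — | extra lapses on switch trials (error cost) |
| `mixing_lapse_rate_short` | 0.05 | — | extra lapses in mixed blocks, short CSI |
| `mixing_lapse_rate_long` | 0.005 | — | same at the long CSI (preparatory reduction) |

Design choices worth making explicit:

* **Penalties are additive in RT, not drift**, so the pipeline's
  mean-difference estimators recover them exactly in expectation. Lapses
  replace the *response* with a fair coin but keep the diffusion RT, so the
  accuracy-side parameters leave mean RT — and hence RT-penalty recovery —
  untouched. RT penalties alone cannot move error rates (a 40-ms shift of
  the decision window changes timeout rates by a fraction of a percent), so
  the error cost and ER-mixing cost have their own lapse-style parameters.
* **The inertia penalty** applies when switching *to* the dominant motion
  task right after an incongruent trial: persisting inhibition of the
  dominant task is the standard account of asymmetric switch costs. A
  corollary: the plain switch cost estimate equals
  `switch_penalty + inertia_penalty / 4` in expectation (the inertia cell is
  a quarter of switch trials), so the unconfounded estimate of the switch
  penalty is the switch cost conditioned on a congruent previous trial —
  which is what the recovery tests use.
* **Default gains are deliberately steep.** With $v \approx 4.5$–7.5 at the
  75/75 coherences of the switching design, trial-level decision-time
  variance is small enough that a 35-ms injected penalty is recoverable
  within ±15% from 30 synthetic participants. The price is that accuracy
  saturates by ~25% target coherence, so absolute RTs and accuracies are not
  human-magnitude — only sign and ordering patterns are generative targets.
  Monotonicity across the full psychometric range is verified with a
  shallow-gain observer (`k_target_motion = 3`) whose accuracy actually
  spans chance to ceiling.
* **Timeouts** (no boundary crossing within the stimulus lifetime net of
  penalties) are scored as errors and excluded from RT summaries.
* **Seeding** is per participant: one seed, trials consuming the RNG stream
  in plan order (the simulation is vectorised across trials); identical
  seeds give identical logs. `simulate_trial()` accepts its own seed for
  single-trial work.
* The error-cost asymmetry direction (more errors switching to color) is not
  parametrized; whatever portion emerges, emerges from the lower color-task
  drift.

What the generator emulates — psychometric monotonicity, a
color-task-specific distractor-congruence gradient, switch and mixing costs,
an equal preparation benefit for repeat and switch trials, inertia-driven
switch-cost asymmetry — and what it does not: practice and fatigue effects,
position-in-run effects, sequential adaptation beyond the previous trial,
RT distribution shapes, and human effect magnitudes. Tests passing on
synthetic data therefore certify the *pipeline* (estimator correctness,
calibration, recovery), not any claim about human behaviour.

# Analysis pipeline

**Cleaning** (`clean_trials()`): responses faster than 200 ms and the first
trial of each block are discarded everywhere; the RT log further drops
errors and timeouts; the accuracy log keeps them scored 0. The filters
commute, so the retained set is order-invariant.

**Transforms**: natural log for RT, $\arcsin\sqrt{p}$ for accuracy
proportions, with inverses for back-transformed reporting; the
back-transformed mean log RT is the geometric-mean RT. Proportions are
computed per participant × condition cell *before* the arcsine transform
(trial-level 0/1 arcsine is degenerate).

**Target/distractor regression** (`regress_target_distractor()`): OLS on
standardized outcome and predictors, observations being participant ×
unique-stimulus cell means pooled across participants (a single df pair per
model; no mixed effects). The motion-task model has 10 target and 10 signed
distractor levels; the color-task model 5 and 20. Signed distractor
congruence carries the distractor coherence as magnitude and the sign of its
response mapping relative to the correct response.

**Costs** (`compute_costs()`): per participant × CSI × congruency,
switch cost = switch − repeat and mixing cost = repeat − single, on
back-transformed RTs (ms) and raw error percentages. Raw percentages are
used for the cost differences; the arcsine path is available for omnibus
accuracy ANOVAs. "Preparatory reduction" of a cost is the CSI main effect of
the 2 (CSI) × 2 (congruency) repeated-measures ANOVA on that cost.

**Repeated-measures ANOVA** (`rm_anova()`): balanced fully-within designs
only. For every effect, subjects are projected onto an orthonormal contrast
basis (Kronecker product over factors); the projected means give the effect
sum of squares, the subject-by-effect scatter the error term, and the
Greenhouse–Geisser epsilon is $\mathrm{tr}(V)^2 / (d\,\mathrm{tr}(V^2))$
for $V$ the covariance of the contrast scores. Corrected dfs are always
reported (no sphericity pre-test); partial eta-squared is
$SS_e/(SS_e+SS_{err})$. The implementation is cross-checked in the test
suite against the paired-$t$ identity ($F = t^2$), the epsilon bounds
$1/(k-1) \le \varepsilon \le 1$, and `car::Anova`'s univariate GG output.

**Chance-level test** (`chance_level_test()`): one-tailed one-sample $t$
against 0.5 on raw accuracies by default (arcsine scale optional), with
Cohen's $d$; zero-variance input is flagged degenerate rather than tested.

**Asymmetry** (`asymmetry_analysis()`): previous-trial congruency is
attached from the plan's own bookkeeping *before* cleaning discards trials;
block-first trials have no previous-trial context and drop out of the
factor. Switch costs per CSI × switch direction × previous congruency use
direction-matched repeat baselines (to-motion switches against motion
repeats) by default — a pooled-repeat baseline is available behind a flag —
and feed the 2 × 2 × 2 ANOVA.

p-values are computed throughout but calibration and recovery — not
p-values — are what the acceptance checks assert.

# Numerical choices and problem sizes

* Euler discretisation at 1 ms; the noiseless limit matches the closed form
  $b/v$ within one step.
* Diffusion paths are simulated in 256-step chunks across all trials of a
  plan at once; chunking only affects speed, not the sampled law given the
  seed.
* Round-half-up for agent counts; toroidal modulo wrap for positions.
* Rejection-sampling caps: $10^4$ shuffle attempts per block (a violated cap
  aborts with a diagnostic rather than relaxing a constraint).
* Derived sub-seeds stay below $2^{31}$.

The test suite runs the seed sweep at 100 seeds per design, regression and
ANOVA oracles at 100 and 50 fuzz cases, parameter recovery and the
qualitative cost pattern on 30-participant synthetic studies (20 replicates
for the pattern), and the chance-test calibration at 2000 replicates of 42
participants — sizes chosen so the whole suite completes in a few minutes on
one CPU while keeping Monte-Carlo error well inside the asserted tolerances.

# Known limitations

* `rm_anova()` requires complete balanced cells; unbalanced data must be
  aggregated or imputed upstream.
* The observer has no parameter-fitting interface — it is a generator, not a
  model of human data.
* The pooled regression ignores participant-level heterogeneity by design
  (matching the single-df-pair reporting convention); a mixed-effects
  reanalysis is out of scope.
* Rendering of stimuli is limited to `autoplot()` scatter frames; no 3-D or
  animated output.
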