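---
title: "Homeostatic reflexes, allostatic control and metacognition: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homeostatic reflexes, allostatic control and metacognition: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allostat)
```

## The model

`allostat` simulates a single homeostatic reflex arc as an active-inference
controller. The controlled quantity is one scalar physiological variable
$x$ (think blood glucose, plasma osmolality, temperature — units are
abstract "state units" throughout). The agent's homeostatic setpoint is a
*clamped Gaussian prior* over $x$: mean $\mu_{prior}$ (the setpoint) and
precision $\pi_{prior}$ (the inverse-variance encoding of the homeostatic
range). A viscerosensory channel reports $y = g(x) + e$, with $g$ a
deterministic coding transform and $e$ zero-mean Gaussian noise.

Three quantities are evaluated at every step:

* log evidence under expected homeostasis,
  $L = \tfrac12(\ln\pi_{prior} - \pi_{prior}\,PE^2) - \tfrac12\ln 2\pi$
  with $PE = y - g(\mu_{prior})$;
* interoceptive surprise $S = -L$ (nats); and
* the squared precision-weighted prediction error
  $\mathrm{pwPE}^2 = \pi_{prior}\,PE^2$, the quadratic term of $L$ and
  the quantity reported as the surprise approximation in trajectories.

Rather than revising its prior, the reflex acts: the action signal is the
gradient of log evidence with respect to the state,
$a = -\pi_{prior}\,PE\,\partial g/\partial x$, and the state follows
$dx/dt = f(a)/\lambda$ with effector mapping $f$ and time constant
$\lambda$. For identity $f$ and $g$ this is a linear feedback loop,
$dx/dt = -(\pi_{prior}/\lambda)(x - \mu_{prior})$ plus noise, whose
closed-form relaxation $x(t) = \mu + (x_0-\mu)e^{-\pi_{prior}t/\lambda}$
is used as an oracle in the tests. Two properties follow directly and are
asserted as tests: corrective speed is proportional to $\pi_{prior}$
(halving times scale as $1/\pi$), and higher prior precision passes more
sensory noise into the state (the controller chases noise harder).

Perception proper — sequential conjugate-Gaussian updating with
precision-weighted prediction errors, $\mu_{t+1} = \mu_t +
\frac{\pi_{data}}{\pi_t + \pi_{data}}(y_t - g(\mu_t))$,
$\pi_{t+1} = \pi_t + \pi_{data}$ — is exposed as `update_belief()`.
Setting the data precision to zero leaves the belief untouched, which is
exactly how the controller's prior is clamped; perception and control are
deliberately separate code paths rather than a unified filter, because
they treat time differently (a static state during perceptual inference,
a moving state under action).

**Allostasis** is anticipatory control: scheduled rewrites of the
setpoint belief. An `allostatic_event` may set a new prior mean, a new
prior precision, or both; events apply from exactly their own time onward
(closed-left, piecewise-constant semantics) and unset fields persist from
the most recent applicable value. Because the event semantics are a fold
over the event list, applying events one at a time is identical to
evaluating the full schedule — a property test. The generative model that
would *produce* allostatic predictions is out of scope; schedules are
user inputs.

## The metacognitive layer

The monitor observes only what the circuit itself could plausibly expose:
its surprise stream and its action output, never the hidden state. At
cadence `eval_every` it examines the trailing `window` seconds:

* `surprise_slope`: OLS slope of $S$ on time. The temporal trend of $S$
  during action is the measurable correlate of a failing (flat or rising)
  versus succeeding (falling) gradient descent on surprise.
* `acting`: max $|a|$ in the window above `action_threshold_frac`
  $\times\ \pi_{prior}$ (default 1%).
* `free_action`: the trapezoidal integral of $S$ over the window, a
  windowed proxy for accumulated negative log evidence. The window length
  is a free parameter of the theory, so it is a configuration parameter
  here (default 5 s).

If acting and the slope is below $-\varepsilon$, a success ($s=1$) is
recorded; acting with slope $\geq -\varepsilon$ records a failure
($s=0$); no action, no evidence. $\varepsilon$ defaults to 1% of the
absolute window-mean surprise per window, which makes the verdict — and
hence everything downstream — invariant under positive rescaling of the
surprise series. The observation is folded into a Gaussian self-efficacy
belief with the same precision-weighted update rule as perception
(observation precision 1 by default), the mean clamped to $[0,1]$ and
the precision capped (default 10) so the belief remains plastic under an
unbounded evidence stream. There are no published equations for this
layer; this operationalisation — an additional hierarchical level
receiving success/failure evidence, reusing the model's own update rule —
is this package's design choice, kept monitor-only (no feedback into the
allostatic schedule) because the bidirectional variant would require
assumptions the theory does not yet fix.

Staging uses dwell times, not instantaneous crossings: `fatigue` after
the self-efficacy mean has stayed below $\theta_{fatigue} = 0.5$ for
$d_{fatigue} = 10\times$ window; `generalized` after it has stayed below
$\theta_{gen} = 0.25$ for $d_{gen} = 50\times$ window; recovery above
$\theta_{fatigue}$ for $d_{recover} = 10\times$ window steps back one
stage at a time. One-step transitions guarantee the first entry into
`generalized` can never precede the first entry into `fatigue`.

## Lesions

Each of the five dysfunction loci is the minimal distortion of its
component, permanent from onset unless a duration is given:

| locus | distortion | default |
|---|---|---|
| sensor | channel reports `gain * g(x) + bias`, predictions unchanged | bias 0.75, gain 1 |
| predictor | allostatic schedule distorted: mean offset, time offset, global precision scaling | precision scale 4 |
| effector | state change scaled by `gain` in [0, 1] | gain 0 |
| body | constant drift added to the dynamics | 0.5 /s |
| metacognition | self-efficacy pinned low and near-rigid | mean 0.1, precision 100 |

A pure sensor bias is fully compensated by an intact reflex — sensed
prediction error returns to zero while the *true* state sits displaced at
$\mu - b$: the "illusion" of dyshomeostasis. That compensation is also
why the predictor default is the precision-scaling variant (the
precision-pathway, monoaminergic reading of flawed prediction weighting):
a mean-offset predictor lesion produces the same compensated, PE-silent
signature as a sensor bias and the two would be indistinguishable from
the monitored features; mean and timing offsets remain available as
parameters. The body-drift lesion against an *identity* effector always
reaches a bounded bias $\mathrm{drift}\cdot\lambda/\pi_{prior}$, since
linear feedback has unbounded corrective capacity; the regime where
dyshomeostasis grows without bound is real only for effectors with finite
capacity, provided here as `saturating_transform(cap)` — drift above
`cap`$/\lambda$ escapes regulation (both regimes are tested).

Separability is checked operationally: five signature features
(steady-state |PE|, run-mean pwPE², surprise slope during the corrective
episode, time to the *unlesioned* scheduled setpoint, final stage) over
20 seeded replicates per class on a shared 80 s panel scenario, z-scored
nearest-centroid classification.

## Numerical choices

* **Integrator**: explicit Euler. The closed loop is linear for the
  default maps, and Euler at the default step is both stable and
  verifiable against the closed form. The default
  $dt = 0.01\,\lambda/\max\pi_{prior}$ (the maximum taken over the whole
  schedule, lesion distortions included) sits 100x inside the stability
  bound $dt < \lambda/\pi_{prior}$; a user-supplied $dt$ violating the
  bound is refused with a diagnostic naming the offending combination,
  and a divergence guard ($|x| > 10^6$) aborts with the step index.
* **Relaxation tolerance**: the Euler-vs-closed-form check uses
  $dt = 10^{-3}\lambda/\pi$ and asserts pointwise relative error of the
  decaying deviation below $10^{-3}$ over the first time constant plus
  error below $10^{-3}$ of the initial displacement over the whole run —
  pointwise relative error of an exponential tail grows without bound for
  any fixed step, so the tail is normalized by the displacement scale.
* **The constant in $L$**: fixed to $-\tfrac12\ln 2\pi$, making $L$ an
  exact Gaussian log density (so $e^{-S}$ integrates to 1, which is
  tested). Dynamics depend only on surprise differences, so the choice is
  inert but is applied consistently everywhere.
* **Perturbations** are additive injections into the *body*: steps
  displace $x$ once within the integration interval containing the
  onset; impulses add `magnitude * overlap` per step, so sustained
  disturbances are impulses with a duration. Sensor-level disturbances
  are expressed as lesions instead.
* **Sensing noise vs. data precision** are decoupled on purpose: the
  controller uses $\pi_{prior}$, not $\pi_{data}$, so the generative
  noise is configured directly as a standard deviation (0.25 in the
  reference scenario) while `data_precision` only matters for
  `update_belief()`.
* **Gradients**: analytic for the built-in transforms, central finite
  difference ($h = 10^{-6}\max(1,|x|)$) for custom functions. A
  vanishing $\partial g/\partial x$ makes the state-to-input mapping
  non-invertible and the action gradient ambiguous; the package raises an
  error there rather than silently choosing a branch.
* **Determinism**: a run's entire noise stream is drawn once from the
  configuration seed, so equal configurations give byte-identical CSV
  output (tested via file hashes).

## The reference scenario

`figure6_preset()` encodes the package's reference study conditions:
baseline belief $(\mu, \pi) = (1, 1)$, identity maps, $\lambda = 1$,
sensory noise sd 0.25, three step perturbations of magnitude 1.5, an
anticipatory setpoint shift to 2 after the first perturbation, a reset to
1 in a predicted safe period, and a precision increase from 1 to 4 when a
perturbation of uncertain direction is anticipated. Only the *ordering*
of the six incidents is meaningful; absolute times are unlabeled in the
underlying theory, so the preset spaces them uniformly
(t = 15, 30, 45, 60, 75, 90 over 120 s; overridable, and no quantitative
check depends on the absolute times). At the default step this is a
48,000-step run. The staging analyses use a 400 s effector-lesion run at
$dt = 0.01$ (40,000 steps) and the separability analysis one hundred
80 s panel runs; sizes chosen so each analysis completes in seconds on a
single core while leaving the dwell-time dynamics ($d_{gen} = 250$ s)
room to unfold.

```{r example}
traj <- run_simulation(figure6_preset(noise_sd = 0))
mean(traj$x[traj$time >= 43 & traj$time < 44.9])   # settled on the shifted setpoint
max(traj$pwpe_sq[traj$time >= 90 & traj$time <= 91]) /
  max(traj$pwpe_sq[traj$time >= 15 & traj$time <= 16])  # precision ratio
```

## What the synthetic scenarios do and do not emulate

The generator covers the conditions the model itself is about: isolated
and sustained perturbations, anticipatory setpoint management, precision
reweighting, and circumscribed single-locus dysfunction, all on one
scalar variable with stationary Gaussian sensor noise. It does not
emulate several properties of real interoceptive data: multiple coupled
physiological variables and setpoint hierarchies, non-stationary or
heavy-tailed noise, delayed or rhythmic (e.g. cardiac/respiratory)
sensing, probabilistic effector mappings ("action precision"), or any
mapping from lesions to anatomy or neuroimaging observables. Passing
tests therefore demonstrate internal consistency of the control and
monitoring mechanisms under the stated conditions — not validity for any
particular physiological system.

## Known limitations

* The monitor's evidence balance is imperfect around transients: when a
  window straddles a perturbation the slope is briefly positive while
  the reflex is in fact succeeding, and in the late tail of a recovery
  the slope flattens before actions fall below threshold, so isolated
  incidents contribute a few spurious failure observations. With isolated
  perturbations the dips in self-efficacy are far shorter than the
  staging dwell times and the system stays `normal` (tested); under long
  *sequences* of incidents, or under sustained sensor noise (where
  micro-actions keep `acting` true at equilibrium), the balance drifts
  and self-efficacy equilibrates well below 1. Staging analyses in this
  package therefore use noise-free scenarios.
* Pre-perturbation "micro-actions" under sensor noise are small relative
  to corrective peaks only in the ratio of the noise sd to the
  perturbation size (0.25 vs 1.5 in the reference scenario); they are not
  orders of magnitude smaller, because the action signal is linear in the
  sensed error.
* One reflex arc, one variable, one-level allostasis; no setpoint
  hierarchies, no learning of schedules, no feedback from the
  metacognitive layer.
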