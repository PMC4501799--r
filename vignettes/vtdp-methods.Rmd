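---
title: "Modeling the developmental switch from spontaneous to evoked vesicle release"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the developmental switch from spontaneous to evoked vesicle release}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtdp)
```

## The model

Synaptic vesicles fuse with the presynaptic membrane in three modes:
spontaneously (SVE), uncorrelated with action potentials; asynchronously
evoked (aEVE), loosely coupled to action potentials through residual
calcium; and synchronously evoked (sEVE), immediately after an action
potential. Early in development spontaneous fusion dominates; mature
synapses communicate mainly through evoked fusion. This package simulates
what that switch does to Hebbian plasticity when the presynaptic timing
variable of the learning rule is the *vesicle* release time rather than the
spike time — vesicle-timing dependent plasticity (VTDP).

The simulated circuit is feed-forward: `n_pre = 500` Poisson presynaptic
neurons project onto `n_post = 10` leaky integrate-and-fire neurons, all to
all. A fixed 20% subset of inputs fires at 8 Hz, the rest at 4 Hz
(population mean 4.8 Hz). Per synapse, the release machinery is divided
into fractions `xi_sve + xi_aeve + xi_seve = 1`, reflecting the relative
abundance of the calcium sensors that support each mode; the developmental
switch is expressed by moving mass from the spontaneous fraction to the
evoked ones.

**Membrane and threshold.** Each output neuron integrates

$$\frac{dV}{dt} = -\frac{V - V_{rest}}{\tau_m} + \frac{I_{ves}}{C_m},
\qquad
\frac{d\theta}{dt} = -\frac{\theta - \theta_{rest}}{\tau_\theta},$$

with a spike when $V \ge \theta$, after which $\theta$ resets to
$\theta_{max}$ (refractoriness) and $V$ to $V_{rest}$. The membrane reset is
a package decision — only the threshold reset is prescribed by the source
model — and follows the standard integrate-and-fire convention; at ~5 Hz
output rates the choice is immaterial because the adaptive threshold
dominates recovery.

**Release.** Per synapse $(i,j)$ and 1-ms step, expected vesicle counts are

$$v_{SVE} = n\, r_m\, \xi_{SVE}\, \frac{P_a}{P_c}\,\Delta t,\qquad
  v_{aEVE} = Ca_i\, \xi_{aEVE}\, \frac{P_a}{P_c}\,\Delta t,\qquad
  v_{sEVE} = n\, \xi_{sEVE}\, \frac{P_a}{P_c} \text{ per spike},$$

with $n = 4$ vesicles per action potential, $r_m$ the *nominal* population
mean rate (4.8 Hz, computed from the configured pattern, not from realized
spike counts), and $P_a/P_c$ the available fraction of the 100-vesicle
pool. Counts are Poisson; released vesicles move to the recycling pool and
return with $\tau_{rec} = 800$ ms. Residual calcium decays with
$\tau_{Ca} = 100$ ms and jumps at each spike by an increment calibrated so
that the *discrete-time* release-rate integral after one isolated action
potential is exactly $n$ vesicles: $A = n(1 - e^{-\Delta t/\tau_{Ca}})/\Delta t$,
which is $n/\tau_{Ca}$ in the continuum limit. This calibration (rather
than the raw $n/\tau_{Ca}$) keeps all three modes at identical mean release
rates at any $\tau_{Ca}$ — including the 2-ms constant used in the
maturation protocol, where the raw increment would inflate asynchronous
release by 27%. With equal mean rates, the three modes differ only in the
spatiotemporal structure of release, which is the experimental contrast the
simulator exists to make.

**Plasticity.** Every released vesicle pairs with its nearest preceding and
nearest following postsynaptic spike. With $\Delta s$ the spike time minus
the release time,

$$\Delta w^+ = \lambda\, w_0^{1-\mu} w^{\mu} e^{-|\Delta s|/\tau}
\;(\Delta s > 0), \qquad
\Delta w^- = -\lambda\, \alpha\, w\, e^{-|\Delta s|/\tau} \;(\Delta s < 0),$$

with $\mu = 0.4$, $\lambda = 0.1$, $\alpha = 0.11$, $\tau = 20$ ms, and
$w_0$ set to 5% of the mean equilibrated weight. Weights live in
$[0,\, 8\,\bar w(0)]$ with hard clipping. Pairing is truncated at
$7\tau = 140$ ms, where the exponential is below $10^{-3}$; nearest-neighbour
(rather than all-to-all) pairing bounds the cost per event and is nearly
identical at these rates. A vesicle released in the same step as the spike
it helped trigger is causally prior, and is potentiated with
$\Delta s = \Delta t/2$.

**Homeostasis.** All weights onto neuron $j$ scale multiplicatively toward
a target rate: $\tau_h\, dw/dt = (r_m - r_j)\, w$ with $\tau_h = 100$ s,
rates in Hz and times in seconds (the equation fixes its units only once a
convention is chosen; this is ours). The rate signal $r_j$ is
$12/(t - t_{(12)})$, the count over the span back to the twelfth-most-recent
spike. Before twelve spikes exist we use the cumulative count over elapsed
time instead: holding the estimator at the target during that phase — a
plausible alternative reading — permanently deadlocks a silent cold start
(no spikes, so no scaling, so no spikes), whereas the cumulative estimator
reads a silent neuron as 0 Hz and lets the controller engage. Scaling is
applied once per 100-ms block, which at $\tau_h = 100$ s is
indistinguishable from per-step application and three orders of magnitude
cheaper.

## Numerical scheme

All linear subsystems — membrane leak, threshold relaxation, calcium decay,
pool recovery, and the EPSC kernel — are advanced with their exact
exponential update factors on the fixed 1-ms grid (for the membrane, the
exact solution with the current held constant over the step). Plain forward
Euler at this step size incurs ~5% per-time-constant error on
$\tau_m = 9.4$ ms; exact integration removes the error at no cost and makes
the simulator verifiable against closed forms to $10^{-6}$, which the test
suite does for every subsystem. EPSC bookkeeping drops vesicle currents
older than `t_window` = 20 ms (< 0.2% of the initial current remains).
Release counts in a step are capped at the available pool, a cap that
essentially never binds at default parameters. The inner loop is compiled
(Rcpp) and consumes R's RNG stream, so a run is bitwise reproducible from
`set.seed()`; `vtdp_streams()` derives named sub-seeds from one master seed
so that adding a diagnostic consuming randomness in one component does not
perturb another.

**Equilibration.** Before an experiment, the network runs under pure
spontaneous release with homeostasis until the trailing 20-s mean output
rate is within 5% of target (both the window and the band are package
choices). The pair rule is disabled during this phase: its reference weight
$w_0$ is *defined* as a fraction of the equilibrated mean weight, which
does not exist yet. The equilibrated mean $\bar w(0)$ then anchors $w_0$,
the weight ceiling, and the pruning threshold.

**The homeostatic set point.** With the pair rule active under pure
spontaneous release, the power-law potentiation/multiplicative depression
rule has its per-synapse fixed point near $2\bar w(0)$; the resulting slow
upward drift balances the homeostatic controller about 0.8–0.9 Hz above
the nominal 4.8 Hz target, so the maintained output rate computed by the
package is ≈ 5.6–5.7 Hz. This is a property of the published constants —
the maintained rate is usefully described as "about 5 Hz", not as exactly
the input mean — and the acceptance machinery measures it rather than
assuming it.

## The competitive rate model

For imprinting experiments the spiking machinery is replaced by an
$N \times N$ rate description: per-synapse exocytosis rates $x_{ij}$ mix a
spontaneous component (Gaussian across synapses, sd 0.05, mean equal to the
evoked grand mean, truncated at zero) and an evoked component that is 0.8
on a random 20% subset of presynaptic rows and 0.4 elsewhere. Weights in
$[0,1]$ evolve by column-wise competition,
$dw/dt = \gamma (x_{ij} - \bar x_j)\, s$ with $\gamma = 10^{-4}$/s and the
soft-bound factor $s = w - w^2$ on the potentiation side, $w^2$ on the
depression side (the boundary values are fixed points; exact equality with
the column mean contributes nothing either way). Column totals are
renormalized every 10 s as the rate-model analogue of homeostatic scaling —
the spiking model's Eq-8 rule needs a firing rate the rate model does not
have, and total input weight is its natural stand-in. Pattern storage is
scored by the mean sign-overlap `pattern_match()` between above-average
weights and the above-average *evoked* pattern.

Package choices here: $N = 100$ (large enough that the null overlap is
within $\pm 3/N$); the unimodal initial mean is 0.5, the mixture mean of the
bimodal alternative (weak $0.2 \pm 0.02$, strong $0.8 \pm 0.08$), so both
initializations start at matched total weight; the "previously encoded"
strong subset is drawn to differ from the presented pattern. The Euler step
defaults to 1 s and the imprinting driver uses 10 s: with $\gamma = 10^{-4}$/s
the largest per-step change is $\sim 2\times 10^{-4}$, and a test verifies
that 1-s and 10-s trajectories agree to $10^{-6}$. The dynamics need
$10^4$–$10^5$ simulated seconds, so a 0.1-s step would only multiply cost.

## Developmental schedule, synaptogenesis and pruning

Expression profiles for Doc2b (spontaneous), Doc2a (asynchronous) and
Synaptotagmin1 × Complexin1 (synchronous) drive the release fractions as
per-gene max-normalized ratios, linearly interpolated in age. Measured
profiles are not bundled; `synth_profiles()` provides parametric stand-ins
with the documented qualitative shapes (decaying sigmoid, transient bump,
rising sigmoids), and `read_expression_profile()` accepts a user table with
the same columns. The age axis runs 0–20 years with stage boundaries at 2 y
(early → childhood) and 12 y (childhood → adolescence and later) — the
stage labels carry the synaptogenesis rate constants $6.6\times10^{-8}$,
$5.0\times10^{-8}$ and $2.5\times10^{-8}$ per unconnected pair per second
(these reproduce the quoted 8%/5%/3% of new synapses per two weeks).
Developmental time is compressed by accelerating these rates $10^6$-fold
while preserving the stages' relative durations, so the full profile spans
~630 simulated seconds. New synapses start at $0.75\,\bar w(0)$ — above the
pruning threshold, so newcomers can be incorporated rather than immediately
culled — with a full vesicle pool. Pruning removes connected synapses
strictly below $0.7\,\bar w(0)$; the printed source for that threshold is
self-referential ("$w_{ij} < 0.7\, w_{ij}$"), and we read both it and the
cap against the equilibrated mean, consistent with the cap appearing
elsewhere as $8\, w_{ij}(0)$. The developmental run starts from 50%
random connectivity (a package choice; the source does not state one), so
synaptogenesis has room to raise density before activity-dependent pruning
lowers it.

Learning is scored by the divergence factor $D(t)$ — the ratio of
high-rate-group to low-rate-group *median* weight (medians are robust and
the ratio is scale-free) — and the learning rate $\Lambda(t)$, its
finite-difference derivative. A centred moving average (10–20 s) is applied
before differencing when locating the peak of $\Lambda$: 1-s snapshot
medians are noisy and the raw difference maximum lands on noise.

## The pairing-protocol (STDP curve) driver

`stdp_curve()` renders the classical induction experiment in vesicle terms:
per offset $\Delta t = t_{post} - t_{pre}$, 50 pairings of one presynaptic
action potential with one *clamped* postsynaptic spike at 1 Hz (slow enough
that consecutive pairings cannot interact through the 140-ms pairing
window; residual calcium does carry over between trials, which is the
physics of the long-$\tau_{Ca}$ immature case). Vesicles sample from the
active fractions — synchronous release locked to the spike, asynchronous
release spread over the calcium transient — and every vesicle pairs with
the flanking postsynaptic spikes under the standard rule. The curve is
reported both as raw $\Delta w$ and as percent of the starting weight; the
timing-sensitivity index is the difference between the +10-ms and −10-ms
points. Shortening $\tau_{Ca}$ from 1 s through 7 ms to 2 ms moves the
curve from a timing-insensitive, potentiation-biased immature form to the
antisymmetric mature form. Pools are clamped full by default in this
driver, as in a low-frequency induction experiment.

## What the synthetic conditions do and do not show

The simulated inputs are stationary, uncorrelated Poisson trains with a
two-level rate pattern; the circuit is feed-forward, excitatory-only, with
no conduction delays, no recurrence, no inhibition, and no postsynaptic
plasticity machinery. The expression profiles are parametric stand-ins with
the right qualitative shapes, not measured transcriptomes, and ages map to
stages only through the stated boundaries. Passing tests therefore
demonstrate the internal logic of the release-mode switch — equal-rate
normalization, competition ordering, maintenance, imprinting, curve
maturation — not quantitative agreement with any particular biological
circuit. Within those conditions, test problem sizes are chosen to be
decisive rather than exhaustive: 200–300-s network runs for
competition/maintenance properties, 20 seeds for the paired imprinting
comparison, 630 s for the developmental trajectory.

## Known limitations

* Release fractions are global per run (scheduled in time but not
  synapse-specific), so synapse-specific switch experiments require
  separate runs.
* Event-level logging is memory-heavy and intended for short runs;
  long-run diagnostics use per-mode totals and snapshots.
* With finite pools, the realized release rates of the three modes differ
  by up to ~3% through release/availability covariance (spike-triggered
  modes release when pools are relatively depleted); the exact equal-rate
  normalization holds for the release probabilities, and is verified with
  pools clamped.
* The homeostatic controller needs tens of seconds of simulated time to
  engage from a cold start; measurements should follow equilibration.
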