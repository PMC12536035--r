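---
title: "Chimera states and theta phase precession: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chimera states and theta phase precession}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(phasechimera)
```

## The scientific question

During active behavior the hippocampal local field potential oscillates at
roughly 8 Hz (theta). Interneurons lock their spikes to fixed theta phases,
while many pyramidal cells fire slightly faster than theta (≈ 9 Hz), so their
spike phase advances on successive cycles — *phase precession* — and groups of
such cells fire in repeatable orders within a cycle (*theta sequences*). A
*chimera state* — a solution of a network of identical coupled oscillators in
which a synchronized and an unsynchronized subpopulation coexist — has exactly
this structure: the synchronized group plays the role of the phase-locked
population (and of the theta rhythm itself), and the unsynchronized group,
which oscillates slightly faster, plays the role of precessing cells.

`phasechimera` implements this computational argument end to end:

1. two Kuramoto-oscillator models with chimera solutions (a nonlocally
   coupled ring, and two weakly coupled populations),
2. observables that map phases onto neuroscience quantities (a
   spike-generating Poincaré section, phenomenological LFPs, Kuramoto order
   parameters),
3. mean-phase-velocity metrics that quantify the two domains and their
   frequency ratio,
4. spike-phase precession and theta-sequence estimators, and
5. a Dale's-law-constrained Izhikevich spiking network trained with
   FORCE/recursive least squares to *embed* the two-population chimera, whose
   single units then show precession and locking.

## The oscillator models

**Ring.** `simulate_ring()` integrates, with fixed-step Euler (`dt = 1e-3`),

$$\dot\phi_i = \rho - \frac{1}{N}\sum_{j=1}^{N}
  \big[1 + A\cos(2\pi(i-j)/N)\big]\,\cos(\phi_i - \phi_j - \beta),$$

with defaults $A = 0.95$, $\beta = 0.2$, $N = 500$. Because the coupling
depends only on phase differences, adding a constant to $\rho$ shifts every
mean phase velocity by the same amount without changing the dynamics of the
differences; the intrinsic frequency is therefore a clean experimental knob.
The kernel is rank-3 ($1 + A\cos\theta_i\cos\theta_j +
A\sin\theta_i\sin\theta_j$), so the coupling is evaluated in $O(N)$ per step;
a unit test pins it to the literal double loop to $10^{-12}$.

**Initial conditions and basins.** The fully synchronized state is also
stable at these parameters. Half the ring at a single common phase with the
other half spread uniformly over the *whole* circle falls into the
synchronized state's basin within tens of time units. With the incoherent
half spread up to roughly ±2 rad around the common phase — or with the
classical localized-random profile $6\,U(0,1)\,e^{-0.76 x^2}$ — the system
lands in the chimera basin essentially always, and every such start converges
to the *same* chimera attractor. `init_ring_phases()` therefore uses a
`spread` parameter, default 1.5 rad; `spread = pi` reproduces the full-circle
variant (and its collapse). This is the one place where the package's
"chimera-like initial condition" is deliberately narrower than the loosest
reading of that phrase, because otherwise the stated study condition — a
persistent chimera — does not hold at all.

**Two populations.** `simulate_twopop()` integrates two groups of $n = 3$
oscillators with strong within-group coupling $\mu = (1+A)/(2n)$ and weak
between-group coupling $\nu = (1-A)/(2n)$ ($A = 0.1$, $\beta = 0.025$), the
printed sums including the self-term (a constant common drift). The factor
$\tau = 1/0.012$ slows the dynamics so that one time unit maps to one
millisecond and the synchronized population, suitably tuned, oscillates at
8 Hz.

Three incoherent initial profiles are provided (`init_twopop_phases()`):

* `"spread"` (default, ±1 rad): reaches a long-lived **breathing chimera** —
  one population fully coherent, the other's order parameter fluctuating
  between ≈ 0.3 and ≈ 0.9 — persisting beyond 40,000 time units;
* `"splay"`: the rotating-wave configuration with order parameter exactly 0.
  Its within-population coupling cancels identically, giving the largest
  frequency gap (mean drift $\sqrt{(\mu n\cos\beta)^2 - (\nu n)^2}/\tau$,
  ≈ 0.60 cycles per 1000 time units), but it is dynamically unstable and
  collapses to full synchrony after ≈ 850 time units;
* `"uniform"`: i.i.d. on the full circle; overshoots the chimera's partially
  coherent state and collapses.

The frequency gap between the populations is independent of $\rho$ (same
rotating-frame argument as for the ring). For the persistent breathing
chimera it is ≈ 0.4 cycles per 1000 time units, so when `calibrate_rho()`
tunes the synchronized population to exactly 8 cycles per 1000 time units
(one rescaled second), the unsynchronized population completes ≈ 8.4 cycles.
The often-quoted 8 : 9 picture corresponds to a gap of 1.0, which these
equations reach only at a considerably larger coupling asymmetry
(A ≈ 0.27) or a faster time constant (τ ≈ 1/0.02); the package reports what
the stated equations actually do.

```{r twopop-demo}
cfg <- twopop_config(rho = 5, seed = 1)
traj <- simulate_twopop(cfg, duration = 600, burn_in = 200)
prof <- classify_sync_domain(mean_phase_velocity(traj, window = 600))
velocity_ratio(prof)
```

**Perturbation.** `perturb_twopop()` (or `simulate_twopop(perturb_at = ...)`)
applies one independent uniform phase kick in $[-m, +m]$ to every oscillator.
The model never prescribes a perturbation; the uniform kick with default
$m = \pi$ is the simplest mechanism that exchanges the synchronized and
unsynchronized roles in seeded runs (the outcome is stochastic — the kicked
state re-converges to a chimera whose coherent population depends on the
seed). Re-convergence takes a few thousand time units.

## Observables

* `phases_to_spikes()` emits a spike whenever an unwrapped phase crosses a
  multiple of $2\pi$ from below, locating the crossing by linear
  interpolation between recorded samples; backward crossings are ignored.
  Per-unit spike counts over a window equal the rotation counts $M_i$ used by
  the velocity metrics — an exact integer identity, tested.
* `compute_lfp()` returns the mean of $\cos(\text{phase})$ over either the
  synchronized set or all oscillators; both give a theta-band trace with the
  same dominant frequency.
* `order_parameter()` returns $R(t) = |n^{-1}\sum_j e^{i\theta_j}|$.

## Mean phase velocity and the ratio

`mean_phase_velocity()` counts complete rotations $M_i$ in a window
($\Delta t = 1000$ by default) and reports $\Omega_i = 2\pi M_i/\Delta t$,
an exact rational in the integer count. The synchronized domain is the slower
one; `classify_sync_domain()` labels units within a relative tolerance
(default 1%) of $\min_i \Omega_i$ as synchronized. The tolerance matters
little for the ratio: over tolerances $10^{-6}$–$0.1$ the ρ = 2.8 ring ratio
moves only between ≈ 0.85 and ≈ 0.83.

`velocity_ratio()` implements the mean of $\Omega_s/\Omega_j^u$ over the $m$
unsynchronized oscillators (population standard deviation as the spread); for
two-population runs both domains share a single velocity, so the ratio is a
scalar with zero spread. Two documented subtleties:

* At ρ = 2.8 this average evaluates to ≈ 0.84 on the ring chimera, while the
  headline figure for the precession regime is ≈ 0.88 — the latter is
  recovered (≈ 0.89) if the average runs over *all* oscillators, i.e. if the
  synchronized units contribute ratio-1 terms. The package keeps the
  as-defined average and documents the discrepancy rather than silently
  switching definitions.
* At ρ = 1 the classical "three unsynchronized spikes per synchronized
  spike, ratio ≈ 0.33" is the spike-count ratio of the synchronized domain
  against the *fastest* unsynchronized oscillators,
  $\Omega_s/\Omega_{max}$ (41 vs. 124 rotations per 1000 time units here);
  the mean over the whole unsynchronized arc is ≈ 0.42.

An uncoupled oscillator obeys $\dot\phi = \rho$ and therefore has mean phase
velocity exactly $\rho$ (`uncoupled_velocity()`); the normalization
$2\pi\rho$ sometimes quoted is inconsistent with the rotation-count
definition. Coupled profiles sit strictly below $\rho$ at every setting
examined: the net effect of the coupling is inhibitory.

`frequency_sweep()` runs the full pipeline over a ρ grid: the ratio grows
monotonically with ρ and the chimera collapses to full synchrony
(ratio 1, collapse flag) at large ρ for both topologies under the fixed-step
integrator.

## Precession and sequences

`assign_spike_phases()` interpolates a reference unwrapped phase (a
synchronized oscillator, or a decoded synchronized component of the trained
network) at each spike time; the integer part of phase/2π is the theta-cycle
index. `precession_report()` fits, per unit, the slope maximizing the mean
resultant length of $\theta_k - s\,c_k$ (circular–linear regression; grid
search on $[-\pi, \pi]$ — the identifiable range for integer cycle indices —
then local refinement; exact on noiseless linear data). Classification
defaults: precessing if $s \le -0.1$ rad/cycle; locked if $|s| < 0.1$ and the
raw mean resultant length is ≥ 0.8; `other` otherwise; fewer than 3 spikes
yields an `insufficient-data` row rather than an error. No slopes are printed
in the source literature for these simulations; the thresholds are package
choices and configurable.

For two constant rates $f_u > f_s$ the slope is $-2\pi(f_u/f_s - 1)$ per
cycle: the 8 : 9 regime gives ≈ −0.79 rad/cycle, and the breathing-chimera
regime (8 : 8.4) gives ≈ −0.31 — comfortably past the precession threshold.

`theta_sequence_score()` ranks units by first-spike time within each cycle
and averages Spearman correlations of those ranks between consecutive cycles:
1 for a frozen order, ≈ 0 for shuffled orders. On the ring the repeatable
order is carried by the slower (partially coherent) flank of the
unsynchronized arc; the faster oscillators shear their order from cycle to
cycle.

## The spiking network and FORCE

`force_network()` builds `N` Izhikevich neurons (all Table-default
parameters exposed via `izh_params()`), a 90%-sparse static weight matrix
with entries $\mathcal N(0, 1/(Np^2))$, encoders $\eta \sim U[-1,1]^m$,
decoders $d = 0$, and $P = I/\lambda$ with $\lambda = 1$. Synapses are double
exponentials advanced by their exact exponential solution; a spike adds
$1/(\tau_r \tau_d)$ to the rise variable. `build_supervisor()` resamples a
two-population trajectory to the network step (0.04 ms) and stacks
$x = (\cos\phi, \sin\phi, \cos\gamma, \sin\gamma)$, a 12-dimensional signal
for $n = 3$.

`train_force()` runs the three FORCE phases (pre-learning with static
weights; learning with RLS decoder updates every 20 steps; post-learning with
the decoder frozen). `rls_update()` is the printed recursion — update $P$,
then $d \leftarrow d - (P_{new} r)e^\top$ — and equals batch ridge regression
on any fixed rate stream to $10^{-8}$ (tested).

**Dale's law.** Each neuron's outgoing weights must share one sign. The
static matrix takes its column's sign at initialization. For the learned
feedback $Q\eta d^\top$ the package uses a non-negative encoder
$|\eta|$ together with decoder rows projected onto their neuron's sign, so
every column of $G\omega^0 + Q|\eta|d^\top$ is sign-definite at every
update; the uniform (neuron-independent) component that a non-negative
encoder adds to the feedback is cancelled by an equal global external
current, which is a shared drive rather than a synapse. Hard per-update
projection destabilizes long RLS runs, so the default `dale_mode = "lazy"`
updates an unconstrained shadow decoder by pure RLS and uses its sign
projection in the network at every step; `"project"` gives the hard variant.

**Gains and scale.** The quoted gains for this architecture disagree by a
factor of ten (1.5 × 10³ vs. 1.5 × 10⁴). At the package's desk scale
(N = 1000, down from 10,000) neither works: the small value leaves the
network nearly silent, the large one is epileptic. The reference
configuration uses G = 6000, Q = 1400, the middle of the stable chaotic
regime found by a coarse grid.

**What training achieves — and what it cannot.** With the breathing-chimera
supervisor calibrated to 8 Hz, 30 s of learning gives post-learning
per-channel correlations ≈ 0.9–0.97 for the synchronized population's
channels, and the decoded output is a genuine chimera: `decode_phases()`
recovers a slow and a fast population, and the trained raster contains both
precessing and phase-locked units (78 and 208 of ~950 active units in the
reference run). The supervisor must itself remain a chimera for its whole
span — the breathing state occasionally collapses to full synchrony on long
horizons, which is detected from the velocity profile at the end of the span
and the initial condition redrawn. The unsynchronized oscillators' channels
are weakly chaotic (the breathing chimera has a finite predictability
horizon), so a frozen autonomous network necessarily de-phases from them;
their correlations over the first post-learning second reach only ≈ 0.4–0.9.
Agreement is therefore judged over a finite window (`success_window`,
default the first second of post-learning), and the package reports
per-channel correlations for both that window and the full post phase. A
uniformly-≥ 0.9 reproduction of all 12 channels would require a
quasi-periodic supervisor; the only such state of these equations (the splay
chimera) is unstable and does not survive a 36 s supervisor.

## Problem sizes and numerical choices

* Ring experiments: N = 500, burn-in 100 time units, measurement window 1000,
  recording every 100 Euler steps (0.1 time units) — spike interpolation
  error is far below `dt` because phases are near-linear on that scale.
  Sweeps record only ~20 samples per window (rotation counts need window
  endpoints only).
* Noise: Euler–Maruyama increments $\sqrt{2D\,dt}\,\mathcal N(0,1)$; the
  diffusion coefficient D is the primitive parameter and
  $\sigma = \sqrt{2D}$ is derived (the quoted (σ, D) pairs are mutually
  consistent only under this reading for the first pair; the others appear
  to be factor-of-10 slips).
* Two-population runs use the same `dt`; supervisors are recorded every
  40 steps so the supervisor grid is exactly the network's 0.04 ms step.
* FORCE: N = 1000 (P is then 10⁶ doubles), 1 s pre-learning, 30 s learning,
  5 s post-learning, RLS every 20 steps. One training run takes a few
  minutes on one CPU.
* Degenerate inputs: empty spike trains, all-synchronized (collapsed)
  profiles, and under-sampled units all return flagged results rather than
  errors; non-finite states abort with the offending integration step.

## What the synthetic data do and do not show

Every input here is generated by the models themselves: there are no animal
positions, place fields, or measured LFPs. Passing tests show that chimera
dynamics *can* produce theta-like rhythms, precession-like phase advances,
spike sequences, and that these survive spiking implementation and noise —
they do not show that the hippocampus uses this mechanism, nor do they probe
heterogeneous neurons, realistic E/I ratios (the network is 50/50), or
biophysical LFPs.

## Known limitations

* The breathing two-population chimera gives a sync:unsync frequency gap of
  ≈ 0.4 cycles per rescaled second, not the 1.0 of the idealized 8 : 9
  picture (see above); the rotating-wave state that would give ≈ 0.6 is a
  transient.
* The as-defined unsynchronized-only velocity-ratio average at ρ = 2.8 is
  ≈ 0.84; 0.88–0.89 corresponds to averaging over all oscillators.
* FORCE reproduction of the chaotic supervisor channels is bounded by the
  supervisor's own predictability horizon.
* Dale's law enforcement for the learned weights is a reconstruction (two
  variants provided); the original construction is not fully specified in
  text form anywhere we could verify.
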