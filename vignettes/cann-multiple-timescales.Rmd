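---
title: "Continuous attractor dynamics with multiple short-term time scales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous attractor dynamics with multiple short-term time scales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mscann)
```

## The model

`mscann` simulates a two-dimensional continuous attractor neural network
(CANN): a sheet of rate neurons on a feature space $(x, y)$ with
translation-invariant Gaussian recurrent coupling and divisive global
inhibition. The synaptic input $U(\mathbf{x}, t)$ evolves as

$$\tau \frac{\partial U}{\partial t} = -U
 + \rho \int J(\mathbf{x} - \mathbf{x}')\, f p\, r\, d\mathbf{x}'
 - V + g\, I_{\mathrm{ext}},$$

with coupling $J(\Delta) = \frac{J_0}{2\pi a^2} e^{-|\Delta|^2 / 2a^2}$ and
firing rate

$$r = \frac{[U]_+^2}{1 + k \rho \int [U]_+^2\, d\mathbf{x}'},$$

so that activity first grows quadratically and then saturates through
shunting inhibition of strength $k$. Four slower processes modulate this
backbone, each a scalar field with first-order kinetics:

* **STF** (short-term facilitation) $f \in [f_{\min}, 1]$, rising with the
  local rate on $\tau_f$: $\tau_f \dot f = f_{\min} - f + \alpha (1 - f) r$.
* **SFA** (spike-frequency adaptation) $V \ge 0$, a negative-feedback
  current tracking $m [U]_+$ on $\tau_v$.
* **recurrent STD** (short-term depression) $p \in [0, 1]$, depleted by the
  presynaptic throughput $f p r$ on $\tau_d$:
  $\tau_d \dot p = 1 - p - \beta f p r$.
* **feedforward STD** $g \in [0, 1]$, depleted by the external input on
  $\tau_g$: $\tau_g \dot g = 1 - g - \eta g I_{\mathrm{ext}}$.

The external input is a Gaussian of strength $A_{\mathrm{amp}}$ and width
set by $4a^2$ in the exponent, optionally moving at speed $v_{\mathrm{ext}}$
along direction $\theta$.

The central claim the experiment drivers reproduce is that with the ordering

$$\tau \ll \tau_f \ll \tau_v \ll \tau_d \ll \tau_g$$

one circuit concurrently supports three seemingly conflicting computations:
persistent activity after a transient stimulus (positive feedback via STF),
adaptation to a sustained stimulus (negative feedback via feedforward STD),
and anticipative tracking of a moving stimulus (mobility via SFA).
`check_timescales()` verifies the ordering (default: each ratio at least 5)
and warns when it fails.

## Discretization and numerics

* **Domain.** The equations are posed on the plane but all interesting
  states are localized, so the model is integrated on a periodic square
  lattice over $(-\pi, \pi]^2$ (default $64 \times 64$ in the drivers, and
  $100\times100$ in the acceptance script; both are stated per run). The
  kernel is evaluated at nearest-image displacements; with $a = 0.5 \ll
  2\pi$ the wrap-around truncation error is of order $e^{-\pi^2/2a^2}
  \approx 10^{-9}$. The recurrent integral is a circular convolution
  computed by FFT, which the test suite checks against a direct
  $O(n^4)$ lattice sum.
* **Density.** $\rho$ multiplies all Riemann sums; `rho = NA` resolves it
  to $n^2 / L^2$ (one neuron per cell), making sums approximate the
  continuum integrals so results are robust to lattice resolution. The
  bundled presets instead pin $\rho = (100/2\pi)^2 \approx 253.3$, the
  reference lattice density: the inhibition values of the documented
  operating points are only meaningful at that density, and pinning it lets
  coarser lattices sit at the same physical operating point.
* **Integrator.** Forward Euler with $dt = 0.1\tau$ by default and a hard
  guard at $dt \le 0.2\tau$. $\tau = 1$ ms is the fastest scale and the
  phenomena of interest are threshold crossings and regime boundaries, so
  first order suffices; a Richardson test verifies the $O(dt)$ error decay,
  and the efficacy bounds ($f \in [f_{\min},1]$, $p, g \in [0,1]$) are
  asserted at every step — excursions beyond $10^{-12}$ abort as
  integration instability rather than being clipped silently.
* **Initial conditions.** The silent state $U = V = 0$, $f = f_{\min}$,
  $p = g = 1$ is the unique rest state and the default. `seed_bump_state()`
  places the Gaussian bump template; by default it also sets $f$ and $p$ to
  their clamped equilibria for the seeded activity, so the seed represents
  a bump that has been active for a while rather than one dropped into
  naive synapses (at $k$ above the bare-bump boundary a cold seed dies
  before facilitation can build up).
* **Stimulus switching** is hard on/off at `t_on`/`t_off`, with no ramp.

## Closed-form anchors

For the bare network ($\alpha = \beta = m = \eta = 0$, so $f$ rests at
$f_{\min}$) the Gaussian bump ansatz
$U = A_u \exp(-|\mathbf{x}-\mathbf{q}|^2/4a^2)$ reduces the fixed-point
equation to a quadratic in $A_u$,

$$2\pi a^2 k \rho A_u^2 - \tfrac{1}{2}\rho \bar J A_u + 1 = 0,
  \qquad \bar J = J_0 f_{\min},$$

whose larger root is the stable amplitude (`stationary_amplitude()`). Real
roots exist below the critical inhibition

$$k_c = \frac{\rho (J_0 f_{\min})^2}{32 \pi a^2},$$

(`critical_inhibition()`). The simulated bump seeded at the analytic
amplitude holds it to better than one percent, which pins down the kernel
normalization and the rate function jointly. Two further conditions are
evaluated analytically: a network with adaptation holds a self-sustained
traveling wave iff $m > \tau/\tau_v$, and a moving stimulus is tracked
anticipatively iff $0 < v_{\mathrm{ext}} < v_{\mathrm{int}}$, the intrinsic
wave speed.

## Measurements

* **Bump center**: the phase of the first circular Fourier mode of the
  rectified field per axis — an activity-weighted circular mean that is
  wrap-correct across the periodic seam. Undefined (`NA`) for silent or
  near-uniform fields.
* **End-state labels**: `silent`, `static_bump`, `traveling_wave` (center
  drift above `eps_drift`, default $10^{-4}$ rad/ms), or `metastable` for a
  run that ends silent after spending at least 30% of its duration above
  half its peak amplitude (a plateau that collapsed).
* **Plateau lifetime** $T_{\mathrm{life}}$: time from stimulus offset until
  the amplitude first falls below half (configurable `theta_off`) of the
  reference level, which is read `5 tau_f` after offset to skip the
  facilitation rebound; for facilitation-free networks the drivers use a
  zero reference delay, since decay can begin immediately. "Length of the
  decaying plateau" admits several operationalizations; this
  threshold-crossing one is scale-invariant, and `theta_off` is exposed
  rather than assumed away.
* **Tracking separation** $S$: mean nearest-image separation between bump
  and stimulus centers projected on the motion direction over the last 30%
  of the run, after a lock check (deviation of the separation from its mean
  below `eps_lock`). A bump counts as surviving only while its amplitude
  exceeds `theta_track` $\times A_{\mathrm{amp}}$ (default 1): a
  self-sustained bump is recurrently amplified above the feedforward drive,
  whereas after collapse only a passive ripple of a fraction of
  $A_{\mathrm{amp}}$ remains. Dead or unlocked runs report $S = 0$ with
  `tracked = FALSE`, keeping "locked on top" and "dead" distinguishable.

## Operating points and open choices

The two bundled presets are described in `?preset`. Choices the source
material left open, and how this package resolves them:

* **$f_{\min}$ of the single-feature networks.** The documented operating
  points of the adaptation-only phase diagram — M at $(k, m) = (0.01, 2.5)$
  holding traveling waves, N at $(0.0249, 0.5)$ marginally unstable — are
  consistent with the boundary $k_c \approx 0.0253$ obtained at the
  reference density with $J_0 f_{\min} = 0.05$. The `"fig1"` preset
  therefore runs the single-feature networks with synapses at full baseline
  efficacy ($f_{\min} = 1$, $J_0 = 0.05$); the combined `"fig2"` preset
  uses $f_{\min} = 0.1$ with $J_0 = 0.5$, the same product.
* **$\tau_d$.** Not fixed by the combined operating point; set to 400 ms,
  which satisfies the ordering with ratio $\ge 5$ on both sides
  ($\tau_v = 80$, $\tau_g = 3500$). Plateau lifetimes scale linearly with
  it (91, 183, 366 ms at $\tau_d$ = 400, 800, 1600 ms), which is the
  substantive claim; its absolute value only moves the proportionality.
* **Point N protocol.** At N the adaptation strength $m = 0.5$ is far above
  $\tau/\tau_v$, so no static bump exists there; the marginal state decays
  from a seeded active state, and the collapse is delayed by the slow
  passage of the adaptation field — the measured lifetime grows with
  $\tau_v$ (about 9, 13, 17 ms at $\tau_v$ = 40, 80, 160 ms on the 64×64
  lattice). The lifetime sweep therefore supports a `"seeded"` protocol
  (start from the bump, offset at $t = 0$) beside the transient-stimulus
  protocol.
* **Intrinsic speed of the combined model.** The free-running combined
  network does not sustain a wave: recurrent depression removes the bump on
  $\tau_d$, and facilitation anchors what remains. The intrinsic speed is
  therefore measured on the depression-free reduction
  (`depression_free()`), matching the reasoning that a tracking bump keeps
  leaving the synapses it has depressed. For the combined model the
  anticipation-to-lag crossover is probed directly in stimulus speed; the
  natural scale separating slow from fast stimuli is $a/\tau_v \approx
  6$ rad/s, and the acceptance suite probes 0.05 (no tracking: depression
  kills the bump before it moves), 0.8 (anticipation, $S v > 0$) and
  20 rad/s (lag, $S v \le 0$).
* **Desk scaling of adaptation runs.** Sustained-input runs scale
  $\tau_g$ down from 3500 ms so that three full decays fit in seconds of
  CPU. Note that at $\tau_g = 350 < \tau_d$ the ordering
  $\tau_d \ll \tau_g$ is violated and the measured decay duration mixes in
  the recurrent-depression transient (doubling ratio ~1.5); the linearity
  of decay duration in $\tau_g$ is therefore asserted on the 700 → 1400 ms
  doubling (measured ratio ~1.9), where the ordering holds again.
* **Boundary conventions.** Both analytic conditions are strict
  inequalities; equality returns `FALSE`.
* **Symmetry breaking.** On a symmetric lattice the symmetric bump is an
  equilibrium even where it is unstable, and the deterministic integrator
  will not leave it; wave measurements therefore seed the adaptation field
  displaced by 0.1 rad, selecting a drift direction without changing the
  measured asymptotic speed.
* **Bisection seeding.** Boundary bisections seed each probe at the vertex
  of the bare amplitude map, $A^* = \bar J / (8\pi a^2 k)$, which lies
  between the stable and unstable roots whenever a bump exists — so
  persistence of the probe is decided by the dynamics, not by knowledge of
  the answer.

## What the tests do and do not show

All quantitative checks run on deterministic simulations of the model
itself; there is no noise, no sampling variability, and no real neural
data. Passing them shows that the implementation integrates the stated
equations correctly (closed-form anchors, convergence, symmetry and bound
preservation) and that the documented regimes — boundary constant
$C \approx 32$, wave onset at $m\tau_v/\tau = 1$, concurrent
persistence/adaptation/anticipation at one parameter set — emerge at the
stated operating points on a 64×64 lattice. They do not show robustness to
biological heterogeneity, stochastic spiking, or parameter mistuning beyond
the ranges actually swept.

## Known limitations

* Forward Euler limits $dt$ to a fraction of $\tau$; stiff parameter
  choices (very large $\beta$ or $\eta$ with small time constants) abort
  with an instability error rather than being integrated adaptively.
* Near regime boundaries the end-state classification depends on run
  length and thresholds (documented defaults); bisection tolerances are
  reported alongside estimates.
* The 1D reduction of the model is not implemented; all simulations are
  two-dimensional.
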