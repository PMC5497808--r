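---
title: "Modelling segmentation-clock waves on a shortening PSM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling segmentation-clock waves on a shortening PSM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(segwave)
```

## The model

During somitogenesis, the presomitic mesoderm (PSM) hosts a collective
genetic oscillation — the segmentation clock — whose position-dependent
slowing produces waves of gene expression that travel from the posterior
tip towards the anterior end, where one segment is laid down per completed
anterior oscillation cycle. `segwave` models the tissue as a continuum of
coupled phase oscillators. The unwrapped phase $\phi(x,t)$ obeys

$$\partial_t \phi + v(x,t)\,\partial_x \phi \;=\; \omega(x,t) +
  \tfrac{\varepsilon}{2}\,\partial_x^2 \phi ,$$

with three ingredients: an intrinsic frequency profile
$\omega = \omega_0\,U(x/\bar{x}(t))$ that is maximal at the posterior tip
($U(0)=1$), decays to a fraction $\sigma$ at the anterior end ($U(1)=\sigma$)
and *jumps to zero* beyond it (arrested tissue); a cell-velocity field
$v = v_0\,V(x/\bar{x}(t))$, $V(\xi)=1-e^{-q\xi}$, vanishing at the tip (the
reference frame) and saturating anteriorly, whose gradient is the local
growth rate; and a diffusive coupling of strength $\varepsilon$ that models
the local synchronisation of neighbouring cellular oscillators. Both
profiles rescale with the instantaneous PSM length
$\bar{x}(t) = x_0 + x_1\tanh\eta(t-\bar{t})$, which for zebrafish shortens
from $x_0+x_1$ to $x_0-x_1$.

All quantities carry fixed units package-wide: micrometres, minutes,
radians. The default parameter set (`zebrafish_parameters()`) is the
calibration for a transgenic zebrafish reporter line at 23.5 °C:

| parameter | value | meaning |
|---|---|---|
| `omega0` | 0.15 rad/min | posterior (maximum) clock frequency |
| `v0` | 0.87 um/min | saturation cell speed |
| `epsilon` | 7 um²/min | phase-coupling strength |
| `k` | 2.07 | frequency-profile shape |
| `sigma` | 0.34 | anterior frequency fraction |
| `q` | 1.80 | velocity-profile shape |
| `t0` | −256 min | initial time (uniform phase) |
| `x0`, `x1` | 417, 202 um | PSM length sigmoid |
| `eta` | −5.09·10⁻³ 1/min | shortening rate constant (signed) |
| `tbar` | 192 min | sigmoid midpoint |

`eta` is stored signed; nothing in the package flips it. The peak
shortening speed is $|x_1\eta| = 1.03$ um/min, attained at $t=\bar t$.

## Observables

From a solved field the package derives the quantities used to compare
with embryo data: the wave count
$K = (\phi(0,t)-\phi(\bar{x},t))/2\pi$ (waves simultaneously spanning the
PSM), the segment count $N = \phi(\bar{x}(t),t)/2\pi$, the segment length
$S \simeq 2\pi/|\partial_x\phi(\bar{x},t)|$, and the decomposition of the
anterior frequency

$$\Omega_A = \frac{d}{dt}\phi(\bar x(t),t)
  = \Omega_P + \Omega_D + \Omega_W,$$

into the posterior frequency $\Omega_P=\partial_t\phi(0,t)$, a Doppler
term $\Omega_D = \dot{\bar x}\,\partial_x\psi(\bar x,t)$ (the anterior end
moves *into* the waves as the PSM shortens, so $\Omega_D>0$) and a
dynamic-wavelength term $\Omega_W = \partial_t\psi(\bar x,t)$ (the pattern
compresses over time, so $\Omega_W<0$), where
$\psi(x,t)=\phi(x,t)-\phi(0,t)$ is the pattern referenced to the tip. In
the zebrafish calibration the Doppler term dominates, so segments form
*faster* than the fastest oscillator in the tissue. The closed-form
classical-wave analogues (`doppler_observed_frequency()`,
`refractive_wave()` and friends) isolate each effect in a setting where
the answer is known exactly; they double as oracles for the decomposition
operators in the test suite.

## Numerical scheme and its choices

The solver uses the method of lines on a fixed uniform lab-frame grid
covering $[0, L]$, with the moving anterior end interior to the grid:

* **Advection** is first-order upwind (backward differences, valid since
  $v \ge 0$). The phase profile is kinked at the anterior frequency jump
  and upwinding is robust there; the price is a numerical diffusion
  $\sim v\,dx/2$, which at the default $dx = 1$ um is two orders below
  the physical coupling.
* **Coupling** is a centred second difference, applied on the whole
  domain including the arrested tissue (`coupling_beyond_psm = TRUE` by
  default; a switch is provided because continuing coupling across the
  arrest front is a modelling choice).
* **Boundaries**: a no-flux (Neumann) ghost node at the posterior tip —
  there are no oscillators beyond it — and a zero-second-derivative
  outflow closure at $x = L$ so waves leave without reflection.
* **Time stepping** is explicit Euler with the *joint*
  advection–diffusion stability bound
  $dt \le 0.9/(v_{\max}/dx + \varepsilon/dx^2)$. The two bounds are not
  independent: taking the minimum of the separate advective and diffusive
  limits can still amplify the Nyquist mode (at the defaults it gives
  $c + 2d \approx 1.01 > 1$), which is why the combined form is used.
  Auto stepping additionally resolves the oscillation period itself,
  which only matters for nearly transport-free configurations.
* **The frequency jump** at $\bar{x}(t)$ is applied exactly: each node is
  classified by $\xi = x/\bar{x}(t)$ every step, with $\xi \le 1$ counting
  as inside. No smoothing.
* **Initial condition** $\phi \equiv 0$ at `t0`. The transient is part of
  the model: `t0` was calibrated so that the observables align with
  experimental staging.
* Off-grid values (e.g. at $\bar{x}(t)$) are linear interpolations of the
  two flanking nodes; there is no randomness anywhere in the solver.

### Discrete estimators for the frequency decomposition

The decomposition identity $\Omega_A = \Omega_P + \Omega_D + \Omega_W$ is
a chain rule and should survive discretisation. Temporal derivatives
($\Omega_A$, $\Omega_P$, $\Omega_W$) are centred differences on the output
frames; $\dot{\bar x}$ is always the analytic sigmoid derivative, never a
finite difference of the stored trajectory, removing one noise source.
The spatial slope inside $\Omega_D$ deserves care: a slope fixed to the
grid cells interacts with the kink at the arrest front and breaks the
identity at $O(dx)$ whenever $\bar x$ crosses a cell. `segwave` instead
uses the time-centred average of the two chord slopes swept by the
anterior end across the half-stencils
$[\bar x(t_i), \bar x(t_{i\pm1})]$ — a genuine centred estimator of
$\partial_x\psi(\bar x, t)$ that is also consistent with the temporal
stencils, leaving an identity residual of order $dt^2$ (about $10^{-6}$
rad/min on the default zebrafish run, versus a tolerance of $10^{-3}$).
For a frozen PSM the swept interval degenerates and the estimator falls
back to a one-sided interior slope (the prefactor $\dot{\bar x}$ is zero
there anyway).

The segment-length gradient $\partial_x\phi(\bar x, t)$ is likewise a
one-sided difference over one grid spacing taken from the PSM interior
with interpolated endpoints, so the estimate varies smoothly as the
anterior end sweeps through cells; the alternative `method = "exact"`
solves $|\phi(\bar x)-\phi(\bar x + S)| = 2\pi$ by bracketing and is used
as a cross-check.

### Segment numbering and the staging convention

With the uniform zero initial phase, $N(t)$ counts anterior cycles since
`t0`; the posterior tip bounds this count by $\omega_0 (t-t_0)/2\pi$, so
at $t=0$ at most ~6 raw cycles can have accumulated. Experimental staging
instead numbers segments so that the 7th forms at $t = 0$;
`staging_offset()` computes the integer shift that anchors the record
nearest $t=0$ to index 7, and reports it rather than hiding it. Analyses
of the shortening run use the 500-minute observation window starting at
$t = 0$ — the window over which the model is compared with embryo data —
so that events from the burn-in transient (whose early, artificially long
segments reflect the uniform initial condition, not the established wave
pattern) are not mixed into windowed summaries such as "which segment is
longest". Within that window the segment-length curve is non-monotonic
with its maximum at staged index 12.

## Time-periodic states and approximations

At frozen PSM length the field relaxes to $\phi = \Omega t + \psi(x)$.
`find_periodic_state()` obtains it by relaxation, declaring convergence
when the profile changes by less than $10^{-4}\cdot 2\pi$ (sup-norm) over
one period, and estimates $\Omega$ as the least-squares slope of the
posterior phase over the final three periods. The weak-coupling
approximations are available in closed form:
$\psi(x) \simeq \int_0^x (\omega - \omega_0)/v\,dx'$ (the integrand's
removable singularity at the tip is handled by open quadrature with the
analytic limit $\omega_0 U'(0)/(v_0 q)$), the phase velocity
$\tilde v = v/(1-\omega/\omega_0)$, and the clock-and-wavefront segment
length $S = v_0 T$.

Two quantitative caveats, both measured by the test suite rather than
assumed: at the calibrated coupling $\varepsilon = 7$ um²/min the
collective frequency is genuinely shifted below $\omega_0$ (to
$\Omega \approx 0.1480$ rad/min at $\bar x_0 = 417$ um, grid-converged),
and because the weak-coupling integrand divides by $v(x) \to 0$ at the
tip, that small shift accumulates to a sup-deviation of $\approx 1.4$ rad
($0.22 \cdot 2\pi$) between the relaxed profile and the quadrature — the
approximation is qualitatively right (the deviation shrinks to 0.63 and
0.21 rad at $\varepsilon = 0.7$ and $0.07$) but not 15%-of-a-cycle tight
at full coupling. Similarly, the anterior boundary layer of width
$\sim\sqrt{\varepsilon/2v'(0)} \approx 30$ um steepens the local phase
gradient, so the measured periodic segment length ($\approx 33$ um) sits
~12% below $v_0 T \approx 36.9$ um; the clock-and-wavefront law holds
approximately, as expected for a graded velocity profile.

## Fitting

Three estimation routes mirror the three data kinds the calibration rests
on, each exercised end-to-end against the package's own seeded
generators:

* `fit_length_dynamics()`: nonlinear least squares of the length sigmoid
  (via `minpack.lm`), with the sign convention $x_1 \ge 0$ so a
  shortening series returns $\eta < 0$.
* `fit_boundary_velocities()`: per-boundary mean velocity (least-squares
  slope) and mean position, then least squares of
  $v_0(1 - e^{-a x})$ with the inverse length $a = q/\bar{x}$ as a single
  parameter — boundary tracking mixes epochs with different PSM lengths,
  so only the combination is identified. (Printed values of $q/\bar x$
  are in 1/um; a far-field-only design leaves $a$ weakly constrained and
  is flagged.)
* `fit_phase_profile()`: forward-simulates the model and minimises a
  circular loss $\sum(1-\cos(\psi_{\rm model}-\psi_{\rm data}-\hat c))$
  over the PSM mask, with $\hat c$ the maximum-likelihood global offset.
  The circular form is insensitive to $2\pi$ wrapping, and the free
  offset makes the objective exactly invariant to a constant added to
  the data. $\omega_0$, $v_0$ and $\varepsilon$ stay fixed (they come
  from direct measurement, not the wave pattern); optimisation is
  derivative-free Nelder–Mead from a coarse multi-start grid over
  $(k, \sigma, q)$, guarding against the $\sigma$–$k$ trade-off, with
  $t_0$ parameterised as $t_{\min} - e^{\theta}$ so the simulation always
  starts before the data.

One identifiability lesson from the recovery studies is worth recording:
$t_0$ is informed by how developed the transient still is during the
observation window. A kymograph that starts long after `t0` (when the
pattern has reached its quasi-steady shape) leaves $t_0$ on a flat valley
of the objective; the bundled generator therefore defaults to windows
that overlap the late transient, and real-data users should expect wide
$t_0$ uncertainty otherwise.

## What the synthetic data do and do not emulate

The generators (`make_length_series()`, `make_boundary_tracks()`,
`make_phase_kymograph()`) reproduce the *structure* of the study's three
data kinds — staged length measurements, tracked boundary positions,
phase-valued kymographs — with additive Gaussian noise of stated sd and a
mandatory seed whenever noise is nonzero. They do not emulate
embryo-to-embryo parameter variability, intensity-to-phase extraction
artefacts, curvature of the body axis, or late-stage deviations from the
length-rescaling ansatz (real wave patterns deviate from it after ~18
segments). Passing recovery tests therefore demonstrates that the
estimators invert the model faithfully under its own assumptions — an
inverse-crime baseline — not that those assumptions hold in any given
dataset.

## Problem sizes used in the checks

The bundled checks run the shortening simulation at $dx = 1$ um on a
900-um domain from $t_0 = -256$ to 520 min (about 6,600 explicit steps),
periodic-state relaxations at $dx = 2$ um, the characteristics oracle at
$dx = 0.05$ um on a short constant-length instance, and fit-recovery
studies on $dx = 8$ um kymographs (20 noisy replicates at 0.3 rad, plus
a noise ladder at 0.5/0.3/0.1/0 rad with 5 replicates each). These sizes
were chosen so the full suite exercises every claim at desk scale; all
resolutions are arguments, not constants.

## Known limitations

One spatial dimension; no phase noise or delay coupling; only the
built-in profile shapes (alternatives would slot in behind
`frequency_profile()` / `velocity_profile()`); the Hopf-bifurcation
interpretation of the anterior frequency jump is outside scope; segment
lengths from the burn-in transient are artefacts of the uniform initial
condition and are excluded from windowed summaries, as described above.

## A minimal session

```{r example, eval = FALSE}
mp <- zebrafish_parameters()
sc <- simulation_config(t_end = 520, dx = 1, L = 900, output_stride = 2L)
pf <- simulate_phase_field(mp, sc)
plot(pf)                                  # kymograph of sin(phi)

recs <- extract_segments(pf)
recs$index <- recs$index + staging_offset(recs)
head(recs)

dec <- decompose_anterior_frequency(pf)
colMeans(dec[dec$t >= 0 & dec$t <= 450, -1])
```
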