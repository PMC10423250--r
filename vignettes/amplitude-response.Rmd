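---
title: "Methods: amplitude response of coupled circadian oscillators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amplitude response of coupled circadian oscillators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(clockamp)
```

This vignette is the package's account of the science it implements: the
model and its assumptions, the parameters and how their defaults were
fixed, the design decisions that were genuinely open, the numerical
choices, and the known limitations. Everything quantitative stated here is
computed by the test suite or by `scripts/acceptance.R`.

## The model and its assumptions

A single cellular clock is the planar normal-form (Poincaré) oscillator

$$\dot\theta = \omega, \qquad \dot r = \varepsilon\, r\,(a^2 - r^2),$$

the minimal dynamical system with a circular attracting limit cycle. Its
three properties — a cycle of radius $a$, constant angular speed $\omega$
independent of $r$, and radial relaxation at a rate set by $\varepsilon$ —
are the whole model; there is no molecular detail. The Cartesian
coordinates are interpreted as mRNA ($x$) and protein ($y$) concentrations
of a core clock gene, so the model assumes (i) a near-circular orbit in the
$(x,y)$ plane, which is what makes the geometric reasoning exact, and
(ii) a rigid quarter-cycle (6 h) lag of protein behind mRNA. Rotation is
counterclockwise:

$$\dot x = -\omega y + \varepsilon x (a^2 - x^2 - y^2) + L_{LIT}, \qquad
  \dot y = +\omega x + \varepsilon y (a^2 - x^2 - y^2) - L_{LID}.$$

Only this orientation is consistent with the circadian-time convention used
throughout (mRNA peak at CT6, trough at CT18, protein peak at CT12) and
with a protein that lags rather than leads its transcript.

Light enters as a rectangular pulse: transcriptional activation (LIT) is an
additive push $L_{LIT} = 3$ nM/h on $\dot x$; degradation (LID) subtracts
$L_{LID} = 3$ nM/h from $\dot y$; a combined pulse applies both, which is
geometrically a single push of magnitude $\sqrt2 L$ directed 45° below the
mRNA axis. "Strength" always means pulse duration in hours at this fixed
magnitude. The origin is the unstable fixed point enclosed by the cycle —
the singularity point. A pulse whose accumulated (rotating-frame)
displacement carries the state onto that point erases the phase and the
amplitude at once; the amplitude response at every other phase and strength
is governed by where the pulse leaves the state relative to that point.

## Parameters and calibration

| parameter | default | units | origin |
|---|---|---|---|
| $\omega$ | $2\pi/24$ | rad/h | 24 h intrinsic period |
| $\varepsilon$ | $10^{-4}$ | 1/(h·nM²) | slow radial relaxation (recovery over one or more cycles) |
| $a$ | ≈ 8.65 | nM | calibrated, see below |
| $L_{LIT}, L_{LID}$ | 3 | nM/h | stimulus magnitude defining "strength = duration" |
| $k_c$ | 3 | nM/h | mean-field coupling magnitude |
| $K_f$ | 20 | nM | coupling half-saturation |

The radius $a$ is the one parameter with no independent handle, and it is
pinned by the singularity experiment: a 3 h LIT pulse beginning at CT17
must drive an on-cycle oscillator to the immediate vicinity of the origin.
`calibrate_radius()` minimizes the post-pulse radius over $a$ using the
full ODE. In the $\varepsilon \to 0$ limit the answer is closed-form: the
pulse accumulates a rotating-frame displacement of magnitude
$(2L/\omega)\sin(\omega T/2) \approx 8.77$ nM, and projecting onto the CT17
onset direction (7.5° past the exact annihilation phase, which is CT16.5
for a 3 h pulse) gives $a \approx 8.70$ nM. The full integration at
$\varepsilon = 10^{-4}$ yields 8.647 nM; the test suite checks the two
agree within 5% and that the optimal onset is within an hour of CT17.

```{r}
calibrate_radius()                      # ~8.647
critical_onset_ct(nominal_oscillator()) # ~CT16.5
```

## The coupled population and the form of the coupling

A tissue is $N$ oscillators with heterogeneous $(\omega_i, a_i)$ coupled
through the mean mRNA level $F = \tfrac1N\sum_i x_i$ via a saturating term
on $\dot x_i$. The design question is whether the coupling should be a
*common forcing*, $k_c F/(F+K_f)$ applied identically to every cell, or a
*diffusive* pull toward the mean, $k_c (F - x_i)/(F + K_f)$. The package
uses the diffusive form, for a dynamical reason that is easy to verify
numerically with these constants.

A common forcing that increases with $F$ is positively correlated with
$\cos\theta$ around the cycle, so it does net outward work on the radius:
its linearized gain on the collective mode, about $k_c/(2K_f) =
0.075$ h⁻¹, exceeds the radial relaxation rate $2\varepsilon a^2 \approx
0.015$ h⁻¹ by a factor of five. A synchronized population therefore
inflates its orbit until the mean field reaches $-K_f$, where the coupling
term diverges and the integration fails — there is no stable synchronized
state at these constants. The diffusive form removes the self-forcing
exactly: a homogeneous synchronized population feels zero coupling, stays
on the single-cell limit cycle, and the term acts only on deviations,
which is what an intercellular synchronizer is for. This also makes the
population's critical stimulus coincide with the single-cell calibration,
so the singularity localizes at the same (CT17, 3 h) cell at both scales.
The integrator guards the denominator and aborts with a diagnostic if
$|F + K_f| < 0.5$ nM (reachable if `a_mean` is pushed toward `K_f`).

The trade-off, measured by the acceptance suite, is that the diffusive pull
re-synchronizes scattered cells within a few hours, so the synchronization
ratio `R_IS` recovers to ≈ 1 over any 24 h window even after a critical
pulse: in this implementation, singularity behavior expresses itself almost
entirely through the per-cell amplitude collapse (`R_IA`, and hence
`R_AA`), not through persistent desynchronization. Attributing a large
share of the collapse to desynchronization instead would require a
coupling weak enough not to re-synchronize within a day — which, per the
argument above, is not stable in this model family at these constants.

## Synthetic populations

`sample_population()` draws $\omega_i \sim N(\bar\omega,
cv_\omega\bar\omega)$ and $a_i \sim N(\bar a, cv_a \bar a)$ independently,
truncated at $10^{-6}$ of the mean. Defaults are $cv_\omega = 0.02$
(period SD ≈ 0.5 h, the scale of period dispersion in clock cell lines)
and $cv_a = 0.05$ (visible amplitude variability without destabilizing the
locked state). The generator emulates static cell-to-cell parameter
heterogeneity only: there is no intrinsic molecular noise, no
amplitude-phase coupling beyond the normal form, and no correlation
between $\omega_i$ and $a_i$. Tests that pass under this generator
therefore certify the analysis pipeline and the deterministic dynamics,
not the stochastic phenomenology of real reporters.

Burn-in starts each cell on its own cycle at a phase drawn uniformly from
a half-circle arc (width configurable via `init_arc`) and integrates the
unstimulated coupled system for 10 intrinsic periods. A full-circle cold
start is supported but converges far more slowly: a fully incoherent
population has $F \approx 0$, the diffusive term then damps every cell
toward the origin, and coherence regrows only at the slow rate
$\varepsilon a^2$. From the half-circle arc the order parameter reaches its
locked value (≈ 0.997 at default heterogeneity) well within the burn-in;
`prepare_population()` warns if the order parameter still drifts more than
$10^{-3}$ per cycle.

## Stimulus timing, windows, and indices

Circadian time during a simulation is defined by the rhythm itself: CT6 is
the mean-field mRNA peak, and one circadian hour is 1/24 of the locked
period. Pulses are scheduled against this anchor (accuracy ≤ 0.05 h, the
output grid step), so heterogeneous populations are stimulated at the
intended phase regardless of the burn-in's absolute phase.

All indices are after/before ratios over fixed 24 h windows:
$[t_{on}-24, t_{on}]$ and $[t_{off}, t_{off}+24]$, excluding the pulse
itself. Amplitude is read directly as max − min of the observable in the
window (no curve fitting or detrending — exact for this model). The
observable is mRNA by default and protein for LID protocols, matching the
channel the stimulus acts on. `R_IS` uses the window-averaged Kuramoto
order parameter of the per-cell geometric phases $\mathrm{atan2}(y, x)$;
averaging over the window rather than sampling a single time point
suppresses sampling noise and is exact in the synchronized limit. Phase
shifts are measured against an unstimulated twin sharing the burn-in,
comparing mean-field peak times on the second cycle after offset, mapped
to (−12, 12] h with advances positive.

## Scan experiments and classification

`run_ars()` scans onset CT × duration, averaging `R_AA`, `R_IA`, `R_IS`
over replicate populations (5 seeds by default; the burn-in is shared
across all cells of a replicate). `find_singularity()` returns the argmin
cell of `R_AA`, breaking exact ties toward the smaller duration, then the
smaller CT. `classify_response()` labels a column monotonic_increasing if
it is nondecreasing within δ = 0.03 and never falls below 1 − δ, and
nonmonotonic if it dips below 1 − δ before rising; δ was set to the
replicate-to-replicate spread of `R_AA` at $N = 100$. The acceptance suite
runs the full-circle classification scans with two replicates — replicate
noise at $N = 100$ is an order of magnitude below δ — and the localization
scans with five; these problem sizes are the package's test conditions,
stated here so the tests are interpretable.

## Numerical choices

* Integrator: `deSolve::lsoda`, rtol $10^{-8}$, atol $10^{-10}$; the
  system is smooth and non-stiff, and tight tolerances make the
  deterministic quantities stable to far below every test tolerance.
* Rectangular pulses are handled by integrating pre/pulse/post epochs
  separately, so the discontinuity never falls inside a solver step.
* Dense output on a 0.1 h grid; window amplitudes and order parameters are
  computed on this grid, and mean-field peak times are refined by local
  parabolic interpolation.
* Degenerate inputs fail loudly: non-finite states, onset windows not
  covered by the trace, pre-stimulus amplitudes below $10^{-8}$ nM
  (division hazard), pre-stimulus order parameter below 0.05, and the
  coupling-denominator guard above.
* `epsilon = 0` is accepted (neutrally stable radius) for diagnostic use;
  the radius is then conserved exactly, which the tests exploit.

## Known limitations

* The amplitude response to very long pulses saturates and then declines
  slightly (the overshoot decays within the fixed 24 h after-window while
  remaining above 1), so at onsets far from the critical phase the
  strict classifier returns `"other"` rather than
  `"monotonic_increasing"` for some columns; the acceptance suite reports
  exactly which cells. A classifier tolerant of post-saturation decline
  would label these monotonic, but the strict rule is kept because it is
  the one the classification tolerance δ was defined for.
* Because the quarter-cycle mRNA→protein lag is rigid, the critical LID
  protocol is the exact −90° rotation of the critical LIT protocol: a ~3 h
  pulse with onset near CT10.5 (pulse centered on the protein peak CT12).
  Scans on a 1 h grid localize it at (CT11, 3 h) or (CT10, 3 h).
* `R_IS` stays near 1 throughout (see the coupling section); analyses that
  need persistent desynchronization require a different coupling family.
* The single-cell ARC for a 3 h LIT pulse has its maximum near CT4–5,
  where the push is aligned with the outward radial direction mid-pulse —
  a geometric consequence of the model, distinct from where the gain
  happens to be sampled in classic two-phase comparisons (CT9 vs CT17).
* Only circular limit cycles and rectangular pulses are supported;
  relaxation-oscillator geometry, photic transduction dynamics, and
  stochastic (SDE) variants are out of scope.
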