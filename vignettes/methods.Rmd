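---
title: "Models, algorithms and design choices in mapeval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, algorithms and design choices in mapeval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mapeval` scores cardiac mapping systems against simulations in which the
transmembrane potential is known everywhere. This vignette explains the
models behind each stage, the parameters that matter, the numerical
decisions we made where the design was genuinely open, and what the
package's desk-scale fixtures do and do not establish about clinical data.

## The tissue model

Electrical activation is governed by the monodomain equation,

$$\chi C_m \frac{\partial V_m}{\partial t} + I_{ion} + I_{stim}
  = \nabla\!\cdot(\sigma \nabla V_m),$$

with surface-to-volume ratio $\chi = 1400\ \mathrm{cm^{-1}}$, membrane
capacitance $C_m = 1.0\ \mathrm{\mu F\,cm^{-2}}$ and isotropic conductivity
$\sigma$. $I_{ion}$ comes from a pluggable cell-model registry:

* **`"nygren"`** — the Nygren et al. (1998) adult human atrial cell model
  (28 state variables besides $V_m$: I~Na~, I~CaL~, I~t~, I~sus~, I~K1~,
  I~Kr~, I~Ks~, pumps and exchangers, intracellular and cleft ion
  concentrations, calcium buffering and sarcoplasmic-reticulum handling),
  implemented in C++ from the published equations. This is the reference
  model for all atrial calibration claims.
* **`"alievpanfilov"`** — the two-variable Aliev–Panfilov excitable model,
  mapped to millivolts via $V_m = 100u - 80$ with a time scale of 12.9 ms
  per dimensionless unit. It exists because sustained reentry at realistic
  atrial wavelengths (CV $\times$ APD $\approx$ 16 cm) does not fit on a
  desk-scale sheet; with its recovery parameter `eps0 = 0.01` the
  activation wavelength shrinks to about 2 cm so that a figure-of-eight
  pair fits on a 4 cm sheet. It is an engineering addition, clearly
  flagged, and is never used for the conduction-velocity calibration.

### The conductivity unit

The atrial literature quotes the target conduction velocity as 55 cm/s,
and the calibrated isotropic conductivity for that target appears in print
as the numeral 0.466. With $\chi = 1400\ \mathrm{cm^{-1}}$ and
$C_m = 1\ \mathrm{\mu F\,cm^{-2}}$, a conductivity of 0.466 **mS/cm**
yields a diffusivity $\sigma/(\chi C_m) = 3.3\times10^{-4}\ \mathrm{cm^2/ms}$
and a Nygren plane-wave velocity of only ~15 cm/s — inconsistent with the
stated calibration. Reading the figure as 0.466 **S/m** (= 4.66 mS/cm)
reproduces ~55 cm/s. `tissue_params()` therefore defaults to
`sigma = 4.66` mS/cm. Only the single unit prefix is normalized; every
other quantity in the package is in the cm/ms/mV/mS system.

### Numerics

* Linear triangular finite elements on surfaces embedded in 3-D; stiffness
  from the in-plane shape-function gradients, capacitive term mass-lumped
  so each implicit step solves one symmetric positive-definite sparse
  system whose Cholesky factorization is computed once and reused.
* Operator splitting per step: the ionic model advances at `dt` (gates by
  Rush–Larsen, concentrations by forward Euler — except intracellular
  calcium, whose buffering terms have Jacobian entries of order
  $4\times10^4\ \mathrm{s^{-1}}$ and are advanced by the exponential
  (linearized) rule), then diffusion advances implicitly (backward Euler).
* No-flux boundaries everywhere (tissue in air).
* `dt = 0.1` ms and 1 kHz saving by default. The splitting is first order:
  at `dt = 0.1` ms and 250 µm spacing the Nygren plane wave runs at
  57 cm/s, and refining `dt` raises it toward ~69 cm/s (about 7% per
  halving at the production step, under 1% per halving below 0.0125 ms,
  where the refinement test operates). The 55 cm/s calibration is defined
  at the production configuration — coarse-step velocity is part of the
  calibration, exactly as in the large-scale simulations the framework
  emulates — so we deliberately did not switch to a higher-order splitting.
* Stimuli add a fixed rate to $dV_m/dt$ over a geometrically selected node
  set; the default 40 mV/ms for 2 ms is strongly suprathreshold for both
  registered models. We chose a fixed deterministic default over
  per-fixture threshold bisection: it removes a calibration loop whose
  result never affects any measured quantity downstream of capture.

## Virtual electrograms

The unipolar extracellular potential at electrode position $x'$ is

$$\phi_e(x') = \int -\sigma_e\, \nabla V_m \cdot \nabla\frac1r\, dV,$$

with $\sigma_e = 7$ mS/cm and $r$ the source-to-electrode distance. The
electrode is a point; there is no bath, no bipolar subtraction, and no
finite-contact averaging. With linear elements $\nabla V_m$ is constant per
element, so the integral is assembled once into a transfer matrix
(electrodes × nodes) and every saved frame costs one matrix–vector
product. Gaussian quadrature is per element: order 1 (centroid), 2
(3-point, default) or 6 (12-point Dunavant rule, used as the refined
oracle in tests; order 2 agrees with it to better than 1% for electrodes
at least 0.05 cm off the tissue). Thin-surface fixtures carry a nominal
wall thickness (0.03 cm, a config field) so the volume element is defined.
An electrode coinciding with a quadrature point is an error naming the
electrode. The formula is applied literally (no $1/4\pi$); this scales all
electrograms by a constant and affects neither activation times nor
patterns.

**Noise.** Declared noise levels are in mV/ms while the signal is in mV.
We add i.i.d. uniform samples on $[-\eta\,\Delta t, +\eta\,\Delta t]$ mV,
with $\eta$ the declared level and $\Delta t$ the 1 ms sampling interval —
numerically level-equal at 1 kHz. Whether the distribution support should
instead be a half-width, or colored across samples, is underdetermined;
this is one consistent reading, recorded here and in `add_noise()`'s
documentation. Noise is deterministic given the recorded seed.

## Activation times, phase and reentry sources

The activation detector takes the forward finite difference on the sample
grid, keeps samples whose derivative exceeds `alpha` with the required
polarity, takes the extremal-derivative sample per suprathreshold episode
(earliest on ties), and greedily discards candidates within `beta` ms of
an accepted activation. Defaults: `alpha` 0.2 mV/ms (positive) for Vm, 1.0
and 0.5 mV/ms (negative) for good- and poor-contact electrograms,
`beta` 100 ms. No interpolation: AcT resolution is the sampling interval.
On paced-sheet fixtures the detected AcT lists are identical across
`alpha` in 0.1–0.3 mV/ms and `beta` in 100–150 ms, mirroring the
sensitivity rationale for those defaults.

Phase is the delay embedding
$\theta(t) = \mathrm{atan2}(V_m(t+2)+30,\ V_m(t-2)+30)$ (offset 30 mV,
delay 2 ms); boundary samples and frames where both arguments are below a
degeneracy floor are NA. Surface phase singularities are nodes whose
ordered one-ring accumulates a wrapped phase difference of $\pm 2\pi$
(threshold $|{\cdot}| > \pi$, the robust midpoint between 0 and $2\pi$);
rings are oriented counterclockwise about the outward normal using the
mesh's consistent triangle orientation. Because a singular point inside a
triangle is enclosed by the one-rings of all three vertices,
edge-connected equal-charge detections are merged into one singularity
reported at the member node nearest the component centroid (lowest index
on ties). Volumetric filament tracing is out of scope: only the
endocardial-surface endpoints are consumed by the analysis.

Reentry sources: PS occurrences over the analysis window (default 1–2 s)
are clustered with `stats::kmeans` (k = 2, `nstart = 10`, seeded — an
established multi-restart implementation used in place of a hand-rolled
k-means++; deterministic given the seed). Cluster centers of mass are the
R+/R− locations; chirality is the majority topological charge. The sign
convention — positive charge about the outward normal = R+ — is fixed
internally and is verified in the tests to agree with the rotation sense
that the AcT-progression classifier reports over the same rotor core.

## Pattern classification

At every electrode with a full ring of 8 grid neighbors (borders are never
centers; basket arrays wrap azimuthally across splines, so only near-pole
rows lack rings), each central AcT is classified with two parameters
(`delta` = 2 ms, `gamma` = 100 ms):

* **F** — for every neighbor, the difference between the neighbor's
  nearest AcT at or after `center − delta` and the central AcT lies in
  $[-\delta, \gamma+\delta]$. Nearest-following is our reading of which of
  several neighbor AcTs participates: it is the one belonging to the same
  wavefront under the $\gamma$ bound.
* **R+ / R−** — a chained progression of AcTs along the clockwise
  (counterclockwise) ring path whose consecutive differences all lie in
  $[-\delta, \gamma+\delta]$, whose loop closes through the starting
  neighbor's next activation (continuation of activation between beats),
  and whose net progression is strictly positive. The chain search is
  exhaustive over candidate AcTs and over the 8 starting rotations; this
  makes detections monotone in `delta` (a property test) where a greedy
  chain would not be.
* R verdicts take precedence over F: a slowly rotating ring also satisfies
  the F bound, and calling it focal would discard the stronger evidence.

## Performance metrics

AcT comparison matches each electrode's list one-to-one against the Vm AcT
list of its nearest endocardial node within `Tol`. Matching processes
truth times in increasing order, each taking the earliest unused measured
time in its window — the earliest-deadline rule, which is
maximum-cardinality for equal-width windows and is checked against an
exhaustive oracle in the tests. `fC` and `fS` are correct and spurious
counts over the number of truth AcTs (`fS` capped at 1), RMS is over
matched pairs, RMS-SD is the standard deviation of per-electrode RMS, and
`AcTPM = fC (1−fS) · 100`. AcTPM is monotone non-decreasing in `Tol` and
the spurious percentage non-increasing (property-tested).

Pattern comparison matches detections to ground-truth events of the same
type within 100 ms and 1 cm; the spatially nearest eligible detection is
credited, additional same-type detections inside a matched event's windows
are duplicates (neither correct nor spurious — a guard against
multi-electrode double counting that the rules otherwise leave open), an
unmatched event paired with a different-type detection is a
misclassification of that event's type, and everything else is spurious.
`AcPPM = fC (1−fS)(1−fM) · 100`; E~T~ (reported for paced/focal types,
which have stimulation times — reentrant beats have only beat windows) and
E~X~ (≤ 1 cm by construction) summarize localization of correct
detections. For reentrant beats the reference times are the Vm AcTs of the
node nearest the source location within the analysis window.

## The blinded workflow

A library entry persists the mesh (VTK), the Vm movie, per-node AcTs, and
the event list (type, beat, location, reference time); paced/focal events
come from the stimulus protocol, reentrant ones from the PS-density
clustering. The administrator-side session enforces the blinding order —
electrode locations and per-electrode noise declarations must be
registered before electrograms are issued — and derives the noise seed
from a recorded master seed, so identical configurations and seeds
reproduce identical exports and reports (tested byte-for-byte). Exports to
the user contain only surface-point coordinates and time/signal columns;
reports are JSON validated against `inst/schema/report-schema.json`. The
Vm store uses RDS (a runtime artifact); the text dialects
(`label,x,y,z`, `time_ms,<label>...`, `site_id,act_ms`,
`type,beat,site_id,time_ms`) are the exchange formats. Roving (
time-varying) catheters and physical signal replay are out of scope.

## What the fixtures emulate — and what they do not

The sheet and spherical-shell geometries stand in for an atrial wall patch
and a closed chamber. Problem sizes were chosen for interactive use: the
calibration strip is 101 × 3 nodes at 250 µm; the paced sheet 81 × 81 at
250 µm (120 ms); the reentry sheet 81 × 81 at 500 µm for 1.5–2 s with the
fast model. Passing tests establish the internal consistency of the whole
chain (solver → electrograms → detection → classification → metrics) and
the published metric arithmetic, at those scales. They do **not**
establish clinical fidelity: no anatomical atrium, no wall-thickness
variation, no fibrosis or anisotropy, no electrogram-morphology validation
against recorded signals, and the fast reentry model trades ionic realism
for a desk-scale wavelength. Basket chirality on closed shells inherits
the grid convention; its visual sense depends on which side of the surface
the viewer occupies, which is fixed only up to the mesh orientation.

## Known limitations

* The Nygren implementation follows the published equations with
  Rush–Larsen gating; it is validated functionally (resting stability,
  upstroke velocity ~150 V/s, APD~90~ ≈ 220 ms, CV calibration), not
  line-by-line against a reference trace.
* First-order splitting ties the effective CV to `dt` (see above).
* The electrogram model omits the $1/4\pi$ normalization and any bath
  loading; absolute amplitudes are therefore only proportionally
  meaningful.
* `compare_act`'s earliest-deadline matching maximizes the number of
  matches, not the RMS of their differences; with dense spurious trains
  the reported RMS can be slightly pessimistic.
* Reentrant "beats" are defined through the AcT list of one reference
  node near the source; a strongly meandering rotor can blur that
  definition.
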