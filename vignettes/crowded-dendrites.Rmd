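---
title: "Crowded dendrites: effective diffusion and calcium microdomains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crowded dendrites: effective diffusion and calcium microdomains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrocrowd)
```

This vignette is the package's account of its science: the models, the
assumptions behind them, the parameters that matter, the numerical
choices, and what the shipped tests do and do not demonstrate.

## 1. The crowding model

### Setting

A small molecule diffusing in a dendrite moves in a Smoluchowski
(overdamped) regime between impenetrable obstacles; every obstacle and
the membrane reflect it. We do not model individual obstacles. Instead
the dendrite, a cylinder of radius $a$, is divided into periodic
compartments of length $L$ whose boundaries are reflecting
cross-sections pierced by one narrow opening of radius $\varepsilon$.
The compartment must be large enough that obstacle statistics are the
same in every compartment; the opening collects all the residual free
volume of a cross-section into one effective hole. No external
potential acts on the particle (nothing in the applications requires
one, so none is exposed in the interface).

### Narrow escape and the effective diffusion constant

The mean first passage time of a Brownian particle (diffusion constant
$D$) out of a compartment of volume $V = SL$, $S = \pi a^2$, through a
single absorbing disk of radius $\varepsilon$ is, to first order in the
hole size,
$$\tau = \frac{V}{4 \varepsilon D}.$$
`mfpt_escape_3d()` implements this; brute-force ray-tracing walkers
reproduce it to ~2–3 % at the default calibrated geometry (the check
runs in the test suite and in `scripts/acceptance.R`).

Transport across many compartments is a hopping process. Two points
deserve care, and both were validated against the package's own 3D
simulator rather than taken on faith:

* **The inter-compartment conductance is two-sided.** The one-sided
  absorbing escape rate is $4\varepsilon D/V$, but the *net* flux
  between two neighboring compartments passes the aperture's access
  resistance twice (once on each side), so the aperture conductance is
  $g = 2\varepsilon D$.
* **The compartment's own bulk resistance acts in series.** Carrying
  mass along one period costs $L/(SD)$ in addition to $1/g$.

Per period the effective diffusion constant is therefore
$$D_\mathrm{eff} \;=\; \frac{L^2}{V}\left(\frac{1}{g} + \frac{L}{SD}\right)^{-1}
 \;=\; D\,\frac{2\varepsilon L}{S + 2\varepsilon L} \;=\; \kappa D ,$$
with $\kappa$ the *compartment parameter*. To leading order in the hole
size $\kappa \approx 2\varepsilon L/S$; the bulk term contributes a
relative $2\varepsilon L/S$, i.e. exactly $\kappa$ (~5 % at the 1/20
calibration), and including it is what makes the calibrated scenes
reproduce the intended slowdown in 3D simulation. $\kappa$ depends on
the geometry only through the product $\varepsilon L$ and is invariant
under $(\varepsilon, L) \to (\varepsilon/c,\, cL)$.

A residual discrepancy remains and is worth stating plainly: the
particle-variance (MSD) growth rate measured in calibrated scenes sits
a further ~5 % above $\kappa D$. This is the finite-aperture
correction to the access resistance, of order $\varepsilon/a$, which
lies beyond the first-order narrow-escape theory the package
implements; we document it rather than absorb it into an empirical
coefficient.

### Calibration

Measurements constrain only the ratio $D_\mathrm{eff}/D$ (1/20 for
fluorescein in dendrites vs aqueous solution). One degree of freedom
remains and is pinned by a convention on the aspect ratio
$\varepsilon/L$. The package default is $\varepsilon/L = 0.025$: the
calibration fixes $\varepsilon L$, so larger ratios mean larger holes,
and the first-order escape formula degrades as $\varepsilon/a$ grows
(measured brute-force error ~9 % at ratio 0.1, ~6 % at 0.05, ~3 % at
0.025). 0.025 is the largest round value keeping the formula within
its stated ~5 % validity. The resulting 1/20 geometry for a 1 μm
dendrite is $L = 0.909$ μm, $\varepsilon = 0.0227$ μm.

### Inhomogeneous openings, jitter, travel times

With position-dependent $\varepsilon(x)$ and $V(x)$ the reduced
description is $\partial_t c = \partial_x^2\!\left(b(x)\,c\right)$ with
$b(x) = 2DL\varepsilon(x)/(S(x) + 2L\varepsilon(x))$; the associated
stochastic equation has drift $a(x) = b'(x)$, which vanishes for
homogeneous openings and points toward larger openings otherwise.

Almost-periodic barriers — positions jittered by a centered random
displacement of standard deviation $\sigma$ — speed transport up.
Expanding the compartment lengths to $O(\sigma^2)$ gives
$$D_\sigma = D_\mathrm{eff}\left(1 + \sigma^2/L^2\right),$$
and the reduced description acquires a fourth-order term,
$$\partial_t u = D_\sigma\, \partial_x^2 u \;-\; D_\mathrm{eff}\sigma^2\, \partial_x^4 u .$$
The exact coefficient of the fourth-order term is fixed here by three
requirements it provably satisfies: the $\sigma \to 0$ limit recovers
the second-order equation; the zeroth moment is conserved (the term is
a perfect flux divergence); and the second-moment growth rate is
$2 D_\sigma$ (the $\partial_x^4$ term does not contribute to the
variance), which is the property the Monte-Carlo comparison tests. The
sign is dissipative (hyperdiffusion), so the equation is stable but
stiff; it is stepped implicitly.

Travel times along a dendrite use the standard first-passage formulas
for the reduced equation: with an absorbing soma at 0 and a sealed tip
at $L_d$, $\tau(x) = x(2L_d - x)/(2 D_\mathrm{eff})$ (250 s from the
tip of a 100 μm dendrite at 20 μm²/s); the outward problem is its
mirror image, and a general quadrature handles position-dependent
compartment volume. The 2D analogue of the escape formula
(`mfpt_escape_2d()`, for membrane receptor corrals) uses the
logarithmic narrow-escape law in the arc half-angle,
$\tau = (A/\pi D)\left(\ln(1/\pi f) + \ln 2 + 1/8\right)$, validated
against an independent walk-on-disk Monte-Carlo (2.75 ± 0.05 simulated
vs 2.67 predicted at $f = 0.05$).

## 2. The Brownian simulator

Scenes are built from analytic surfaces — the cylinder wall, planar
annular barriers with circular openings, end caps (reflecting,
absorbing, or reflecting with an absorbing axial hole), and optionally
a spine: a neck cylinder normal to the lateral wall with a tangent
spherical head. Analytic ray intersections replace any surface mesh:
the physics is identical and there are no faceting artifacts. With a
dozen analytic surfaces there is nothing for a spatial partition index
to accelerate, so none is used. Two geometric approximations are made
at the spine junction: the curved wall is treated as locally planar at
the attach point (error $\sim n^2/2a \approx 0.05$ μm for a 0.3 μm
neck), and the head sphere is centered so its cross-section at the
neck top equals the neck bore exactly.

Particles advance by an Euler scheme: each step draws an isotropic
Gaussian displacement with per-axis variance $2D\,\Delta t$ and traces
it through the scene, reflecting specularly (possibly several times in
one step) or stopping at absorbing elements. Flat reflecting planes
are exact under specular reflection; accuracy is limited near
absorbing elements and near opening edges, where a straight segment
can misclassify a Brownian excursion. The adaptive step therefore
resolves *features*: the step length is
$f \cdot \max(d_\mathrm{feature},\, \phi \cdot s_\mathrm{feature})$
with $f$ = `adaptive_min_fraction` (default 0.4, in the 0.3–0.5 band
appropriate for this scheme), $d$ the distance to the nearest
absorbing element or opening edge, $s$ that feature's own size and
$\phi$ = `min_scale_fraction` (default 0.1; accuracy-sensitive runs
use 0.05, which halves the residual step-size bias in apparent-D
estimates at roughly 2–4× the cost). Each particle carries its own
clock; a scheduler freezes particles at every sampling tick, where
concentrations in full-cross-section sampling volumes and axial
moments are recorded. Runs are bit-reproducible for a fixed seed
(single-threaded, R's RNG).

Two estimators extract an apparent 1D diffusion constant: the axial
variance slope (`"msd"`, with a particle-resampling bootstrap CI) and a
least-squares match of the recorded line scan to the reduced equation
with $D$ as the only free parameter (`"fit1d"`, the experimental
procedure; CI by particle bootstrap on simulated records). Their
systematic offsets differ at the percent level — profile-shape fits
weight the lattice-like near-field, variance slopes the far field — so
the suite checks their agreement within joint uncertainty rather than
coincidence.

The simulator is validated against the exact eigenfunction series for
a bare cylinder with absorbing ends (`validate_absorbing_cylinder()`):
survival and local-concentration curves agree with the series at the
1 % level with $10^4$ particles.

## 3. Calcium dynamics

Free calcium in a 1D dendritic segment evolves by
reaction–diffusion with linear particle densities (particles/μm;
1 μM ↔ 602.214·S particles/μm, about 470 for a 1 μm dendrite):

* **Buffers.** Sequential mass-action ladders
  $B_{j-1} + \mathrm{Ca} \rightleftharpoons B_j$: calmodulin with four
  steps (rate pairs 160/405, 160/405, 2.3/2.4, 2.3/2.4 in
  1/(μM·s) and 1/s) and calcineurin with one (50/25); totals 25 and
  10 μM at the default (medium) level, 10/5 (low) and 100/25 (high)
  as alternatives. Buffers are immobile by default; diffusion terms
  exist but default to zero. The unbound state is eliminated by
  conservation, so per-node buffer totals are conserved exactly.
* **Dye.** Fluo-4, 2 μM, rates 60/170, treated as one more buffer; on
  by default to mirror the imaging condition.
* **Pumps.** PMCA (Hill coefficient 1.0, 9200/μm²) and NCX (1.7,
  300/μm²) extrude with saturable Hill kinetics; surface densities
  convert to per-length sinks through the perimeter $2\pi a$.
* **Spines.** Passive perfect absorbers: the sink rate is the inverse
  narrow-escape time to the neck opening,
  $k = 4 r_\mathrm{neck} D / V_\mathrm{comp}$, applied over one
  compartment length around each spine (or as a density). Off by
  default in the shipped scenarios.
* **Synaptic input.** NMDA-receptor trains: each pulse is a
  dual exponential with rise 3 ms and decay 80 ms, normalized so its
  peak is the single-receptor current of 9 pA; pulses sum linearly.
  Current converts to ions via the calcium fraction over $2e$ and
  enters over a 0.05 μm footprint.

The method of lines on a 0.05 μm grid (reflecting ends) is integrated
with a stiff sparse solver (`deSolve::ode.1D`, lsodes). System-wide
pump, spine and injection rates are emitted along the trajectory so a
budget audit can close the books: free + buffer-bound + dye-bound +
cumulative pumped + cumulative spine-absorbed − cumulative injected is
constant to $10^{-4}$ relative in the shipped test (injection
integrated in closed form, removal by trapezoid on a 0.1 ms output
grid); with all sinks and sources off, conservation holds to
$10^{-6}$.

Spread is half of the full width at half maximum of the free-calcium
profile above baseline, by linear interpolation at half the
instantaneous peak; multimodal profiles are flagged and measured around
the global peak.

### Masked parameters and what depends on them

Several standard-table entries are not legible in the source material
and ship as literature-based fills, flagged in every scenario report:
PMCA and NCX per-pump turnover (27 and 4800 ions/s), their
half-saturations (0.45 and 1.8 μM), the NMDA calcium fraction (0.1),
the initial pulse amplitude (1 μM) and the aqueous/crowded calcium
diffusion constants (400/20 μm²/s).

The *microdomain* result is robust to all of these: across every fill
combination we examined, the maximal spread under 1 s NMDA trains at
20–100 Hz stays below ~1 μm, far inside the few-micron bound. The
*frequency-saturation* result is not: with the fills above, a 9 pA
train injects ~2.8×10⁶ ions/s at peak, the removal pathways saturate
near the source, and the half-maximum width of the (very large) free
calcium peak keeps growing roughly linearly with input frequency
instead of becoming stationary above 20 Hz. Stationarity appears only
when removal near the source is effectively linear in calcium — e.g.
pump turnovers one to two orders of magnitude weaker, or dominant
passive spine sinks — because a linear quasi-steady profile
$c \propto e^{-|x|/\lambda}$, $\lambda = \sqrt{D/k}$, has an
amplitude-independent width, and trains merge into sustained input
once the interpulse interval drops below the 80 ms decay time (i.e.
above ~12–20 Hz). The pump-rate exponents are exactly the masked
quantities, so the package reports what its parameters produce rather
than tuning them to the expected outcome.

## 4. Fixtures and the fitter

`generate_fixture()` forward-solves the reduced equation from a
Gaussian uncaging spot (width 1 μm), samples it on the line-scan grid
(0.7 ms period, 0.6 μm steps), and averages replicates with additive
Gaussian noise (default SD 0.03 on the normalized signal, 7
replicates); the true $D$ travels only in a sidecar.
`fit_diffusion_constant()` solves the same equation spectrally (one
cached eigendecomposition of the reflecting Laplacian, exact in time)
from the record's first frame, profiles out one global amplitude, and
optimizes $D$ alone; both time-origin conventions are evaluated. For
records from bounded scenes the true domain should be passed
(`L_domain`); the padded-domain default is for open-ended records.
Parameter recovery holds within 10 % across 20 seeds in each of the
three regimes of interest (20, 27, 400 μm²/s). The fitter's forward
model is always the 1D reduced equation — 3D-simulated records enter
only as data.

### What the synthetic fixtures do not capture

The generator emulates acquisition geometry and additive noise only.
Real line scans add photon shot noise with signal-dependent variance,
optical blur, bleaching, focus drift and out-of-focus background, and
real dendrites taper, branch and carry spines. Passing the recovery
suite therefore shows the analysis pipeline is consistent, not that
these experimental nuisances are harmless.

## 5. Problem sizes and defaults

Chosen once for the shipped tests and scripts: Brownian validation
runs use $10^4$ particles (50 ms–0.3 s simulated; the longer runs give
the strongly compartmentalized default geometry, whose per-compartment
residence time is ~40 ms, a clean long-time window); escape-time
comparisons use $10^4$ walkers; calcium scenarios use a 20 μm segment
at dx = 0.05 μm for 10 ms (pulses) or 1 s (synaptic trains). Halving
dx changes measured spreads by under 2 %.

## 6. Known limitations

* The homogenized theory is first order in the hole size; measured
  transport in calibrated scenes runs ~5 % above it (finite-aperture
  correction), and the escape-time formula is good to ~3 % at the
  default calibration, degrading for larger openings.
* The reduced description is valid only at times long against the
  compartment residence time and scales above $L$; fitting it to early
  or sub-compartment data underestimates $D$.
* The spine junction geometry is locally planar; very wide necks on
  thin dendrites would need the exact curved junction.
* Calcium is 1D: radial gradients under point-like influx are averaged
  away, which flattens the extreme near-source concentrations a 3D
  model would show.
* No calcium stores, CICR, voltage dynamics or Mg-block kinetics; the
  NMDA train sums linearly with no receptor saturation.
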