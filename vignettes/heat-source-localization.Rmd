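---
title: "Methods: steady-state bioheat modelling and heat-source inversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: steady-state bioheat modelling and heat-source inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoloc)
```

## The model and its assumptions

A metabolically active mass embedded in tissue acts as a heat source; some
of its heat is conducted to the skin and exchanged with the environment,
leaving a measurable warm spot. `thermoloc` models this with the
steady-state point-source solution of the bioheat equation. The modelling
assumptions are strong and deliberate:

1. **Steady state.** The transient term is dropped; the thermogram is
   assumed to be taken after the surface field has equilibrated.
2. **Homogeneous, isotropic tissue** of conductivity $k$. Layered skin,
   fat and gland structure is not represented.
3. **Equivalent point source.** Metabolic heat generation and blood
   perfusion in the vicinity of the mass are absorbed into a single
   effective source of power $Q$ (W). In an infinite medium its radial
   field is $T(r) = Q/(4\pi k r) + T_0$ (`point_source_field()`).
4. **Spherical-source equivalence.** A sphere of radius $R$ whose top lies
   at depth $d$ is represented by a point source at the *effective depth*
   $d_{\mathrm{eff}} = d + R$. This is exact in the model, and the package
   asserts bit-equality between the two parameterizations.
5. **Convective surface exchange.** An energy balance at the skin surface
   with heat-exchange coefficient $h_0$ gives the surface temperature at
   lateral offset $a$ from the point above the source:
   $$T(a) = T_e + \frac{Q}{4\pi h_0\left[(d+R)^2 + a^2\right]}.$$

Two conventions of this surface relation circulate, differing by a factor
of $\pi$ in the denominator ($4 h_0$ versus $4\pi h_0$). The package uses
$4\pi h_0$ throughout: it is the form consistent with the $4\pi$ of the
point-source solution and with the closed-form intensity inversion, and it
is the only one that reproduces the reference temperature values the
regression tests pin down (peak 28.2996 °C and span 1.6597 °C for the
standard 0.045 W / 1.05 cm / 5 mm study case at ambient 26.6 °C, and the
0.41 / 0.24 / 0.3 °C perturbation deltas). The discrepancy is noted here
once; all code uses a single convention.

Note a geometric consequence that is easy to misread: at fixed *top* depth
$d$, enlarging the radius moves the equivalent point source *deeper*
($d_{\mathrm{eff}} = d + R$ grows), so the peak temperature **falls** as
$R$ grows. Only at fixed *center* depth would the profile be independent
of $R$. Qualitative statements in parts of the literature that the peak
rises with radius are inconsistent with this parameterization, and the
package follows the model (its own perturbation numbers above do too).

### Units

All lengths are meters, powers watts, and $h_0$ W/(m²·K), i.e. SI.
Temperatures are stored and reported in °C; the tissue parameter table
keeps the arterial and environmental temperatures in kelvin, as such
tables are conventionally printed, with `kelvin_to_celsius()` /
`celsius_to_kelvin()` converting. Every model output depends on
temperature *differences* only, so the scale choice is observationally
neutral — a property the test suite asserts as ambient-shift equivariance.

### Tissue parameters

`tissue_params()` carries the standard constants for sound breast tissue:
conductivity $k = 0.52$ W/(m·K), surface exchange $h_0 = 8.77$ W/(m²·K),
blood specific heat 4186 J/(kg·K) and density 1000 kg/m³, metabolic heat
generation $q_m = 700$ W/m³ (tumor tissue: 25 000–90 000 W/m³), perfusion
rate $5.2\times10^{-4}$ s⁻¹, arterial temperature 310.15 K and ambient
300.15 K (27 °C). Only $h_0$, $q_m$ and the ambient temperature enter the
steady-state surface model; the remainder is retained because users of
bioheat models expect the full table, and because the perfusion and
capacitance terms matter for any future transient extension.

## Analytic inversion

From the peak temperature $T_{max}$, one local reading $T(a)$ at known
offset $a$, and the ambient $T_e$:

$$d_{\mathrm{eff}} = a\sqrt{\frac{T(a)-T_e}{T_{max}-T(a)}},\qquad
  Q = 4\pi h_0 a^2\frac{(T(a)-T_e)(T_{max}-T_e)}{T_{max}-T(a)}.$$

On noiseless forward data these are exact for **every** choice of $a$ (a
property tested over a thousand randomized sources), and the depth formula
provably returns $d_{\mathrm{eff}} = d + R$, never $d$. The package
therefore treats the effective depth as the primary estimand and reports
the decomposition $d = \max(d_{\mathrm{eff}} - R,\,0)$ explicitly, rather
than pretending depth and radius are separately identifiable from a
surface profile — they are not: the profile depends on $(Q, d+R)$ only.

Two radius routes are provided. The intensity route is
$R = (Q/(q_m A_t))^{1/3}$ with a volume constant $A_t$ defaulting to
$10^{-6}$; the intensity-free route,
$R^3 = (T(a)-T_e)(a^2+d^2)\,4\pi h_0/(q_m 10^{-6})$, is algebraically the
composition of the intensity route with the intensity inversion, and the
package asserts that identity to machine precision. **The units of these
relations do not cohere dimensionally** (the $10^{-6}$ "single-cell
volume" constant is a convention, not a volume in m³), so the result is
documented as a radius *score*: useful for ranking and for recovering the
intensity via $R^3 q_m 10^{-6}$, not physically calibrated. For this
reason the decomposition floors $d$ at zero when the score exceeds the
effective depth. Both $q_m$ and $A_t$ are configurable.

`localize_from_thermogram()` ties the steps together: the hotspot is
located (on grids, as the centroid of the maximal pixel set — a
deterministic, sub-pixel-stable tie-break), up to five observation pairs
are formed at their exact measured distances from the peak, and the
per-offset estimates are combined by the **median**, which is exact on
noiseless data (all offsets agree) and robust under noise. Flat inputs
raise a "no source detected" error; a peak on the image boundary sets a
warning flag, since the offsets then sample only one flank.

## The neural surrogate and parameter refinement

A single-hidden-layer feed-forward network (3 inputs, 10 sigmoidal hidden
units, linear output — the conventional "three-layer" architecture read as
one hidden layer of 10 neurons, since a three-layer network cannot have
ten layers) is trained on seeded uniform samples of $(Q, d, R)$ from a
configurable box, with the noiseless forward profile at fixed offsets as
the target. Defaults: $Q\in[0.01, 0.5]$ W, $d\in[0.005, 0.04]$ m,
$R\in[0, 0.01]$ m, 500 samples, 21 offsets spanning $\pm 5$ cm.

Numerical choices, each visible in `surrogate_config()`:

- **Input normalization**: per-feature min–max to $[0,1]$ over the
  training ranges, stored with the model.
- **Log-scale target**: the peak elevation spans roughly 0.04–180 °C over
  the default box; fitting on the linear scale spends all network capacity
  on the hottest corner. The network therefore represents
  $\log(T - T_e)$ and predictions are exponentiated back.
- **Case weights** proportional to (peak elevation)$^{1.5}$: pure
  log-scale fitting equalizes *relative* error, but the convergence
  criterion (held-out RMSE on the peak temperature, threshold 0.05 °C) is
  absolute. The intermediate exponent moves the loss toward absolute
  accuracy while keeping the absolute error mildly increasing with source
  intensity.
- **Multi-start**: backpropagation (via `nnet`, BFGS) is restarted from 3
  seeded initializations and the network with the lowest held-out peak
  RMSE is kept. A run that still misses the threshold is returned with
  `converged = FALSE`, never silently.
- **Serialization**: weights are written to JSON at 17 significant digits,
  which round-trips IEEE doubles exactly; a reloaded model predicts
  bit-identically without `nnet` present.

`refine_parameters()` polishes an initial $(Q, d, R)$ estimate against an
observed profile by minimizing the RMS surrogate-vs-observed elevation
mismatch with a derivative-free Nelder–Mead search, box-bounded to the
training ranges by projection plus penalty. Because the forward map is
flat along the $d$-vs-$R$ split at fixed $d+R$, an unregularized search
drifts along that direction chasing surrogate approximation error; the
objective therefore adds a proximal (Tikhonov-style) penalty —
`proximity` (default 2 °C) times the squared range-normalized displacement
from the initial point. At 10 % displacement this costs about 0.02 °C,
the order of the surrogate's own error, so the unidentifiable direction is
anchored while the data-determined directions, whose curvature is orders
of magnitude larger, move freely. The penalty vanishes at the initial
point, which guarantees the refined parameters never fit worse than the
initial ones. The reported *peak discrepancy* — closed-form model peak
minus surrogate peak at the solution — measures the surrogate's local
fidelity and grows with source intensity.

## Sensitivity analyses

`perturb_parameter()` evaluates the forward model at a base source and at
a copy with one parameter changed by a signed fraction (or to an explicit
value; the sign of each published study case is stated explicitly because
"changed by 20 %" alone is ambiguous). Over the standard base case the
peak is most sensitive to depth: a +20 % depth change moves it more than
−20 % intensity or radius changes do, and the peak delta is exactly linear
in the intensity change at fixed geometry.

`temperature_perturbation_study()` propagates a seeded uniform measurement
error of $\pm f$ through a profile in two modes: *absolute* (each Celsius
temperature multiplied by $1+u$; worst case $f\cdot T_{max}$, which is the
1.41 °C figure at $f = 0.05$ on the standard case) and *range* (each
temperature shifted by $u$ times the profile span; every deviation bounded
by $f\cdot(T_{max}-T_{min})$, 0.083 °C on the same case). Uniform rather
than Gaussian error is used because only a symmetric percentage band is
specified for camera error; the distribution choice is configurable
territory but fixed here for reproducibility.

`relative_error_table()` reports $100\,|est-true|/true$ per parameter with
the **true value as denominator** — the convention consistent with the
reproducible rows of the reference error analyses; one published noisy-depth
figure (66.2 %) instead divides by the estimate and is treated as an
inconsistency of that source, not matched by the package convention.

## The synthetic thermogram generator

`generate_synthetic_thermogram()` evaluates the forward model on a pixel
lattice (isotropic pitch, top-left origin, physical coordinates
`origin + (index-1)·pitch`) at each pixel's radial distance from the
hotspot center, then applies one of three seeded noise models:

- `elevation_percent` — multiplicative uniform error on the elevation
  above ambient, ambient kept exact. This is the "10 % model noise" used
  for noisy training data; it acts on the elevation because the ambient
  reference is independently measured in practice.
- `absolute_percent` — multiplicative uniform error on the absolute °C
  reading (the "±5 % temperature error" camera model).
- `gaussian_additive` — additive Gaussian error in °C.

Every synthetic grid records its full provenance (source, surface
parameters, lattice, noise kind/magnitude/seed) and can be regenerated
bit-for-bit from it, including after a CSV round trip. Grids are written
as a plain numeric matrix under `# key = value` headers; temperatures are
serialized at 10 decimals by default so that read-after-write reproduces
the field to well below $10^{-9}$ °C (a 4-decimal export matching typical
printed precision is available via the `digits` argument).

What the generator does **not** emulate: anatomy (curved or layered
breast geometry), camera physics (point-spread, focus, vignetting,
radiometric calibration), spatially correlated noise, or multiple sources.
Passing tests therefore demonstrate correctness of the method under its
own model assumptions plus idealized pixel noise — not clinical validity.

## Problem sizes and reproducibility

The shipped studies use sizes chosen to make every stochastic claim a
distributional one while staying comfortably reproducible on a laptop:
1 000 randomized sources for the inversion round-trip property, 100 seeds
for the noisy-grid localization error distribution, and 20 independently
seeded surrogate trainings (400 samples, 3 000 epochs, 3 starts each) for
the refinement recovery study, whose reference configurations are a
noiseless 0.35 W / 2 cm / 5 mm source started from (0.356, 0.0202, 0.005)
and a 0.05 W / 1 cm / 0.09 mm source observed under 10 % elevation noise.
The noiseless rerun recovers depth within 2 %, intensity within 4 % and
radius within 10 % with peak discrepancy below 0.05 °C in at least 90 % of
seeds, and the noisy rerun shows strictly larger error distributions —
property bounds, not bit-level reproductions, because the exact outcome of
any particular historical network training run is not recoverable. Every
random draw in the package (sampling, weight initialization, noise)
requires an explicit seed and restores the caller's RNG state.

## Known limitations

- Single dominant source; overlapping hotspots are out of scope.
- The steady-state, homogeneous-tissue point-source model is a screening
  approximation, not a patient-specific thermal model.
- Depth and radius are not separately identifiable from a surface profile;
  only their sum is. All depth claims should be read as effective depth.
- The radius relations are dimensional conventions; treat $R$ from them as
  a score.
- The three-temperature screening estimate reports an intensity *range*
  over an assumed depth interval plus its mean; the mean depends on the
  depth grid and is a documented averaging convention, not a measurement.
- Command-line refinement lives on the `invert` subcommand (which has a
  profile to refine against) rather than on `estimate`, whose inputs are
  three scalars.
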