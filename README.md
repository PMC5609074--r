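# thermoloc

Localization of an embedded heat source — typically a superficial tumor —
from skin-surface temperature data (infrared thermograms).

A metabolically active mass buried in tissue warms the skin above it. Under
steady-state conditions the temperature field of the surrounding tissue is
well approximated by the point-source solution of the bioheat equation, and
the skin-surface temperature at lateral offset *a* from the point directly
above the source is

    T(a) = Te + Q / (4 π h0 [(d + R)² + a²])

where `Te` is the ambient temperature (°C), `Q` the source power (W), `h0`
the convective heat-exchange coefficient of the skin surface (W/(m²·K)),
`d` the depth of the source top below the surface (m) and `R` the source
radius (m). A sphere of radius `R` at depth `d` is exactly equivalent to a
point source at the *effective depth* `d + R`.

The model inverts in closed form from just two surface readings — the peak
temperature `Tmax` and one local reading `T(a)` at a known offset:

    d + R = a · sqrt( (T(a) − Te) / (Tmax − T(a)) )
    Q     = 4 π h0 a² (T(a) − Te)(Tmax − Te) / (Tmax − T(a))
    R³    = (T(a) − Te)(a² + d²) · 4 π h0 / (q_m · 10⁻⁶)

with `q_m` the volumetric metabolic heat generation (W/m³). The package
implements, on top of this core:

- **Forward simulation** — 1D profiles, 2D synthetic thermograms on a pixel
  lattice, one-at-a-time parameter sweeps, seeded noise models
  (multiplicative error on the elevation above ambient or on the absolute
  temperature, additive Gaussian).
- **Analytic inversion** — hotspot detection, observation pairs at one or
  several offsets with median aggregation, both radius routes, and the
  effective-depth decomposition `d = max(d+R − R, 0)`.
- **Neural surrogate refinement** — a 3-input, 10-hidden-unit, feed-forward
  network trained on forward-model samples and used inside a bounded
  derivative-free search to refine `(Q, d, R)` against a whole observed
  profile.
- **Sensitivity analysis** — ±20 % parameter perturbations, ±5 %
  temperature-error propagation, and relative-error tables for estimated
  parameters.
- A **command-line interface** (`exec/thermoloc`) with `simulate`,
  `invert`, `estimate`, `sensitivity` and `surrogate-train` subcommands
  over annotated-CSV grids and JSON reports.

## Worked example

Simulate a noisy thermogram of a 0.1 W point source 1.4 cm deep, then
recover the source from the image alone:

```r
library(thermoloc)

tissue <- tissue_params()                      # k = 0.52, h0 = 8.77, ambient 27 degC
source_true <- heat_source(Q = 0.1, d = 0.014, R = 0)

grid <- generate_synthetic_thermogram(
  source_true, tissue, shape = c(41, 41), pixel_pitch = 0.0025,
  noise = noise_spec("elevation_percent", 0.10, seed = 7))
grid
#> Thermogram grid: 41 x 41 pixels, pitch 0.0025 m, T_env 27 degC
#>   temperatures in [27.1650, 31.7463] degC; provenance: synthetic

localize_from_thermogram(grid, tissue)
#> Heat-source inversion result
#>   effective depth d+R = 0.0128708 m
#>   intensity Q         = 0.0866516 W
#>   radius R (eq_radius_temps)     = 4.98379
#>   decomposed depth d  = 0 m
#>   observations used   = 5 offset(s)
```

With 10 % elevation noise the effective depth comes back within 8 %
(0.0129 m vs 0.014 m) and the intensity within 14 % (0.087 W vs 0.1 W);
on a noiseless grid both are exact to machine precision. The radius score
follows the conventional intensity-free relation, whose units do not
cohere dimensionally — see the methods vignette for why it is reported as
a score rather than a calibrated length, which here also floors the
decomposed depth at zero.

The three-temperature screening workflow needs no image at all:

```r
estimate_source(T_env = 20, T_max = 35.2, T_skin = 30)
#> Intensity estimate from (T_env, T_skin, T_max) = (20, 30, 35.2) degC
#>   depths 0.006-0.01 m (R = 0.001 m): Q in [0.08208, 0.2027] W, mean 0.1385 W
#>   warm-region radius (to T_skin): 0.005048-0.007932 m
```

The same pipeline is available from a shell:

```sh
thermoloc simulate --Q 0.1 --d 0.014 --R 0 --shape 41x41 --pitch 0.0025 \
  --noise-kind elevation_percent --noise-mag 0.1 --seed 7 -o grid.csv
thermoloc invert -i grid.csv -o report.json
```

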