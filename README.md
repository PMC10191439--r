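# flickerspec

High-throughput flicker spectroscopy of biomolecular condensates in R.

Biomolecular condensates — stress granules, nucleoli, P-bodies — are
membraneless droplets whose mechanics govern how they fuse, grow, and deform
other cellular structures. Their interfacial tension σ and interfacial
bending rigidity κ can be read out *in cellulo*, without touching the cell,
from the thermal flicker of their boundaries in time-lapse fluorescence
microscopy. flickerspec implements the full chain for users of spinning-disk
or confocal condensate imaging: granule detection and tracking, sub-pixel
boundary extraction, Fourier mode statistics with a base-shape correction,
spectrum fitting, and population summaries — plus a synthetic-data subsystem
that generates ground-truth fluctuating droplets so every stage can be
validated.

## The model

The interface is described by the Helfrich free energy (tension σ plus
bending κH²/2, no spontaneous curvature). Equipartition over spherical
harmonic modes, projected onto the imaged equatorial contour D(φ), predicts
the time-averaged spectrum of the relative contour modes v_q:

    <|v_q|²> = (k_B T / κ) Σ_{l=q..l_max}  N_lq² P_lq(0)²
               / [ (l+2)(l−1) (l(l+1) + σ̄) ],        σ̄ = σR²/κ

Low modes feel tension (power ~ q⁻¹), high modes feel bending (~ q⁻³), with
a crossover near q ≈ √σ̄ — that shape difference makes σ and κ separately
identifiable from one time-averaged spectrum. Because granules are not
perfectly spherical on average, each measured mode is split into a static
part |C_q|² = |⟨v_q⟩|² and a fluctuating part |F_q|² = ⟨|v_q|²⟩ − |C_q|²;
only |F_q|² is thermal and is what gets fitted. |C_2|² doubles as a
circularity (elongation) measure.

`helfrich_fit()` is the central modelling function: it returns a classed
object with `print`, `summary`, `coef`, `predict`, `plot`, `residuals` and
`simulate` methods, estimates (κ, σ̄) by RMS log-residual minimization, and
also fits tension-only and bending-only variants — the error differences
between them drive the population quality filters.

## Worked example

Simulate a 300-frame video of one thermally fluctuating granule with known
mechanics (κ = 2 k_BT, σ̄ = 50, R = 0.78 µm, SNR 5), then run the full
analysis pipeline on the rendered images:

```r
library(flickerspec)

truth <- model_params(kappa = 2, sigma_bar = 50, radius = 0.78)
vid   <- simulate_droplet_video(truth, optics_model(), n_frames = 300,
                                seed = 11, l_sim = 40, m_max = 15)
res   <- run_pipeline(vid, pipeline_config())
print(res)
#> Flicker-spectroscopy pipeline result: 1 granules analyzed
#> Granule filtering:
#>   input                      : 1
#>   outline pass rate >= 0.60  : 1  (-0)
#>   delta error >= 0.03        : 1  (-0)
#>   fit error <= 0.50          : 1  (-0)
#> Population summary (geometric mean [67% band]):
#>  quantity n geometric_mean   band_lo   band_hi
#>     sigma 1      0.7183050 0.7183050 0.7183050
#>     kappa 1      0.6466317 0.6466317 0.6466317
```

The granule survives all three quality filters and its interfacial tension
comes out at 0.72 µN/m against a ground truth of

```r
convert_units(2, 50, 310, 0.78e-6)$sigma_physical * 1e6
#> [1] 0.7034674
```

i.e. recovered within a few percent from rendered images at SNR 5. (The
fitted rigidity at this image quality is biased low, because the highest
contour modes of a 12 px granule sit at the detection noise floor — see the
methods vignette; contour-level rigidity recovery is tested to a few
percent.) On a noiseless model spectrum the fit is essentially exact, and
only the two-term model fits well:

```r
sp  <- model_spectrum(truth)
fit <- helfrich_fit(data.frame(q = sp$q, F2 = sp$power), radius_um = 0.78)
print(fit)
#> Projected Helfrich spectrum fit
#>   kappa      = 2 kB*T
#>   sigma_bar  = 50  (sigma = 0.7035 uN/m at R = 0.78 um, T = 310 K)
#>   fit errors: full 0.0000 | tension-only 0.2659 | bending-only 0.2414
```

Real TIFF stacks go through the same entry point
(`run_pipeline("stack.tif", pipeline_config(pixel_size = 0.065))`), writing
per-granule tables, filter counts and a run report; a thin command-line
wrapper with `analyze` / `simulate-droplet` / `simulate-rigid` /
`zplane-study` subcommands is installed under `inst/scripts/flickerspec`.

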