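---
title: "Flicker spectroscopy of biomolecular condensates: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flicker spectroscopy of biomolecular condensates: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(flickerspec)
```

## The physical model

A liquid-like condensate in a cell is never at rest: thermal agitation makes
its interface flicker. The statistics of that flicker encode the mechanics of
the interface. flickerspec models the interface with the Helfrich free
energy — a quadratic expansion in the deformation, with an interfacial
tension term $\sigma$ (energy per area) and a bending term
$\tfrac{\kappa}{2}H^2$ ($H$ the total curvature, $\kappa$ the bending
rigidity). Spontaneous curvature and saddle-splay contributions are assumed
absent, and the droplet is assumed quasi-spherical with mean radius $R$.

Expanding the droplet surface in real orthonormal spherical harmonics,
$r(\theta,\phi) = R[1 + \sum_{lm} u_{lm} Y_{lm}(\theta,\phi)]$, each
coefficient is an independent quadratic mode with stiffness
$\kappa (l+2)(l-1)[l(l+1) + \bar\sigma]$, where
$\bar\sigma = \sigma R^2/\kappa$ is the dimensionless tension. Equipartition
then fixes every variance:
$$\langle u_{lm}^2 \rangle
  = \frac{k_B T}{\kappa (l+2)(l-1)[l(l+1) + \bar\sigma]}.$$

A microscope sees only the equatorial cross-section. Writing the contour as
$D(\phi)$ and its relative Fourier amplitudes as $v_q$ (one-sided, normalized
so that $D = R(1 + 2\varepsilon\cos q\phi)$ gives $|v_q| = \varepsilon$), the
projection of the 3-D modes onto the contour gives the time-averaged
spectrum implemented in `model_spectrum()`:
$$\langle |v_q|^2 \rangle = \frac{k_B T}{\kappa} \sum_{l=q}^{l_{max}}
  \frac{N_{lq}^2 P_{lq}(0)^2}{(l+2)(l-1)[l(l+1) + \bar\sigma]},$$
with $N_{lq}^2 = \frac{2l+1}{4\pi}\frac{(l-q)!}{(l+q)!}$ the
spherical-harmonic normalization and $P_{lq}$ the associated Legendre
functions. Terms with odd $l+q$ vanish by parity. The crossover mode
$q \approx \sqrt{\bar\sigma}$ separates a tension-dominated regime at low $q$
(power $\sim q^{-1}$) from a bending-dominated regime at high $q$
($\sim q^{-3}$); this difference in shape is what makes $\kappa$ and
$\sigma$ separately identifiable from a single time-averaged spectrum.

Because nothing in the derivation fixes the normalization of $v_q$, we chose
the one-sided convention above and **validated it against a brute-force
oracle** rather than trusting the algebra: equipartition-sampled 3-D shapes,
sectioned at the equator and decomposed exactly like measured data, must
reproduce `model_spectrum()` within Monte-Carlo error. This closure (in
`tests/testthat/`, at $10^5$ shapes in the acceptance suite) ties the
analytic sum, the harmonic conventions, and the simulator together; a
mistake in any one of them breaks it.

Two numerical points. The Legendre weights are evaluated with the standard
fully-normalized three-term recurrence, which is stable far beyond $l = 150$
(naive factorial ratios overflow near $l \approx 85$); tests cross-check
them against a closed-form log-gamma expression and a quadrature of the
normalization integral. The harmonic sum converges slowly in its tail: at
the default truncation $l_{max} = 75$ the highest fitted modes still change
at the $10^{-3}$–$10^{-2}$ level when the truncation is doubled. This is
inherent to the projected spectrum, not to the implementation; it is far
below the statistical error of any per-granule spectrum, and
`model_spectrum(conv_tol =)` exposes an explicit convergence check.

## From images to spectra

The pipeline (`run_pipeline()`) mirrors standard condensate imaging
practice, stage by stage:

* **Detection.** Granules are bright blobs on a non-zero, cell-to-cell
  varying cytoplasmic background, so global thresholding is unreliable;
  `detect_granules()` uses a multi-scale difference-of-Gaussians band-pass
  (geometric scale ladder, ratio 1.6, radii 3–30 px) with local maxima above
  a contrast threshold (default 8% of the frame intensity range — the
  threshold is not dictated by theory and is exposed in `detect_config()`).
  Centers are refined to sub-pixel precision by quadratic interpolation of
  the detector response.
* **Extent.** `estimate_extent()` flood-fills from the seed at half the
  maximum image intensity (connected component of the thresholded image).
  Masks under 100 px are rejected as too small to analyze. Because peak
  brightness varies between cells, a per-granule local-maximum reference is
  available as an option.
* **Boundary.** `extract_contour()` casts 400 evenly spaced rays from the
  mask centroid and places the edge at the maximum outward intensity
  *descent* $-\nabla I \cdot \hat r$ (for a bright object on a dark
  background the outward radial gradient at the edge is negative). The
  gradient uses the five-point fourth-order stencil, exact through quartic
  intensity fields; by default the image is pre-smoothed with a 1 px
  Gaussian to suppress pixel noise. Rays are sampled at 0.25 px by bilinear
  interpolation, and the peak is refined by a least-squares parabola over a
  ±1 px window. A three-point parabola at 0.25 px spacing would sit inside a
  single bilinear cell — piecewise linear, hence carrying no curvature
  information — which is why the window spans the pixel grid. On clean
  renderings this localizes a circular edge to a few hundredths of a pixel
  (asserted < 0.05 px RMS in the tests).
* **Validation and tracking.** A boundary is rejected frame-by-frame if any
  adjacent-point jump exceeds 0.2 of the mean radius (merging granules and
  overhangs violate the radial representation); the per-granule fraction of
  accepted frames is the outline pass rate. Tracking is greedy
  nearest-center linking in global distance order (deterministic and
  invariant to detection order), with a 5-frame memory.

**Base-shape correction.** Condensates are not perfectly spherical on
average. Each mode is therefore split into a static part and a fluctuating
part, $|F_q|^2 = \langle|v_q|^2\rangle - |\langle v_q\rangle|^2$ and
$|C_q|^2 = |\langle v_q\rangle|^2$ (`aggregate_modes()`); only $|F_q|^2$ is
thermal and enters the fit, and $|C_2|^2$ doubles as a circularity measure.
Skipping this correction visibly biases both parameters when a static
elongation is present — the acceptance suite constructs exactly that case.
The complex mean is taken in the detected frame without rotational
registration; granules that rotate between frames convert static power into
apparent fluctuations (see the rigid-body generator below).

Mode $q = 1$ mixes with center placement error and is excluded from fits;
modes above $q = 15$ are below the resolution of typical spinning-disk data
for the smallest granules and are truncated.

## Fitting and filtering

`helfrich_fit()` minimizes the RMS $\log_{10}$ residual between measured
$|F_q|^2$ and the model over $q = 2..15$ — a uniform multiplicative weight
across the decades a spectrum spans; a uniform factor-10 offset scores
exactly 1. The error surface is scanned on a deterministic 60×60 log-log
grid ($\kappa \in [10^{-2}, 10^4]\,k_BT$, $\bar\sigma \in [10^{-4}, 10^6]$,
bracketing reported condensate values by more than two decades) and refined
by Nelder–Mead; no randomness is involved. Two one-parameter variants are
fitted alongside: tension-only, the analytic $\kappa \to 0$ limit with
single parameter $\sigma R^2/k_BT$ (substituting $\kappa = 0$ naively is
singular), and bending-only ($\bar\sigma = 0$); both have closed-form
log-least-squares solutions. Modes whose corrected $|F_q|^2$ is non-positive
(possible under noise) are dropped, with at least 5 modes required. When
$\sqrt{\bar\sigma} > q_{max}$ the crossover lies outside the fitted window,
the error valley is flat in $\kappa$, and the fit is flagged
(`crossover_beyond_qmax`); such granules carry no rigidity information.

Populations are filtered in three sequential stages (`apply_filters()`,
counts reported per stage): outline pass rate ≥ 0.60; error increase when
rigidity is dropped ≥ 0.03; full-model error ≤ 0.5. The two error thresholds
are kept at their conventional defaults but are configurable, since their
absolute meaning depends on the exact error definition. On the pass-rate
cutoff the available descriptions disagree (keep if closed in ≥ 60% of
frames, versus remove if rejected in > 60%); we default to the stricter
pass ≥ 0.60 and expose the threshold. Summaries are geometric means with
±1 SD log-normal bands (`population_stats()`), the natural description of
quantities spread over orders of magnitude.

`convert_units()` maps the dimensionless estimates to physical units,
$\kappa_{phys} = \kappa\,k_BT$ and $\sigma = \bar\sigma \kappa_{phys}/R^2$,
with $R$ the time-averaged mean radius. The default temperature is 310 K
(live mammalian cells) and is configurable.

## The synthetic-data subsystem

`sample_equilibrium_modes()` draws shapes directly from the equipartition
distribution; `equatorial_contour()` sections them; `render_frame()` turns
contours into camera frames (anti-aliased rasterization, Gaussian PSF of
1.3 px, uniform background at 20% of the foreground, white Gaussian noise at
SNR 5 — the conditions of typical spinning-disk condensate imaging at
0.065 µm/px); `simulate_droplet_video()` assembles 1000-frame bursts.
Defaults: granule radius 0.78 µm (≈ 12 px, the middle of the reported
0.4–1.6 µm range), i.i.d. shapes per frame (only time-averaged spectra are
fitted; an Ornstein–Uhlenbeck option would be needed for dynamics, which is
out of scope), `fixed_shape = TRUE` renders one quenched shape with fresh
noise per frame as a fixed-cell mimic.

What the generator does **not** emulate: photobleaching, EMCCD gain noise,
non-Gaussian PSFs, out-of-focus light, neighbouring granules and organelles,
or temporal correlation of shapes. Passing tests therefore demonstrate
correctness of the method on its own model assumptions, not performance on
any particular instrument.

Two exactness shortcuts keep large Monte-Carlo runs cheap without
approximation: harmonic orders with $|m| > q_{max}$ are exactly orthogonal
to contour modes $q \le q_{max}$, so closure studies may band-limit with
`m_max`; and a band-limited contour is exactly represented by any $n$ points
with $n > 2 l_{sim}$, so 64-point contours suffice there. Defaults remain
full-band and 400 points. For ground-truth analyses, `decompose_contour()`
accepts the known `base_radius`: normalizing by the *realized* mean radius
(as one must for measured data) is nonlinear and introduces a small Jensen
bias, visible only at the large fluctuation amplitudes of tension-free
parameter sets.

**Off-equator sections.** A granule imaged away from its equator is cut by
a plane parallel to the equator at height $R\sin(\delta)$, i.e. along the
small circle at polar angle $\theta_0 = \pi/2 - \delta$. To first order the
apparent radius is $\rho(\phi) = R\sin\theta_0 [1 +
u(\theta_0,\phi)/\sin^2\theta_0]$: the mean radius shrinks as $\cos\delta$
while relative fluctuations are amplified by $1/\cos^2\delta$.
`zplane_robustness()` re-sections identical shape draws over a tilt grid
(pairing removes Monte-Carlo noise from the comparison); within 20° the
fitted parameters shift by far less than the width of typical population
distributions.

**Rotating rigid bodies.** `simulate_rigid_rotation()` builds a quenched
rough shape (amplitudes uniform on $[0,1]$ scaled by $1/l$ over
$l = 2..15$, one random phase per $(l,m)$ — the published description of
the phase factors is ambiguous, and this reading is recorded as ours) and
applies cumulative random rotations (axis uniform on the hemisphere, angle
$\sim N(0, 2^\beta)$, default $\beta = 0$). Such series mimic solid-like
granules whose boundary motion is rotation rather than flicker. A caveat
discovered while validating this generator: under full rotational averaging
a $1/l$-amplitude quenched spectrum has per-degree variance $\propto l^{-2}$
— the same $l$-scaling as a tension-dominated Helfrich spectrum — so
rotating rigid bodies are *spectrally similar* to fittable droplets and
their absolute fit errors, while several-fold larger than those of live
simulations, do not always exceed the 0.5 rejection threshold under our
error definition. The tests assert the separation between rigid and live
series rather than a universal rejection.

## Problem sizes and reproducibility

Every stochastic operation takes an explicit seed and restores the caller's
RNG state; identical seeds give bit-identical output, and `run_pipeline()`
is deterministic given its input. The test suite uses $10^5$ shapes for the
spectrum closure, 50 replicates of 1000-frame contour-level simulations for
parameter recovery (median errors ~2%, asserted against 20%/25%
tolerances), 20 replicates for the base-shape correction study, 20 seeds
for the rigid-body comparison, and 100–120 frame rendered videos for
image-level round trips — sizes chosen so the statistical assertions are
stable while the whole suite stays comfortably runnable on a laptop.

## Known limitations

* At SNR 5 the per-ray edge localization error is a few tenths of a pixel;
  static mode amplitudes average it down to the 0.01 px scale over frames
  and rays, but per-frame high-$q$ powers ($q \gtrsim 8$ at 12 px radius)
  are noise-dominated. Tension survives this robustly; image-level rigidity
  estimates at SNR 5 are biased low, which is why quantitative recovery
  claims are made at the contour level.
* Granule rotation between frames is not registered; the static term of a
  rotating elongated granule leaks into $|F_q|^2$.
* Viscosity and frequency-domain analysis are out of scope by design; the
  generator's i.i.d. frames make any apparent temporal correlation in
  simulated videos an artifact of the renderer, not a model feature.
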