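---
title: "Methods: correcting laser speckle flowmetry for tissue optical properties"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correcting laser speckle flowmetry for tissue optical properties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Laser speckle imaging (LSI) estimates blood flow from the blurring of a
coherent speckle pattern over the camera exposure: the spatial contrast
$K = \sigma(I)/\langle I \rangle$ in a small window falls as scatterers
move faster. The conventional speckle flow index,
$\mathrm{SFI} = 1/(2TK^2)$, is only a relative measure, and worse, it is
confounded by tissue optics: higher absorption shortens photon paths and
*raises* $K$ at constant flow, while higher scattering lengthens them and
*lowers* $K$. Spatial frequency domain imaging (SFDI) measures the
absorption coefficient $\mu_a$ and reduced scattering coefficient
$\mu_s'$ pixel by pixel, which makes it possible to undo this confound
and report an absolute flow quantity. This package implements the full
processing chain of such a combined instrument and the correction method
at its core.

# Models

## Diffuse reflectance and optical-property inversion

For a homogeneous semi-infinite medium, the spatial-frequency-domain
diffusion solution gives a closed-form diffuse reflectance

$$R_d(f_x) = \frac{3A\,\mu_s'/\mu_{tr}}
  {(\mu_{eff}'/\mu_{tr} + 1)(\mu_{eff}'/\mu_{tr} + 3A)},\qquad
  \mu_{eff}' = \sqrt{3\mu_a\mu_{tr} + (2\pi f_x)^2},$$

with $\mu_{tr} = \mu_a + \mu_s'$ and the boundary coefficient $A$
computed from the effective reflection coefficient polynomial in the
refractive index $n$ (`boundaryTerms()`). Measured reflectance comes from
three-phase demodulation: a sinusoid projected at phases 0°/120°/240° has
AC amplitude $\tfrac{\sqrt 2}{3}\sqrt{(I_1-I_2)^2+(I_2-I_3)^2+(I_3-I_1)^2}$
— $\sqrt2/3$ is the unique constant for which a sinusoid of amplitude
$A$ demodulates to exactly $A$, and the combination rejects any common DC
offset. A planar ($f_x = 0$) pattern carries no spatial phase, so its
three frames are nominally identical and the planar amplitude is taken as
their mean; the renderer and the demodulator share this convention.
Amplitudes are Gaussian-smoothed and ratioed against a phantom of known
properties measured identically, which cancels the illumination profile
and camera response.

The pair $(R_d(0), R_d(0.3\,\mathrm{mm^{-1}}))$ determines
$(\mu_a, \mu_s')$ uniquely inside the physical range. Rather than linear
interpolation over a scattered point cloud, the package inverts the same
closed form directly: a damped Newton iteration in
$(\log\mu_a, \log\mu_s')$, seeded at a fixed interior point, with a
finite-difference Jacobian and step backtracking. The forward lookup
table (`buildRdLut()`, 512 linearly spaced nodes over
$\mu_a \in [10^{-4}, 0.2]$ and $\mu_s' \in [10^{-3}, 3]$ mm$^{-1}$)
defines the admissible region: pixels whose solution does not converge
(reflectance pairs outside the attainable set, e.g. (0.99, 0.99)) or
falls outside the axis ranges are flagged invalid and carry `NA` — never
extrapolated, because extrapolated $\mu_a$ is unphysical and would
silently poison the chromophore fit downstream. Scattered-data inverse
interpolation over the grid, the obvious alternative, trades ~1%
interpolation error for independence from the forward model; since the
table here *is* built from the same closed form, direct inversion is
strictly more accurate (round-trip errors are at numerical precision) and
equally deterministic.

## Chromophores and wavelength transfer

Absorption maps at 660/780/850 nm are unmixed into oxy- and
deoxy-hemoglobin by per-pixel least squares on the extinction system
$E\,c = \mu_a$, with $E$ in mm$^{-1}$/µM including the $\ln 10$ factor
(one constants file, approximate compiled hemoglobin spectra; every
forward and inverse chromophore computation uses the same table, so
round trips are exact by construction). Total hemoglobin and oxygen
saturation follow by definition. The LSI wavelength sits outside the
SFDI set, so $\mu_a(633)$ is reconstructed from the fitted
concentrations, and $\mu_s'(633)$ from the Mie-type power law
$\mu_s'(\lambda) = A(\lambda/850)^b$ fitted in log space — exact when
the inputs lie on a power law, least-squares otherwise.

## Speckle contrast and the Db inversion

The exposure-integrated contrast model is

$$K^2 = \frac{2\beta}{T}\int_0^T g_1^2(\tau)\left(1 - \frac{\tau}{T}\right)d\tau,$$

with $g_1$ the normalized correlation-diffusion field autocorrelation; the
Brownian term enters as an extra, $\tau$-dependent absorption
$\tfrac13\mu_s' k_0^2\, 6 D_b \tau$ inside $\mu_{eff}'$, with
$k_0 = 2\pi n/\lambda$. Two structural properties anchor the method and
are enforced by tests: at $D_b = 0$ the integral collapses to $T/2$ and
$K = \sqrt\beta$ exactly; and at $f_x = 0$ (planar LSI illumination) a
joint rescaling of $(\mu_a, \mu_s')$ leaves $K^2$ unchanged — absorption
and scattering shifts of equal proportion cancel, which is precisely why
only their *ratio* of change corrupts uncorrected SFI.

Inversion for $D_b$ goes through a 3-D table of the integral over
$(D_b, \mu_a, \mu_s')$ (defaults: 256 linear $D_b$ nodes up to
$2\times10^{-5}$ mm²/s, 128 nodes each for $\mu_a \in [10^{-4}, 0.3]$ and
$\mu_s' \in [10^{-3}, 3]$ mm$^{-1}$). Per pixel, $(\mu_a, \mu_s')$ fix a
$K^2(D_b)$ profile by bilinear interpolation; the profile is strictly
decreasing, so 1-D monotone interpolation along the $D_b$ axis yields the
answer with guaranteed uniqueness — more robust than 3-D scattered
interpolation over the table's point cloud, which is the documented
alternative. Contrast above $\sqrt\beta$ (super-static, unphysical) or
below the profile minimum (flow beyond the table's dynamic range) is
flagged invalid. Optical properties outside the axes raise an error
rather than clamping: a clamped $\mu_a$ would fabricate flow.

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| exposure $T$ | 0.010 | s | camera exposure of the acquisition design |
| LSI wavelength | 633 | nm | laser line |
| SFDI wavelengths | 660/780/850 | nm | hemoglobin sensitivity |
| spatial frequencies | 0, 0.3 | mm⁻¹ | DC + AC pair separating µa from µs′ |
| refractive index $n$ | 1.4 | — | typical soft tissue; the boundary terms depend on it; exposed because no single value is universal |
| Gaussian window / σ | 15 px / 2.5 px | — | shot-noise suppression of AC maps; σ = window/6 keeps the kernel contained; applied to sample and phantom alike so the ratio is unbiased |
| contrast window | 5 px | — | standard spatial-contrast window; border pixels are invalid, not padded |
| moving average | 50 frames | — | ≈1 s at 50 Hz for time courses |
| $D_b$ axis max | 2×10⁻⁵ | mm²/s | covers tissue-like diffusion coefficients with headroom |
| raw frame rate | 50 | Hz | 18-frame cycle → 2.8 Hz effective SFDI rate |

# The synthetic generator

The generator exists so that every stage has a closed loop against known
ground truth; it emulates the *statistics* the pipeline consumes, not the
instrument.

**SFDI frames** are rendered from the same reflectance forward model the
inversion uses: a DC level proportional to $R_d(0)$ plus a modulated term
proportional to $R_d(f_x)$, with optional additive Gaussian noise.
Noise-free renderings round-trip demodulation → calibration → inversion
to numerical precision, which isolates algorithmic errors from model
errors.

**Speckle frames** are fully developed fields: white complex Gaussian
noise filtered through a circular pupil (setting the speckle/pixel size
ratio, and hence the effective β) and transformed to the image plane.
Temporal decorrelation is imposed *exactly* at discrete sub-exposure
samples by Cholesky-factoring the target field correlation matrix; the
frame intensity is the sub-sample average. The default field law is
exponential, $g_1(\tau) = e^{-\tau/\tau_c}$, and `tauCForDb()` picks the
$\tau_c$ whose *discrete* exposure-integrated contrast equals the
correlation-diffusion $K^2$ at the target $D_b$ — so the closed loop
tests the inversion, not the sub-sampling scheme. Frames are mutually
independent (only spatial contrast is consumed downstream), and every
stack is bit-reproducible from its seed.

Two numerical choices matter and were made deliberately:

* **Mean counts 30 (8-bit).** Fully developed speckle intensity is
  exponentially distributed; a mean near 65 counts clips about 2% of
  samples at the 255 ceiling, which truncates the *static* distribution
  far more than the narrower dynamic one and biases the β-normalized
  contrast ratio by several percent. The default mean keeps the ceiling
  at ~8.5 means (clipped fraction ~2×10⁻⁴).
* **Temporally pooled cycle contrast.** The single-frame 5×5 sd/mean
  estimator carries a multiplicative bias that depends on the intensity
  distribution's shape, and the shape differs between the static phantom
  (β estimation) and the dynamic sample — the biases do not cancel.
  `cycleContrast()` therefore averages the window variance and window
  mean over the frames of a cycle *before* taking the ratio; the window
  sampling factor is then identical for the static and dynamic stacks
  and cancels per pixel. The per-frame estimator is retained for SFI
  time courses, where normalization removes scalar biases anyway.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: camera noise beyond additive
Gaussian + quantization (no read-noise structure, no fixed-pattern
noise), speckle fields with spatially varying dynamics inside one
coherence area (piecewise-constant regions are composited, so boundaries
are sharp), partially polarized or partially developed speckle, static
scatterer layers (a skull), inter-camera registration error, and any
deviation of real tissue from the homogeneous semi-infinite diffusion
geometry. In particular, on real data the diffusion model's known
low-albedo inaccuracy (a Monte Carlo forward model would differ from the
diffusion closed form at high $\mu_a/\mu_s'$) propagates into both the
optical-property maps and the $D_b$ scale; here forward and inverse share
one model, so that error is invisible by construction.

# Numerical choices

* The scalar $K^2$ model uses adaptive Gauss–Kronrod quadrature
  (`stats::integrate`) at relative tolerance 10⁻⁹; a failure to converge
  is an error carrying the offending parameters, never a silent value.
* Table construction integrates all optical-property nodes of a $D_b$
  slice simultaneously with a 256-node Gauss–Legendre rule on a
  log-stretched time axis ($\tau = T e^{-L(1-u)}$, $L = 34$), which
  resolves decay scales down to $\sim T e^{-L}$; agreement with the
  adaptive route is asserted to 10⁻⁸ relative in the tests. The
  $D_b = 0$ slice is set to β analytically.
* Newton inversion of reflectance pairs runs in log space (positivity for
  free), caps steps at 1.5 log-units, backtracks on residual increase,
  and declares a pixel invalid if the residual norm exceeds 10⁻⁹ after 80
  iterations. Duplicate reflectance pairs (homogeneous scenes) are
  solved once and broadcast.
* The moving-average filter is centred with partial windows at the series
  edges, so constant series are unchanged; for even lengths the window
  extends one extra sample forward.
* Degenerate inputs fail loudly: non-positive refractive index, zero
  transport coefficient, zero phantom amplitude (with the affected pixel
  count), rank-deficient extinction matrices, out-of-axis lookup queries,
  and filter lengths exceeding the series all raise errors; unphysical
  *data* (unattainable reflectance, super-static contrast, all-zero
  windows) are flagged per pixel instead, because one bad pixel must not
  abort a map.

# Problem sizes

The test suite exercises the pipeline at 48×48 to 96×96 scenes with
reduced lookup tables (e.g. 128-node reflectance grids, 128×48×48 $K^2$
grids), and the acceptance suite runs the full chain on a seeded
256×256, 3-cycle dataset; the round-trip tolerances (1% for optical
properties, 2% for $D_b$ table inversion, 5% for end-to-end recovery)
are met with margin at these sizes. Axis counts are resolution choices,
not study conditions: the defaults reproduce the full-resolution tables
(512² and 256×128×128) and remain practical on a single core.

# Known limitations

The homogeneous semi-infinite assumption is load-bearing: layered media
(skull, coverslip) and large vessels with directed, singly scattered
flow are outside the model, and $D_b$ over such structures is a
mischaracterization of the true dynamics. The Brownian form is an
effective description of parenchymal (capillary-dominated) motion. The
18-frame cycle assigns one optical-property set to 18 consecutive LSI
frames, so sub-cycle optical changes (pulsatility) are not corrected.
Multi-exposure contrast models, motion-artifact correction and CMRO₂
computation are out of scope.
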