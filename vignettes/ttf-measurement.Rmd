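---
title: "Automated TTF measurement: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated TTF measurement: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ttfqa)
```

## Why a task-transfer function

The modulation-transfer function characterizes the spatial resolution of a
linear, shift-invariant imaging chain. Filtered back-projection CT is close
enough to that ideal that one MTF per reconstruction kernel suffices.
Iterative and deep-learning reconstructions are not: their effective
resolution depends on the local contrast and noise of the object being
imaged. The task-transfer function (TTF) addresses this by measuring the
transfer curve *per insert* of a multi-pin phantom, so that every contrast
level (bone, acrylic, polyethylene, air, ...) gets its own resolution curve,
indexed by the insert's contrast-to-noise ratio (CNR). `ttfqa` automates the
whole measurement from a single axial slice, with no user-drawn ROIs.

## The measurement chain

1. **Body segmentation.** The slice is thresholded at −200 HU (halfway
   between air and any tissue-equivalent plastic); the largest 8-connected
   component is kept and interior holes are filled, so that air or
   low-density pins remain part of the body. The phantom diameter is the
   equivalent-circle diameter $2\sqrt{A/\pi}$ of the mask. The exterior is
   then set to exactly 0 HU by element-wise multiplication with the mask.
2. **Pin segmentation.** Each material of the selected phantom template is
   thresholded with its HU window (see `get_template()`), restricted to an
   interior search disk of 0.8 body radii (the phantom shell would otherwise
   masquerade as bone or teflon). Components outside 25–400 % of the
   template's nominal pin area are rejected as speckle; the largest valid
   component wins and its binary-mask centroid becomes the pin center. The
   AAPM template's Acrylic/Polycarbonate/Nylon windows overlap in HU, so for
   that phantom the template stores each pin's approximate polar angle and
   candidates are assigned by nearest angle — geometry is the only remaining
   discriminator.
3. **ROI placement and CNR.** The pin edge radius is first re-estimated from
   the binned radial profile as the radius where the profile crosses the
   midpoint between the inner and outer plateau medians. Threshold
   segmentation systematically under- or over-shoots the edge whenever the
   HU window is asymmetric about the pin's actual HU (e.g. an air pin at
   −1000 HU with a window reaching only −900), and the profile crossing is
   immune to that bias. The inner ROI is a disk of 1/10 of the phantom
   diameter; the background ROI is a concentric annulus at 1.1–1.5 pin radii
   whose inner radius additionally keeps a guard band of 2.5 measured
   25–75 % edge widths beyond the edge. Starting the annulus exactly at the
   edge would feed the blurred transition into the noise estimate and bias
   the CNR low by tens of percent; the adaptive guard band keeps the noise
   estimate clean at any realistic blur. CNR is
   $|\mu_{in}-\mu_{out}|/\sigma_{out}$; a noiseless background yields an
   infinite CNR and an explicit `zero_background_noise` flag rather than a
   silent division by zero.
4. **Circular-edge ESF.** Every pixel within `pin radius + added_size` of
   the centroid contributes one (distance, HU) sample; the distance is the
   Euclidean distance minus the refined edge radius, so the edge sits near
   zero. The default `added_size` of one pin radius gives a sample cloud
   covering both plateaus with several thousand points at clinical pixel
   sizes; fewer than 200 samples is rejected as unmeasurable.
5. **Phase alignment.** The cloud is split into 32 angular sectors; each
   sector's monotone-smoothed profile is intersected with the midpoint
   between the robust plateau medians, and the sector is shifted so its
   crossing sits at zero. This removes the edge-phase dispersion caused by
   residual centroid error or slight pin ellipticity, which would otherwise
   blur the pooled ESF and bias the fitted transition rate low. Sectors with
   no detectable crossing are dropped; more than half failing aborts the
   pin. The estimator is a midpoint-crossing statistic — fast, closed-form
   and assumption-light.
6. **Single-logistic fit.** The pooled cloud is fitted with
   $\mathrm{ESF}(x) = a/(1+e^{-b(x-c)}) + d$ on the inward axis
   $x = -(r-R)$, so $d$ is the background plateau and $a$ the pin-minus-
   background amplitude ($a<0$ for pins darker than the background). The
   fit is trust-region non-linear least squares (Levenberg–Marquardt via
   `minpack.lm`, analytic Jacobian, four deterministic restarts spanning
   3× in the rate parameter). Initialization is closed-form: plateau medians
   for $a$ and $d$, the mid-crossing for $c$, and the 25–75 % transition
   width $w$ for $b_0 = 2\ln 3 / w$. Amplitudes below 3× the background
   noise attach a `low_contrast` flag; an amplitude indistinguishable from
   zero is a hard error, because a logistic fitted to pure noise has no
   interpretable width.
7. **LSF and TTF.** The fitted ESF is differentiated *analytically*:
   $\mathrm{LSF}(x) = a\,b\,e^{-b(x-c)}/(1+e^{-b(x-c)})^2$, a sech²
   profile. Analytic differentiation is exact and noise-free, which is the
   point of fitting first. The LSF is evaluated on a uniform 0.02 mm grid
   over $\pm 20/b$ (tails below $10^{-6}$ of the peak — "zeroed"),
   sign-normalized to a positive peak and area-normalized to unit sum
   ("normalized"), zero-padded to at least 4096 points and transformed with
   the FFT. The TTF is the DFT modulus normalized to 1 at zero frequency;
   f50 and f10 are linear interpolations at the first downward crossings of
   0.5 and 0.1, with a flag if the curve later re-crosses the level.

The closed-form consequence used throughout the tests: the normalized TTF
of the logistic model is $s/\sinh s$ with $s = 2\pi^2 f/b$, giving
$f_{50} = 0.11030\,b$, $f_{10} = 0.22797\,b$, and a universal ratio
$f_{50}/f_{10} = 0.48386$ for *any* single-logistic fit. The ratio is a
useful internal consistency check on reported summary pairs. With curve
fitting disabled (`ttf_config(enable_curve_fit = FALSE)`) the TTF comes
from the binned empirical ESF derivative instead — noisier, but
model-free; at CNR ≈ 200 the two routes agree on f50 to within a few
percent.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `body_threshold_hu` | −200 | HU | separates air from any body material |
| ROI diameter | body diameter / 10 | mm | fixed aspect rule; capped at 0.8 pin radii for small pins |
| `annulus_inner`, `annulus_outer` | 1.1, 1.5 | pin radii | background just outside the edge, plus an adaptive guard band |
| `added_size_mm` | one pin radius | mm | ESF sample length beyond the edge |
| `sector_count` | 32 | — | ~10° sectors: enough samples per sector, resolves ellipticity |
| `lsf_grid_spacing_mm` | 0.02 | mm | Nyquist 25 mm⁻¹, far above any CT cutoff |
| `fft_length` | 4096 | — | frequency spacing ≈ 0.012 mm⁻¹ before interpolation |

## The synthetic phantom generator

`render_phantom()` draws a circular water-equivalent body (air at −1000 HU
outside) with disk inserts, rasterized with 8× supersampled antialiasing
(pin areas accurate to <1 %), convolved with a Gaussian kernel of known
σ — whose TTF is exactly $e^{-2\pi^2\sigma^2 f^2}$, hence
$f_{50} = \sqrt{\ln 2}/(\sqrt{2}\pi\sigma)$ — and degraded with seeded
i.i.d. Gaussian noise. Per-pin kernels emulate the contrast-dependent
resolution of iterative/deep-learning reconstructions; because rendering is
linear, blurring each pin's contrast delta separately is exact. The
`acr_like` preset is a 200 mm body in a 200 mm FOV at 512², matching the
computational multi-pin module it emulates; the default noise of 4.85 HU
puts bone/air near CNR 200 and the plastic pins near CNR 20–25, the regime
reported for such phantoms. Defaults of σ = 0.5 mm give f50 ≈ 0.375 mm⁻¹,
i.e. a moderate clinical kernel.

What the generator does **not** emulate: correlated CT noise texture
(reconstruction colors the NPS; white noise is a simplification), projection
physics (no sinogram, no beam hardening), phantom tilt, and the exact vendor
pin layouts (ring layouts are synthetic and labeled as such). Passing tests
therefore demonstrate correctness of the measurement chain under known
ground truth, not scanner-level validation.

## Numerical choices and degenerate inputs

* Pixel-grid rasterization acts as a box aperture on top of the requested
  Gaussian blur, and a logistic fitted to an erf-shaped edge is a slight
  model mismatch; together they bias recovered f50 low by ~2–4 % at
  0.39 mm pixels. This is a property of any sampled edge measurement and is
  inside the validation tolerances (5 % at high CNR).
* 8-connectivity for components; binary-mask (not intensity-weighted)
  centroids.
* First-crossing rule with an ambiguity flag for non-monotonic TTFs; the
  single-logistic model cannot produce one, but the empirical route can.
* Degenerate inputs fail loudly with typed conditions: no foreground, a
  missing pin (named), colliding materials, too few ESF samples, no edge
  contrast, non-convergent fits.
* DICOM I/O is restricted to single-frame uncompressed explicit-VR
  little-endian CT; stored 16-bit integers round-trip HU within 0.5.

## Problem sizes in the test-suite

The validation suite renders 512² slices (≈0.39–0.49 mm pixels), uses 50
noise realizations for end-to-end blur recovery, 100 for the fit's
Monte-Carlo noise check, and sweeps pixel spacing over 0.31–1.0 mm — sizes
chosen to exercise the clinically relevant range while keeping the full
suite around a minute of CPU.

## Known limitations

* Single-logistic fitting assumes a monotone edge profile; edge-enhancing
  kernels with overshoot (non-monotonic ESFs) need a double-logistic model,
  which is deliberately out of scope — such fits show up here as elevated
  `rmse_hu` and the ambiguity flag.
* Four phantom families are built in; others can be added via
  `write_template()`/`read_template()` YAML files, including expected polar
  angles when HU windows overlap.
* No tilt/alignment correction and no multi-slice averaging: each slice is
  measured independently, and any averaging is left to the user.
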