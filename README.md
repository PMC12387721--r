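# ttfqa — automated task-transfer function measurement for CT

`ttfqa` measures the **task-transfer function (TTF)** — the
contrast-specific spatial-resolution curve recommended by AAPM TG-233 for
modern CT reconstructions — fully automatically from a single axial slice
of a multi-pin image-quality phantom. It is aimed at medical physicists
running CT quality assurance: no hand-drawn ROIs, one call per slice.

For linear, shift-invariant systems (classic filtered back-projection) a
single MTF describes resolution. Iterative and deep-learning
reconstructions are contrast- and noise-dependent, so resolution must be
measured per insert: the TTF of each pin, indexed by its contrast-to-noise
ratio (CNR).

## Method

For each pin of the phantom:

1. body segmentation at −200 HU, equivalent-circle diameter, exterior set
   to 0 HU;
2. pin segmentation by material HU windows (built-in templates for a
   computational/ACR 464-style 4-pin module, the 5-pin AAPM CT phantom and
   the 9-pin Catphan 604; overlapping windows resolved by pin geometry);
3. inner ROI (1/10 of the phantom diameter) and background annulus →
   CNR = |μ_in − μ_out| / σ_out;
4. circular-edge ESF: radial samples across the pin edge, phase-aligned
   per angular sector;
5. single-logistic fit ESF(x) = a / (1 + e^(−b(x−c))) + d
   (trust-region least squares);
6. analytic derivative → LSF (sech² profile), zeroed and area-normalized;
7. TTF(f) = |FFT(LSF)| normalized to 1 at f = 0; report f50 and f10
   (frequencies in mm⁻¹ where the TTF falls to 0.5 and 0.1).

A synthetic phantom renderer with closed-form ground truth (Gaussian
kernels: f50 = √(ln 2)/(√2 π σ)) backs the validation suite.

## Worked example

```r
library(ttfqa)

# render the computational ACR-style phantom: 200 mm water body, four pins
# (Bone 955 / Polyethylene -95 / Air -1000 / Acrylic 120 HU),
# Gaussian blur sigma = 0.5 mm, noise SD 4.85 HU
spec <- phantom_preset("acr_like", seed = 1)
slice <- render_phantom(spec)$image

res <- measure_slice(slice, "computational_acr")
res$rows
#>       material       cnr f50_inv_mm f10_inv_mm fit_rmse_hu flags
#> 1         Bone 197.45936  0.3643558  0.7530572    5.490043
#> 2 Polyethylene  19.36670  0.3606414  0.7452959    4.903778
#> 3          Air 205.99865  0.3642418  0.7528221    5.511329
#> 4      Acrylic  24.79969  0.3657407  0.7558977    4.875175
```

Reading the output: all four pins carry the same blur, so their f50 agree
within 0.005 mm⁻¹ despite CNRs spanning 19–206 — the linear shift-invariant
behavior expected of this generator. The measured f50 ≈ 0.364 mm⁻¹ sits
within 4 % of the kernel's closed-form value `gaussian_f50(0.5)` =
0.3748 mm⁻¹ (pixel-aperture sampling accounts for the small deficit), and
every f50/f10 pair obeys the single-logistic ratio law
f50/f10 = 0.4839.

Batch use and file output:

```r
path <- simulate_to_dicom("catphan_like", seed = 5, out_dir = "sim")
rep  <- run_measurement(path, "catphan604")     # 9 pins
write_report(rep, "out", plots = TRUE)          # report.csv / report.json / PNG
```

or from a shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli","ttfqa.R",package="ttfqa"))')
Rscript $CLI simulate --preset acr_like --seed 1 --out sim
Rscript $CLI measure --phantom computational_acr --input sim --out results --plots
```

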