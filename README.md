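# adcgan

Synthesis of zoomed-FOV-quality apparent diffusion coefficient (ADC) maps
from single-b-value full-FOV prostate diffusion MRI, with the complete
evaluation stack, runnable end to end on built-in synthetic phantoms.

## The problem

ADC maps are central to prostate cancer detection: dense tumors restrict
water diffusion, so malignant lesions show low ADC. Full-field-of-view
(f-DWI) echo-planar diffusion imaging — the workhorse acquisition — suffers
from phase-encode-direction geometric distortion, blur, and low SNR, which
corrupt both the geometry and the quantitative values of the fitted ADC map
(f-ADC). Zoomed-FOV acquisitions (z-DWI) avoid most of this but need
special hardware. This package implements a supervised learning alternative:
a least-squares GAN whose generator G maps a single-b-value f-DWI slice X to
a synthesized ADC map S = G(X) of zoomed-FOV quality, trained against z-ADC
references Y with

    L_D     = E[(D(Y) - 1)^2] + E[D(S)^2]
    L_G     = E[(D(S) - 1)^2] + lambda1 * sum_i theta_i * ||C_i(S) - C_i(Y)||^2_2

where C is a frozen benign/malignant recognition network providing features
at levels {0, 1, 3, 5} (level 0 = the raw image), lambda1 = 0.1, and the
level weights theta (initialized 1/4) are re-normalized each epoch in
proportion to the previous epoch's per-level losses. One model is trained
per input b-value (M50, M1000, M1500).

Everything around the model is included: a seeded zonal prostate phantom
simulator (mono-exponential signal, Rician noise, phase-encode distortion),
mono-exponential ADC fitting, preprocessing, RMSE/PSNR/SSIM/FSIM, prostate
AP/LR diameter distortion, a simulated two-reader ROI protocol, and
ICC / ROC-AUC / DeLong / rank statistics. The conv-net engine (convolutions,
backpropagation, Adam) is implemented in the package with compiled kernels
and is verified by finite-difference gradient checks.

## Worked example

```r
library(adcgan)

# one paired phantom case: clean (zoomed-FOV-like) and degraded (full-FOV-like)
ph <- make_phantom(phantom_spec(), seed = 11)
z_adc <- fit_adc(ph$clean_dwi)      # reference-quality fit
f_adc <- fit_adc(ph$degraded_dwi)   # distorted arm

# lesion reading: mean ADC in a 0.5-0.8 cm^2 ROI at the lesion center
roi <- simulate_reader_rois(ph$masks$lesion, ph$spec$voxel_spacing,
                            c(0.5, 0.8), jitter_px = 1, seed = 1)
c(truth = mean(ph$true_adc$data[ph$masks$lesion]),
  z = roi_mean(z_adc, roi), f = roi_mean(f_adc, roi)) * 1e3
#>     truth         z         f
#> 0.6205654 0.6267707 0.6350106

# the degraded arm distorts the gland's anterior-posterior diameter
diameter_distortion(mask_from_adc(f_adc), ph$masks$prostate)$delta_ap  # mm
#> [1] 10.45
diameter_distortion(mask_from_adc(z_adc), ph$masks$prostate)$delta_ap
#> [1] 1.9
```

This case carries a malignant lesion with true ADC 0.62 x 10^-3 mm^2/s —
well below the benign ~0.98 level — and both fits read it to within a few
percent, but the full-FOV arm's anterior-posterior diameter error (10.5 mm)
is more than five times that of the clean arm (1.9 mm): the geometric
distortion the synthesis framework is built to remove.

The full study (phantom cohort -> ADC fitting -> classifier -> three GANs ->
synthesis -> metrics -> reader statistics -> report tables):

```r
report <- run_study(study_config("desk", seed = 1, out_dir = "study_out"))
report$metrics_summary   # RMSE/PSNR/SSIM/FSIM per method, incl. f-ADC baseline
report$roc               # AUCs per ADC set + DeLong comparisons
```

A thin CLI wraps the same functions: `adcgan study --profile desk --seed 1
--out study_out`, plus `phantom`, `fit`, `synthesize`, and `metrics` verbs.

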