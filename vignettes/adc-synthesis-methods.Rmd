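---
title: "Methods: GAN-based synthesis of zoomed-FOV-quality ADC maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GAN-based synthesis of zoomed-FOV-quality ADC maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Prostate diffusion-weighted imaging (DWI) acquired with full-field-of-view
(f-DWI) single-shot echo-planar readouts suffers from geometric distortion
along the phase-encode (anterior-posterior) direction, blur, and low SNR.
Apparent diffusion coefficient (ADC) maps fitted from such data inherit those
artifacts, which degrades both the geometry of the gland and the diagnostic
separation between benign and malignant lesions. Zoomed-FOV DWI (z-DWI)
largely avoids the distortion but needs dedicated hardware/software.

`adcgan` implements a supervised image-to-image translation framework that
learns to map a *single-b-value* f-DWI slice to an ADC map of zoomed-FOV
quality (an "s-ADC"), using z-ADC maps as references, and the complete
evaluation stack needed to judge such a model: ADC fitting, image-quality
metrics, a simulated-reader ROI protocol, and agreement/diagnostic
statistics. Because real paired acquisitions are not redistributable, the
package ships a seeded zonal prostate phantom simulator; the whole study runs
end-to-end on synthetic data.

## Model

The generator $G$ maps a normalized input slice $X$ (single-b-value f-DWI)
to a synthesized map $S = G(X)$; the discriminator $D$ scores $S$ against
real references $Y$ (normalized z-ADC). Both objectives are least-squares
GAN losses:

$$\mathcal{L}_D = \mathbb{E}\big[(D(Y)-1)^2\big] + \mathbb{E}\big[D(S)^2\big],
\qquad
\mathcal{L}_G^{adv} = \mathbb{E}\big[(D(S)-1)^2\big],$$

with expectations taken as means over all discriminator output scores of a
batch (the discriminator is fully convolutional, so its output is a score
map). A *multi-level verification* (MLV) term compares features of $S$ and
$Y$ extracted by a frozen benign/malignant recognition model $C$ at levels
$i \in \{0, 1, 3, 5\}$:

$$\mathcal{L}_G^{mlv} = \sum_{i} \theta_i \,\big\lVert C_i(S) - C_i(Y)\big\rVert_2^2,
\qquad
\mathcal{L}_G = \mathcal{L}_G^{adv} + \lambda_1 \mathcal{L}_G^{mlv},
\quad \lambda_1 = 0.1 .$$

Level 0 is the raw image itself, giving the generator direct pixel-wise
supervision; levels 1, 3, 5 index the conv-activation units of $C$. The
weights $\theta_i$ start at $1/4$ and are re-normalized once per epoch in
proportion to the previous epoch's mean per-level losses,

$$\theta_i^{(j)} = \frac{L_i^{(j-1)} + \varepsilon}{\sum_n L_n^{(j-1)} + \varepsilon},$$

so the worst-reconstructed level is pushed hardest. The per-level term is
the squared L2 norm of the feature difference (summed over feature elements,
averaged over the batch), exactly as the objective is written. This matters:
an alternative per-element mean would shrink the level-0 term to around
$10^{-2}$, and at $\lambda_1 = 0.1$ the generator would then see essentially
only the adversarial gradient — it learns to produce realistic-*looking*
maps with no per-case correspondence (near-zero inter-method agreement in
early experiments). With the squared-norm form the reconstruction term
dominates the objective and the adversarial term acts as a realism
regularizer, the balance typical of supervised image-to-image translation.
$\varepsilon = 10^{-8}$ guards the all-zero corner of the $\theta$ update.
A per-element-mean reduction remains available as an option for analysis.
Two ablations need no code changes: $\lambda_1 = 0$ is a pure least-squares
GAN, and a fixed uniform $\theta$ is an unweighted perceptual loss.

### Architectures

* **Generator** — `n_down` = 3 stride-2 convolutions (widths $w, 2w, 4w$),
  5 residual blocks at the bottleneck, then 3 upsampling "deconvolution"
  stages (nearest-neighbor upsample + convolution, which avoids checkerboard
  artifacts of strided transposed convolutions). Every convolution is
  followed by (non-affine) instance normalization and ReLU except the output
  stage, which uses a sigmoid so outputs live in the same [0, 1] normalized
  ADC units as the references. Inputs must be divisible by $2^3$.
* **Discriminator** — 5 convolutions (3 strided), leaky-ReLU, instance
  normalization except the first layer, linear 1-channel score map.
* **Recognition model** $C$ — a reduced VGG-style stack of five
  conv-ReLU units with max-pooling and a flatten + dense head, pre-trained
  with cross-entropy on labelled (benign/malignant) reference slices and
  then frozen. An early design with a global-average-pooling head failed to
  learn the task — the lesion occupies only a few percent of the slice and
  global pooling washes it out — so the standard VGG flatten head is used.

There is no deep-learning runtime in the package's environment, so the
networks, backpropagation, and the Adam optimizer are implemented in the
package (compiled im2col convolution kernels; everything else vectorized R).
Correctness rests on finite-difference gradient checks in the test suite,
which verify the full generator, discriminator, and MLV gradients.

Training uses Adam (default moments) at learning rate 0.001 for both
networks, batch size 5, and 50 epochs at full scale (224 x 224); one model
is trained per input b-value ($M_{50}, M_{1000}, M_{1500}$). The framework's
recipe fixes the rate, batch, and epochs but not the optimizer;
adaptive-moment gradient descent is the conventional choice. All
randomness (initialization, shuffling, splits) flows through explicit seeds;
two runs with the same seed produce identical loss histories.

## Phantom simulator

The simulator is the package's stand-in for the patient cohort and defines
the study conditions; it emulates, per 2-D axial case:

* **Anatomy** — a prostate ellipse (30 x 38 mm) containing an anterior
  transitional-zone ellipse and a peripheral-zone rim, plus an optional
  posterior lesion disc (default radius 6.5 mm, seeded lateral placement).
  Zone masks exclude the lesion. The background is air-like (negligible
  signal): a soft-tissue background medium was deliberately rejected because
  the Rician noise floor biases its fitted ADC into the prostate range on
  the low-SNR arm, which would make any image-based delineation of the gland
  meaningless.
* **Tissue ADC** — drawn once per case per tissue from
  $\mathcal{N}(\mu, \sigma)$ with $\mu$ (x $10^{-3}$ mm²/s) 1.43 (PZ),
  1.20 (TZ), 0.98 (benign lesion), 0.61 (malignant lesion) and SDs 0.17,
  0.16, 0.18, 0.11 — zoomed-FOV tissue values reported for prostate MRI —
  held constant
  within the tissue and modulated by a smooth ±5% texture field. S0 carries
  a ±10% smooth texture so a constant-intensity shortcut cannot invert it.
* **Signal** — mono-exponential decay $S(b) = S_0 e^{-b \cdot ADC}$ at
  $b = 50, 1000, 1500$ s/mm², with Rician magnitude noise
  $\sqrt{(S+n_1)^2 + n_2^2}$, $n_i \sim \mathcal{N}(0, (\sigma s_0)^2)$
  (2% of S0 for the clean arm).
* **Degraded (full-FOV) arm** — in order: a smooth random displacement
  field applied along the anterior-posterior (row) axis only, rescaled so
  its peak equals `max_displacement_px` (default 4 px — the magnitude is not
  published; the default is chosen so the AP-diameter penalty of the f-arm
  is clearly expressed while the gland stays recognizable); Gaussian blur
  (1.2 px); a 2x downsample/upsample resolution loss; and 3% Rician noise.
  Phase-encode-directed distortion is the EPI physics being imitated; no
  k-space simulation is attempted.

What the phantom does *not* emulate: 3-D anatomy, bladder/rectum signal,
susceptibility-induced signal pile-up, T2 shine-through, perfusion/kurtosis
deviations from mono-exponential decay, and scanner-specific intensity
scales. Passing tests therefore demonstrate that the framework's mechanics
(losses, adaptation, training dynamics, statistics) behave as specified on
controlled data — not that the model reaches clinical performance on real
prostate MRI.

## Evaluation stack

* **ADC fitting** — per-voxel ordinary least squares of $\ln S$ on $b$
  (the standard scanner reconstruction; unweighted, deterministic), signal
  floor $10^{-6} \max S$ before the log, output clipped to
  $(0, 4) \times 10^{-3}$ mm²/s.
* **Preprocessing** — bilinear resampling with
  $n_{out} = \mathrm{round}(n_{in} \cdot sp_{in}/sp_{out})$, symmetric
  center crop, bilinear rescale to the unified resolution, min-max or
  percentile normalization to [0, 1]. Affine alignment is an internal
  normalized-cross-correlation search (integer translation grid, then
  per-axis scale grid, then coordinate descent with shrinking steps) —
  deterministic, and validated by known-transform recovery. In the phantom
  study both arms share one grid by construction, so the study pipeline does
  not re-align them; the aligner has the external-tool contract for real
  data. Manual slice curation is replaced by a deterministic rule (keep
  slices by mask area) as a matter of reproducibility; in the 2-D phantom
  study every case is one slice.
* **Image quality** — RMSE and PSNR on jointly normalized intensities; SSIM
  with the original constants (11-tap Gaussian window, sigma 1.5,
  K1 = 0.01, K2 = 0.03, valid-window mean); FSIM from log-Gabor phase
  congruency (4 scales x 4 orientations, min wavelength 6, multiplier 2,
  sigmaOnf 0.55, k = 2 noise compensation) and Scharr gradient similarity
  with T1 = 0.85, T2 = 160 on a joint [0, 255] rescale. Metrics are
  computed per slice and then averaged; a PSNR of a perfect pair is
  reported as infinite and excluded from means with a count.
* **Diameter distortion** — the simulated reader measures the gland's AP/LR
  extent on each ADC map via `mask_from_adc()`: band threshold
  (0.4-1.95 x $10^{-3}$ mm²/s), a 3 x 3 majority filter (twice), and the
  center-connected component. No pre-smoothing: the background's
  zero-clipped noise would be biased upward into the tissue band by
  averaging.
* **Reader ROIs** — circular ROIs of 0.5-0.8 cm² (lesions) or ~0.45 cm²
  (zones), centered at the mask centroid plus seeded jitter, falling back
  to the deepest interior point when the centroid placement cannot contain
  the minimum area inside the mask eroded by one pixel; two readers, two
  repetitions.
* **Statistics** — single-measure ICC from two-way ANOVA mean squares in
  both common forms: ICC(A,1) (two-way random, absolute agreement; the
  conservative default for inter-method questions) and ICC(C,1) (two-way
  mixed, consistency), with 95% CIs from F-distribution bounds. AUC by the
  rank formulation with ties counted 1/2 and a DeLong variance CI; paired
  AUCs compared with the DeLong test on structural components. Mann-Whitney
  (exact for combined n <= 10 without ties), paired t, and Spearman wrap
  the standard R implementations. All p-values are two-sided.

## The study runner and its scale profiles

`run_study()` executes the full flow — cohort, ADC fitting, normalization,
classifier pre-training, one GAN per b-value, synthesis on held-out cases,
metrics, diameters, reader measurements, statistics — with per-stage
caching keyed by a configuration hash, so interrupted runs resume at stage
granularity and a fixed seed reproduces byte-identical report tables.

The `desk` profile (default) uses 60 training, 20 test, and 5 volunteer
cases at 64 x 64 (the ~61 mm field of view preserved by scaling the pixel
spacing), 20 epochs, and reduced widths (generator/discriminator 16,
recognizer 8); it completes in minutes on one CPU. The `paper` profile
(150/50/10 cases, 224 x 224, 50 epochs, full widths) is the same code path
at the full clinical-study scale. Test-suite fixtures use 32 x 48 px variants of the
same generator. The desk problem sizes are the package's chosen trade-off
between statistical resolution and a turnaround that allows the whole study
to be re-run routinely.

## Numerical choices and degenerate inputs

* Signal floor before the log fit; fitted maps clipped to the physiological
  range; all-zero voxels land at the clip floor and are counted.
* Normalization of references uses the fixed clip range
  $(0, 4)\times10^{-3} \mapsto [0,1]$, so synthesized maps de-normalize
  without dataset statistics.
* Constant images normalize to all zeros; a flat *fixed* image is an error
  for alignment (correlation undefined); a flat pair has FSIM 1 by
  convention, a single flat image against a structured one is an error.
* Ties: AUC counts ties 1/2; Mann-Whitney uses the tie-corrected normal
  approximation when exactness is unavailable; max-pooling routes gradients
  to the first maximal element.
* Degenerate DeLong variance with equal scores returns z = 0, p = 1;
  unequal AUCs with zero variance raise an error.
* ICC with zero between-subject variance returns 0 with a degeneracy flag.

## Known limitations

* The phantom's simplicity means quantitative desk-scale results (AUCs,
  ICCs, metric means) are not comparable to clinical patient values; only
  directions and mechanics are.
* The degraded arm's corruption (smooth warp, blur, resolution loss, noise)
  biases f-ADC values but is nearly homogeneous across cases, so it barely
  disturbs the *across-case ranking* of lesion ADC: f-ADC keeps essentially
  perfect benign/malignant discrimination on phantoms, unlike clinical
  full-FOV ADC, whose per-case heterogeneous artifacts (susceptibility
  pile-up, misregistration, motion) degrade it. The synthesized maps
  therefore cannot beat the f-ADC baseline on phantom AUC; what the phantom
  study does reproduce is the equivalence of synthesized and reference maps
  (non-significant DeLong difference) and the geometric and image-quality
  advantages over the f-ADC baseline.
* The recognition model is trained on phantoms, not ImageNet; with the
  published tissue SDs the benign/malignant distributions genuinely overlap
  (Bayes error around 10%), so its held-out accuracy is capped accordingly.
* The aligner is affine-only by design; the simulated distortion is
  deliberately non-affine, so alignment cannot (and is not expected to)
  undo it.
* Single-channel 2-D axial slices only; no 3-D context.
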