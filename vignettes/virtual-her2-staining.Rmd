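---
title: "Virtual HER2 staining: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual HER2 staining: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vstain)
```

## The problem

HER2 status in breast tissue is read from immunohistochemically (IHC)
stained sections: a brown DAB chromogen marks membranous HER2 expression
and a blue-purple hematoxylin counterstain marks nuclei. Chemical IHC
staining is slow, costly and variable. Virtual staining replaces it with
an image-to-image model: four autofluorescence (AF) channels captured from
the *unlabeled* section (DAPI, FITC, TxRed, Cy5 filter cubes) are
translated into a brightfield-equivalent HER2 image by a conditional
generative adversarial network. vstain implements that workflow end to
end — training-pair registration, the network and its losses, tiled
whole-slide inference, feature-based stain quantification, and the
statistics of a blinded reader study — together with a synthetic tissue
simulator that makes every stage testable without patient data.

## The conditional GAN

The generator is an attention-gated U-Net with four resolution levels.
Each down block is a two-convolution residual block (3×3 kernels, a 1×1
convolution on the residual path), a Leaky ReLU (slope 0.1) and a 2×2
max-pool; channel counts run (4, 64, 128, 256) → (64, 128, 256, 512). The
up path mirrors it with bilinear 2× upsampling; each up block gates its
encoder skip through an additive attention gate (two 1×1 projections to
half the skip width, ReLU, 1×1 to one channel, sigmoid) and concatenates
the gated skip with the upsampled tensor before a residual block; the
printed channel lists (1024, 1024, 512, 256) → (1024, 512, 256, 128)
count the tensor entering each block *from below*, i.e. before
concatenation — with a centre block mapping 512 → 1024 this is the only
accounting under which the sequences are mutually consistent. A final
residual block and a 3×3 convolution produce three linear output
channels; values are clipped to [0, 1] only at export. There are no
normalisation layers; all convolutions carry biases; weights are seeded
He-normal. The output bias is initialised at 1 (white), the transmittance
of bare glass, so early optimisation is not spent learning the
predominantly white background.

The discriminator maps an RGB image through an initial 64-channel
convolution and five residual blocks, each doubling channels and halving
resolution (the second convolution of each block has stride 2), then
global average pooling and two fully connected layers (512 hidden units —
the smallest conventional choice, as the reference description leaves it
open) to a single logit.

Training minimises

$$\ell_G = \alpha\,L_1^{smooth}(y, \hat y)
  - \lambda \log\frac{1 + \mathrm{SSIM}(y, \hat y)}{2}
  + \gamma\,\mathrm{BCE}(D(\hat y), 1), \qquad
  \ell_D = \mathrm{BCE}(D(\hat y), 0) + \mathrm{BCE}(D(y), 1)$$

with $(\alpha, \lambda, \gamma) = (10, 0.2, 0.5)$, smooth-L1 transition
$\beta = 1$, and SSIM constants $c_1 = 0.01^2$, $c_2 = 0.03^2$ (the
standard constants for a unit dynamic range; a printed source that lists
"0.012 and 0.032" is read as $0.01^2$/$0.03^2$, a typographic loss of
superscripts). The SSIM inside the loss uses *global* per-image statistics
— exactly the printed formula — while reported SSIM values use the
conventional sliding-window mode (11×11 Gaussian window, σ = 1.5); the
mode is always explicit. Optimisation is AdamW (learning rates $10^{-4}$
generator / $10^{-5}$ discriminator, weight decay $10^{-5}$ — the decay
coefficient is not pinned by the source and is configurable) with two
generator updates per discriminator update; "2:1" is read
generator-favouring, consistent with the weak adversarial weight
$\gamma = 0.5$. The best model is the checkpoint with minimal validation
MSE (ties resolve to the earliest step), validated on full tiles rather
than crops so selection reflects inference conditions.

All tensors are `[H, W, C, N]` R arrays; the convolution, pooling and
upsampling kernels run in single precision through a small reverse-mode
tape. Unit tests compare every kernel and every loss against
double-precision brute-force oracles.

## Registration of training pairs

AF stacks (before staining) and brightfield WSIs (after staining) of the
same section are first aligned globally: determinant-of-Hessian blob
keypoints at scales σ = 2, 4, 8 on representative channels (DAPI for AF,
inverted luminance for brightfield), normalised intensity-patch
descriptors, mutual-nearest-neighbour matching with a 0.85 ratio test,
and a RANSAC similarity fit refined by least squares on the inliers;
fewer than three inliers is a hard registration failure. Aligned slides
are cropped into co-located 1024-pixel tile pairs.

Local distortion is removed by block-matching elastic registration. A
direct cross-modality correlation is ill-posed, so a *style bridge* — a
reduced generator with the same architecture, trained supervised
(smooth-L1 + SSIM) and fine-tuned rather than retrained between rounds —
renders each AF tile in brightfield style first. Matching then proceeds
coarse-to-fine: at factors 4 and 2 small blocks (1/4 of the configured
block size) with a wide search capture large shifts; at full resolution
the block size is halved and then quartered over refinement passes with a
tight ±3-pixel search. The tight fine-scale radius matters: cellular
texture is quasi-periodic at the inter-cell spacing, and a wide
fine-scale search aliases onto the wrong cell. Block estimates more than
3 MAD from the field median are treated as mismatches and re-imputed from
neighbours; sub-pixel peaks come from a parabola fit clamped to ±0.5 px;
sparse estimates are interpolated from the true block-centre coordinates,
Gaussian-smoothed (σ = block/4), and composed across passes in the
pull-back convention. A final guarantee pass smooths the field until its
maximum local gradient is below 1 px/px, the fold-over limit. The
train–register loop repeats up to 5 rounds, stopping early when the
median residual block displacement falls below the tolerance (0.5 px
default) and halting with a warning if the residual grows on two
consecutive rounds. A cleaning pass flags pairs with post-registration
correlation < 0.5 or tissue fraction < 10% — an automated, reproducible
proxy for what is otherwise a manual review step.

Displacement fields use 0-based, pixel-centred (row, col) coordinates and
the pull-back convention `out(x) = img(x + f(x))`; recovered fields are
therefore compared against the *numeric inverse* of a synthetic
ground-truth warp. Accuracy claims are made where displacement is
observable: on textured regions. A field simply cannot be estimated on
featureless background, which is why the warp-recovery tests run on the
stroma-textured AF channel.

## Whole-slide inference

Inference tiles the AF WSI with a 64-pixel overlap, normalises each AF
channel by its training-time 0.1/99.9 percentile window (the policy
travels with the fitted model, since per-channel exposure differs),
applies the generator per tile and blends with raised-cosine feathering;
per-pixel weights are renormalised to sum to one, and edges flush with
the slide border keep full weight. Output values are clipped to [0, 1].

## Stain quantification

Brightfield images are unmixed by colour deconvolution in optical
density, $OD = -\log_{10}(\max(rgb, \varepsilon))$, with unit stain
vectors hematoxylin ≈ (0.650, 0.704, 0.286) and DAB ≈ (0.269, 0.568,
0.778) (the standard conventions; the third vector is the normalised
cross product) and negative densities clipped. Nucleus statistics apply
an Otsu threshold to the hematoxylin density, morphological opening with
a disk (radius 2 by default; EBImage supplies the morphology), a minimum
component area (30 px at tile scale) and 8-connected component counting —
8-connectivity is also why the labelling is implemented in the package's
own C++ rather than through `EBImage::bwlabel`, which is 4-connected.

Membrane quantification re-renders the DAB density alone as an RGB image
(Beer–Lambert with the other stains zeroed) — the natural reading of
"transform the separated DAB channel into HSV", which requires a colour
image — converts to HSV and thresholds the saturation channel at
s = 0.10, 0.12, …, 0.50. The area fraction versus s is the
*characteristic curve*; its trapezoidal integral is the AUC (maximum 0.4
by construction) and the largest 8-connected component fraction at
s = 0.25 is the *membrane connectedness*. PSNR uses peak 1 with a 100 dB
cap for identical images; SSIM and SSIM of the deconvolved DAB channel
(clipped to [0, 1]) use the windowed mode. Colour histograms are
normalised by total pixel count and smoothed with a Gaussian kernel
renormalised to unit mass.

## Blinded-study statistics

Whole-slide scores (0, 1+, 2+, 3+) from multiple readers are aggregated
into 4×4 confusion matrices (assigned × reference). Two summaries are
reported: the diagonal sum (correctly scored slides) and the weighted
off-diagonal error $\sum_{i \ne j} n_{ij}\,|i - j|$ with scores coded
0–3 — the only reading of "absolute off-diagonal errors" consistent with
a 36-evaluation modality in which 17 off-diagonal slides can carry an
error of 18. Agreement between modalities uses a two-sided Pearson
chi-square (no continuity correction) on a modality-by-category table;
the table layout is a policy (correct-vs-incorrect per modality by
default, assigned-score margins as an alternative) because the original
construction is not printed. The default layout depends only on the two
diagonal sums; on the bundled margins it gives the agreement value
χ²(1) with p ≈ 0.475 that the acceptance script recomputes. Quality scores (1–4 per
metric per ROI per reader, membrane clearness undefined on HER2-negative
ROIs) are compared by one-sided paired t-tests on d = virtual − IHC with
alternative mean d < 0 ("IHC better"); all-zero differences give the
uninformative p = 0.5, constant nonzero differences the degenerate limit
0 or 1. The ROI harness samples seeded, tissue-constrained ROIs at
identical coordinates in both modalities — 12 paired WSIs × 10 ROIs × 2
modalities = 240 patches at study scale.

Because the original pathologists' record-level tables are not publicly
available, the package ships a clearly labelled *synthetic* stand-in
(`inst/extdata/synthetic_scores_*.csv`) constructed to match the study's
printed marginal summaries exactly (36 evaluations per modality; diagonal
sums 22 and 19; weighted off-diagonal errors 14 and 18). The stats module
treats any such table purely as input.

## The synthetic tissue simulator

`generate_latent()` places cells by seeded dart throwing (minimum
separation 20 px), with nucleus radii uniform in 4–7 px, a membrane ring
centred 2.5 px outside the nucleus, and a smooth stromal field. The
grade model maps the diagnostic phenotypes onto testable knobs:

| grade | stained cells | complete rings | ring completeness | DAB OD | thickness |
|------:|--------------:|---------------:|------------------:|-------:|----------:|
| 0     | 0             | 0              | —                 | 0      | —         |
| 1+    | 40%           | 2%             | 0.15–0.45         | 0.15   | 1.2 px    |
| 2+    | 50%           | 30%            | 0.50–0.85         | 0.40   | 1.6 px    |
| 3+    | 80%           | 60%            | 0.60–0.90         | 0.90   | 2.2 px    |

Complete-ring counts are assigned as exact rounded counts, so the
">10% of cells with complete membranous staining" criterion for 2+/3+
holds by construction, and grade-0 tiles carry no membrane stain at all.
`render_pair()` renders the IHC member by Beer–Lambert from hematoxylin
density on nuclei (peak OD 0.7) and DAB density on membranes (plus a
faint cytoplasmic DAB term at 2+/3+, echoing the dim cytoplasmic staining
of strongly positive tumours); unstained pixels render exactly white. The
four AF channels are saturating mixtures `1 − exp(−2.2·mix)` of the
latent maps plus seeded Gaussian noise (σ = 0.02; Poisson shot noise is
available but off — the source is silent on AF noise, and additive
Gaussian is the conservative default for averaged sCMOS exposures). DAPI
weights nuclei, FITC stroma/cytoplasm, TxRed cytoplasm, and Cy5 carries a
membrane-proportional signal, so the AF → IHC map is single-valued across
grades. This encodes the premise of the whole method — that HER2
expression leaves an autofluorescence signature. It is deliberately a
*stronger* premise than real tissue offers: real AF membrane contrast is
subtler and confounded, so a passing desk-scale study shows the pipeline
can learn and quantify the mapping it is given, not that label-free HER2
prediction works clinically. Other idealisations: cells are circular,
non-overlapping and single-scale; there are no staining artifacts, folds
or out-of-focus regions; the IHC render is noise-free.

## Desk-scale study conditions

The bundled study that stands in for full-scale training runs the
reduced network (all channel counts divided by 8) on 200 synthetic
128-pixel pairs (50 per grade, 10 tiles per pseudo-patient, 20
patients), split 80/10/10 by patient, trained for 2500 generator updates
on 64-pixel crops with batch 4, and evaluated on the held-out patients by
windowed SSIM, plus the grade ordering of the membrane characteristic
AUC on freshly simulated tiles stained by the fitted generator. These
sizes are the package's chosen desk-scale conditions; the full-scale
schedule (256-px crops, batch 28, tens of thousands of steps on >20,000
patches) is what the defaults of `train_control()` document.

One training detail is added at desk size: adaptive adversarial
balancing (`adaptive_adv = TRUE`). In a short schedule the discriminator
is still close to its random initialisation, so its term in the
generator loss acts as a noise force whose magnitude does not shrink as
the reconstruction converges; on unlucky seeds it visibly destabilises
training (validation MSE oscillates, backgrounds acquire texture).
Capping the adversarial gradient at the reconstruction gradient's norm —
both measured at the generator output, the same adaptive-weight device
used by perceptual-adversarial models such as VQGAN — ties the
adversarial push to the remaining reconstruction error and restores
monotone convergence on every seed tried, while leaving the loss
definition, its weights and the 2:1 update schedule untouched. The
full-scale schedule (where the discriminator has hundreds of thousands
of updates to become a real adversary) does not need the cap, and
`train_control()` leaves it off by default.

```{r desk-scale}
pairs <- synth_dataset(n_per_grade = 50, tiles_per_patient = 10,
                       geometry = her2_geometry(height = 128, width = 128),
                       seed = 11)
fit <- fit_virtual_stainer(pairs,
  gen_cfg = generator_config(scale = 8),
  disc_cfg = discriminator_config(scale = 8),
  control = train_control(crop = 64, batch = 4, max_steps = 2500,
                          adaptive_adv = TRUE, seed = 5))
print(fit)
plot(fit)
```

## Numerical choices and degenerate inputs

* Seeds: every stochastic step (simulation, splitting, crop sampling,
  RANSAC, weight init) draws from R's RNG under an explicit seed and
  restores the caller's RNG state; identical inputs give bit-identical
  outputs.
* Warping: bilinear pull-back with replicate-edge fill by default;
  nearest-neighbour for label images; constant images are preserved and
  outputs never leave the input value range (interpolation is convex).
* Otsu on a constant channel, registration of a featureless image, empty
  checkpoint lists, sub-minimum patient counts and mismatched shapes all
  raise immediate, message-bearing errors rather than propagating NaNs.
* Zero-variance t-tests: p = 0.5 when all differences are zero, else the
  degenerate 0/1 limit by sign.
* Chi-square tables drop zero-margin categories with a message, and warn
  when expected counts fall below 5.
* The smooth-L1/BCE implementations are numerically stable for logits up
  to at least 1e4; SSIM of two constant images is exactly 1.

## Known limitations

* The simulator's AF–IHC link is idealised (see above); desk-scale
  success is a software validation, not a biological one.
* Elastic registration reports displacement only where texture exists;
  on blank background the field is an interpolation.
* The full-scale (scale = 1) networks are instantiable and run forward
  on CPU, but training them is out of scope here.
* The chi-square layout and the reference scoring of real slides are
  inputs/policies, not reproductions of the original study's private
  data.
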