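# vstain — label-free virtual HER2 immunohistochemistry in R

HER2 (human epidermal growth factor receptor 2) status guides breast
cancer treatment and is read from immunohistochemically stained tissue:
brown membranous DAB staining scored on the four-level HercepTest scale
(0, 1+, 2+, 3+) against a blue hematoxylin nuclear counterstain. Chemical
IHC staining takes a day per slide, needs a histotechnology lab, and
fails often enough that a substantial fraction of slides must be
discarded. **Virtual staining** replaces the chemistry with computation:
a conditional generative adversarial network translates four
autofluorescence channels (DAPI, FITC, TxRed, Cy5) captured from the
*unlabeled* section into a brightfield-equivalent HER2 image.

vstain is a complete R implementation of that workflow, aimed at
computational-pathology researchers who want every stage inspectable and
testable on a desk:

* **synthetic tissue simulator** — seeded paired tiles (AF stack + IHC
  render + ground-truth masks) with grade-dependent membranous staining,
  so the entire pipeline runs without patient data;
* **registration** — feature-based global alignment (blob keypoints +
  RANSAC similarity), 1024-px tile pairing, and style-bridge-assisted
  pyramid block-matching elastic registration with an iterated
  train–register refinement loop;
* **network** — attention-gated U-Net generator (channel lists
  4,64,128,256 / 64,128,256,512 down and 1024,1024,512,256 /
  1024,512,256,128 up), residual CNN discriminator, and the composite
  loss

  ℓ_G = α·smoothL1(y, ŷ) − λ·log((1 + SSIM(y, ŷ))/2) + γ·BCE(D(ŷ), 1),
  ℓ_D = BCE(D(ŷ), 0) + BCE(D(y), 1)

  with (α, λ, γ) = (10, 0.2, 0.5), trained by AdamW at a 2:1
  generator:discriminator update ratio (the tensor kernels and
  reverse-mode tape are part of the package, in Rcpp/RcppArmadillo);
* **inference** — tile-wise staining of whole-slide images with
  raised-cosine feathered stitching;
* **metrics** — hematoxylin/DAB colour deconvolution, nucleus counts and
  areas (Otsu + morphology + 8-connected components), the membrane
  characteristic curve (saturation-threshold sweep s = 0.10…0.50), its
  AUC, membrane connectedness, PSNR/SSIM/SSIM_DAB and colour histograms;
* **statistics** — 4×4 HER2 confusion matrices with diagonal and
  weighted off-diagonal summaries, two-sided chi-square agreement tests,
  one-sided paired t-tests on reader quality scores, and the seeded
  paired-ROI sampling harness.

## Worked example

Simulate a grade-mixed cohort, fit the desk-scale stainer (all channel
counts divided by 8), and quantify its output:

```r
library(vstain)

pairs <- synth_dataset(n_per_grade = 50, tiles_per_patient = 10,
                       geometry = her2_geometry(height = 128, width = 128),
                       seed = 11)
fit <- fit_virtual_stainer(pairs,
  gen_cfg  = generator_config(scale = 8),
  disc_cfg = discriminator_config(scale = 8),
  control  = train_control(crop = 64, batch = 4, max_steps = 2500,
                           adaptive_adv = TRUE, checkpoint_every = 250,
                           seed = 5))
print(fit)
#> Virtual HER2 stainer (conditional GAN)
#>   generator: attention U-Net, 898,035 parameters (scale 1/8)
#>   trained: 2500 generator / 1250 discriminator updates
#>   best checkpoint: step 2500, validation MSE 0.00531
#>   split: 160 train / 20 val / 20 test tiles (patient-disjoint)
```

The fitted object is a regular S3 model with `print`, `summary`,
`coef`, `plot` (loss and model-selection curves) and `predict` methods.
Staining a held-out tile and scoring it:

```r
id  <- fit$split$test_ids[1]               # "g0_t011", a held-out grade-0 tile
out <- predict(fit, pairs[[id]]$af)        # [128, 128, 3] in [0, 1]
ssim(out, pairs[[id]]$ihc, mode = "window")
#> [1] 0.8945892

cs <- membrane_stats(separate_stains(out))
cs$auc                                      # membrane characteristic AUC
#> [1] 0.0008618164
```

Windowed SSIM well above 0.8 against the rendered ground truth (0.89
averaged over the 20 held-out tiles of this run) means the generator
reproduces nuclei and membrane rings of unseen patients; the membrane
characteristic AUC of its outputs rises monotonically with the HER2
grade of the input tile (0.00053, 0.00079, 0.0040, 0.0361 for grades 0
to 3+ in this run), the feature-based readout used to compare virtual
and chemical staining. The blinded-study arithmetic runs on long-form
score tables:

```r
scores <- read_score_records(system.file("extdata",
  "synthetic_scores_wsi.csv", package = "vstain"))
confusion_summaries(build_confusion(scores, "virtual"))
#> diag_sum weighted_offdiag_error
#>       22                     14
confusion_summaries(build_confusion(scores, "ihc"))
#> diag_sum weighted_offdiag_error
#>       19                     18
```

(The bundled table is a synthetic stand-in whose marginal summaries match
the published reader study; see the vignette.)

A thin command-line front end with `simulate`, `register`, `train`,
`stain`, `evaluate` and `stats` subcommands is installed under
`inst/scripts/vstain`.

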