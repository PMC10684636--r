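---
title: "Privacy-preserving federated transfer learning for direct PET attenuation and scatter correction: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fedasc methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Quantitative whole-body PET requires attenuation and scatter correction
(ASC), conventionally derived from a co-acquired CT. In
^68^Ga-PSMA/DOTA-TATE imaging this CT-based correction is the step where two
notorious artefacts enter: *halo* artefacts — photopenic rings around very
hot structures (bladder, kidneys) caused by scatter over-correction under a
non-negativity constraint — and *mismatch* artefacts — bands of over- or
under-correction at the lung-diaphragm interface when the emission data and
the CT disagree spatially. A network that maps the *uncorrected* (non-ASC)
image directly to the corrected (CT-ASC) image sidesteps the CT entirely:
since both artefacts live in the corrected image and not in the network
input, a model trained on artefact-free pairs reproduces a clean corrected
image even when the clinical CT-ASC image is artefacted. That is the
disentanglement mechanism this package studies.

Because multi-centre clinical data cannot be pooled freely, the package
compares three training regimes on a synthetic multi-centre cohort:

* **CeBa** (centre-based): each centre trains alone on its own data;
* **CeZe** (centralized): all data pooled at one site;
* **FTL** (federated transfer learning): differentially private federated
  averaging builds a global model without moving images, which is then
  fine-tuned per centre into personalized models.

## The synthetic cohort

No clinical images ship with the package; the `synthetic_cohort` module
generates a cohort whose *structure* mirrors an 8-centre ^68^Ga study:
per-centre matrix sizes (180, 168, 256, 440, 168, 200, 192, 192), seven
PSMA centres and one DOTA-TATE centre, and per-centre clean-image counts
(16, 71, 49, 49, 51, 57, 89, 39; 421 in total). Each patient is a 2-D
coronal phantom (the training is 2-D) built from parameterized ellipses:
body, photopenic lungs, liver, spleen (hot only under DOTA-TATE, reflecting
somatostatin-receptor physiology), hot kidneys, hottest bladder, and 0-3
random lesions. Geometry by ellipse keeps every organ area analytically
checkable.

The reference CT-ASC image is the blurred phantom (Gaussian PSF of
per-centre FWHM, mask-renormalized so activity is redistributed inside the
body rather than smeared into background); the non-ASC image is the same
activity multiplied by a smooth attenuation-suppression field

\[ A(x, y) = \exp(-\mu_{\text{eff}}\, d(x, y)), \]

with \(d\) an effective tissue depth (in mm) that grows toward the body
centre and is reduced inside the lungs (air attenuates less). Defaults:
\(\mu_{\text{eff}} = 0.008\,\mathrm{mm}^{-1}\), pixel spacing 4 mm, lung
relief 0.6. \(A \in (0, 1]\), so non-ASC \(\le\) CT-ASC pixelwise in the
noiseless limit — the package's "attenuation realism" invariant. Noise is
Gaussian with SD proportional to \(\sqrt{\text{intensity}}\)
(Poisson-flavoured variance scaling), applied independently to both images.

Artefact injectors operate on clean pairs only and record exact masks:

* `inject_halo()` multiplies CT-ASC by \(1 - s\,K(x,y)\) with \(K\) a
  triangular annular kernel (peak 1 at the annulus mid-radius) centred on
  the hottest organ; default severity 0.6, annulus from 1.3 organ radii
  outward, width 8% of the matrix. The non-ASC input is untouched — the
  halo is a *correction* artefact.
* `inject_mismatch()` recomputes the correction with the diaphragm boundary
  of \(A\) displaced by `shift_px` rows (default 4), producing a band of
  exactly `|shift_px|` rows per affected column.

What the generator deliberately does **not** emulate: 3-D geometry,
sinogram/reconstruction physics, true scatter kernels, CT synthesis,
anatomical variability beyond ellipse parameters and lesions. Tests passing
on this cohort show the *pipeline and mechanisms* work under controlled
heterogeneity; they say nothing about clinical image quality, and the
clinical headline numbers of multi-centre studies are out of reach of a
phantom study by construction.

## Preprocessing

The chain mirrors clinical practice for ^68^Ga quantification: activity
(Bq/ml) is converted to SUV with the decay-corrected injected dose
(`SUV = activity * weight / (dose * 2^(-delay/T½))`, tissue density
1 g/ml, ^68^Ga half-life 67.71 min); images are cropped to the body contour
(largest connected component above 1% of max on the non-ASC image; the same
box is applied to both roles so the pair stays co-registered); zero-padded
to a common bounding box (232 x 168 at clinical scale, 64 x 48 in the
desk-scale studies — padding only, never resampling); and normalized by
fixed divisors, 2 SUV for non-ASC and 5 SUV for CT-ASC, then clipped to
[0, 1]. The divisors are chosen so that roughly 90% of intensities land
below 1; the clipped fraction is recorded per image, and clipping is the
one non-invertible step of `denormalize_suv()`.

Splits are per centre: `floor(0.8 n)` training share (the remainder is the
test set) and `floor(0.1 |share|)` of the share held out for validation,
drawn *inside* the 80% share. Applied to the 8-centre clean counts this
yields training shares (12, 56, 39, 39, 40, 45, 71, 31) — 333 training and
88 test images, which is the package's exactly reproducible arithmetic
check. `floor` is the unique rounding consistent with all eight counts.

## The network

The regressor is a compact nested-U encoder-decoder with residual U-blocks
and deep supervision, written against the package's own reverse-mode tape
(see below). Each stage is a residual U-block: an input
conv-batchnorm-ReLU, an inner encoder/decoder of depth `rsu_inner_depth`
with 2x2 max pooling and nearest upsampling, and a residual skip around the
block. Decoder stages concatenate the upsampled deeper features with the
encoder skip. Every decoder stage (and the deepest encoder) emits a
1-channel side output upsampled to input resolution; a 1x1 convolution
fuses the side maps into the final output. All outputs pass a clamp to
[0, 1], matching the normalized targets; the output-head biases start at
0.25, mid-range. The loss is the mean squared error of the fused output
plus, under deep supervision, the MSE of every side output with equal
weights. Training attaches the L2 terms to the *pre-clamp* values: for
targets inside [0, 1] this has the same optimum, and it removes the hard
clamp's dead zero-gradient region — without it, an unlucky initialization
can permanently silence most of the image (we observed >80% of body pixels
stuck at exactly 0 for one seed in four). An optional global gradient-norm
clip (`grad_clip`) is available as a further stabilizer at higher learning
rates.

Optimization is Adam (lr 0.001, the standard setting for this family of
direct-ASC models) with decoupled weight decay 0.0001 and optional cosine
annealing. Batch-norm running statistics are frozen at inference and travel
inside the flat parameter vector as *non-trainable* entries: they are
averaged without noise during federation and excluded from DP clipping — a
documented privacy caveat, and the standard answer to the
FedAvg-with-batch-norm pitfall (naively averaging activations statistics
under noise destroys them).

Inputs are padded internally to a multiple of \(2^{S + L - 2}\) (stages
\(S\), inner depth \(L\)) and cropped on output. Desk-scale default:
\(S = 3\), 8 channels, \(L = 2\); the benchmark studies use \(S = 2\),
8 channels, \(L = 2\), about 6k parameters. Receptive field matters more
than parameter count here: the attenuation factor at a pixel depends on its
depth from the body surface, so the network must "see" the body contour
from the deepest tissue; inner-block pooling (\(L = 2\)) is what buys that
at 64 x 48.

### Why a hand-built tape

No deep-learning framework is part of the package's dependency footprint.
The tape stores every feature map as a `(pixels * batch) x channels`
matrix; 3x3 convolution is a cached-index gather plus one BLAS matrix
product (im2col), pooling/upsampling are integer row gathers, and backward
passes are the standard adjoints. Gradients are verified against central
finite differences in the test suite (relative error < 1e-7). On one CPU a
training epoch over 16 images at 64 x 48 with the benchmark network takes
on the order of a second.

## Federated learning and differential privacy

One round of DP-FedAvg: the server broadcasts the global parameters; each
centre runs `local_epochs` of local training *continuing its own Adam
moments and shuffle stream across rounds*; updates \(\Delta_k\) are
L2-clipped to \(C\); the server forms \(\sum_k w_k \Delta_k\) plus
Gaussian noise of SD \(z\, C\, \max_k w_k\) per trainable coordinate, and
steps the global model. Weights default to `by_n` (weighted federated
averaging). With DP disabled the server computes the exact weighted
parameter average \(\sum_k w_k \theta_k\) — algebraically the same thing,
and in the single-client limit *bitwise* equal to centralized training,
which the test suite asserts as the FedAvg-centralized consistency check.

Privacy accounting uses Gaussian differential privacy: with replace-one
client adjacency the per-round sensitivity is \(\max_k w_k\, C\) against
noise SD \(z\, C \max_k w_k\), so each round costs \(\mu = 1/z\)
independent of \(C\) and the weights; rounds compose as the root sum of
squares (\(\mu_{\text{tot}} = \sqrt{R}/z\) for \(R\) uniform rounds), and

\[ \delta(\varepsilon) = \Phi(-\varepsilon/\mu + \mu/2)
   - e^{\varepsilon}\,\Phi(-\varepsilon/\mu - \mu/2). \]

Client subsampling amplification is deliberately not modelled: with a
handful of hospitals every client participates in every round. Disabling DP
yields an explicit "no guarantee" spend object, never a silent
\(\mu = \infty\). All clients run in one process — faithful to the
single-server compute model such studies actually use.

After the federated rounds, each centre fine-tunes the global model on its
own data at a scaled learning rate (default 0.1x; the benchmark uses 0.3x,
which suits its short schedules), keeping the checkpoint with the lowest
validation loss (the unmodified global model is a candidate, so fine-tuning
can never worsen the validation loss).

The exact DP constants of any given clinical deployment (clip norm, noise
multiplier, rounds) are configuration, not claims; the benchmark default
(\(C = 3\), \(z = 0.1\)) keeps the mechanism exercised end-to-end with a
deliberately weak formal guarantee, because at 6k parameters and 15 images
per centre strong noise would swamp the signal — the privacy-utility
trade-off is the user's dial, reported via the accountant.

## Metrics and statistics

MAE, MSE, SSIM and PSNR are computed inside the body mask (background zeros
would flatter every metric), in both the normalized and the SUV domain
(MAE scales by the 5-SUV divisor between them when nothing clipped). PSNR
uses the reference dynamic range; SSIM uses an 11-pixel Gaussian window
(SD 1.5, stabilizers \(k_1 = 0.01\), \(k_2 = 0.03\)) on the *joint* range
of the two images — the joint range keeps SSIM symmetric in its arguments,
which the package treats as an invariant. Group summaries report
mean ± SD with a normal-approximation 95% CI
(\(\bar{x} \pm 1.96\, s/\sqrt{n}\)).

The statistics module implements the comparison machinery such studies
report: a paired Wilcoxon signed-rank test (exact mode enumerates the full
sign-assignment null via convolution over the — possibly tied, averaged —
ranks; approximate mode uses the tie-corrected normal approximation with
continuity correction), Benjamini-Hochberg step-up q-values, ICC from a
two-way mixed-effects ANOVA decomposition (single-rater consistency
ICC(3,1) by default, absolute agreement as an option, labels poor/fair/
good/excellent at 0.40/0.60/0.75), an exact-binomial McNemar test, and the
Stuart-Maxwell marginal homogeneity test (generalized-inverse chi-square;
reduces exactly to the McNemar chi-square at K = 2). Five-point ratings are
dichotomized at score >= 4 ("high") into paired 2x2 tables per region and
category. Where base R provides the same computation (`wilcox.test`,
`p.adjust`, `mcnemar.test`, `aov`), it serves as an independent oracle in
the tests rather than the implementation, so each route checks the other.

## The desk-scale studies and their sizes

Two canonical experiments are exported so that tests and the acceptance
script run the same code:

* `scenario_benchmark()`: per seed, a fresh heterogeneous three-centre
  cohort (20 clean patients per centre, 64 x 48, distinct blur/noise/
  tracer), CeBa vs FTL with matched training budgets (CeBa gets
  `n_rounds + fine_tune_epochs` local epochs; FTL spends the same split
  between federated rounds and fine-tuning). Across five seeds the median
  test MAE of FTL should not exceed CeBa's: the federation sees three times
  the data of any single centre and personalization recovers
  centre-specific character, which is precisely the argument for FTL over
  CeBa.
* `halo_benchmark()`: one centre, 16 clean training pairs, 100 epochs,
  then 12 halo-injected patients; the score is the MAE reduction inside
  the halo annulus relative to the artefacted corrected image, with the
  noise-free pre-artefact image as truth.

The problem sizes (64 x 48 pixels, ~6k parameters, 15-16 training images
per centre, 5 seeds) are chosen so the full suite runs on a single CPU in
tens of minutes while leaving every mechanism — heterogeneity, federation,
DP noise, personalization, artefact disentanglement — genuinely exercised.

## Numerical choices and degenerate inputs

* Clamp gradients: zero outside (0, 1) (measure-zero boundary irrelevant).
* Max-pool ties break toward the earliest corner of the 2x2 block.
* `crop_to_body` on an all-zero image, metrics on an empty mask, Wilcoxon
  with all-zero differences, McNemar with no discordant pairs, and
  Stuart-Maxwell on diagonal tables all raise typed degenerate-input
  errors rather than returning numbers.
* PSNR of a perfect reconstruction is reported as `+Inf`, never clipped.
* `pad_to_box` refuses inputs larger than the target (no silent resizing).
* Exact Wilcoxon doubles the ranks so tied average ranks become integers;
  the convolution is over at most `n(n+1)` cells, exact for n <= 30.

## Known limitations

* The phantom is 2-D and piecewise-constant; the attenuation field is a
  monotone surrogate, not a line-integral; scatter is not simulated
  beyond its artefactual signature.
* DP accounting covers trainable parameters only; batch-norm running
  statistics are shared un-noised.
* The qualitative reader study that motivates the rating statistics cannot
  be reproduced without human raters; the stats module is exercised on
  synthetic ratings with known properties instead.
* Single-process federation ignores communication cost, stragglers and
  client failures.
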