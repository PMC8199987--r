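---
title: "Model inversion attacks on 3D segmentation networks: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model inversion attacks on 3D segmentation networks: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Encoder–decoder segmentation networks compress an input volume $X$ into a
latent representation $Z = \mathrm{Enc}(X)$ — the most condensed description
of the image inside the network — before a task decoder expands $Z$ into a
segmentation $Y = \mathrm{Dec}(Z)$. If an attacker can observe latent codes
of the images a published model was trained on (a white-box scenario that is
realistic for many publicly released medical-imaging models), they can train
their *own* decoder $\hat D$ on an independent image database and use it to
reconstruct the private training images: $\hat X = \hat D(Z)$. A successful
reconstruction of a brain MRI is a privacy breach: subjects can potentially
be re-identified from their anatomy.

`segrecon` implements this attack end to end for two standard 3D
architectures — a U-Net (encoder–decoder with skip connections) and a
SegNet-style network (same encoder–decoder, no skip connections) — together
with four ways of quantifying attack success, and a synthetic cohort
generator that lets the entire study run on a desktop CPU in minutes.

## The attack

The target model is trained for 3-class brain-tissue segmentation (a gyral
ribbon, deep grey matter, remaining brain tissue; background is an explicit
fourth softmax class because whole padded volumes are segmented). The
attacker then:

1. freezes the encoder (an id-audited contract in `run_attack()`: the
   encoder parameters are compared bit-exactly before and after);
2. trains the inversion decoder on the attacker cohort only, minimizing the
   mean squared reconstruction error
   $L = \mathbb{E}_{X \in X_\mathrm{attack}} \lVert \hat D(\mathrm{Enc}(X)) - X \rVert^2$;
3. reconstructs each private subject from its latent code. Following the
   study's threat model, private latent codes are assumed given; inferring
   them from segmentation confidences is out of scope.

The cross-validated design partitions the cohort so each subject is private
in exactly one fold (by default 4 folds of 4 private / 12 attacker subjects);
across folds every subject is reconstructed exactly once, which makes the
identification matrices square.

## The synthetic cohort

The generator (`phantom_params()`, `generate_cohort()`) emulates the
statistical structure the study depends on, not MRI physics:

* a smoothly deformed ellipsoidal brain whose surface band — thresholded
  from a sinusoidally modulated distance-to-surface function — plays the
  role of the folded cortical ribbon; interior Gaussian bumps play deep grey
  matter; the rest of the ellipsoid is the third tissue class;
* per-subject identity through a smooth random warp (white noise smoothed at
  $\sigma = g/8$ voxels, rescaled to a per-component SD of `deform_sigma`,
  default 1.5 voxels at $g = 32$): subjects share anatomy yet are mutually
  distinguishable, exactly what the re-identification experiment requires;
* a multiplicative bias field (smoothed white noise normalized to a peak
  relative deviation `bias_amplitude`, default 0.2) and additive Gaussian
  noise (`noise_sigma`, default 0.02 on class means of order 0.5);
* optionally a bright skull/scalp shell, so the "skull-stripped vs
  with-skull" contrast — how much of the imaged head the model actually
  segments — can be studied without a stripping algorithm.

Intensity means default to grey-matter-dark / white-matter-bright
(gyri 0.55, deep grey 0.40, remainder 0.85, skull 1.15, arbitrary units),
qualitatively like T1-weighted contrast. All anatomy fields are closed-form
functions of the (warped) coordinates, so labels are exact, regeneration is
bit-identical given the seed, and with noise and bias disabled every tissue
class is exactly piecewise-constant — which is what makes the generator
usable as ground truth for the preprocessing estimators.

What the phantoms do *not* emulate: Rician noise, partial-volume voxels,
scanner-specific artefacts, real cortical topology, pathology. Passing tests
on phantoms therefore demonstrate that the pipeline's mechanics and its
relative orderings (true vs other subjects, skull-stripped vs with-skull,
original vs reconstruction) behave as the attack theory predicts — not that
absolute scores transfer to real MRI databases.

## Preprocessing

* **Padding**: zero-padding to dimensions divisible by $2^\mathrm{depth}$
  (e.g. a 181×217×181 scan padded to 224³ for a depth-4 network), split
  evenly with the extra voxel trailing, and recorded so cropping back is
  bit-exact.
* **Bias-field correction**: a classify-and-correct surrogate — cluster the
  log-intensities inside the brain mask into three tissue classes
  (deterministic Lloyd iterations seeded at spread quantiles), subtract the
  per-class log-mean, and take the heavily low-passed (Gaussian,
  FWHM = half the image extent, mask-weighted) residual as the log bias
  field; five estimate-and-divide passes; total gain fixed so the mean
  intensity in the mask is unchanged. On bias-free images the residuals
  vanish and the correction is neutral to well under 1%. The generator's
  stored true field validates the estimator (residual field within 10%
  for an injected 30% bias).
* **Normalization**: the 1st/99th percentiles inside the brain mask mapped
  to [0, 1] with clipping. Chosen because it is monotone, robust to
  outliers, invariant to affine intensity changes, and it fixes the SSIM
  `data_range` at 1 for every subject.
* **Label fusion**: an explicit lookup table (with an error naming any
  unmapped label) collapses fine-grained structures to the study's classes;
  in the with-skull condition the shell is fused into background, so the
  segmentation task covers a smaller fraction of the head.
* The brain mask is taken from labels 1–3; no skull-stripping algorithm is
  included by design.

## Networks and training

Both architectures share the encoder: `depth` blocks of (3³ convolution,
ReLU, 2×2×2 max pooling) with `base_filters` filters doubling per block, so
the latent code has `base_filters`·2^(depth−1) channels on a grid
`2^depth`-fold smaller per axis. The decoder mirrors this with
nearest-neighbour upsampling followed by convolution (avoiding
transposed-convolution checkerboards); the U-Net concatenates the matching
encoder feature map before each decoder convolution, the SegNet-style
variant does not — the retained architectural difference is exactly the
skip connections. Only pooling factor 2 is supported; the layer arithmetic
is otherwise fully parameterized (the full-scale 16-filter depth-4 / 224³
configuration is expressible, the desk-scale default is 4 filters at
depth 2 on 32³).

Training choices (unspecified in the underlying experimental design, fixed
here once): voxel-wise cross-entropy over background + 3 tissue classes;
Adam, volume-at-a-time updates; learning rate 5·10⁻³ for the small
segmentation nets (25 epochs) and 10⁻³ for the inversion decoder (30
epochs). The inversion decoder holds out 20% of the attacker cohort for
early stopping (patience 8, best weights restored) to keep desk-scale runs
stable. The inversion decoder uses a *leaky* rectifier (slope 0.01): with
plain ReLU a small decoder whose every gradient passes through few channels
can die wholesale in the first epochs and collapse to predicting the cohort
mean; a leaky slope removes that failure mode without otherwise changing
the architecture. Its final convolution is linear. A depth-0 (purely
linear) decoder variant exists for analysing invertible linear encoders,
where the optimum is known in closed form and training recovers it to
machine precision.

All stochastic choices flow from one master seed through a fixed derivation
tree (cohort, folds, per-fold initialization and shuffling seeds), so a
full `run_experiment()` is bit-reproducible; the compiled kernels are
single-threaded and allocation-deterministic.

## Metrics

* **SSIM**: cubic uniform window of side 7 (tractable in 3D), standard
  constants $C_1 = (0.01 r)^2$, $C_2 = (0.03 r)^2$ with $r = 1$ after
  normalization; local statistics are border-normalized so partial windows
  use the voxels they cover. Identical volumes score exactly 1; two
  constant volumes 0 and 1 score the closed-form $C_1/(1+C_1)$.
* **Intensity correlation** (`intensity_correlation()`): Pearson
  correlation of grey levels inside a mask. The reconstruction literature
  often labels this score "MCC"; the Matthews correlation coefficient
  proper is a binary-classification quantity that does not apply to grey
  levels, so the continuous cross-correlation is what is implemented, with
  the naming conflict noted in the documentation.
* Both similarity metrics are evaluated on the *union* of the two subjects'
  brain masks: padded background would otherwise inflate similarity.
* **Deformation magnitude**: after two-phase registration (below), the mean
  Euclidean norm (mm) of the non-linear displacement field; smaller = more
  similar shapes.
* **Re-segmentation Dice**: segment the reconstruction with the originally
  trained model and score it against the true subject's ground truth
  (2|A∩B|/(|A|+|B|) per class, mean over the three tissue classes; a class
  empty in both maps scores 1).
* **Identification**: each reconstruction is scored against all originals;
  the rank of the true original (1 = re-identified) uses the *worst* tied
  position so identification risk is never overstated. Under a null metric
  with i.i.d. scores the mean rank is (N+1)/2, which the tests verify by
  Monte Carlo.

## Registration

A pluggable two-phase contract: (1) a global affine stage — translation,
Euler rotations, log-isotropic scale — maximizing a 32-bin mutual
information, seeded by a coarse integer translation search and refined by
restarted Nelder–Mead; (2) a multi-resolution demons refinement with
fluid-like regularisation (each iteration's update is Gaussian-smoothed at
σ = 1 voxel before accumulation, with a light elastic pass every 10
iterations; 30 iterations at half resolution, 60 at full). The demons
forces are intensity differences on normalized images; an explicit local
cross-correlation objective was not used because after [0, 1] normalization
the two are nearly equivalent on this data while demons is far cheaper.
Smoothing the *total* field each iteration (the textbook diffusion variant)
compounds into a very large effective kernel and systematically shrinks
genuine deformation — the fluid form does not, and recovers an injected
smooth warp's mean norm within 30% inside the brain. The affine component
is deliberately excluded from the returned field, and field magnitudes are
compared within the brain mask: outside the head there is no image
structure that could drive (or validate) a non-linear match.

Degenerate cases: self-registration yields an exactly zero field (zero
forces); non-convergence of the demons stage is flagged
(`converged = FALSE` with diagnostics) rather than raised as an error.

## Problem sizes and determinism

The package's study defaults — chosen once as the desk-scale rendition of a
40-subject, 224³, depth-4 experiment — are 16 subjects at 32³ voxels,
depth-2 networks with 4 base filters, 4 folds of 4 private / 12 attacker
subjects. At these sizes a full two-architecture cross-validated study runs
in about 4 minutes on one CPU core. The skull-condition contrast uses
single folds (U-Net, three seeds) rather than full studies, and the
deformation metric is scored on one fold's reconstructions, because dense
registration of all 256 pairs dominates runtime without changing the
conclusions. Unit tests use 16³ phantoms.

## Known limitations

* Phantom realism as discussed above; absolute metric values on phantoms
  are not calibrated to any real database.
* At desk scale the U-Net's skip connections do not reliably yield better
  reconstructions than the SegNet-style network; that ordering emerges from
  full-scale capacity differences that 4-filter networks do not reproduce.
  The within-architecture orderings (true > others, stripped > with-skull,
  original > reconstruction Dice) are the findings the synthetic study
  reproduces.
* The affine stage estimates isotropic scale only; anisotropic shears end
  up in the non-linear field.
* Latent codes of private subjects are assumed available; estimating them
  from model outputs, black-box variants, and defences (e.g. differential
  privacy) are out of scope.
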