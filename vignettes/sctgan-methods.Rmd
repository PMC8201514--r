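---
title: "Synthetic CT from MV-CBCT: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic CT from MV-CBCT: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sctgan)
```

## The problem

Megavoltage cone-beam CT (MV-CBCT) acquired on the treatment machine shows
the patient's anatomy of the day, but scatter, noise and beam effects corrupt
its Hounsfield units (HU) so badly that it cannot be used for contouring or
dose calculation in adaptive radiotherapy. `sctgan` translates MV-CBCT
volumes into *synthetic CT* (sCT) volumes with CT-like HU fidelity using a
cycle-consistent adversarial network (CycleGAN) trained on **unpaired**
slices, and evaluates the result with the standard image-similarity metrics
(MAE, PSNR, NCC, SSIM) and the Dice similarity coefficient for contours.

Because clinical CT/CBCT data cannot be shipped, the package includes a
seeded pelvic-phantom simulator with a parametric CBCT degradation model, so
the entire pipeline — preprocessing, training, inference, evaluation — is
exercisable and testable at desk scale.

## Preprocessing

Volumes are resampled to a common grid (default 0.8789 × 0.8789 mm in-plane,
3 mm slices), centre-cropped or padded to 512 × 512 (any multiple of 8 is
accepted; the generator has three stride-2 stages), body-masked with Otsu's
threshold, and the outside-body region is set to −1000 HU. Intensities are
then mapped to the network range by the affine map

$$ I_s = \frac{2\,(I_{\mathrm{orig}} + 1000)}{4095} - 1, \qquad
   I_{\mathrm{orig}} \in [-1000, 3095], $$

so −1000 HU ↦ −1 and 3095 HU ↦ 1. Values outside the HU domain are clipped
before scaling, which keeps every scaled image inside $[-1,1]$.

Raw Otsu thresholding leaves couch fragments and opens internal air pockets;
the mask is therefore cleaned to the **largest connected component** with
**holes filled** (both switchable). Without the cleanup, the −1000
background assignment would delete rectal air pockets that belong inside the
body. Cropping is centred; an odd margin puts the extra pixel on the
high-index side. Slices of a CT/CBCT pair are matched by z position within
half a slice thickness (1.5 mm at the default grid) — the volumes are assumed
already aligned, as they are when acquired sequentially at the same couch
position; registration is out of scope.

The chain is idempotent: running it on its own output changes nothing
(the grid already conforms, the background is already −1000), and scaling is
tracked separately from the HU-domain steps so data is never scaled twice.

## Networks

Both generators share one architecture (independent weights): a residual
U-Net on single-channel slices —

* 7×7 stride-1 head convolution;
* three 3×3 stride-2 down-convolutions with channels 32, 64, 128;
* nine 3×3 residual blocks at the bottleneck;
* three ×2 nearest-neighbour upsampling stages, each followed by a 3×3
  convolution, with U-Net skip concatenations from the same-resolution
  down-stage outputs;
* a tail residual block and a final 7×7 convolution with tanh output.

The discriminators are PatchGANs: three 4×4 stride-2 convolutions
(channels 32, 64, 128), a 4×4 stride-1 convolution to 256 channels, and a
4×4 stride-1 convolution to a one-channel patch score map; with zero padding
1 everywhere a side-$s$ input yields an $(s/8-2)$-sided map (512 → 62,
64 → 6). Instance normalisation follows every convolution except the final
one of each network and the discriminator's first layer; activations are
ReLU in the generator and leaky ReLU (slope 0.2) in the discriminator. The
7×7 layers use reflection padding 3; all other convolutions use zero
padding 1. The unnormalised first discriminator layer follows the PatchGAN
lineage and is load-bearing here: instance normalisation applied directly
to a linear convolution of the input cancels global affine intensity
changes exactly, and a discriminator blind to global HU bias and contrast
cannot supply the adversarial signal that absolute-HU restoration depends
on.

Design notes on points the architecture description leaves open:

* *"Unpooling with stride 2"* is implemented as nearest-neighbour ×2
  upsampling followed by the stated convolution: a fully convolutional down
  path has no pooling indices, so max-unpooling is not meaningful.
* U-Net skips concatenate channels (three skips: head→last up stage, down-1,
  down-2 to the matching resolutions).
* Weights are initialised from N(0, 0.02), the convention of the
  image-translation network family this architecture belongs to; on the
  phantom it converges markedly faster than fan-in-scaled initialisation
  (instance norm makes layer scales largely self-correcting, so the smaller
  weights cost nothing in signal propagation).
* The networks are implemented from first principles in this package (C++
  convolution/normalisation primitives, explicit backpropagation, Adam);
  correctness is enforced by finite-difference gradient checks in the test
  suite rather than by trust in a framework.

## Losses and training

The generator objective is

$$ \mathcal{L}_G = \lambda_{cycle} L_{cycle} + \lambda_{idem} L_{idem}
  + \lambda_{adv} L_{adv} + \lambda_{grad} L_{grad}, \qquad
  (\lambda_{cycle}, \lambda_{idem}, \lambda_{adv}, \lambda_{grad}) = (20, 1, 1, 1). $$

* $L_{cycle}$: L1 between each image and its two-generator cycle
  reconstruction, both directions.
* $L_{idem}$: L1 between $G(x)$ and $G(G(x))$ — a generator applied to its
  own output should change nothing. The alternative same-domain identity
  reading $\lVert G(y) - y\rVert_1$ is available via
  `train_config(idem_mode = "identity")`.
* $L_{adv}$: least-squares GAN terms — the patch score map of a fake is
  regressed toward 1 for the generator; the discriminator loss is
  $\tfrac12\,\mathrm{mean}[(D(\mathrm{real})-1)^2] +
  \tfrac12\,\mathrm{mean}[D(\mathrm{fake})^2]$. The "compare with an array
  filled with 0 or 1" description reads naturally as regression to label
  maps, hence least squares rather than cross-entropy.
* $L_{grad}$: L1 between the absolute row- and column-difference maps of
  input and output, preserving edges; invariant to constant offsets.

Training uses Adam (learning rate $10^{-4}$, $\beta_1 = 0.5$ — the standard
first-moment decay for adversarial training; only "Adam" and the learning
rate are prescribed), batch size 1, for a configured number of epochs
(clinical scale: 100) — slices are sampled **independently** from the CT and
CBCT pools each step, so the pairing present in the phantom data is never
used. Gaussian noise (default sd 0.01 in scaled units ≈ 20 HU) is added to
the generator inputs as regularisation, and fresh noise of the same sd is
added to every discriminator input — fakes, and *clean* reals. The symmetric
noising matters: without it the discriminator can win by detecting the
regularisation noise itself, or the exact −1 background of real slices (a
tanh output can only approach −1), and the adversarial signal for HU
restoration collapses. For the same reason the cycle and gradient losses
target the clean slices, not the noised network inputs: the noise is
regularisation, and asking the generators to reproduce it rewards texture
invention. Both generators are updated jointly against the full objective,
then both discriminators; one global seed makes runs bit reproducible, and
checkpoints carry parameters, Adam moments, RNG state and loss history, so a
resumed run is bit-identical to an uninterrupted one.

A 50-image replay buffer feeds the discriminator updates: with probability
1/2 the discriminator sees a buffered earlier fake instead of the current
one. Without it the generator/discriminator pair oscillates visibly late in
training and single-checkpoint evaluations become erratic; the buffer is the
standard damper in this network family and is switchable
(`train_config(replay_pool = 0)`). Learning-rate decay, by contrast, is not
applied — the learning rate is part of the published configuration.

## The phantom and the degradation model

Each phantom slice is a schematic pelvic cross-section on a −1000 HU
background: an elliptical soft-tissue body (≈30 HU, Gaussian texture sd 12)
with a subcutaneous fat rim (≈−90 HU), two bony femoral heads and a
vertebral block (≈600 HU), a bladder (≈10 HU), and a rectum with an
optional air pocket. Placement is jittered per slice relative to the body
axes; organ masks are exact by construction, which makes DSC evaluation
oracle-free. The anatomy is deliberately schematic — ellipses and circles,
no 3-D continuity across slices and no atlas realism — sufficient to
exercise masking, translation learning and the metrics while keeping the
repository free of data.

The pseudo-CBCT degradation applies, in a fixed order: scatter-like blur
admixture $(1-w)\,I + w\,\mathrm{blur}_\sigma(I)$; a multiplicative
low-frequency shading field (radial cupping centred on the body plus a
random low-frequency wave); contrast scaling; a global HU bias; additive
Gaussian noise; clipping to $[-1000, 3095]$; and restoration of the exact
−1000 background so the body outline is preserved. Defaults (amplitude
0.25, blur σ 2 px with weight 0.3, noise sd 25 HU, bias −60 HU,
contrast 0.85) were chosen once so that the within-body MAE between phantom
CT and pseudo-CBCT sits near 100 HU — the order of magnitude reported for
MV-CBCT against planning CT — and are treated as fixed study conditions.
Real MV-CBCT physics (projection-space scatter, reconstruction artifacts)
is out of scope, so success on the phantom demonstrates that the pipeline
can learn and invert *this class* of low-frequency, global corruptions; it
does not certify performance on clinical data.

## Metrics

MAE, PSNR, NCC and SSIM follow their standard volumetric definitions with
population (divide-by-N) moments; PSNR takes MAX to be the maximum HU of the
reference image (switchable to a fixed peak), which makes it the one
asymmetric metric. SSIM defaults to **global** mode — the closed form
evaluated with whole-image moments — with the standard stabilisers
$c_1 = (0.01 L)^2$, $c_2 = (0.03 L)^2$, $L = 4095$; a windowed mode
(sliding-window average of the same form) is provided. DSC is
$2|A\cap B| / (|A| + |B|)$ on voxel counts; a denominator of
$|A|\,|B|$ would be neither dimensionless nor bounded by 1, so the sum
convention is used. Metrics are computed over the full preprocessed grid by
default (outside-body voxels are −1000 in every image, mirroring
preprocessing); every metric accepts an optional body mask because the
region convention genuinely changes the numbers — global SSIM in particular
is inflated by the shared background.

Reports aggregate across cases as mean ± SD with the **sample** (n−1) SD.

## Problem sizes for the shipped experiments

The package's own experiments (test suite and `scripts/acceptance.R`) run a
scaled-down configuration chosen to keep a full run on one CPU within
minutes while leaving the method unchanged: 64 × 64 slices, base width 8
(a quarter of the clinical 32), 3 residual blocks, 200 training + 20
held-out slice pairs, and 2000 training iterations at batch 1 — the same
optimizer, losses, noise regularisation and data conventions as the
clinical-scale configuration, which remains the package default
(`train_config()`, `preprocess_config()`, `gen_arch()`).

## Known limitations

* 2-D slice-wise translation; volumes are reassembled post hoc with no
  3-D consistency enforcement.
* No registration: CT/CBCT inputs must already share a frame of reference.
* The DICOM reader covers uncompressed, explicit-VR little-endian,
  single-frame series only (the subset its synthetic writer produces and
  typical CT exports use); sequences and compressed syntaxes are rejected.
* No learning-rate decay and no replay buffer; both were considered and
  left out as unstated in the architecture lineage, and the training loop
  is deliberately minimal.
* The phantom's realism bounds what green tests prove about clinical data
  (see above).
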