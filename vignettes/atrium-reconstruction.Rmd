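---
title: "Reconstructing the left atrium from sparse catheter paths"
author: "atriarecon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing the left atrium from sparse catheter paths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During catheter ablation for atrial fibrillation, the electro-anatomic
mapping system must present the operator with a map of the left atrial (LA)
endocardial surface, including the four pulmonary-vein (PV) ostia that are
the ablation targets.  Dense "fast anatomical mapping" acquires that surface
by having the catheter touch much of the chamber wall, which takes on the
order of ten minutes.  A much quicker maneuver -- entering through the
trans-septal puncture and visiting the four PV ostia in sequence -- takes
under three minutes but samples only a sparse path, most of it inside the
blood pool rather than on the wall.  `atriarecon` implements a complete
system that learns to recover the full chamber from that sparse path:

1. a seeded generator of atrium-like shapes with landmarks (standing in for
   a proprietary statistical shape model),
2. a simulator of catheter-like traversal paths inside those shapes,
3. a dense encoder--decoder network (DED) mapping a voxelized path to an
   occupancy probability volume, with two loss-shaping devices -- a
   boundary-enhancement mask and spatial weight-smoothing regularization
   (SWR),
4. a V-Net-style volumetric convolutional baseline,
5. a mean-shape baseline and the rigid PV-ostia registration that places
   acquired clouds into its frame, and
6. an evaluation suite (radius-restricted symmetric surface distances,
   Hausdorff distance, paired one-tailed t-tests).

All data live on a voxel grid (`GridSpec`), by default $45^3$ voxels at a
2.666 mm pitch.  We read the 2.666 figure as a voxel *edge length*:
$45 \times 2.666 \approx 120$ mm is an anatomically plausible LA bounding
cube, whereas reading it as a voxel volume would make the grid span only
62 mm.  Both dims and pitch are configurable.

## The synthetic atrium generator

No public statistical LA shape model was available, so the generator is a
documented parametric construction: the zero level set of a blended
signed-distance-style field consisting of

* a gently bent ellipsoidal chamber body (semi-axes ~32/26/24 mm, a
  posterior bend),
* four capsule PV tubes anchored at the body wall along per-PV directions
  (radius ~6.5 mm, length ~15 mm),
* a spherical appendage bump,

combined with a log-sum-exp soft minimum of 4 mm blend width so junctions
are smooth.  The surface is extracted by marching tetrahedra (a Kuhn 6-tet
cube subdivision, which has no ambiguous cases and yields watertight
meshes) on the field sampled at `meshRes` mm -- 1 mm by default, i.e.
independent of the much coarser training grid.  Landmarks are placed by
root-finding on the field itself: each PV ostium on the surface rim where
the tube axis crosses the body wall, the septum point on the
right-posterior body wall.

Parameters are drawn from a multivariate normal (`ShapeModelSpec`) with
fixed, documented mean and diagonal covariance -- these are *choices*, not
estimates fitted to imaging data.  A draw is kept when its Mahalanobis
distance from the mean is at most 3.  Because that gate keeps only the
central $\chi^2_d(9)$ mass, its acceptance rate collapses as the number of
varying parameters $d$ grows (at $d = 25$ only ~0.1% of draws survive,
which would trip the generator's own acceptance-rate guard).  The default
model therefore varies 17 parameters (body semi-axes, bend, PV
directions/radii, appendage size) and pins the remaining 8 (PV lengths,
appendage and septum directions) to their means, giving ~6% acceptance
while preserving the stated Mahalanobis-3 filter semantics.  Degenerate
geometry (a non-watertight or non-genus-0 surface, or a voxel interior
that is not one 6-connected component) is rejected and resampled.

What the generator emulates: chamber-scale anatomy, four separate PV
stumps, an appendage, smooth junctions, and shape variability concentrated
in PV position and body proportions.  What it does not emulate: real CT
statistics, wall thickness, PV branching, non-four-PV variants, or
pathology.  Tests passing on these shapes therefore demonstrate the
*mechanics* of the system (data generation, training, metric computation
and the relative ordering of methods), not clinical accuracy.

## Path simulation

Entry points are the interior voxels nearest the septum and the four
ostium landmarks.  A traversal graph connects 26-neighbouring interior
voxels; a step of Euclidean length $\ell$ whose midpoint lies $d_\mathrm{wall}$ mm
from the nearest wall voxel costs
$\ell \left(1 + w / (1 + d_\mathrm{wall})\right)$.  With $w = 0$ this is the
geometric shortest path; the default $w = 2$ penalizes wall-hugging so
routes curve toward the chamber center, as a catheter tip pushed through
the blood pool does.  The four legs septum→PVLS→PVLI→PVRI→PVRS are solved
by Dijkstra's algorithm with a deterministic tie-break (the
smallest-index predecessor among equal-cost alternatives), so fixtures are
byte-stable.  26-connectivity was chosen over 6-connectivity to avoid
staircase paths.

Augmentation turns the polyline into a realistic cloud: around every path
point, `n = 5` isotropic Gaussian samples of scale `sigma = 2` mm, each
kept with probability `sF = 0.5`; kept points are filtered to the mesh
interior and then jittered by a Gaussian displacement of scale
`muS = 1` mm.  The jitter deliberately comes *after* the interior filter:
a vibrating catheter can push slightly through the wall, so augmented
clouds may marginally exit the chamber.  All four values are package
defaults with no anatomical calibration behind them, and all are exposed
in `AugmentationConfig`.

## The dense encoder--decoder

The DED is a multilayer perceptron over flattened volumes:
$N \to k \to k \to N$ with $N = \prod \text{dims}$ and $k = 350$.  The
output layer reuses the transpose of the input weight matrix ("tied
weights"), realized as a single stored matrix used in both places, so the
tying invariant cannot drift during optimization.  ReLU activations and
batch normalization (momentum 0.1, $\epsilon = 10^{-5}$) follow every
layer but the last, which is a sigmoid producing per-voxel occupancy
probabilities; 0.5 thresholding (ties to 1) binarizes them.  During
training the input is multiplied by a Bernoulli mask (zeroing rate 0.3,
no rescaling -- inputs are binary indicators), in the style of a denoising
autoencoder.  The mask rate of 0.3 is a package default.

The loss for prediction $x$ and target $z$ is
$$L(x,z) = \alpha\,\mathrm{BCE}(x,z) - (1-\alpha)\,\mathrm{DICE}_\Omega(x,z),
\qquad \alpha = 2/5,$$
with probabilities clamped to $[10^{-7}, 1-10^{-7}]$ inside the BCE and a
soft DICE $\;2\sum \Omega x z / (\sum \Omega x + \sum \Omega z)$ with
$\epsilon = 10^{-7}$ stabilization (a squared-denominator variant is
available as a config switch; the linear form is the default).

**Boundary enhancement.**  The mask $\Omega$ weights voxels by proximity
to the chamber wall, computed from the unsigned Euclidean distance
transform $D(v)$ of the boundary voxel set (voxel units; a mm mode
exists).  The literal algebraic form $\Omega(v) = (1+\beta)/(1+PN(D(v)))$ with
$PN$ the normal density ($\sigma = 1.5$) *increases* with distance -- it
equals ~11.85 on the boundary and tends to $1+\beta = 15$ far away --
which runs against the purpose of concentrating weight *on* the
boundary.  The package ships both readings: mode `"literal"` implements
that algebraic form; mode `"peaked"` (default) implements the
boundary-concentration intent, $\Omega(v) = 1 + \beta\,PN(D(v))/PN(0)$,
maximal (15) on the boundary and decaying to 1.  Both are tested against their closed forms.

**Spatial weight smoothing.**  Because each input/output weight is indexed
by a voxel, each hidden unit's weight vector is an image over the grid.
The SWR penalty is the sum over units and voxels of the squared forward
finite-difference spatial gradient, doubled for the tied output layer
(`swrPenalty()`; a spatially constant map scores 0, and a unit ramp on a
$3^3$ grid scores exactly 36).  In the *training objective* the penalty
enters as its per-weight mean, $\lambda \cdot \mathrm{SWR}/(Nk)$: the raw
sum grows with $Nk$ and would overwhelm a per-voxel-mean data term by
many orders of magnitude at the named $\lambda$ values.  With this
scaling the variants behave sensibly: $\lambda = 0.05$ ("SWR005") is a mild smoother
that trains essentially as well as $\lambda = 0$, and $\lambda = 75$
("SWR75") forces visibly smooth weight maps at a modest DICE cost;
trained-weight roughness decreases strictly along
$\lambda = 0 \to 0.05 \to 75$.

Training uses Adam (learning rate $10^{-3}$, batch 20, $\beta = 0.9/0.999$),
seeded shuffling, and aborts on a non-finite loss naming the epoch and
batch.  The optimizer settings are package defaults.

## V-Net baseline

The volumetric baseline is an encoder of convolution + batch-norm + ReLU
stages each followed by 2× max-pooling (four stages by default, filter
counts 16→32→64→128), a bottleneck with dropout (rate 0.1), and a decoder
of learned up-sampling stages (nearest-neighbour upsampling followed by a
learned convolution) with same-size skip concatenations; the first and
last convolutions use enlarged 5³ kernels, and the output is a sigmoid.
45³ inputs are zero-padded to 48³ and cropped back.  It trains on the same
pairs with the same loss under a uniform mask; SWR does not apply -- the
smoothing penalty is defined on voxel-indexed dense weights, which a
convolutional model does not have.  Filter counts, kernel sizes and the
dropout rate are package choices.

## Mean shape, registration, preprocessing

The mean shape is the voxel-wise average of the training volumes with its
0.5 binarization and the arithmetic mean of the per-shape landmarks.  It
is both the no-learning baseline (the same volume is the "reconstruction"
for every case) and the reference frame for clinical-style inputs: per-PV
centroids of the tagged points are rigidly registered (closed-form SVD
solution with reflection correction, no scaling, 4 correspondences;
the septum is excluded by default) to the mean-shape ostia, the transform
is applied to the whole cloud, and the cloud is binned into the network
grid.  Preprocessing is exactly invariant to rigid motion of the
acquisition, and noiseless synthetic motions are recovered to machine
precision.  Mean-shape landmarks are taken as the mean of generator
landmarks rather than re-detected on the mean volume -- simpler and
deterministic.

## Evaluation

Meshes are extracted from (probability) volumes by the same marching-
tetrahedra kernel at iso 0.5, after zero-padding so surfaces touching the
grid border close; the largest connected component is kept.  The metric is
the *nearest-vertex* distance (not point-to-triangle), with
vertex densities made comparable by extracting both meshes at the same
grid resolution; restricted means consider source vertices within a given
radius of *at least one* of the four PV ostia (the union of balls --
an intersection would typically be empty at 10 mm).  The symmetric value
averages the two directional means; both directions are also reported.
The significance test against the baseline is the exact paired one-tailed
Student t-test of mean(baseline − method) > 0, with zero-variance
degeneracies resolved by sign (identical error lists give p = 0.5).

## The scaled-down benchmark

The package's acceptance benchmark runs the whole system at desk scale:
a $24^3$ grid at 5 mm pitch (same 120 mm physical extent), 200 training
and 50 test shapes (meshes sampled at 2.5 mm), default augmentation, and
the SWR005 DED trained for 150 epochs -- about 7 minutes on one CPU core.
Under these conditions the trained network reaches a median test DICE
above 0.9 and beats the mean-shape baseline's symmetric surface distance
at the 15 mm radius with p-values many orders of magnitude below 0.05.
The problem sizes were chosen so the whole suite completes on a laptop
CPU; the network widths (350+350) are kept at full scale.

These numbers quantify the synthetic benchmark only; clinical accuracy
can only be judged on patient data, which the package deliberately does
not ship.  What the benchmark establishes is the central comparison --
a trained DED reconstructing unseen chambers better than the static mean
shape, especially around the PV ostia.

## Numerical choices and degenerate inputs

* Iso-surfacing nudges field values exactly at the iso level by $10^{-12}$
  so no degenerate (zero-area) triangles arise; vertices are deduplicated
  by grid-edge key, making meshes watertight by construction.
* Voxelization casts rays through deterministically jittered voxel-column
  centers (a fixed ~$4 \times 10^{-4}$ fraction of the pitch), keeping
  parity counting exact for meshes in general position.
* Dijkstra breaks cost ties by the smallest predecessor index after the
  distance pass, so paths are reproducible across platforms and BLAS
  builds.
* Batch normalization uses biased batch variance and running statistics
  with momentum 0.1; inference always uses running statistics (batch
  statistics would be degenerate for single inputs).
* The EDT is the exact Felzenszwalb lower-envelope transform, computed
  per axis with the physical spacing.
* Empty augmentation (`n = 0` or `sF = 0`) returns the input path
  unchanged; an all-outside point cloud errors rather than producing an
  empty volume; volumes that do not cross the iso level refuse to produce
  a mesh.

## Known limitations

* The generator's shape statistics are invented defaults; nothing about
  real anatomical covariance should be inferred from them.
* Nearest-vertex (not point-to-triangle) distances slightly overestimate
  true surface distances at coarse mesh resolution; both meshes are
  extracted at the same resolution to keep the comparison fair.
* The DED operates on a fixed grid; a different grid requires retraining.
* Training is CPU-bound matrix algebra; the package is written for
  desk-scale experiments, not GPU-scale sweeps.
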