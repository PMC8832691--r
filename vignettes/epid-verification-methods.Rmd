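---
title: "In vivo EPID verification: models, simulator and numerical choices"
author: "epidverify authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In vivo EPID verification: models, simulator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The verification problem

During an IMRT delivery the electronic portal imaging device (EPID) behind
the patient records a transmission image (TI): the photon fluence that made
it through the patient, converted to greyscale by the panel. If a TI
predicted from the treatment plan agrees with the measured TI, the delivery
— machine output, MLC positions, patient setup, patient anatomy — was
consistent with the plan; if not, something changed. The catch is
predicting the TI: the panel is a layered industrial device whose exact
composition is proprietary, so modelling its response from first principles
is impractical in most clinics.

`epidverify` implements a two-stage workaround. First, the physical EPID is
replaced *in silico* by homogeneous solid water: a 5 cm slab (HU 0) is
inserted into the planning CT with its top face 47 cm below the isocentre,
so that a scoring plane 50 cm below the isocentre sits at 3 cm water depth
(the upstream 3 cm acting as build-up). A Monte-Carlo system can compute
dose to water in that slab without knowing anything about the panel.
Second, a U-net learns the residual mapping from that water-dose plane to
the real measured TI — off-axis response, glare, gain, and the removal of
the MC noise — from paired examples.

Because each field must be simulated at gantry zero (the virtual slab
cannot rotate with the gantry), the plan is split into single-field plans
whose gantry angles are set to zero, and the CT is counter-rotated instead:

1. couch HU substitution ([`replaceCouch()`]) — requires an explicit couch
   mask; no reliable automatic couch detection exists, so when no mask is
   given the step is skipped with a warning;
2. anti-clockwise axial rotation by the original gantry angle
   ([`rotateAxial()`]);
3. axial extension with air to cover the slab geometry
   ([`extendAxial()`]);
4. solid-water insertion with an air gap between couch exit and slab top
   ([`insertSolidWater()`]).

`buildCombinedCT()` chains the four steps and records the applied rotation.
Slab and gap are assigned *after* rotation, so those regions are exactly
0 HU and -1000 HU with no interpolation bleed.

### Conventions

Patient coordinates are mm with the isocentre at the origin; x is the IEC
crossline axis (patient left positive), y the beam axis at gantry zero
(depth below isocentre positive), z inline. "Anti-clockwise" is defined in
the standard axial display (patient left on image right, anterior up); the
display convention is recorded because different vendors print axial slices
differently. MLC bank B sits on the negative crossline side, so a leaf-pair
gap is `mlcA - mlcB` and closed pairs have `mlcA == mlcB`. Rotation uses
bilinear interpolation with -1000 HU fill; on smooth volumes composing two
rotations agrees with the summed angle to a few HU, and the package's tests
quantify this.

## The synthetic detector simulator

The reference-scale study trained on 1500 measured clinical fields. Those data
are not reproducible on a desk, so the package ships a parametric simulator
(`detectorModel()`, `waterDose()`, `trueResponse()`) that plays the role of
both the MC dose engine and the physical panel. It deliberately contains
every effect that makes the dose-to-TI mapping *not* a global scaling:

* **Fluence**: control-point apertures accumulated with trapezoidal
  meterset weighting, blurred by a source penumbra (sigma 1.5 mm at the
  isocentre plane), multiplied by quadratic off-axis "horns"
  (`hornCoeff = 0.06` at `(r_iso / 200 mm)^2`), magnified by
  `sid/sad = 1.5` and attenuated by the per-ray inverse square.
* **Attenuation**: `exp(-mu_eff * path)` with `mu_eff = 0.0457 /cm` (a
  standard narrow-beam effective value for 6 MV in water), where the
  radiological path through the slab stack and any inserts accounts for ray
  obliquity, setup shifts, phantom rotation and relative electron density.
  A small in-water lateral spread (2 mm) smooths the result.
* **MC-like noise**: Gaussian with `sd = noiseRel * sqrt(D * Dmax)`,
  `noiseRel = 0.01`, giving about 1% relative noise at the dose maximum —
  the statistical texture of a well-converged MC calculation.
* **Detector response** (`trueResponse()`):
  `TI = gain x oar(r) x (glare (*) dose)` with a normalized two-Gaussian
  glare kernel (92% core of 1.5 mm, 8% tail of 25 mm) and a radially
  declining off-axis response `oar(r) = 1 - 0.063 (r/100 mm)^2`. The
  flood-field calibration of a real panel flattens the detector while the
  beam keeps its horns; the net effect is that max-normalized dose and TI
  profiles of a 15 cm x 15 cm field disagree by about 10% at the in-field
  edge, which is the calibration target for these two defaults. The
  detector response is what the network must learn; `gain = 120` sets the
  greyscale scale.

The thorax-like phantom (`thoraxPhantom()`) is a water block with two 0.25
relative-density lung boxes and a 1.1-density cord cylinder. It is a stated
synthetic stand-in: the commercial thorax phantom used clinically has
proprietary geometry. Homogeneous phantoms use the standard thickness set
3, 5, 8, 10, 12, 15, 18, 20, 24 cm of 40 cm x 40 cm solid water.

What the simulator does *not* emulate: scatter-to-primary structure beyond
the glare kernel, panel backscatter from the support arm, beam spectrum
changes with depth, and inter-fraction anatomy deformation. Passing tests
therefore demonstrate that the pipeline recovers a known detector transform
under realistic noise — not that the network generalises to clinical
measurements.

## The response network

The U-net (`networkSpec()`, `trainResponseNet()`) has encoder blocks of two
3 x 3 same-padded ReLU convolutions followed by 2 x 2 max pooling, a
mirrored decoder with 2 x 2 nearest-neighbour upsampling, skip
concatenation and two further convolutions per level, a final 1 x 1
projection, and the input added to the projection output. The residual
output means an untrained network with a zeroed final layer is the identity
map — a property the tests assert — and the network only has to learn the
(smaller) detector correction. Channel widths double per level; the
reference configuration is depth 5 with 64 base channels on the 256 x 192
grid (8 x 6 bottleneck). The residual addition uses the raw final-layer
output (no activation after the add).

Inputs are the noisy water-dose maps cropped and resampled to the analysis
grid; targets are the noiseless synthetic TIs. Both are divided by fixed
dataset-level constants (the training-split maxima), stored with the model,
so absolute response levels are learned rather than per-image shapes. Loss
is MSE; the optimizer is Adam at learning rate 1e-4 with the conventional
remaining defaults, batch size 12, 2000 epochs at reference scale.

### Desk-scale profile

Everything in this package runs on one CPU core, so the shipped
`quicktestConfig()` scales the study down: 300/40/40
train/validation/test fields on the 128 x 96 analysis grid (3.125 mm
pitch), a depth-3 base-16 network, Adam at 2e-3 with the step size halved
twice late in training, and 24 epochs. The final 1 x 1 projection is
zero-initialised so training starts from the exact identity map, which
converges markedly faster under the residual design; the raised learning
rate and its decay partially compensate for the roughly 250-fold reduction
in image-gradient evaluations relative to the reference recipe. That
reduction has a cost: the desk-scale network is under-trained relative to
the reference run, and its residual error — quantified per run by the
test-split gamma summary and the loss history the experiment writes — is
dominated by incomplete convergence rather than by noise pass-through or
capacity. The backend is single-precision im2col + BLAS with seeded weight
initialisation and batch order, so a run is bit-reproducible at a fixed
thread count.

## Gamma analysis

`gammaIndex()` implements the global 2D gamma index: for each reference
point at or above the low-dose threshold (5% of the reference maximum;
points below are excluded from pass rate and mean gamma alike),

```
gamma(p) = min over displacements r, |r| <= 3 dta :
           sqrt( |r|^2 / dta^2 + (E(p + r) - R(p))^2 / (dd% x max(R) / 100)^2 )
```

with the evaluated image interpolated bilinearly at steps of `dta/10`.
Normalization is global to the *reference* image maximum; the package fixes
reference = measured, evaluated = predicted (gamma is not exactly symmetric
in its arguments, and a constructed example in the tests shows the
asymmetry). The optimized search enumerates displacements sorted by
distance and stops when the distance term alone exceeds the current
minimum — exact relative to the interpolation grid, which the brute-force
engine (`exhaustive = TRUE`) verifies point-by-point in the tests. Note
that the *continuum* gamma is monotone under loosening criteria; on the
discrete search grid this holds exactly only when the two runs share one
interpolation step, which is how the property is tested.

The error-sensitivity protocol (`sensitivityStudy()`) delivers 21
deliberate errors — MU scalings (+1/+3/+5/+10/-5%), lateral and anterior
isocentre shifts (5/10/20 mm), gantry offsets (+5/+10 deg), four MLC error
classes, and added solid water (5/10/20/30 mm) — and compares the
*unperturbed* prediction with the *perturbed* synthetic measurement at
3%/3 mm. Anterior shifts on homogeneous phantoms leave the radiological
path of every ray unchanged (a parallel slab has the same chord wherever it
sits along the ray), which is the mechanism behind the protocol's
insensitivity to anterior offsets; the simulator reproduces it exactly and
the tests assert it to < 0.1%.

## Numerical choices and degenerate inputs

* Aperture rasterisation opens a cell iff its centre lies strictly inside
  jaws and leaf gap; closed pairs contribute nothing. Widening any gap
  never closes a cell (monotonicity property test).
* Resampling windows are defined in physical mm, never integer source
  pixels, so the 50 cm / 512 = 0.977 mm MC export pitch is handled exactly;
  the measured 1024 x 768 panel image is reduced by exact 4 x 4 block
  averaging (matching the panel's signal integration) rather than point
  sampling.
* The plane extractor interpolates linearly between bracketing coronal
  planes (nearest-plane selectable).
* The bilinear samplers tolerate a 1e-6-pixel border epsilon so that exact
  90/180-degree rotations do not lose edge voxels to fill values.
* Gamma refuses to run when every reference point is below threshold
  ("nothing to evaluate"), and the experiment runner refuses configs with
  zero test fields.
* Training aborts with a diagnostic when the loss stops being finite.

## Reproducing the study figures

`scripts/acceptance.R` regenerates everything from a single seed: the
dataset, the trained network, the test-split gamma summary, the two
sensitivity figures (with the true detector transform as predictor, making
them deterministic given the field sample), and the 20 cm slab profile
comparison. Runtime is dominated by network training (about 12-15 minutes
on one core at the desk-scale profile); dataset generation takes under a
minute and the gamma analyses a few seconds each.

## Known limitations

* The simulator's detector model is parametric and smooth; real panels
  have pixel-level gain texture, dead pixels and arm backscatter that are
  not modelled, so measured-data performance cannot be inferred from the
  synthetic figures.
* VMAT arcs, wedged fields and non-coplanar couch angles are out of scope;
  the plan reader rejects them.
* The DICOM codec reads and writes explicit-VR little-endian only — enough
  for the RT Plan and CT series round trip it exists for, not a general
  DICOM implementation.
* The inverse problem (converting a measured TI back to water dose) is not
  attempted.
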