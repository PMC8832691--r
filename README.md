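# epidverify

Two-dimensional *in vivo* treatment verification for static-gantry IMRT
with an electronic portal imaging device (EPID), runnable end to end on a
single CPU.

## The problem

During radiotherapy delivery, the EPID behind the patient records a
transmission image (TI) of the photons that passed through. Comparing a
*predicted* TI against the *measured* one catches dose errors, setup
errors, MLC faults and anatomy changes while the patient is on the table.
The hard part is predicting the TI: the flat-panel detector is a layered
proprietary device that is impractical to model from first principles.

`epidverify` implements a two-stage approach:

1. **Equivalent EPID.** The panel is replaced *in silico* by a 5 cm
   solid-water slab (HU 0) inserted into the planning CT with its top face
   47 cm below the isocentre, so the scoring plane 50 cm below the
   isocentre lies at 3 cm water depth behind its build-up. Each field of
   the RT plan is split into its own zero-gantry plan and the CT is
   counter-rotated by the gantry angle, producing a "combined CT" any
   Monte-Carlo dose engine can consume without knowing the panel design.
2. **Learned detector response.** A U-net converts the water-dose map at
   the equivalent-EPID plane into the detector greyscale image, learning
   the off-axis response, glare and gain difference between dose and
   signal — effects that make the conversion *not* a simple rescaling —
   and removing the Monte-Carlo noise.

Predicted and measured TI are then compared with the standard global 2D
gamma index

    gamma(p) = min over |r| <= 3 DTA of
               sqrt( |r|^2/DTA^2 + dD(r)^2 / (DD% * max(ref)/100)^2 )

at 3%/3 mm and 2%/2 mm with a 5% low-dose threshold, and a 21-error
sensitivity protocol (MU scalings, setup shifts, gantry offsets, MLC
faults, phantom-thickness changes) quantifies what the method can detect.

A parametric detector-response simulator stands in for the Monte-Carlo
engine and the physical panel, so the whole pipeline — plan splitting,
combined CT, dataset generation, network training, gamma verification,
sensitivity study — runs and is tested at desk scale. See the vignette
(`vignettes/epid-verification-methods.Rmd`) for the models and every
numerical choice.

## Worked example

```r
library(epidverify)

# a 3-beam IMRT plan, split into single-field zero-gantry plans
plan <- randomPlan(3, gantryAngles = c(30, 120, 270), seed = 42)
parts <- splitPlan(plan)
parts[[1]]
#> TreatmentPlan 'synth1857_B1' on Trilogy: 1 beam(s)
#>   beam B1        279.5 MU, gantry   0.0 deg (original  30.0), 3 control points

# combined CT for the first field
ct <- syntheticPhantomCT()
cc <- buildCombinedCT(ct, beams(parts[[1]])[[1]],
                      couchMask = array(FALSE, dim(voxels(ct))))
huAt(cc, c(0, 500, 0))   # 0    : solid water at the scoring plane
huAt(cc, c(0, 460, 0))   # -1000: air gap above the slab

# synthetic dose -> image -> verification for one open field
model <- detectorModel()
beam  <- beamField("demo", 100, list(
  controlPoint(0, 0, rep(75, 60), rep(-75, 60), c(-75, 75), c(-75, 75)),
  controlPoint(1, 1, rep(75, 60), rep(-75, 60), c(-75, 75), c(-75, 75))))
g     <- epidGrid(144, 112, 400 / 128)
dose  <- waterDose(beam, slabPhantom(10), model, grid = g, seed = 1)
meas  <- trueResponse(waterDose(beam, slabPhantom(10), model, grid = g,
                                noise = FALSE), model, 128, 96)
gammaIndex(meas, meas, gammaCriteria(3, 3))
#> GammaResult 3%/3 mm (5% threshold): pass rate 100.00%, mean gamma 0.000 over 5764 points
```

The full synthetic experiment (generate 380 fields, train the network,
gamma-verify the held-out test split) is one call:

```r
run <- runExperiment(quicktestConfig(), outDir = "run1")
summarizeTestSplit(run)
```

It prints the minimum and mean gamma pass rate and the mean of the
per-field mean gamma for both criteria over the 40 test fields; expect
roughly 12-18 minutes on one core, almost all of it network training.
The delivery-error study is `sensitivityStudy()`, whose rows (`Ea1` ...
`Ee4`) follow the protocol described in the vignette.

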