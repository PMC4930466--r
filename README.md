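# pancmorph

Quantitative pancreas morphometry from abdominal MRI segmentations, for
imaging scientists studying how the pancreas changes in type 2 diabetes
and after diabetes reversal. The pancreas in type 2 diabetes is small and
has a strikingly irregular, serrated border; `pancmorph` turns those
qualitative observations into numbers:

* **Volumetry** — organ volume by slice summation from polygon ROIs or 3D
  binary masks (NIfTI/TIFF), and the BMI-normalised pancreas volume index
  (volume/BMI, cm³·m²·kg⁻¹).
* **Border fractal dimension** — the core estimator. The 3D mask is
  projected to a 2D silhouette, the outer 8-connected border is
  extracted, and its box-counting fractal dimension is estimated as

  FD = mean over grid offsets of the OLS slope of log N(s) vs log(1/s),

  where N(s) counts grid cells of side s containing border pixels, sizes
  run dyadically over 2–32 px and each size is scanned from 10 seeded
  random grid origins. FD ≈ 1 for a smooth outline and grows towards 2
  with increasing border serration; duplicate measurements and their CV
  quantify precision.
* **Fat quantification** — three-point Dixon water–fat separation
  (IP = W+F, OP = (W−F)e^{iφ}, E3 = (W+F)e^{2iφ}; φ estimated from
  E3·conj(IP)), pancreas fat % via three 100 mm² uniform-tissue ROIs on
  each of two slices, and visceral fat % at L2–L3 from the subcutaneous
  boundary pair.
* **Cohort statistics** — responder classification (fasting plasma
  glucose < 7 mmol/l after an 8-week very low calorie diet), Table-1-style
  mean ± SEM summaries, paired/unpaired Student's t, Mann–Whitney U and
  Pearson/Spearman correlations following the field's reporting
  conventions.
* **Synthetic data** — serrated ellipsoid phantoms with a tunable
  serration amplitude, analytic fractal fixtures (line, circle, filled
  square, Koch curve), Dixon phantoms with known fat-fraction truth, and
  simulated two-group/three-timepoint cohorts, so the entire pipeline is
  testable without patient data.

## Worked example

```r
library(pancmorph)

## a serrated organ phantom: ellipsoid with 20% radial serration
m <- generate_organ_phantom(base_radii = c(25, 20, 15),
                            serration_amplitude = 0.2,
                            serration_frequency = 12,
                            voxel_spacing = rep(0.3, 3),
                            grid_shape = c(240, 200, 150), seed = 1)

compute_volume(m)
#> <volume_result> 31.675 cm^3 over 114 slices with ROI

fd_of_mask(m, axis = "anterior_posterior", n_offsets = 10,
           n_replicates = 2, seed = 42)
#> <fd_replicates> FD = 1.0548 over 2 replicates (axis anterior_posterior)
#>   replicate CV = 0.689% (FDs: 1.0496, 1.0599)
```

The volume is the foreground voxel count times the 0.027 mm³ voxel
volume; 31.7 cm³ sits in the range reported for diabetic pancreata. The
FD of 1.05 says the projected border of this mildly serrated phantom is
measurably rougher than a smooth outline (FD ≈ 1.00 at zero amplitude;
the same phantom at amplitude 0.4 reads ≈ 1.12), and the 0.7% replicate
CV is the grid-ensemble noise of the estimator itself. Calibration:

```r
fd_boxcount(generate_fractal_fixture("koch", size = 512, iterations = 5),
            n_offsets = 10, seed = 1)
#> <fd_fit> FD = 1.2274 (mean of 10 per-offset slopes, sd 0.0415)
#>   5 box sizes: 2, 4, 8, 16, 32 px; mean R^2 = 0.9966
```

against the Koch curve's analytic dimension log 4/log 3 = 1.2619. A
Dixon phantom round-trips its known fat-fraction map exactly in the
noiseless case:

```r
ramp <- matrix(rep(seq(0, 50, length.out = 100), each = 100), 100)
ph <- generate_dixon_phantom(ramp, phase_error_rad = 0.3)
max(abs(dixon_separate(ph$triplet)$ff_percent - ramp))
#> [1] 1.065814e-14
```

An end-to-end run over a manifest of masks and Dixon triplets:

```r
man <- create_demo_inputs("demo", n_per_group = 2, seed = 5)
run_pipeline(man, "demo/out", run_config(seed = 11))
# -> volume.csv, fd.csv, fat.csv, report.csv, table1.csv, contrasts.csv,
#    provenance.json   (byte-identical on rerun with the same seed)
```

A command-line wrapper with subcommands `simulate`, `volume`, `fd`,
`fat`, `report`, `run` and `blind` is installed at
`system.file("cli", "pancmorph.R", package = "pancmorph")`.

## Testing

```r
testthat::test_dir("tests/testthat", package = "pancmorph",
                   load_package = "installed")
```

The suite checks, among others: FD calibration against sets of known
dimension, exact agreement of the box counter with brute-force
enumeration, volumetric accuracy and grid convergence against analytic
solids, exact noiseless Dixon inversion and sub-1-pp noisy recovery,
agreement of every statistical test with closed forms and enumeration,
cohort mean recovery, and byte-identical pipeline reruns.

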