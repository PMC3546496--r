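# planareit

Three-dimensional electrical impedance tomography (EIT) difference imaging
for bladder-volume monitoring with a planar electrode array — a complete,
tested simulation-and-reconstruction pipeline in R.

Continuous bladder monitoring matters for patients who cannot sense filling
(spinal-cord injury, unconscious or elderly patients); catheterization is
invasive and ultrasound is impractical for continuous use. EIT offers a
non-invasive alternative: a probe with an 8 x 8 array of 4 mm electrodes
(8 mm gaps) rests on the lower abdomen, a back electrode provides the
current return, and boundary voltages are converted into a 3D image of the
conductivity change caused by urine (0.892 S/m) against tissue-like
background (0.1 S/m).

The package implements the whole chain on synthetic cuboid phantoms:

* **Forward model** — complete-electrode-model P1 finite elements on a
  deterministic tetrahedral tank mesh; 10 mA injected from each of the 64
  electrodes in turn, 63 voltages read per injection:
  64 x 63 = 4032 measurements per frame. Sensitivity matrix `J` by the
  adjoint method.
* **Inverse problem** — one-step linearized difference imaging with the
  regularization family

  ```
  delta_x = (J'J + lambda I + eps diag(J'J))^(-1) J' [F(x_p) - V]
  ```

  (Tikhonov: `eps = 0`; NOSER: `lambda = 0`; combined: both terms — the
  default), solved by Cholesky factorization without explicit inverses and
  with measurement whitening by the reference frame.
* **Boundary detection** — the anomaly's steplike edge surface as the
  Laplacian zero-crossing with gradient magnitude above a threshold `T`:
  per-edge tests `|grad f(P1)| + |grad f(P2)| >= 2T` and
  `lap f(P1) * lap f(P2) < 0`, edge elements with >= 3 intersected edges,
  pseudo-edge removal by connected-component size, 3D region growing, and
  crack-free marching-tetrahedra triangulation.
* **Quantification** — 1 mm voxel grid (180 x 150 x 80 = 2,160,000 cubes);
  a cube is counted when >= 4 non-coplanar vertices are enclosed by the
  surface; anomaly position as the half-amplitude-set center of mass
  `sum(sigma_m p_m) / sum(sigma_m)`; signed per-axis position errors as
  percentages of the domain extent.

## Worked example

Simulate the 64 mL phantom model (4 x 4 x 4 cm saline cube, 15 mm under the
electrode plane) at 40 dB channel SNR and run the full pipeline:

```r
library(planareit)
cfg <- phantom_model("64mL", noise = list(snr_db = 40, seed = 1))
st  <- run_full(cfg)
print(st)
#> anomaly_stats: 62123 valid cubes = 62.123 mL; position (89.7, 73.3, 56.7) mm
round(st$volume_error_pct, 2)
#> [1] -2.93
round(st$position_error_pct, 2)
#> [1] -0.15 -1.13 14.60
```

Reading the output: 62,123 valid 1 mm cubes give an estimated volume of
62.1 mL against the true 64 mL (−2.9%). The center of mass lands within
~2 mm laterally of the true center (90, 75, 45) mm; the depth coordinate is
biased toward the electrode array (+14.6% of the 80 mm domain height), the
expected behavior of a one-sided array whose sensitivity decays with depth.

The three-model study (64, 125, 320 mL) in one call:

```r
run_phantom_study(seed = 1)
```

Lateral position errors stay within ~2% for all three models. Volume
recovery is accurate for the 64 mL target but degrades severely for the
larger inclusions (see the methods vignette for the analysis: the linearized
one-step image of a large high-contrast conductor concentrates in a shallow
cap, and the Laplacian zero-crossing surface then encloses a nearly
size-independent region).

A command-line driver with `simulate | reconstruct | extract | quantify |
full` subcommands is installed at `inst/cli/planareit.R`:

```sh
Rscript inst/cli/planareit.R full --out run1 --seed 1 --verbose
```

Each stage persists open-format artifacts (frames as CSV, mesh and fields
as legacy VTK, surfaces as ASCII STL/PLY, statistics as JSON/CSV) into the
run directory, and every stage can restart from them.

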