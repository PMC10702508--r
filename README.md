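# sectmap

Voxel-wise estimation of **mass density** and **proton relative stopping
power (RSP)** from single-energy CT (SECT) Hounsfield units, for proton
therapy treatment planning research.

A proton plan's dose accuracy hinges on converting each CT voxel into the
density and RSP maps the dose engine consumes; the uncertainty of that
conversion is what forces clinical 2.5–3.5 % + 1 mm range margins.
`sectmap` implements three converter families side by side:

1. **Stoichiometric calibration** — the clinical physics reference.  The
   forward attenuation model
   `HU/1000 + 1 = ρ̂_e,w · (1 + Ẑ^1.86 k₁ + Ẑ^3.62 k₂) / (1 + Ẑ_w^1.86 k₁ + Ẑ_w^3.62 k₂)`
   is fitted to mean insert CT numbers of an electron-density phantom by
   bounded nonlinear least squares (k₁, k₂ are the scanner-spectrum
   coefficients), and RSP follows from the Bethe equation with
   Bragg-additivity mean excitation energies and I(water) = 75 eV.  The
   resulting HU → (ρ, RSP) curve is piecewise linear with flat
   extrapolation.
2. **DECT empirical models** — published piecewise formulas,
   ρ = −0.1746 + 1.176 ρe (0.26 g/cm³ for inflated lung) and a
   four-branch RSP model in Zeff, taking scanner-console ρe/Zeff maps as
   input.
3. **Deep voxel regressors** — an ANN (one hidden layer of 30 tanh
   units on the voxel HU), a 1D FCNN (three kernel-3 convolutions over an
   along-row HU window + fully connected 256/128/64 layers) and a 1D
   ResNet (kernel-7 stem + five residual blocks with channels
   64/128/256/512/1024 and projection shortcuts), trained per target with
   minibatch Adam on per-voxel MSE.  The network engine (im2col + BLAS
   convolutions, backprop, Adam) is implemented in the package and
   verified against finite-difference gradients.

Because the underlying physical phantom scans are not distributable, the
package also ships a **virtual phantom simulator** (electron-density and
anthropomorphic-torso layouts, forward-model HU, Gaussian noise, optional
bias field, paired ground truth) and **APE/MAPE evaluation** machinery
(per-voxel absolute percentage error maps, per-tissue MAPE ± sd tables,
model comparison with best-per-cell flags), so the complete
train/calibrate/evaluate study runs from code alone.

## Worked example

```r
library(sectmap)

mats <- read_material_library()             # CIRS 062M / Gammex 467 / torso fixtures
k    <- spectrum_coefficients(1.5e-3, 2.5e-5)

# simulate an electron-density phantom scan (sigma = 15 HU)
vol <- render_phantom(make_layout("EDP_062M"), mats, k,
                      noise_model(sigma_hu = 15, seed = 1))

# stoichiometric calibration from the noisy insert means
ins  <- vol$truth[vol$truth$label != 1, ]
hu   <- vapply(ins$label, function(l) mean(vol$hu[vol$labels == l]), numeric(1))
fit  <- fit_spectrum_coefficients(mats[ins$material], hu)
fit
#> <spectrum_coefficients> k1 = 0.00148947, k2 = 2.50215e-05
#>   fitted on 9 observations, residual norm 0.94 HU

curve <- build_calibration_curve(c(mats["Water"], mats[ins$material]), fit)
head(curve$nodes, 3)
#>           hu   rho       rsp      material
#> 1 -802.66228 0.203 0.1995710 Lung (Inhale)
#> 2 -519.99442 0.494 0.4850011 Lung (Exhale)
#> 3  -84.37318 0.965 0.9650896       Adipose
```

The fitted coefficients recover the generating pair (1.5e-3, 2.5e-5) to
better than 1 % from a σ = 15 HU scan.  The full study analogue — train the
ANN/FCNN/ResNet on the electron-density phantom, test on the torso
phantom, compare all five models — is one call:

```r
r <- run_benchmark(seed = 1, out_dir = "bench")
r$comparison$DENSITY
```

which prints (mass density MAPE %, best model per row flagged; seed 1):

| Tissue | Stoichiometric | DECT empirical | ANN | FCNN | ResNet |
|---|---|---|---|---|---|
| Torso Lung | 4.53 ± 5.08 | — | 6.58 ± 4.93 | **1.36 ± 1.83** | 5.45 ± 6.35 |
| Torso Bone | 0.55 ± 0.41 | 1.09 ± 0.81 | 1.80 ± 0.59 | **0.44 ± 0.33** | 1.62 ± 1.65 |
| Torso Spinal Cord | 1.33 ± 0.67 | 1.31 ± 0.93 | 0.94 ± 0.72 | **0.92 ± 0.32** | 1.56 ± 0.78 |
| Torso Brain | 1.06 ± 0.58 | 1.44 ± 1.11 | **0.89 ± 0.67** | 0.99 ± 0.75 | 2.85 ± 2.56 |
| Torso Breast | **0.68 ± 0.31** | 1.53 ± 1.13 | 1.01 ± 0.78 | 0.97 ± 0.54 | 1.45 ± 1.07 |
| Torso Soft Tissue | 1.38 ± 0.85 | 1.35 ± 1.01 | **1.01 ± 0.75** | 1.12 ± 0.34 | 1.50 ± 1.00 |

Reading it: the stoichiometric curve is noise-limited, worst where the
curve is steepest (lung); the single-voxel ANN cannot denoise and does
worse than the curve on lung; the windowed FCNN both denoises and fits the
conversion, cutting the lung error roughly threefold and beating the
reference on bone — the qualitative pattern of the physical-phantom
studies this package emulates.  The DECT density model does not apply to
normal lung tissue (its lung cell is empty by construction).

A command-line wrapper covers the same pipeline
(`inst/cli/sectmap simulate | calibrate | empirical | train | predict |
evaluate | benchmark`), and the methods vignette
(`vignettes/sectmap-methods.Rmd`) documents the models, parameter choices
and the simulator's scope.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the end-to-end synthetic benchmark at the given seed (simulation,
spectrum-coefficient fit, calibration curve, network training, five-model
evaluation), writes the report CSVs and comparison tables under
`results/benchmark/`, and writes the results JSON to `--out`.
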