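---
title: "Methods: SECT tissue parametrization in sectmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SECT tissue parametrization in sectmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Proton treatment planning converts a single-energy CT (SECT) volume of the
patient into voxel maps of mass density and relative stopping power (RSP).
Both conversions are uncertain — clinically a 2.5–3.5 % + 1 mm range margin
absorbs the error — because a single CT number confounds density and
elemental composition, and because CT noise propagates through a steep
conversion curve.  `sectmap` implements and compares three families of
voxel-wise converters:

1. **Stoichiometric calibration** (physics reference): a parametric
   attenuation model fitted to scanned tissue surrogates, plus the Bethe
   equation.
2. **DECT empirical models** (second reference): published piecewise
   formulas taking relative electron density and effective atomic number as
   scanner-console inputs.
3. **Deep voxel regressors**: an ANN, a 1D fully convolutional network
   (FCNN) and a 1D residual network (ResNet) trained on phantom scans with
   known ground truth.

Because the underlying physical phantom scans are not publicly
distributable, the package ships a virtual phantom simulator so that the
complete train/calibrate/evaluate loop is reproducible from code alone.

## Stoichiometric calibration

The linear attenuation of a mixture relative to water is parametrized as

$$\frac{HU}{1000} + 1 = \hat\rho_{e,w}\,
  \frac{1 + \hat Z^{1.86} k_1 + \hat Z^{3.62} k_2}
       {1 + \hat Z_w^{1.86} k_1 + \hat Z_w^{3.62} k_2},$$

where $\hat\rho_{e,w}$ is the electron density relative to water, $\hat Z$
an effective atomic number, and $k_1, k_2$ ratios of the coherent-scatter
and photoelectric weights to the incoherent (Klein–Nishina) weight.  The
two exponents come from the classical $Z^n$ / $Z^m$ cross-section
parametrization with $n = 2.86$ and $m = 4.62$ (each term's
electron-weighted cross section carries $Z^{n-1}$ and $Z^{m-1}$).
`fit_spectrum_coefficients()` estimates $(k_1, k_2)$ by bounded nonlinear
least squares (`nls`, `port` algorithm, lower bounds 0, start
$(10^{-3}, 10^{-4})$, tolerance $10^{-12}$) from the mean insert CT numbers
of an electron-density phantom scan.  Bounds matter: both ratios are small
positive numbers and an unbounded solver can wander negative.  A design in
which every material is water-like (equal $\hat Z$) makes the ratio
collapse to $\hat\rho_{e,w}$ for *any* coefficients; the fit refuses such
designs explicitly.

The effective atomic number is never defined in the source formulation; we
adopt the standard electron-fraction power mean
$\hat Z = (\sum_i \lambda_i Z_i^p / \sum_i \lambda_i)^{1/p}$ with
$\lambda_i = w_i Z_i / A_i$, evaluating each term of the attenuation model
with its own exponent ($p = 1.86$ and $3.62$).  DECT-style maps use the
conventional $p = 3.1$.

RSP at therapeutic energies comes from the Bethe equation as a ratio to
water,

$$RSP = \hat\rho_{e,w}\,
  \frac{\ln[2 m_e c^2 \beta^2 / (I_m(1-\beta^2)) - \beta^2]}
       {\ln[2 m_e c^2 \beta^2 / (I_w(1-\beta^2)) - \beta^2]},$$

with $I_w = 75$ eV (ICRU 49).  The proton energy that sets $\beta$ is not
fixed by the method; we default to a mid-range 100 MeV
($\beta^2 = 1 - (m_p c^2 / (T + m_p c^2))^2 \approx 0.183$), exposed in
`physics_constants()`.  RSP varies only weakly with $T$ in the therapeutic
window.  The mixture mean excitation energy $I_m$ uses the Bragg additivity
rule (electron-fraction log mean).  A known consequence: Bragg additivity
over the shipped elemental I-values gives $I \approx 69$ eV for water
rather than the assigned 75 eV, so the stoichiometric RSP carries a small
systematic offset for water-like tissues (about 1 %).  This is a real
limitation of the additivity rule, visible in the benchmark's soft-tissue
RSP rows, and we deliberately do not calibrate it away.

The calibration curve maps HU to (density, RSP) through the calibration
materials themselves: each material contributes a node (predicted HU,
library density, Bethe RSP).  Between nodes we interpolate piecewise
linearly and extrapolate flat beyond the end nodes — the common clinical
TPS convention; the source method does not state its interpolation rule, so
this is a package decision.  Duplicate HU nodes keep the denser material
(with a warning).

## DECT empirical models

The density model is affine in relative electron density,
$\rho = -0.1746 + 1.176\,\rho_e$, with inflated lung fixed at
0.26 g/cm³; the RSP model is piecewise in $Z_{eff}$ with
left-closed/right-open branch boundaries at 0.5, 8.5 and 10.  Both are
implemented exactly as printed, including the physically odd
$0 \le Z_{eff} < 0.5$ branch (no element has $Z_{eff} < 1$); that branch is
unreachable for real inputs and documented as such.  $\rho_e$ and $Z_{eff}$
are accepted as given maps — the package never performs dual-energy
material decomposition.  Inflated lung is an explicit mask, not an HU
threshold, because no detection rule is defined.  The density model is not
applicable to normal lung tissue, and lung rows are omitted from DECT
density evaluation accordingly.

## Deep voxel regressors

All three networks regress a scalar tissue property from CT-number input,
one network per target (density and RSP are never derived from one
another):

* **ANN** — input is the single voxel's HU; one hidden layer of 30 tanh
  units; scalar linear output.
* **FCNN** — input is an along-row HU window; three kernel-3 stride-1
  convolutions (8, 16, 16 channels — widths are package choices, the source
  states only "seven hidden layers"), then fully connected layers of widths
  256, 128, 64 and a linear output.
* **ResNet** — a kernel-7 stride-2 stem convolution (64 channels), five
  residual blocks with channels 64, 128, 256, 512, 1024 (each two
  convolutions plus a 1×1 projection shortcut), global average pooling and
  a linear output.  The published block table is internally inconsistent:
  it lists shortcut stride 2 in every block although block 1's main path
  has stride 1 and block 5's has total stride 4, and its kernel-2/pad-1
  rows would grow the signal at stride 1.  We resolve this by using
  "same"-style padding (every convolution's output length is
  $\lceil L/\mathrm{stride}\rceil$) and setting each shortcut's stride to
  the product of its block's main-path strides — the unique choice that
  reproduces the table's shapes wherever the table is self-consistent.  The
  accompanying text also says "four sequences of residual blocks" where the
  table lists five; we follow the table.  The output head is
  zero-initialized: global average pooling over 1024 He-initialized
  channels otherwise gives the untrained network a large output variance
  that wastes the optimizer's budget on a transient.

How a 2D slice becomes 1D input is not defined in the source; we use
along-row (x-direction) sliding windows centered on the predicted voxel,
edge-padded by replication (default length 64, configurable — the
benchmark uses 8 for the FCNN and 16 for the ResNet, see below).  HU inputs are scaled by 1/1000 to keep
tanh/ReLU units in a healthy range; targets are untouched.

Training uses minibatch Adam on the mean squared per-voxel error (the
source specifies only "the difference between the true value and predicted
value at each voxel"; MSE is the standard regression reading, and an L1
option is exposed).  Protocol-faithful defaults: batch size 100, learning
rate $10^{-5}$.  The epoch budget, early stopping (patience on a 10 %
label-stratified validation split) and the split itself are package
choices.  All randomness — initialization, shuffling, splitting — derives
from explicit seeds; two runs with the same seed are bitwise identical, and
`parameter_checksum()` fingerprints the weights.

## The virtual phantom world

`make_layout()` and `render_phantom()` emulate the four physical phantoms
as 2.5D cylinder cartoons: a stack of identical axial slices (all methods
are voxel-wise, so axial variation adds cost without coverage), voxels
assigned by center-point membership (no partial-volume mixing), noiseless
HU from the forward attenuation model at "scanner-truth" coefficients,
plus additive Gaussian voxel noise and an optional smooth multiplicative
bias field.  Defaults: 128×128 in-plane at 1 mm, 8 slices, σ = 15 HU (a
plausible clinical head-protocol noise level; the physical scans' per-site
CTDI values cannot be translated into σ without scanner modelling), bias
amplitude 0.

Geometry is proportioned so that insert diameters (~26 voxels) exceed the
convolutional window (8–16 voxels in the benchmark), as in the physical
phantoms where 30 mm inserts span ~46 voxels of a 512 grid.  This ratio
matters: if the window is wider than the insert, every training window
mixes insert and background context and the FCNN's fully connected layers
latch onto training-phantom context that does not transfer to the test
phantom.  We observed exactly this failure mode at a 32-voxel window with
9 mm inserts before fixing the proportions.

The torso templates are simplified ellipse-and-disc stand-ins for the
anthropomorphic phantoms (lungs, bone, spinal cord, a brain-surrogate
region, breast, and a soft-tissue ROI in a soft-tissue body) — emulations,
not geometric replicas.  Insert compositions are approximations (vendor
compositions are unpublished); densities and reference RSP values are the
published manufacturer/measured values.  Ground truth tables carry each
label's density, reference RSP, relative electron density and
$Z_{eff}(3.1)$.

What a green synthetic benchmark does **not** establish: performance on
real scanner data with beam hardening, scatter, reconstruction kernels and
partial-volume mixing, none of which the simulator models; nor accuracy of
the approximate surrogate compositions.

## The end-to-end benchmark

`run_benchmark()` mirrors the published study design at desk scale: train
on the electron-density phantom, test on the torso phantom, evaluate all
five models per tissue with MAPE ± APE-sd and best-per-cell flags.  The
DECT reference receives truth $\rho_e$/$Z_{eff}$ maps per label plus
Gaussian console noise (σ = 0.015 on $\rho_e$, 0.3 on $Z_{eff}$ — set once
as plausible scanner-console variability).  Evaluation runs on contoured
tissue ROIs (the per-material insert regions), mirroring the manual
contours of the physical study; the body background is used for training
but not scored.

Scaling decisions, fixed before acceptance and documented here: Adam at
$10^{-3}$ instead of $10^{-5}$ with capped per-label sample counts and
small epoch budgets (the published protocol trained on a GPU with an
unstated epoch budget; at $10^{-5}$ a CPU-minutes budget cannot converge),
and short windows (8 voxels for the FCNN; 16, its downsampling minimum, for the ResNet) with the FCNN trained for the full fixed budget — early stopping is disabled because the validation MSE plateaus long before the out-of-domain denoising stops improving.  The ResNet, two orders of magnitude more expensive
per sample, gets a deliberately small budget (10 epochs on ≤2500 samples);
it is evaluated like the others but is expected to be the least converged
of the three — consistent with the source's own observation that the
deepest model is not necessarily the most robust when the input is a
single SECT channel.

Numerical behaviour to expect, all reproduced by the acceptance tests: the
stoichiometric curve is essentially exact in the mean (the simulator's
forward model is the same attenuation law) so its per-tissue MAPE is almost
pure noise propagation, steepest where the curve is steep (lung); the ANN
cannot denoise (single-voxel input) and tracks the noise floor; the FCNN
averages over its window and beats both references on the noise-dominated
lung and bone rows while staying under 2 % on soft tissue.

## Degenerate inputs and numeric choices

* Unknown element symbols, non-unit weight-fraction sums, negative
  densities: loud errors at construction.
* Bethe logarithm argument ≤ 1 (proton energy too low for the material's
  I): domain error.
* NaN HU voxels propagate as NA through curve application, with a logged
  count.
* Label volumes must be grid-congruent with the CT; mismatches are errors,
  never silent resampling.
* Duplicate calibration nodes: densest material wins, with a warning.
* APE requires a nonzero reference; a zero-reference label is an error
  naming the label.
* Percentages are carried as percent (not fractions) end to end.

## Known limitations

* The simulator's noise is i.i.d. Gaussian; real CT noise is correlated
  and object-dependent, and artifacts (rings, streaks) are not modelled
  beyond an optional smooth bias field.
* The stoichiometric RSP inherits the Bragg-additivity bias discussed
  above.
* DICOM support is a minimal explicit-VR little-endian CT subset intended
  for round-tripping simulated data, not a general DICOM implementation.
* The ResNet is faithful in architecture but not in training budget at
  benchmark scale.
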