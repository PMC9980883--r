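---
title: "Methods: forward models, the three-ratio loss, and montage optimizers"
author: "tistim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forward models, the three-ratio loss, and montage optimizers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models implemented in `tistim`, the assumptions
behind them, the tunable parameters and their defaults, and the design
choices made where the design was genuinely open. It states no empirical
result that the package's tests or `scripts/acceptance.R` do not themselves
compute.

## Problem setting

Temporal-interference stimulation (tTIS) drives two sets of scalp
electrodes at nearby high frequencies. Each carrier is too fast to modulate
neurons directly; the envelope of their superposition beats at the
difference frequency and is taken as the effective stimulus. The package
works throughout with the *normal component* of the electric field on the
cortical surface — the direction cortical pyramidal neurons are most
sensitive to — and assumes neural recruitment depends only on the beat
amplitude, not on carrier frequency or waveform details. Nominal carrier
frequencies are carried as metadata only; nothing numeric depends on them.

Under the quasi-static approximation the field is linear in the currents:
for M electrodes with electrode 1 as reference, the N×(M−1) lead-field
matrix `E` maps free-electrode currents (mA) to per-node normal fields
(V/m). The reference current is implied by Kirchhoff's law and never
multiplied in.

## The beat envelope and its two algebraic forms

For per-node signed fields `a = E_n^{f1}`, `b = E_n^{f2}` the package
provides `modulation(a, b, form)` with

* `signed_difference`: `|a + b| − |a − b|`,
* `envelope_min`: `2·min(|a|, |b|)`.

The two agree exactly wherever `a·b ≥ 0` and differ by sign elsewhere.
Physically, for two sinusoids of *different* frequencies a relative sign is
only a phase offset, and the beat envelope is `2·min(|a|, |b|)` regardless;
the envelope form is therefore the canonical reported modulation, and tACS
modulation is the peak-to-peak value `2|E_n|` (its `modulation(f, f)`
reduction).

**Training form.** The optimizers also default to the envelope form, and
this was a deliberate decision. The generator network feeds each
per-frequency field layer through an absolute-value activation before the
modulation layer, so the difference-of-absolutes expression is evaluated on
*amplitudes*, where it equals the envelope. Evaluating it instead on raw
signed fields makes the ratio loss unbounded below: where the two fields
have opposite signs the modulation goes negative, the concentration ratio
can flip sign at a random initialization, and gradient descent then chases
`MR/(PR·CR) → −∞`. We observed exactly this failure on the spherical
fixture. The raw signed form remains available via
`modulationForm = "signed_difference"` for users who want to study it, with
this caveat documented.

## The three-ratio loss

For a target node set T (areas approximated by node counts, with no
triangle-area weighting):

* `PR = max_T Mod / max_{T^c} Mod`
* `CR = (Σ_T Mod / |T|) / (Σ Mod / N)`
* `MR = #{ i ∈ T^c : Mod_i > mean_T Mod } / |T|`
* `Loss = MR / (PR · CR)` (exponents fixed to 1 by default and configurable
  in `stimLoss`).

Numerical conventions, chosen once and tested:

* Mis-stimulation uses a *strict* inequality; a node exactly at the
  target-mean modulation does not count.
* `PR` with a zero non-target peak is `+Inf`; `0/0` returns 0 with a
  warning. `CR` of identically zero modulation is 0. `PR·CR = 0` makes the
  loss `+Inf` with a "degenerate montage" warning.
* For gradient training MR is relaxed to a sigmoid mis-area,
  `Σ_{T^c} 1/(1 + exp(−slope·(Mod_i − mean_T Mod)))`, slope 1 by default in
  the package's V/m scale. PR, CR and exact MR are invariant under positive
  rescaling of the modulation; the smooth MR is not, which is why the slope
  is exposed. At steep slopes the relaxation converges to the exact count
  except for nodes inside the O(1/slope) transition band around the
  threshold — the tests build their "tie-free" instances with a margin
  around the threshold for precisely this reason.

## Safety normalization

Each frequency channel is normalized in two stages: scale so the largest
electrode current is exactly 2 mA, then, if the summed absolute current
exceeds 8 mA, rescale so it equals 8 mA exactly (a zero-sum channel then
carries at most 4 mA of anodal current). Both stages are positive scalar
rescalings, so zero-sum is conserved and exactly one of the two limits is
binding except on the measure-zero boundary. The default applies limits per
frequency channel — matching two independent current sources — with a
`joint` mode (limits on the concatenated channels) available because
hardware that multiplexes both carriers through shared electrodes would
share the budget. Inside the training graph the max and branch points are
handled by subgradients (the branch set has measure zero); no smoothing is
applied.

## Spherical forward model

The FEM head models of subject-specific pipelines are replaced by an
analytic concentric-shell sphere. Electrodes are *point* current sources on
the scalp sphere (the 1 cm disc of HD electrodes is metadata): the
optimization consumes only the lead-field matrix, and point sources keep
the model closed-form. For each Legendre degree `l ≥ 1` the potential in
shell k is `A_k (r/R)^l + B_k (R/r)^{l+1}` times `P_l(cos γ)`; coefficients
propagate outward from the innermost shell (regularity: `B = 0`) by
enforcing continuity of `V` and `σ ∂V/∂r`, and the surface condition for a
unit point current fixes the overall scale. Columns are radial
(surface-normal) fields for (+1 mA at electrode m+1, −1 mA at reference),
in V/m per mA. Explicit 2×2 interface inverses keep equal-conductivity
shells exactly transparent, so the homogeneous-sphere series is recovered
as a special case — the basis of the forward-model acceptance check, which
agrees with an independently coded order-420 homogeneous series to better
than 1e−6 (observed: machine precision).

Defaults, all configurable:

* Shells scalp/skull/CSF/brain at 92/86/80/78 mm — typical adult
  proportions; subject geometry is out of scope. Conductivities 0.465,
  0.010, 1.654, 0.276 S/m; white matter (0.126 S/m) available as an
  optional fifth shell at 65 mm, below the default cortex sampling radius
  so cortex nodes stay in gray matter.
* Series order L = 80. With cortex at 70 mm the term ratio is 70/92 ≈ 0.76,
  so the geometric tail at L = 80 is ~3e−10 of the leading scale. A
  truncation warning carrying the tail estimate fires when the relative
  tail exceeds `tailTolerance` (1e−4), as happens for nodes close to the
  scalp at low orders.
* Units are fixed: mm, mA, S/m, V/m — keeping the unit-slope sigmoid on a
  sane numeric scale.
* 69 electrodes by default, placed by a deterministic Fibonacci lattice on
  the upper spherical cap (polar angle ≤ 75°) plus a 12-electrode ring at
  82°, standing in for a 10–10-patterned HD cap. The published layouts
  project from an ellipsoid whose parameters are not recoverable, and the
  optimizers are layout-agnostic, so exact 10–10 coordinates are not
  reproduced.

**Cortex node sampling.** `sampleCortexNodes(n, radius)` places nodes
quasi-uniformly on a 70 mm sphere. A single spherical surface, however, has
no structure at depth: every depth-indexed anchor along a ray selects the
same surface patch, which would make depth studies vacuous. Real cortical
surfaces reach different depths through folding, so the study fixtures use
`innerRadius` to fill the 25–70 mm shell with uniform volume density
(low-discrepancy radii, Fibonacci directions, a fixed decorrelating
permutation) as a folded-cortex stand-in. Node normals are radial by
convention in both cases.

## Random lead-field fixture

`generateRandomLeadField` emulates the two properties of FEM lead fields
the optimizers actually exploit: spatial smoothness over the cortex
(Gaussian radial-basis fields with a 30 mm length scale) and per-electrode
magnitude decay with distance from that electrode (`exp(−depth_decay·d)`,
default 0.03/mm, 0 disables the trend). It is seeded and bitwise
reproducible. It does *not* emulate tissue boundaries, anisotropy,
tangential field components, the spatial correlation between columns of
neighboring electrodes, or realistic amplitude spectra — so tests passing
on it show the optimizers handle smooth, depth-attenuated linear forward
models, not that they handle real heads.

## Targets and study designs

Depth-indexed targets map index i ∈ 1..5 to an anchor at radius
`(1 − 0.12·i)` times the mean cortex radius along a fixed anterior
meridian, then take the 50 nearest nodes (k-nearest by Euclidean distance,
verified against a brute-force oracle). This preserves the monotone
shallow-to-deep ordering that the depth design tests; the head-proportion
construction of the original design is anatomy-specific and out of scope.
Multi-target runs use four fixed, well-separated anchors at 0.75 of the
cortex radius (anterior/posterior × left/right combinations standing in
for the prefrontal and parieto-temporo-occipital folds); the partition
plane used for the separate two-hemisphere evaluation is always an explicit
design field (`"y"` = left/right, `"x"` = anterior/posterior), never
inferred, because the published description of which pair gets which plane
is internally inconsistent. Replicates are seeds: five by default, a
desk-scale substitute for a cohort of head models, and trend claims are
asserted as majority-of-seeds properties because the optimizers are
stochastic in their initialization.

## Generator network (USNN)

The generator takes a constant unit input — no data, the setting is
unsupervised — through fully connected hidden layers (linear map, ReLU,
layer normalization with trainable gain/offset, ε = 1e−5) to a linear
electrode layer with one output per free electrode per frequency channel
(2(M−1) outputs for tTIS, M−1 for tACS). The downstream physics — zero-sum
expansion, safety normalization, field superposition, envelope, loss — is
fixed and non-trainable. Everything is implemented with hand-written
reverse-mode gradients (verified against central finite differences in the
test suite) and Adam; no autodiff framework is used.

Defaults and choices:

* Three hidden layers of width 64 — the smallest stack that converged
  reliably in exploratory runs; depth/width are configurable. The
  overparameterized generator exists to escape the local minima that plague
  direct gradient descent on the currents.
* Zero-sum is imposed *by construction* (the reference electrode carries
  minus the sum of the generator's M−1 free outputs) rather than learned,
  so Kirchhoff's law holds exactly at every step.
* Adam at learning rate 1e−3 with standard moment decays (0.9/0.999) —
  library-conventional defaults, surfaced in `UsnnConfig`.
* 1000 epochs for single targets, 2000 for multi-target studies.
* The *minimum-loss iterate* is returned, not the last: with a fixed
  per-epoch cost the extra bookkeeping is free and dominates last-iterate
  returns. The recorded best loss is asserted (in tests) to equal
  `patternLoss` of the returned pattern.
* Degenerate all-zero generator output at initialization triggers one
  re-initialization with `seed + 1`, then an error; a NaN loss aborts with
  a diagnostic naming the learning rate and slope.
* Training is exactly deterministic given the configuration: the only
  random element is the seeded weight initialization, and the
  implementation is single-threaded base R.

On small instances the network is checked against a dense grid search over
channel directions (safety normalization removes per-channel scale, so a
3-electrode tTIS instance reduces to two angles). As a stochastic
optimizer it can occasionally stall in a local minimum from an unlucky
initialization, so the optimality check runs a small multi-start (best of
three seeds at default settings) — the way a practitioner would run it.

## Genetic-algorithm baselines

Both GA encodings minimize the same loss as the network (smooth MR by
default). `two_pair` chromosomes hold (anode, cathode, current magnitude)
per frequency — note the magnitude gene is inert after safety
normalization of a single pair, which always pins the pair at ±2 mA;
`hd` chromosomes hold all 2(M−1) free currents. Operators are binary
tournament selection, uniform crossover (rate 0.9), Gaussian mutation
(rate 0.1, s.d. = 0.2 of the 4 mA current range; index genes are resampled
uniformly and anode/cathode collisions repaired), and elite conservation
(10 by default), making the per-generation best loss non-increasing.
These are conventional GA settings, declared rather than inferred, and all
exposed in `GaConfig`. Fitness evaluation is vectorized across the
population. Evaluation-call bookkeeping (epochs for the network,
population × generations for the GA) is reported by the comparison driver.

## Problem sizes

The test suite and acceptance script run at desk scale, chosen once:
500-node, 69-electrode folded-cortex spherical fixtures for the depth and
budget studies (400–1000 epochs, five seeds), a 2000-node fixture for the
single timed full-scale run, 60-node spheres for forward-model fidelity,
and 10–30-node fixtures for oracle comparisons. These sizes keep every
oracle exhaustively checkable while exercising the same code paths as
full-scale runs.

## Known limitations

* The spherical model omits anatomy, tissue anisotropy and electrode-skin
  interface effects; absolute field magnitudes should not be read as
  dosimetry.
* Only the normal field component is modeled; directional envelope
  maximization over orientations is out of scope.
* Neural response is reduced to envelope amplitude; no recruitment model.
* The smooth mis-area is unit-sensitive through its slope; comparisons
  across lead fields with very different field scales should set the slope
  accordingly.
* Each optimization is per-instance; nothing is learned that transfers
  across head models.
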