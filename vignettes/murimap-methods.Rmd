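---
title: "Models and methods behind murimap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind murimap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

murimap processes mouse brain MRI sessions — anatomical T2-weighted
volumes, diffusion-weighted series and resting-state BOLD series — into
atlas-referenced quantitative outputs: bias-corrected anatomy, scalar
diffusion maps, streamline tractograms, and structural and functional
connectivity matrices. This vignette explains the models, the parameters
that matter, the numerical choices, and what the synthetic phantoms used
by the test suite do and do not establish about real data.

## Geometry and conventions

A volume is an array plus per-axis voxel spacing in mm, a three-letter
anatomical orientation code, and (for 4D series) the repetition time in
seconds. All processing happens in the right-handed "neurological" RAS
frame: the first storage axis increases toward the subject's right, the
second anteriorly, the third superiorly. Re-orientation is a pure index
permutation/flip — never an interpolation — so the voxel value multiset
is preserved exactly. Voxel indices are 0-based and world coordinates are
`index × voxel_size`; the world origin is the corner voxel's centre. The
header-scaling utility multiplies the stored voxel size by a constant
(typically 10, to mimic human-scale geometry for tools calibrated to it)
while leaving the data bit-identical; it is exposed as an explicit
operation rather than auto-applied, since nothing inside the package
needs the trick itself.

Transforms follow the resampling (pull-back) convention: a transform maps
*target-grid* world points to *source* points, and applying it means
sampling the source image at the mapped points. A session chain for a
modality therefore runs: modality affine (modality grid → anatomy space),
then the session's non-linear field, then the anatomy affine (anatomy →
template/atlas space). The non-linear field is estimated once per session
on the anatomical scan and reused verbatim by every other modality; only
the small affine link is re-estimated per modality. Label and mask images
are always resampled nearest-neighbour, so a warped label set can shrink
but never grow.

## Noise and quality metrics

Air-background voxels of a magnitude MR image follow a Rayleigh
distribution with scale σ. The estimator histograms the image (256 bins),
smooths the counts, finds the first antimode after the background mode
(requiring a genuine dip — below half the mode — followed by a later
tissue peak), and fits σ by maximum likelihood to all voxels below that
cutoff, using the *truncated* Rayleigh likelihood so the cutoff itself
introduces no bias. When no antimode exists (e.g. a pure-noise image) the
fit falls back to the lowest intensity decile, again with the truncated
likelihood. SNR is mean in-mask signal over the Rayleigh noise standard
deviation σ·√(2 − π/2), reported both as a ratio and in dB.

Image agreement is summarized by three metrics: a per-voxel L2 (the
root-mean-square intensity difference, normalized by voxel count so
values are comparable across image sizes — the normalization is a package
choice), zero-mean normalized cross-correlation, and SSIM with the
standard stabilizers K1 = 0.01, K2 = 0.03 on the joint dynamic range and
a Gaussian window of σ = 1.5 voxels (the SSIM literature's defaults; no
specific parameters are mandated by the pipeline this package
re-implements). Slice-wise variants report all three per axial slice.
Both intensity images and rendered label volumes can be compared; the
modality tag decides nothing here.

## MICO bias-field correction

Surface coils impose a smooth multiplicative intensity field b(x) on the
true tissue signal. MICO models the masked image as b(x)·c_k plus noise,
where c_k is the centroid of tissue class k, and minimizes

E = Σ_x Σ_k u_k(x) · (I(x) − b(x) c_k)²

by alternating exact updates: memberships (with fuzzifier q = 1 the
minimizer is the hard assignment to the nearest class; q = 2, the fuzzy
closed form, is available as an option), centroids (bias-weighted least
squares), and the bias coefficients over a polynomial basis (weighted
normal equations). Each step is an exact coordinate minimizer, so the
energy is non-increasing — the test suite asserts this on every fitted
trace. Defaults: 3 classes (grey matter, white matter, CSF), a 3rd-order
polynomial basis (20 functions over mask coordinates scaled to [−1, 1]),
at most 100 iterations, relative energy tolerance 1e-6. Centroids are
initialized by k-means on the masked intensities under a private fixed
seed; the bias starts at the constant-1 field.

The energy is invariant to the gauge b → s·b, c → c/s; the fit fixes it
by normalizing the field to mean 1 inside the mask. Correction divides by
the field inside the mask and leaves outside voxels untouched; fields
below 1e-6 are treated as an error rather than corrected through.
Whether to fit before or after skull stripping is left to the caller —
both orders work, and the pipeline driver fits inside a preliminary brain
mask.

## Brain masking

The package masks brains without external binaries: Otsu threshold,
largest 6-connected component (a vectorized frontier BFS), one round of
morphological closing with the 6-neighbour cross, and an outer constraint
to a sphere of 1.5× the user's brain-radius hint around the intensity
centre of mass. This is adequate for high-contrast rodent data and for
all phantoms; it makes no claim to match dedicated skull-stripping tools
on low-contrast or pathological scans, for which an externally produced
mask can be supplied anywhere a mask is accepted.

## Registration

The registration scheme is multi-step: template→anatomy is estimated as
an affine (6 DOF rigid by default; 12 DOF available) followed by a
B-spline free-form deformation; DTI and BOLD spaces get affine-only links
to the anatomy and reuse the session's non-linear field.

**Metric.** The similarity between two intensity histograms is a
Kullback–Leibler divergence, and the package exposes exactly that —
`kl_similarity()`, the divergence between the *marginal* histograms over
the overlap — as a validation metric. As an objective for transform
search, however, the marginal form is blind to spatial rearrangement: a
translation of an object inside the field of view changes neither
histogram. The registration objective is therefore the joint-histogram
form of the same divergence — the negative mutual information, i.e.
−KL(joint ‖ product of marginals), with 32 bins per image — which reduces
histogram divergence *and* is sensitive to misalignment, and degrades
gracefully to monomodal cases. The descent contract (final metric ≤
initial metric, asserted on every run) is stated on this joint metric.

**Affine stage.** Derivative-free Nelder–Mead over translation + Euler
angles (+ log-scales and shears at 12 DOF), through a coarse-to-fine
pyramid of factor-2 box-downsampled, lightly smoothed images. Two
safeguards matter on low-contrast data: (1) deterministic random restarts
at the coarsest level, and (2) a greedy 1-D grid sweep over each rotation
axis (±20° in 2.5° steps) before each level's simplex search — the coarse
levels are nearly rotation-insensitive for compact brains, so without the
sweep the fine level can start inside a local basin it cannot leave.
Each level runs three simplex rounds (each restart re-inflates the
simplex, escaping plateaus of the binned metric). If the optimum is worse
than the identity beyond numerical tolerance, the identity is returned
with a warning flag.

**Non-linear stage.** The deformation x → x + u(x) is parameterized by
cubic B-spline control displacements on a regular grid whose spacing is
user-set between 1 and 5 mm (default 2.5 mm). After affine pre-alignment
and z-score intensity normalization, the objective is

mean_x (M(x + u(x)) − F(x))²  +  penalty · Σ relu(−J)  +  bending · ‖Δ²C‖²/n

where J is the Jacobian determinant of the map evaluated on the control
lattice (central differences), the hinge penalizes folding with default
weight 0.3, and the bending term is the mean squared second difference of
the control displacements (normalized per lattice node so the weight,
default 0.005, is grid-size independent). The sum-of-squares data term is
used because the template-to-subject problem this stage serves is
monomodal after normalization; its gradient — the exact derivative of the
trilinear interpolant, chained through the separable B-spline basis — is
analytic, which L-BFGS requires for reliable line searches. The joint
histogram metric is still evaluated before and after for the descent
contract. Diagnostics returned with every fit: the objective trace, the
dense-field folding fraction (warning above 0.5%) and the displacement
RMS.

**What the recovery tests show.** On tissue phantoms, a (3, −2, 1)-voxel
shift is recovered to well under half a voxel, a 10° rotation to under a
degree, and a 2-voxel-amplitude sinusoidal warp to under half a voxel RMS
against the numerically inverted true field (the recovered field is the
*inverse* displacement, computed by fixed-point iteration as the test
oracle). Warp recovery uses a 1.5 mm control grid: a fine-enough basis to
represent the warp, while the piecewise-constant interior of the phantom
leaves finer grids partially unconstrained. Real brains carry texture
that constrains the interior more, but these tests establish correctness
of the machinery, not registration accuracy on real pathology.

## Atlas operations

The ontology is a CSV forest (id, acronym, name, parent_id) — an open
stand-in for database-backed atlas ontologies; validation checks id
uniqueness, parent existence and acyclicity. Parental aggregation walks
each voxel's label up the child→parent chain to the nearest member of the
requested parent set; labels with no such ancestor are mapped to
background and reported as orphans, so non-background voxel count is
conserved up to the reported orphans. Aggregation is idempotent once the
codomain lies inside the parent set.

Hemisphere splitting adds a code offset (default 20000, above any toy
atlas code; configurable for real atlases) to non-background voxels right
of the midline, by default the central x column of the atlas-space
volume — the split is applied in atlas space before any warping, so the
anatomical midline is the atlas's own. Splitting before or after
parental aggregation both work; the operations commute because the
offset arithmetic never collides with ontology ids. ROI overlap reports
and incidence maps are voxel-counting operations with the obvious
contracts (fractions sum to one with background; the incidence value at a
voxel is the number of subjects covering it).

## Diffusion pipeline

**Motion correction** is slice-wise: breathing-driven displacement in
fast rodent EPI differs between slices, so each z-slice's time series is
aligned independently to the series' middle frame with an in-plane rigid
transform. Per slice only 3 DOF exist (two translations, one rotation);
this is the slice-wise adaptation of a 6-DOF volume tool, and the
3-versus-6 difference is inherent to the slice-based mode of operation.
Estimation is a brute-force integer-shift SSD search (±5 voxels) followed
by translation-only and then full-rigid simplex refinement — the staging
prevents the rotation DOF from absorbing translation error on smooth,
low-contrast slices. Reported parameters are the *motion* (the inverse of
the applied correction) in mm and degrees; signal-free slices are flagged
and left untouched.

**Tensor fit.** Ordinary least squares on ln S = ln S0 − b gᵀDg per
masked voxel, all voxels sharing one precomputed pseudo-inverse.
Non-positive signals are floored at machine epsilon and counted; negative
eigenvalues are clamped to zero and counted. Noiseless forward-simulated
signals are recovered to solver precision (the suite asserts 1e-6
relative error over 100 random SPD tensors), and FA/MD/RD/AD follow the
eigenvalue formulas with FA ∈ [0, 1] and FA(0) ≔ 0.

**Tractography** is deterministic Euler integration along the principal
eigenvector: seeds uniform over masked voxels with sub-voxel jitter, step
0.5 mm, direction taken from the *nearest voxel* (no tensor
interpolation — the simplest scheme consistent with Euler stepping),
sign-aligned with the previous direction, propagated both ways from the
seed. A streamline stops on mask exit, FA below `fa_stop`, or a turn
exceeding 55°; fibers outside [0.5, 12] mm are discarded; generation
stops exactly when one million fibers have been *retained* (the cap
counts retained, not attempted, fibers; attempts are capped at 10× for
safety). `fa_stop` defaults to 0.2 — the field-standard white-matter
threshold, exposed as a parameter since the termination criteria were
tuned empirically in the pipeline this package re-implements without the
threshold being printed. Propagation is batched and vectorized (65,536
seeds per batch), which keeps a million-fiber run around half a minute in
pure R; with the seed fixed, output is bit-identical across runs.

**Connectivity.** For each streamline the set of distinct labels its
points traverse is computed; every unordered pair in that set increments
the symmetric matrix, and single-region fibers count on the diagonal
("pass-through" counting). Endpoints-only counting is available
(`count = "end"`) since "passing or ending" admits both readings; fibers
touching no label are tallied as background and excluded.

## rs-fMRI pipeline

The stage order is: slice-wise motion correction → optional slice-timing
correction → in-plane smoothing → temporal high-pass → regional
extraction → optional nuisance regression → Pearson correlation.

Slice timing linearly interpolates each slice's series to the first
acquired slice's phase; it is off by default, as resting-state
correlation analyses are insensitive to sub-TR offsets. Smoothing is a
2D Gaussian of 3.0 mm FWHM applied within each axial slice of each
frame — never across z (EPI voxels are strongly anisotropic in z) nor
across time; the impulse response is asserted against a directly computed
separable kernel.

The high-pass filter at 0.01 Hz subtracts a Gaussian-weighted running-line
(local linear) trend and removes the mean. The Gaussian weight scale is
σ = 1/(4·cutoff) seconds (25 s at 0.01 Hz): this choice attenuates a
0.002 Hz drift by more than 90% while passing 0.05 Hz fluctuations within
10% at TR 1.42 s — the band behaviour the filter contract demands; with
the wider σ = half the cutoff period used by some packages, the running
line tracks a 500 s-period drift too loosely and leaves ~18% of it in the
residual, violating the stop-band requirement. A hard spectral cut
(`method = "fft"`) is available; note a brick wall leaks energy of
non-periodic-in-window drifts into the passband, which is why it is not
the default.

Respiration regressors: the breathing trace is baseline-corrected by a
~2 s running median; inspiration peaks are local maxima exceeding
0.3× the inter-decile range of the corrected trace (an adaptive
threshold — no absolute amplitude is assumed, making the regressor
invariant to trace scaling); the instantaneous rate (1/inter-peak
interval) is sampled at the volume trigger times. Nuisance handling is
ordinary least-squares residualization of the *regional* series against
the regressor, off by default: whether the original pipeline regresses
respiration out of the data or only records it alongside is not
determinable, so both paths are exposed and neither asserted as original
behaviour.

Functional connectivity is plain Pearson correlation of regional mean
series (symmetric, unit diagonal, entries in [−1, 1]; Fisher z
optional); zero-variance regions are flagged and zeroed rather than
propagating NaN. No partial correlation and no global-signal regression
are offered.

## Synthetic data

The generators are pure functions of their arguments — identical seeds
give bit-identical output, and the caller's RNG stream is left
undisturbed. They emulate the *structure* each stage consumes, not mouse
anatomy:

* **Tissue phantom** — nested ellipsoidal intensity classes (unequal
  in-plane semi-axes and posteriorly offset inner classes, so the phantom
  is rotationally asymmetric like real anatomy) on an air background,
  with Rician noise built from two Gaussian channels (SNR defined as
  class mean over Gaussian σ).
* **Bias field** — a random polynomial of chosen order, rescaled to a
  target range (realized inside a supplied mask, e.g. the brain, since
  that is where the range is meaningful) with mean exactly 1.
* **DWI phantom** — straight, bent or crossing tubes of prolate tensors
  (eigenvalues 1.5/0.5/0.5 ×10⁻³ mm²/s) in an isotropic background,
  with signals from the exact exponential model over a 30-direction
  electrostatically optimized scheme (pairwise inverse-square-angle
  repulsion with antipodal symmetry; minimum pairwise angle above 25°).
  The straight tube is a flat-ended cylinder so every fiber can span the
  full length — the geometry the span contract measures.
* **BOLD network** — regional signals as shared within-block factors plus
  idiosyncratic noise plus a common sinusoidal respiration confound;
  voxel series add voxel noise; a matching breathing trace with per-TR
  triggers and the designed correlation matrix are returned. With the
  default variances the designed within-minus-between correlation
  contrast is ≈0.41, so the pipeline contract (>0.3 after processing)
  leaves honest head-room for estimation noise.
* **Toy atlas** — a complete tree ontology with leaves painted as
  mirrored left/right slabs.

Passing phantom tests establishes algorithmic correctness (recovery of
known ground truth under the stated noise), not performance on real mouse
brains: phantoms have no susceptibility distortion, no partial-volume
mixtures beyond voxelization, piecewise-constant tissue interiors, and
exactly Rician noise.

## Problem sizes and runtime

The test suite and the acceptance script run on one CPU in a few minutes
total. Sizes were chosen as the smallest that leave each contract
meaningfully testable: 32×32×24 tissue phantoms for bias correction and
registration; 24×24×12 to 24×32×12 DWI grids (the million-fiber cap run
uses the larger grid and takes ~30 s); 600-frame BOLD series at TR
1.42 s, matching a typical resting-state acquisition length; 64³ noise
fields for the Rayleigh estimator. The pipeline driver's integration test
uses deliberately reduced settings (fewer pyramid levels, few hundred
fibers) since it tests orchestration, not accuracy.

## Known limitations

* The affine metric needs an intensity distribution with some contrast;
  featureless images make the mutual-information surface flat.
* The FFD stage assumes monomodal (or intensity-normalizable) image
  pairs; a Parzen-window information gradient would be needed for truly
  multimodal non-linear registration.
* Fine FFD control grids are under-determined in textureless regions;
  the bending term interpolates, but dense-field accuracy claims are
  only made where the image constrains the field.
* Slice-wise motion correction estimates 3 in-plane DOF per slice;
  through-plane motion is not modelled.
* Tractography uses nearest-voxel principal directions; no tensor
  interpolation, no probabilistic variant, no crossing-fiber model (the
  crossing phantom exists to document this limitation: inside a crossing
  voxel the fitted tensor is oblate and tracking terminates on the FA
  criterion).
* Bruker/DICOM conversion is out of scope; NIfTI is the ingest format.
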