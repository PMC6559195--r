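# murimap

Atlas-based processing of structural and functional mouse brain MRI, as a
self-contained R package.

Small-animal MRI labs routinely acquire three kinds of scans per session —
a T2-weighted anatomical image, a diffusion-weighted (DTI) series and a
resting-state BOLD (rs-fMRI) series — and want every result expressed in
the coordinate system of a reference brain atlas so that regions can be
compared across animals, time points and studies. Mouse data defeats most
human neuroimaging tooling: voxels are an order of magnitude smaller,
surface coils impose strong intensity bias fields, and fast breathing
produces slice-wise (not volume-wise) motion. `murimap` implements the
full processing chain for this setting, with synthetic phantom generators
so that every stage is testable without any external data, binaries or
downloads.

## What the package computes

* **Pre-processing** — re-orientation to the right-handed "neurological"
  RAS convention as a pure index permutation; header voxel-size scaling
  (the ×10 trick that makes mouse data digestible by human-calibrated
  tools); SNR from the Rayleigh air background, estimating the noise
  scale σ by a truncated maximum-likelihood fit below the first histogram
  antimode; brain masking (Otsu threshold, largest 6-connected component,
  morphological closing, sphere constraint).
* **Bias-field correction** — multiplicative intrinsic component
  optimization (MICO): alternating closed-form minimization of
  E = Σ_x Σ_k u_k(x) (I(x) − b(x) c_k)² over fuzzy tissue memberships
  u, class centroids c and a smooth polynomial bias field b, with the
  coefficient-of-variation (CV) metric to quantify the gain in tissue
  homogeneity.
* **Registration** — a multi-step scheme: one affine + B-spline
  free-form-deformation registration of the anatomy per session, with the
  non-linear field reused (never re-estimated) for the DTI and BOLD
  spaces, which are linked by affine-only transforms. The affine stage
  minimizes a joint-histogram Kullback–Leibler metric (negative mutual
  information) by multi-resolution derivative-free search; the FFD stage
  minimizes an intensity data term plus a hinge penalty on negative
  Jacobian determinants (weight 0.3) and a bending-energy regularizer,
  by L-BFGS with analytic gradients. Validation metrics: per-voxel L2,
  normalized cross-correlation (CrC) and SSIM, volume-wise or slice-wise.
* **Atlas operations** — hierarchical ontology handling (CSV of id,
  acronym, name, parent_id): aggregation of fine labels to a parental
  atlas by nearest-ancestor walk, sagittal hemisphere splitting with a
  code offset, ROI overlap reports and multi-subject incidence maps.
* **Diffusion** — slice-wise rigid motion correction (each z-slice's time
  series aligned independently, the behaviour volume-wise correction
  cannot produce); log-linear least-squares tensor fit
  ln S = ln S0 − b gᵀDg; FA / MD / RD / AD maps
  (FA = √(3/2)·‖λ − MD‖/‖λ‖); deterministic Euler streamline tractography
  (step 0.5 mm, 55° angle threshold, fibers kept in [0.5, 12] mm,
  generation stopping at one million retained fibers) and region×region
  structural connectivity matrices.
* **rs-fMRI** — optional slice-timing correction; in-plane-only Gaussian
  smoothing at 3.0 mm FWHM; 0.01 Hz temporal high-pass; respiration
  regressors from a breathing trace with scanner triggers (inspiration
  peaks above an adaptive threshold → instantaneous rate at trigger
  times); regional mean time series and Pearson functional connectivity
  with optional nuisance residualization.
* **Orchestration** — `run_pipeline()` drives a whole session from one
  validated configuration and writes a JSON manifest with MD5 checksums;
  a thin CLI (`inst/cli/murimap`) exposes each stage as a subcommand.

## Worked example

Simulate a diffusion series with a known fiber tube, fit tensors, track,
and count connections between two regions split along the tube:

```r
library(murimap)
dw <- make_dwi(layout = "tube", snr = 20, seed = 7)     # 30-direction scheme
tf <- fit_tensor(dw$dwi, dw$scheme, dw$brain_mask)
print(tf)
#> <tensor_field> 2712 voxels fitted (grid 24 x 24 x 12)
#>   clamped eigenvalue voxels: 0, floored signals: 0
maps <- scalar_maps(tf)
median(maps$FA$data[dw$tube_mask$data != 0])
#> [1] 0.6056471   # truth for eigenvalues (1.5, 0.5, 0.5)e-3 mm^2/s is 0.603
fibers <- track_deterministic(tf, dw$tube_mask, fiber_cap = 2000, seed = 42)
print(fibers)
#> <streamline_set> 2000 fibers (65536 seeds attempted)
#>   length: median 8.5 mm, range [0.5, 8.5] mm, step 0.5 mm
```

Splitting the tube into two regions and counting fibers per region pair:

```r
#> <connectivity_matrix> structural, 2 regions
#>      1    2
#> 1   62 1855
#> 2 1855   83
```

1855 fibers connect the two halves of the tube (the off-diagonal), while
62 and 83 short fibers stay inside one half (the diagonal) — exactly the
geometry the phantom was built with.

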