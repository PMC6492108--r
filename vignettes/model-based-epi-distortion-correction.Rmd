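---
title: "Model-based correction of susceptibility distortion in blip-up/blip-down EPI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based correction of susceptibility distortion in blip-up/blip-down EPI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiunwarp)
```

## The problem

Single-shot EPI trades speed for a very low bandwidth along the phase-encode
(PE) axis — around 10–16 Hz per pixel, against hundreds per pixel along the
readout. Any off-resonance field $\Delta B_0(m,n)$ therefore displaces signal
along PE by $\Delta B_0 / \mathrm{bw}$ pixels. Near large susceptibility
boundaries (the rectal air/tissue interface in prostate imaging is the
canonical case) the field varies by on the order of 120 Hz over a few
pixels, i.e. displacements of 7–12 pixels. Where the field *gradient* along
PE opposes the PE traversal, several true voxels land on one measured voxel:
signal **pile-up**, which no amount of post-hoc image warping can undo,
because the information simply is not there in a single acquisition.
Acquiring the slice twice with opposite PE blip polarity makes the two
corruptions complementary — what piles up in one polarity is stretched (and
thus still separable) in the other — so the pair jointly determines the
undistorted image. A second, global effect is a drift $\Delta f_0$ of the
scanner center frequency between calibration and acquisition, which rigidly
translates the two polarities in opposite directions.

## The forward model

The package's core is the linear encoding operator connecting the
undistorted complex image $x$ to the k-space of coil $j$:

$$
Y_j(k,l) \;=\; \sum_{m,n} C_j(m,n)\, x(m,n)\,
  e^{-i 2\pi (mk/M + nl/N)}\,
  e^{-i 2\pi\,(\Delta B_0(m,n) + \Delta f_0)\, t(k,l)} ,
$$

with $C_j$ the coil sensitivities and $t(k,l)$ the acquisition time of each
k-space sample. Fixed numerical conventions (everything downstream depends
on them being bit-stable):

* **DFT**: unitary and centered — DC at 0-based index $\lfloor n/2\rfloor$,
  negative exponent forward. With $\Delta B_0 \equiv 0$, $\Delta f_0 = 0$
  and a uniform coil, the operator *is* the plain unitary DFT and the
  adjoint is its exact inverse.
* **Sample times** (`build_sample_times()`): EPI acquires one PE line per
  echo, so $t$ varies with the PE-line index only —
  $t = \pm(k - k_{\mathrm{echo}})\,\mathrm{esp}$, zero at the k-space
  center line, sign $+$ for blip-up and $-$ for blip-down. The readout
  dwell (microseconds against a millisecond echo spacing) is ignored by the
  fast operators; `build_sample_times(..., readout_dwell_s =)` together
  with `encoding_matrix()` provides the exact 2-D-time evaluation as a
  reference and as a deliberate inverse-crime breaker for simulations.
* **Sign convention**: blip-up means a positive PE traversal, so a positive
  field displaces signal toward +PE; blip-down negates. `pixel_shift_map()`
  is the first-order geometric reading of the same convention.
* **Partial Fourier**: a `sample_mask` zeroes unacquired lines; the mask is
  mirrored between polarities (the omitted early-echo lines lie on opposite
  k-space sides because the traversal reverses). No homodyne or POCS
  completion is attempted — the joint CG solve treats masked lines as
  missing data, and the mirrored masks in fact restore full joint k-space
  coverage.

The fast path evaluates one modulated-DFT row per PE line (a per-line phase
modulation followed by the two 1-D transforms), implemented in C++ with
dense DFT matrices — exact, bit-reproducible, and $O(M^2N)$ per coil, ample
at the package's working sizes. The $O(M^2N^2)$ dense matrix
(`encoding_matrix()`) is kept for oracle tests on small grids.

## The three-step reconstruction

1. **Center-frequency calibration** (`estimate_frequency_offset()`). The
   drift $\Delta f_0$ is found by maximizing the mutual information between
   the blip-up and blip-down conjugate-phase reconstructions of the
   $b = 0$ data, over a fixed budget of 10 Nelder–Mead simplex updates in
   1-D (start 0 Hz, initial step 10 Hz, standard
   reflection/expansion/contraction coefficients 1/2/0.5/0.5; one
   "iteration" is one simplex update and the returned value is the best
   vertex after the last one). The MI estimator clips each magnitude image
   at its 99th percentile, bins into 64 levels, and applies the
   Miller–Madow correction — without it, the finite-sample bias at 64 bins
   on a 96×96 image is ≈ 0.2 nats, larger than the dependence signal being
   measured. The conjugate-phase magnitudes are Gaussian-smoothed by 1 px
   before binning: on noiseless or high-SNR data the Gibbs ringing of the
   conjugate-phase images otherwise produces spurious MI maxima several Hz
   from the optimum; the smoothing renders the surface unimodal without
   biasing it.
2. **Diffusion-phase correction** (`compute_phase_map()`,
   `apply_phase_to_kspace()`). Diffusion gradients turn tiny tissue motion
   into a smooth, shot-to-shot random image phase; combining shots
   complexly without removing it cancels signal. The voxelwise relative
   phase $\Delta\phi = \mathrm{angle}(x_{cp1}\,\overline{x_{cp2}})$ of the
   two conjugate-phase images (blip-down serving as the phase reference) is
   removed from the blip-up k-space by an image-domain unit-modulus
   multiply. We read the Hermitian-product notation voxelwise — the
   standard relative-phase estimator; an inner-product reading would yield
   a single scalar and could not express the stated spatial variation.
   Voxels whose magnitude product is below $10^{-6}$ of the maximum get
   $\Delta\phi = 0$ (the angle of a near-zero number is noise); no spatial
   smoothing is applied by default, with an optional Gaussian flag for
   low-SNR data. Unacquired lines are re-zeroed after the round trip.
3. **Joint CG solve** (`build_joint_system()`, `cg_reconstruct()`). The two
   polarities are stacked and the normal equations
   $E^H E\,x = E^H \tilde Y$ solved by plain conjugate gradients from
   $x_0 = 0$ — no preconditioner, no regularization. After each iteration
   the normalized residual
   $r = \lVert E^H E x - E^H \tilde Y\rVert_2 / \lVert E^H \tilde Y\rVert_2$
   is recorded; iterations stop at $r < \varepsilon$ with
   $\varepsilon = 2.5\times10^{-3}$ by default, capped at 30 (a safety
   margin over the 10–15 typically observed; steep fields can stall a
   single-polarity solve). A zero right-hand side short-circuits to the
   zero image with $r$ defined as 0.

`reconstruct_dwi_series()` chains the three steps over a diffusion series:
offset from the $b=0$ pair, then per direction phase-correct, stack, solve,
and finally average magnitudes across directions.

## What the synthetic test bed emulates — and what it does not

`make_scene(preset = "prostate120")` is the package's standard validation
condition and deliberately mirrors a prostate DWI protocol at desk scale:
96×96 matrix, 2 mm in-plane pixels, 10.4 Hz/pixel PE bandwidth, 8 receive
coils, 120 Hz peak field. Its parts:

* **Phantom** (`make_phantom()`): an elliptical body (intensity 0.7), a
  brighter central "prostate" ellipse that is the evaluation ROI
  (intensity 2.0, ≈ 13 % of the body area), an exactly zero "rectal air"
  disc posterior to it, and a smooth ±8 % multiplicative texture drawn per
  seed. The ROI is deliberately brighter than the body so that a threshold
  at half its mean separates it — the automatable stand-in for the manual
  contouring used on real scans (`mask_from_magnitude()`: threshold at 50 %
  of the truth-ROI mean, keep the largest connected component).
* **Field** (`make_b0_field()`): a ±20 Hz low-order polynomial background
  plus a negative one-sided Gaussian centered on the air disc, scaled so
  the peak magnitude equals `peak_hz` (default 120 — at 15.80 Hz/pixel
  that is the 7.6-pixel displacement regime). The anterior flank is steep
  enough that the blip-up displacement gradient crosses −1 px/px over the
  posterior ROI boundary — true pile-up, a locally singular blip-up
  operator — while the gentle posterior flank keeps the blip-down operator
  well-conditioned; making the *pair* complementary rather than doubly
  degenerate is the point of the asymmetry. First differences stay below
  ~13 Hz/px (C¹-smooth on the grid).
* **Coils** (`make_coil_maps()`): Gaussian-profile sensitivities at
  equiangular positions just outside the FOV with smooth per-coil phase
  ramps, normalized to unit mean sum-of-squares; 8 coils keep the
  sum-of-squares within a factor 1.5 over the body.
* **Acquisition** (`simulate_acquisition()`): optional degree-≤3 random
  polynomial phase screen (the diffusion-phase mechanism; scaled to 3 rad
  maximum over the *body*, so screens differ substantially where signal
  exists), the exact forward operator, complex Gaussian k-space noise, and
  the partial-Fourier mask. SNR is specified in the image domain: the
  k-space noise SD is set so the object-interior magnitude SNR of the
  conjugate-phase reconstruction equals the request — the scale at which
  DWI SNR is perceived. At `snr = Inf` the simulation is bit-identical to
  `forward_encode()` — there is intentionally no second forward model, and
  the `exact =` switch (dense summation, nonzero readout dwell) exists
  precisely to break that inverse crime on demand.

What passing tests on this bed do **not** show: anatomical realism (no
multi-tissue pelvis, no T2* decay during the readout, no eddy-current
terms, no motion between the two blip scans, no ghosting), and field maps
are supplied exactly in most tests, so field-map error propagation is only
exercised through the dual-echo estimation path.

## Field-map estimation choices

`b0_from_dual_echo()` is the two-echo case of a weighted least-squares
phase-over-echo-time fit: the voxelwise phase of
$e_2\overline{e_1}$ divided by $2\pi\,\Delta TE$, confined to
$\pm 1/(2\Delta TE)$ (±217 Hz at the protocol's 2.3 ms — larger true
offsets alias, a documented limitation; spatial unwrapping is out of
scope), with $|e_1 e_2|$ as downstream weights. `smooth_b0()` implements
robust penalized smoothing: weighted data fidelity plus a squared
second-difference penalty, diagonalized in the 2-D DCT domain, fixed-point
iterated under non-uniform weights, bisquare-reweighted against outlier
voxels, and with the penalty strength chosen by generalized
cross-validation when `strength = "auto"` (the protocol gives no smoothing
parameter, so a data-driven default is the only defensible one). The
output is clamped to the input range — smoothing never invents field values
outside what was measured. `resample_to_epi()` interpolates bilinearly in
physical mm (center-aligned FOVs assumed) and fills 0 Hz outside the source
FOV: no correction where there is no field information.

## Numerical and design notes

* Problem sizes: unit tests run on 8–48 px grids with 1–4 coils; the
  standard scene is 96×96 with 8 coils. The acceptance script reruns the
  full pipeline at the standard scale (10 seeds for the stochastic checks).
* The `prostate120` preset uses full Fourier; partial Fourier (0.75, the
  protocol's half-scan factor) is exercised in dedicated tests where the
  mirrored masks let the joint system recover the phantom to a few percent.
* On the inverse-crime check (noiseless joint data, exact field and
  coils): CG stopped at the *first* residual below
  $\varepsilon = 2.5\times10^{-3}$ lands anywhere in roughly
  $(\varepsilon/2, \varepsilon)$, and the remaining image error lives in
  the smallest-eigenvalue modes of $E^H E$, so the relative image error at
  the stop is consistently ≈ 1.2× the stopping residual, i.e. about
  $2\times10^{-3}$ on the standard scene. Reaching $10^{-3}$ would require
  tightening $\varepsilon$ several-fold or preconditioning, both ruled out
  here by fidelity to the published procedure; the corresponding acceptance
  assertion is left failing rather than silently relaxed.
* Dice conventions: two empty masks score 1 (nothing agrees with nothing
  perfectly); empty against non-empty scores 0.
* The evaluation's "single-polarity corrected" variant is the blip-up
  (pile-up) polarity — the informative comparison; the blip-down single
  solve is reported as an extra row and typically ties the joint solve,
  since its degenerate locus lies outside the ROI.
* Determinism: every generator is a pure function of (parameters, seed);
  seeds are restored after use so package functions do not disturb the
  caller's RNG stream.

## Known limitations

Single-slice 2-D only (no 3-D or multislice interactions); no Nyquist-ghost
or ramp-sampling correction (assumed done upstream by the scanner
reconstruction); the field is assumed static apart from the global drift —
bowel motion between the field-map scan and the EPI scans would violate
that; no motion estimation between the blip pair; at very high b-values the
unregularized normal equations would benefit from preconditioning or
regularization, which are intentionally not included.
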