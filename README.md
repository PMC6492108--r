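# epiunwarp

Joint model-based reconstruction for susceptibility-distorted single-shot
EPI, built for the blip-up/blip-down acquisition scheme used in prostate
diffusion MRI. Near the rectal air/tissue interface the B0 field varies by
~120 Hz, which at an EPI phase-encode bandwidth of 10–16 Hz/pixel displaces
signal by 7 or more pixels and — where the field gradient opposes the
phase-encode traversal — *piles up* several true voxels into one measured
voxel. One acquisition cannot undo pile-up; two acquisitions with opposite
blip polarity can, because the same region is stretched (still separable) in
the reverse traversal.

The package is for MRI reconstruction researchers: it provides the
off-resonance-aware encoding operator, the three-step correction pipeline,
a physics-based synthetic test bed, and quantitative evaluation.

## The model

The undistorted complex image `x` maps to the k-space of coil `j` through

    Y_j(k,l) = sum_{m,n} C_j(m,n) x(m,n)
               exp(-i2π(mk/M + nl/N))
               exp(-i2π(ΔB0(m,n) + Δf0) t(k,l))

with coil sensitivities `C_j`, per-voxel off-resonance `ΔB0` (Hz), global
center-frequency drift `Δf0` (Hz), and sample times `t` that ramp linearly
with the phase-encode line index — positive traversal for blip-up, negated
for blip-down. Reconstruction proceeds in three steps:

1. **Δf0 calibration** — maximize mutual information between the blip-up and
   blip-down conjugate-phase reconstructions of the b = 0 pair (10
   Nelder–Mead iterations).
2. **Diffusion-phase correction** — remove the voxelwise relative phase
   `angle(x_cp1 · conj(x_cp2))` from the blip-up k-space (blip-down is the
   reference), so the two shots combine coherently.
3. **Joint CG solve** — stack both polarities and all coils and solve the
   normal equations `E^H E x = E^H Y` by conjugate gradients, stopping when
   the normalized residual `||E^H E x − E^H Y|| / ||E^H Y||` falls below
   ε = 0.0025.

## Worked example

```r
library(epiunwarp)

# standard synthetic condition: 96x96, 2 mm pixels, 10.4 Hz/px, 8 coils,
# 120 Hz peak field over the rectal-air disc
scene <- make_scene(preset = "prostate120", seed = 1)
pair  <- simulate_pair(scene, f0_hz = 47, snr = 20, seed = 1)

# step 1: recover the center-frequency drift from the pair
est <- estimate_frequency_offset(pair$up, pair$down, scene$coils_true,
                                 scene$b0_true, scene$geometry)
est
#> Center-frequency offset estimate: 48.594 Hz (10 Nelder-Mead iterations)
#>   objective (negative MI) trace: -0.9521 -1.1470 -1.1470 -1.1470 -1.1485 ...

# step 3 (no diffusion phase in this pair): joint model-based solve
b0 <- b0_map(scene$b0_true$delta_b0_hz, f0_offset_hz = est$f0_hz)
rec <- cg_reconstruct(build_joint_system(pair$up, pair$down,
                                         scene$coils_true, b0,
                                         scene$geometry))
rec
#> Model-based reconstruction: 96 x 96 image, 10 CG iterations, converged
#>   final normalized residual: 0.00194

# how much geometry was at stake, and how well each variant does
max(abs(pixel_shift_map(scene$b0_true, scene$geometry)))
#> [1] 11.53846        # pixels of displacement at 10.4 Hz/pixel
evaluate_scene(scene, f0_hz = 47, snr = 20, seed = 1)[, 1:2]
#>            variant      dice
#> 1   uncorrected_up 0.7134638
#> 2 uncorrected_down 0.7579693
#> 3     corrected_up 0.9854369
#> 4   corrected_down 1.0000000
#> 5            joint 1.0000000
```

The drift injected at 47 Hz comes back within 1.6 Hz (0.15 pixel at this
bandwidth); the joint reconstruction converges in 10 iterations and its
thresholded ROI mask matches the truth exactly, while the uncorrected
images — displaced by the drift and, for blip-up, piled up at the
prostate's posterior boundary where the field gradient opposes the
traversal — lose 24–29 Dice points.

A thin CLI over the same functions ships in `inst/cli/epi-unwarp`
(verbs: `simulate`, `fieldmap`, `estimate-offset`, `phase-correct`,
`reconstruct`, `evaluate`, `run-all`).

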