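# Synthetic scene generators and the acquisition simulator.

test_that("every generator is a pure function of (parameters, seed)", {
  g <- grid_geometry(48, 48, bw_per_pixel_hz = 10.4)
  a <- make_scene(geometry = g, seed = 5, peak_hz = 120, n_coils = 4)
  b <- make_scene(geometry = g, seed = 5, peak_hz = 120, n_coils = 4)
  expect_identical(a$truth_image, b$truth_image)
  expect_identical(a$b0_true$delta_b0_hz, b$b0_true$delta_b0_hz)
  expect_identical(a$coils_true$maps, b$coils_true$maps)
  expect_identical(a$roi_mask, b$roi_mask)
  y1 <- simulate_acquisition(a, "blip_up", snr = 20, seed = 3)
  y2 <- simulate_acquisition(b, "blip_up", snr = 20, seed = 3)
  expect_identical(y1$data, y2$data)
  # a different seed changes the texture
  expect_false(identical(a$truth_image,
                         make_scene(geometry = g, seed = 6)$truth_image))
})

test_that("phantom layout: ROI fraction, exact-zero air, masks nest", {
  sc <- make_scene(preset = "prostate120", seed = 1)
  frac <- sum(sc$roi_mask) / sum(sc$body_mask)
  expect_gt(frac, 0.10)
  expect_lt(frac, 0.20)
  expect_true(all(Mod(sc$truth_image)[sc$air_mask] == 0))
  expect_true(all(sc$body_mask[sc$roi_mask]))
  expect_false(any(sc$roi_mask & sc$air_mask))
})

test_that("B0 field: peak scaling, background-only limit, smoothness, pile-up arithmetic", {
  g <- grid_geometry(96, 96, bw_per_pixel_hz = 10.4)
  b120 <- make_b0_field(g, peak_hz = 120, seed = 1)
  expect_equal(max(abs(b120$delta_b0_hz)), 120, tolerance = 1e-9)
  b0 <- make_b0_field(g, peak_hz = 0, seed = 1)
  expect_lte(max(abs(b0$delta_b0_hz)), 20 + 1e-9)
  # C1 smoothness proxy: bounded first differences along both axes
  expect_lt(max(abs(diff(b120$delta_b0_hz))), 25)
  expect_lt(max(abs(diff(t(b120$delta_b0_hz)))), 25)
  # 120 Hz at 15.80 Hz/pixel sits in the 7-8 pixel range
  g158 <- grid_geometry(96, 96, bw_per_pixel_hz = 15.80)
  mx <- max(abs(pixel_shift_map(b120, g158)))
  expect_gte(mx, 7); expect_lte(mx, 8)
  # one polarity folds (pile-up), mirrored for the other
  slope_up <- diff(pixel_shift_map(b120, g, "blip_up"))
  expect_lt(min(1 + slope_up), 0)
  expect_error(make_b0_field(g, peak_hz = -5), "non-negative")
})

test_that("coil maps: unit single-coil option, smooth adequate coverage, determinism", {
  g <- grid_geometry(48, 48, bw_per_pixel_hz = 10.4)
  c1 <- make_coil_maps(g, n_coils = 1, seed = 1)
  expect_equal(c1$maps[, , 1], matrix(1 + 0i, 48, 48))
  c8 <- make_coil_maps(g, n_coils = 8, seed = 1)
  sos <- apply(abs(c8$maps)^2, c(1, 2), sum)
  body <- make_phantom(g, 1)$body_mask
  expect_gt(min(sos[body]), 0.2)
  expect_lt(max(sos[body]) / min(sos[body]), 10)
  expect_identical(c8$maps, make_coil_maps(g, n_coils = 8, seed = 1)$maps)
})

test_that("noiseless simulation is bit-identical to the forward operator (no second model)", {
  g <- grid_geometry(32, 32, bw_per_pixel_hz = 10.4)
  sc <- make_scene(geometry = g, seed = 2, peak_hz = 60, n_coils = 3)
  y <- simulate_acquisition(sc, "blip_up", f0_hz = 13, snr = Inf, seed = 1)
  b0 <- b0_map(sc$b0_true$delta_b0_hz, f0_offset_hz = 13)
  yref <- forward_encode(sc$truth_image, sc$coils_true, b0,
                         build_sample_times(g, "blip_up"), g)
  expect_identical(y$data, yref$data)
  # and the zero-field, uniform-coil, no-offset case is the plain DFT
  scz <- sc; scz$b0_true <- zero_field(g); scz$coils_true <- uniform_coil(g)
  yz <- simulate_acquisition(scz, "blip_up", snr = Inf, seed = 1)
  W <- epiunwarp:::.dft_mat(32)
  expect_lt(max(Mod(yz$data[, , 1] - W %*% sc$truth_image %*% W)), 1e-10)
  expect_error(simulate_acquisition(sc, "blip_up", snr = 0), "snr")
})

test_that("requested image-domain SNR is realized in the conjugate-phase recon", {
  sc <- make_scene(preset = "prostate120", seed = 3)
  g <- sc$geometry
  tu <- build_sample_times(g, "blip_up")
  clean <- simulate_acquisition(sc, "blip_up", snr = Inf, seed = 4)
  noisy <- simulate_acquisition(sc, "blip_up", snr = 20, seed = 4)
  x_clean <- adjoint_encode(clean, sc$coils_true, sc$b0_true, tu, g)
  x_noisy <- adjoint_encode(noisy, sc$coils_true, sc$b0_true, tu, g)
  obj <- sc$body_mask & Mod(sc$truth_image) > 0
  sig <- mean(Mod(x_clean)[obj])
  noise_sd <- sqrt(mean(Mod(x_noisy - x_clean)[obj]^2))  # complex noise SD
  snr_real <- sig / noise_sd
  expect_gt(snr_real, 20 * 0.6)
  expect_lt(snr_real, 20 / 0.6)
})

test_that("simulated offset produces equal and opposite image shifts", {
  # zero-field scene isolates the pure drift translation of +/- f0/bw pixels
  sc <- make_scene(preset = "prostate120", seed = 5)
  g <- sc$geometry
  sc$b0_true <- zero_field(g)
  b0z <- zero_field(g)
  shifts <- sapply(c("blip_up", "blip_down"), function(pol) {
    tt <- build_sample_times(g, pol)
    y47 <- simulate_acquisition(sc, pol, f0_hz = 47, seed = 5)
    y0 <- simulate_acquisition(sc, pol, f0_hz = 0, seed = 5)
    center_of_mass_pe(Mod(adjoint_encode(y47, sc$coils_true, b0z, tt, g))) -
      center_of_mass_pe(Mod(adjoint_encode(y0, sc$coils_true, b0z, tt, g)))
  })
  # sharp phantom edges ring under the non-integer sinc shift, so the
  # center of mass is a slightly blunted probe here (the smooth-blob case
  # pins +/- f0/bw to 0.1 px in the acceptance suite)
  expect_equal(unname(shifts["blip_up"]), 47 / 10.4, tolerance = 0.08)
  expect_equal(unname(shifts["blip_down"]), -47 / 10.4, tolerance = 0.08)
  expect_lt(abs(shifts[["blip_up"]] + shifts[["blip_down"]]), 0.25)
  # with the full susceptibility field the drift still moves the two
  # conjugate-phase recons in opposite directions
  sc2 <- make_scene(preset = "prostate120", seed = 5)
  dir2 <- sapply(c("blip_up", "blip_down"), function(pol) {
    tt <- build_sample_times(g, pol)
    y47 <- simulate_acquisition(sc2, pol, f0_hz = 47, seed = 5)
    y0 <- simulate_acquisition(sc2, pol, f0_hz = 0, seed = 5)
    center_of_mass_pe(Mod(adjoint_encode(y47, sc2$coils_true, sc2$b0_true, tt, g))) -
      center_of_mass_pe(Mod(adjoint_encode(y0, sc2$coils_true, sc2$b0_true, tt, g)))
  })
  expect_gt(dir2[["blip_up"]], 0)
  expect_lt(dir2[["blip_down"]], 0)
})

test_that("pile-up brightens the steep-gradient locus in the uncorrected blip-up image", {
  sc <- make_scene(preset = "prostate120", seed = 6)
  g <- sc$geometry
  y <- simulate_acquisition(sc, "blip_up", snr = Inf, seed = 6)
  sos <- apply(abs(sc$coils_true$maps)^2, c(1, 2), sum)
  img <- Mod(adjoint_encode(y, sc$coils_true, zero_field(g),
                            build_sample_times(g, "blip_up"), g)) / sos
  expect_gte(max(img), 1.5 * max(Mod(sc$truth_image)))
})

test_that("exact dense simulation with readout dwell differs from the fast path (inverse-crime breaker)", {
  g <- grid_geometry(16, 16, bw_per_pixel_hz = 10.4)
  sc <- make_scene(geometry = g, seed = 7, peak_hz = 60, n_coils = 2)
  y_fast <- simulate_acquisition(sc, "blip_up", snr = Inf, seed = 1)
  y_exact0 <- simulate_acquisition(sc, "blip_up", snr = Inf, seed = 1,
                                   exact = TRUE, readout_dwell_s = 0)
  y_exact <- simulate_acquisition(sc, "blip_up", snr = Inf, seed = 1,
                                  exact = TRUE, readout_dwell_s = 2e-5)
  expect_lt(rel_err(y_exact0$data, y_fast$data), 1e-9)
  expect_gt(rel_err(y_exact$data, y_fast$data), 1e-6)
})
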