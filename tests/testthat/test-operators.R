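# Encoding operator E and adjoint E^H: degeneracy to the plain DFT, the
# inner-product adjoint identity, equivalence with the dense reference
# matrix, and the first-order geometric effect of a constant field.

test_that("with zero field and a uniform coil the operator pair is the unitary DFT pair", {
  g <- small_geom(16)
  x <- random_complex(16, 16, seed = 4)
  cm <- uniform_coil(g)
  b0 <- zero_field(g)
  tu <- build_sample_times(g, "blip_up")
  y <- forward_encode(x, cm, b0, tu, g)
  W <- epiunwarp:::.dft_mat(16)
  expect_lt(max(Mod(y$data[, , 1] - W %*% x %*% W)), 1e-12)
  # unitary: E^H E = identity
  xr <- adjoint_encode(y, cm, b0, tu, g)
  expect_lt(max(Mod(xr - x)), 1e-12)
  # impulse at the DC voxel has flat k-space magnitude
  d <- matrix(0 + 0i, 16, 16); d[9, 9] <- 1
  yd <- forward_encode(d, cm, b0, tu, g)
  expect_lt(diff(range(Mod(yd$data))), 1e-12)
})

test_that("adjoint identity <Ex, y> = <x, EH y> holds to 1e-10 over random draws", {
  worst <- 0
  for (i in 1:100) {
    n <- sample(c(8, 16, 24, 32, 48), 1)
    g <- small_geom(n, bw = runif(1, 8, 16),
                    pf = sample(c(1, 0.75), 1))
    J <- sample(1:4, 1)
    pol <- sample(c("blip_up", "blip_down"), 1)
    x <- random_complex(n, n, seed = i)
    cmaps <- array(complex(real = rnorm(n * n * J), imaginary = rnorm(n * n * J)),
                   c(n, n, J))
    cm <- coil_maps(cmaps)
    b0 <- if (i %% 3 == 0) zero_field(g) else
      b0_map(matrix(rnorm(n * n, 0, 50), n, n), f0_offset_hz = rnorm(1, 0, 30))
    tt <- build_sample_times(g, pol)
    y <- random_kspace(g, J, pol, seed = 1000 + i)
    Ex <- forward_encode(x, cm, b0, tt, g)$data
    EHy <- adjoint_encode(y, cm, b0, tt, g)
    lhs <- sum(Conj(as.vector(Ex)) * as.vector(y$data))
    rhs <- sum(Conj(as.vector(x)) * as.vector(EHy))
    worst <- max(worst, Mod(lhs - rhs) / (Mod(lhs) + 1e-300))
  }
  expect_lt(worst, 1e-10)
})

test_that("fast operator matches the dense encoding matrix on 16x16 grids", {
  g <- small_geom(16)
  set.seed(7)
  x <- random_complex(16, 16, seed = 7)
  coil <- random_complex(16, 16, seed = 8)
  b0 <- b0_map(matrix(rnorm(256, 0, 60), 16, 16), f0_offset_hz = 11)
  for (pol in c("blip_up", "blip_down")) {
    tt <- build_sample_times(g, pol)
    E <- encoding_matrix(coil, b0, tt, g)
    y_dense <- matrix(E %*% as.vector(x), 16, 16)
    y_fast <- forward_encode(x, coil_maps(coil), b0, tt, g)$data[, , 1]
    expect_lt(rel_err(y_fast, y_dense), 1e-9)
    # adjoint agrees with the conjugate-transposed dense matrix
    yk <- random_kspace(g, 1, pol, seed = 21)
    x_dense <- matrix(Conj(t(E)) %*% as.vector(yk$data[, , 1]), 16, 16)
    x_fast <- adjoint_encode(yk, coil_maps(coil), b0, tt, g)
    expect_lt(rel_err(x_fast, x_dense), 1e-9)
  }
})

test_that("dense matrix honors partial-Fourier masks and 2-D readout-dwell timing", {
  g <- small_geom(16, pf = 0.75)
  x <- random_complex(16, 16, seed = 3)
  tt <- build_sample_times(g, "blip_up")
  E <- encoding_matrix(matrix(1 + 0i, 16, 16), zero_field(g), tt, g)
  y <- matrix(E %*% as.vector(x), 16, 16)
  expect_true(all(y[!acquired_lines(g, "blip_up"), ] == 0))
  # nonzero dwell makes the time map genuinely 2-D and the fast path refuses it
  tt2 <- build_sample_times(g, "blip_up", readout_dwell_s = 5e-6)
  expect_gt(max(abs(tt2$times_s - tt2$times_s[, 1])), 0)
  b0 <- b0_map(matrix(40, 16, 16))
  expect_error(forward_encode(x, uniform_coil(g), b0, tt2, g), "readout")
  E2 <- encoding_matrix(matrix(1 + 0i, 16, 16), b0, tt2, g)
  expect_false(isTRUE(all.equal(E2, E)))
})

test_that("a constant effective field translates the image by f/bw pixels, opposite per polarity", {
  n <- 64
  g <- grid_geometry(n, n, bw_per_pixel_hz = 15.80)
  blob <- gaussian_blob(n)
  cm <- uniform_coil(g)
  b0 <- zero_field(g, f0 = 47.15)
  b0z <- zero_field(g)
  base <- center_of_mass_pe(blob)
  shifts <- sapply(c("blip_up", "blip_down"), function(pol) {
    tt <- build_sample_times(g, pol)
    y <- forward_encode(blob, cm, b0, tt, g)
    center_of_mass_pe(Mod(adjoint_encode(y, cm, b0z, tt, g))) - base
  })
  expect_equal(unname(shifts["blip_up"]), 47.15 / 15.80, tolerance = 0.1 / 3)
  expect_equal(unname(shifts["blip_down"]), -47.15 / 15.80, tolerance = 0.1 / 3)
  expect_equal(unname(shifts["blip_up"] + shifts["blip_down"]), 0,
               tolerance = 1e-6)
})

test_that("pixel shift map converts field to displacement with polarity sign", {
  g <- grid_geometry(8, 8, bw_per_pixel_hz = 15.80)
  b120 <- b0_map(matrix(120, 8, 8))
  expect_equal(pixel_shift_map(b120, g)[1, 1], 120 / 15.80)
  expect_true(pixel_shift_map(b120, g)[1, 1] >= 7 &&
                pixel_shift_map(b120, g)[1, 1] <= 8)
  expect_equal(pixel_shift_map(zero_field(g), g), matrix(0, 8, 8))
  b47 <- zero_field(g, f0 = 47.15)
  expect_equal(pixel_shift_map(b47, g, "blip_up")[3, 3], 2.984177,
               tolerance = 1e-6)
  expect_equal(pixel_shift_map(b47, g, "blip_down"),
               -pixel_shift_map(b47, g, "blip_up"))
  expect_error(pixel_shift_map(b120, grid_geometry(8, 8)), "geometry")
})

test_that("conjugate-phase recon restores a distorted blob where the field gradient is small", {
  n <- 32
  g <- grid_geometry(n, n, bw_per_pixel_hz = 12)
  blob <- gaussian_blob(n, center = c(12, 16), sigma = 2.5)
  # gentle PE ramp: ~2 px displacement at the blob, small local gradient
  r <- matrix(seq_len(n), n, n)
  b0 <- b0_map(60 * (r - 1) / (n - 1))
  cm <- uniform_coil(g)
  tt <- build_sample_times(g, "blip_up")
  y <- forward_encode(blob, cm, b0, tt, g)
  xcp <- adjoint_encode(y, cm, b0, tt, g)
  expect_lt(abs(center_of_mass_pe(Mod(xcp)) - center_of_mass_pe(blob)), 1)
  # the uncorrected image, by contrast, is visibly displaced
  xun <- adjoint_encode(y, cm, zero_field(g), tt, g)
  expect_gt(abs(center_of_mass_pe(Mod(xun)) - center_of_mass_pe(blob)),
            abs(center_of_mass_pe(Mod(xcp)) - center_of_mass_pe(blob)))
})

test_that("operators accept a column phase-encode axis via transposition", {
  g_row <- small_geom(12)
  g_col <- grid_geometry(12, 12, pe_axis = "col", bw_per_pixel_hz = 10.4)
  x <- random_complex(12, 12, seed = 5)
  b0r <- b0_map(matrix(rnorm(144, 0, 40), 12, 12))
  b0c <- b0_map(t(b0r$delta_b0_hz))
  tu_r <- build_sample_times(g_row, "blip_up")
  tu_c <- build_sample_times(g_col, "blip_up")
  y_row <- forward_encode(x, uniform_coil(g_row), b0r, tu_r, g_row)
  y_col <- forward_encode(t(x), uniform_coil(g_col), b0c, tu_c, g_col)
  expect_lt(max(Mod(t(y_col$data[, , 1]) - y_row$data[, , 1])), 1e-12)
})
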