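# Shared small fixtures, built in code.

small_geom <- function(n = 16, bw = 10.4, pf = 1) {
  grid_geometry(n, n, pixel_mm = c(2, 2), bw_per_pixel_hz = bw,
                partial_fourier = pf)
}

random_complex <- function(n_row, n_col, seed) {
  set.seed(seed)
  matrix(complex(real = rnorm(n_row * n_col),
                 imaginary = rnorm(n_row * n_col)), n_row, n_col)
}

random_kspace <- function(geom, n_coils, polarity, seed, mask = NULL) {
  set.seed(seed)
  n <- geom$n_pe * geom$n_ro * n_coils
  if (is.null(mask)) mask <- acquired_lines(geom, polarity)
  kspace(array(complex(real = rnorm(n), imaginary = rnorm(n)),
               dim = c(geom$n_pe, geom$n_ro, n_coils)),
         polarity = polarity, sample_mask = mask)
}

uniform_coil <- function(geom) coil_maps(matrix(1 + 0i, geom$n_pe, geom$n_ro))

zero_field <- function(geom, f0 = 0)
  b0_map(matrix(0, geom$n_pe, geom$n_ro), f0_offset_hz = f0)

smooth_field <- function(geom, scale = 30, seed = 1) {
  set.seed(seed)
  u <- (seq_len(geom$n_pe) - geom$n_pe / 2) / geom$n_pe
  v <- (seq_len(geom$n_ro) - geom$n_ro / 2) / geom$n_ro
  cf <- runif(5, -1, 1)
  f <- cf[1] * outer(u, rep(1, geom$n_ro)) + cf[2] * outer(rep(1, geom$n_pe), v) +
    cf[3] * outer(u^2, rep(1, geom$n_ro)) + cf[4] * outer(rep(1, geom$n_pe), v^2) +
    cf[5] * outer(u, v)
  b0_map(scale * f / max(abs(f)))
}

gaussian_blob <- function(n, center = c(n / 2, n / 2 + 1), sigma = n / 16) {
  r <- matrix(seq_len(n), n, n)
  cmat <- t(r)
  exp(-((r - center[1])^2 + (cmat - center[2])^2) / (2 * sigma^2))
}

center_of_mass_pe <- function(m) {
  m <- abs(m)
  sum(seq_len(nrow(m)) * rowSums(m)) / sum(m)
}

rel_err <- function(a, b) sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))
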