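# Synthetic pelvis-like test bed: phantom, susceptibility field with a
# pile-up-inducing perturbation at the rectal-air interface, coil maps, and a
# simulated blip-up/blip-down multicoil acquisition. Every artifact is a pure
# function of (parameters, seed).

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# normalized coordinates: u along PE (anterior -> posterior), v along readout,
# both roughly [-1, 1]
.uv_grid <- function(geometry) {
  u1 <- (seq_len(geometry$n_pe) - 1 - (geometry$n_pe - 1) / 2) / (geometry$n_pe / 2)
  v1 <- (seq_len(geometry$n_ro) - 1 - (geometry$n_ro - 1) / 2) / (geometry$n_ro / 2)
  list(u = outer(u1, rep(1, geometry$n_ro)),
       v = outer(rep(1, geometry$n_pe), v1))
}

.in_ellipse <- function(u, v, center, semi) {
  ((u - center[1]) / semi[1])^2 + ((v - center[2]) / semi[2])^2 <= 1
}

# scene layout in normalized coordinates (shared by phantom and B0 builders)
.scene_layout <- list(
  body_center = c(0.05, 0), body_semi = c(0.72, 0.60),
  roi_center  = c(0.18, 0), roi_semi  = c(0.22, 0.26),
  air_center  = c(0.58, 0), air_radius = 0.13,
  # one-sided perturbation widths: steep anterior flank (toward the prostate),
  # gentle posterior flank, moderate readout-direction width
  b0_sigma_ant = 0.115, b0_sigma_post = 0.30, b0_sigma_ro = 0.20,
  body_value = 0.7, roi_value = 2.0, texture_amp = 0.08)

#' Pelvis-like numerical phantom
#'
#' Piecewise-smooth scene: an elliptical "body" (intensity 0.7), a brighter
#' central "prostate" ellipse that serves as the evaluation ROI (intensity
#' 2.0), and a zero-signal "rectal air" disc posterior to it. A smooth
#' multiplicative texture (max 8 percent) is drawn per seed; the air disc is
#' exactly zero. Deterministic given (geometry, seed).
#'
#' @param geometry A [grid_geometry()].
#' @param seed Integer seed.
#' @return List with `truth_image` (complex matrix), `roi_mask`, `body_mask`,
#'   `air_mask`.
#' @export
make_phantom <- function(geometry, seed = 1) {
  g <- .uv_grid(geometry)
  L <- .scene_layout
  body <- .in_ellipse(g$u, g$v, L$body_center, L$body_semi)
  roi <- .in_ellipse(g$u, g$v, L$roi_center, L$roi_semi)
  air <- .in_ellipse(g$u, g$v, L$air_center, rep(L$air_radius, 2))
  img <- matrix(0, geometry$n_pe, geometry$n_ro)
  img[body] <- L$body_value
  img[roi] <- L$roi_value
  tex <- .with_seed(seed, {
    z <- matrix(rnorm(length(img)), nrow(img), ncol(img))
    z <- EBImage::gblur(z, sigma = max(2, round(geometry$n_pe / 24)))
    1 + L$texture_amp * z / max(abs(z))
  })
  img <- img * tex
  img[air] <- 0
  list(truth_image = img + 0i, roi_mask = roi & !air, body_mask = body,
       air_mask = air)
}

#' Synthetic susceptibility off-resonance field
#'
#' A smooth low-order polynomial background (within +/- 20 Hz) plus a
#' negative, one-sided Gaussian perturbation centered on the rectal-air disc
#' (steep anterior flank, gentle posterior flank), scaled so the peak
#' absolute field equals `peak_hz`. The sign and asymmetry make the local PE
#' field gradient oppose the blip-up traversal on the anterior side of the
#' disc only: the blip-up polarity exhibits signal pile-up over the posterior
#' boundary of the prostate ROI (the local displacement gradient crosses
#' -1 pixel/pixel there, the regime in which that polarity's encoding
#' operator becomes singular), while blip-down sees stretching. The field
#' stays C1-smooth — first differences well under 25 Hz/pixel at the default
#' 96 x 96 / 120 Hz configuration.
#'
#' @param geometry A [grid_geometry()].
#' @param peak_hz Peak absolute off-resonance in Hz (0 gives the polynomial
#'   background only).
#' @param seed Integer seed (background polynomial coefficients).
#' @return A [b0_map()] with zero global offset.
#' @export
make_b0_field <- function(geometry, peak_hz = 120, seed = 1) {
  if (peak_hz < 0) stop("peak_hz must be non-negative", call. = FALSE)
  g <- .uv_grid(geometry)
  L <- .scene_layout
  cf <- .with_seed(seed, runif(5, -1, 1))
  bg <- cf[1] * g$u + cf[2] * g$v + cf[3] * g$u^2 + cf[4] * g$v^2 +
    cf[5] * g$u * g$v
  bg <- 20 * bg / max(abs(bg))
  if (peak_hz == 0) return(b0_map(bg))
  du <- g$u - L$air_center[1]
  dv <- g$v - L$air_center[2]
  su <- ifelse(du < 0, L$b0_sigma_ant, L$b0_sigma_post)
  raw <- bg - peak_hz * exp(-(du^2 / (2 * su^2) + dv^2 / (2 * L$b0_sigma_ro^2)))
  b0_map(raw * peak_hz / max(abs(raw)))
}

#' Synthetic coil sensitivity maps
#'
#' Smooth complex Gaussian-profile sensitivities centered at equiangular
#' positions just outside the field of view, with a small per-coil smooth
#' phase ramp; normalized so the mean sum-of-squares sensitivity is 1.
#' `n_coils = 1` returns the uniform unit map.
#'
#' @param geometry A [grid_geometry()].
#' @param n_coils Number of receive channels.
#' @param seed Integer seed (angular jitter and phase ramps).
#' @return A [coil_maps()].
#' @export
make_coil_maps <- function(geometry, n_coils = 8, seed = 1) {
  if (n_coils < 1) stop("n_coils must be at least 1", call. = FALSE)
  if (n_coils == 1)
    return(coil_maps(matrix(1 + 0i, geometry$n_pe, geometry$n_ro)))
  g <- .uv_grid(geometry)
  maps <- array(0 + 0i, dim = c(geometry$n_pe, geometry$n_ro, n_coils))
  pars <- .with_seed(seed, list(jit = runif(n_coils, -0.1, 0.1),
                                ph0 = runif(n_coils, -pi, pi),
                                pu = runif(n_coils, -0.4, 0.4),
                                pv = runif(n_coils, -0.4, 0.4)))
  for (j in seq_len(n_coils)) {
    th <- 2 * pi * (j - 1) / n_coils + pars$jit[j]
    cu <- 1.15 * cos(th); cv <- 1.15 * sin(th)
    mag <- exp(-((g$u - cu)^2 + (g$v - cv)^2) / (2 * 0.85^2))
    maps[, , j] <- mag * exp(1i * (pars$ph0[j] + pars$pu[j] * g$u +
                                     pars$pv[j] * g$v))
  }
  sos <- apply(abs(maps)^2, c(1, 2), sum)
  coil_maps(maps / sqrt(mean(sos)))
}

#' Assemble a complete synthetic scene
#'
#' Bundles phantom, B0 field and coil maps on one geometry. The
#' `"prostate120"` preset is the package's standard validation condition:
#' 96 x 96 grid, 2 mm pixels, 10.4 Hz/pixel PE bandwidth, full Fourier,
#' 8 coils, 120 Hz peak field.
#'
#' @param geometry A [grid_geometry()]; defaults to the preset's grid.
#' @param seed Integer seed propagated to all generators.
#' @param peak_hz Peak absolute off-resonance in Hz.
#' @param n_coils Number of coils.
#' @param preset `NULL` or `"prostate120"`.
#' @return An object of class `phantom_scene` with fields `truth_image`,
#'   `roi_mask`, `body_mask`, `air_mask`, `b0_true`, `coils_true`,
#'   `geometry`, `seed`.
#' @export
make_scene <- function(geometry = NULL, seed = 1, peak_hz = 120, n_coils = 8,
                       preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "prostate120")
    geometry <- grid_geometry(96, 96, pixel_mm = c(2, 2),
                              bw_per_pixel_hz = 10.4)
    peak_hz <- 120; n_coils <- 8
  }
  if (is.null(geometry))
    geometry <- grid_geometry(96, 96, pixel_mm = c(2, 2),
                              bw_per_pixel_hz = 10.4)
  ph <- make_phantom(geometry, seed)
  structure(c(ph, list(b0_true = make_b0_field(geometry, peak_hz, seed),
                       coils_true = make_coil_maps(geometry, n_coils, seed),
                       geometry = geometry, seed = seed, peak_hz = peak_hz)),
            class = "phantom_scene")
}

# smooth random phase screen: 2-D polynomial of degree <= 3, coefficients
# drawn per seed. Normalized so the maximum absolute phase over the body
# region (where it matters for signal combination) is max_rad; two
# independent screens then differ by up to ~2 * max_rad there, enough for
# severe cancellation when shots are combined without phase correction.
.phase_screen <- function(geometry, seed, max_rad = 3.0) {
  g <- .uv_grid(geometry)
  L <- .scene_layout
  cf <- .with_seed(seed, rnorm(9))
  th <- cf[1] * g$u + cf[2] * g$v + cf[3] * g$u^2 + cf[4] * g$u * g$v +
    cf[5] * g$v^2 + cf[6] * g$u^3 + cf[7] * g$u^2 * g$v +
    cf[8] * g$u * g$v^2 + cf[9] * g$v^3
  body <- .in_ellipse(g$u, g$v, L$body_center, L$body_semi)
  max_rad * th / max(abs(th[body]))
}

#' Simulate one multicoil EPI acquisition
#'
#' Applies an optional smooth random diffusion-phase screen to the truth
#' image, runs the forward encoding operator with the scene's B0 field plus a
#' global offset `f0_hz` and the polarity's sample times, adds iid complex
#' Gaussian k-space noise, and applies the partial-Fourier mask. The noise
#' scale is set in the image domain: `snr` is the object-interior magnitude
#' SNR of the resulting conjugate-phase reconstruction (`snr = Inf` is
#' noiseless and bit-identical to [forward_encode()] of the phase-screened
#' truth). With `exact = TRUE` the dense encoding sum with a genuinely 2-D
#' sample-time map (readout dwell included) is used instead of the fast
#' per-line operator — this deliberately breaks the inverse crime of
#' simulating and reconstructing with the identical model (small grids only).
#'
#' @param scene A [make_scene()] result.
#' @param polarity `"blip_up"` or `"blip_down"`.
#' @param f0_hz True global center-frequency offset in Hz.
#' @param snr Object-interior image-domain SNR; `Inf` for noiseless.
#' @param diffusion_phase `"none"` or `"smooth_random"`.
#' @param seed Integer seed (phase screen and noise).
#' @param exact Use the dense exact-summation forward model.
#' @param readout_dwell_s Readout dwell time for `exact = TRUE` (seconds).
#' @return A [kspace()] object; the phase screen (radians) is attached as
#'   attribute `"phase_screen"` and the k-space noise SD as `"sigma_k"`.
#' @export
simulate_acquisition <- function(scene, polarity = c("blip_up", "blip_down"),
                                 f0_hz = 0, snr = Inf,
                                 diffusion_phase = c("none", "smooth_random"),
                                 seed = 1, exact = FALSE,
                                 readout_dwell_s = 5e-6) {
  polarity <- match.arg(polarity)
  diffusion_phase <- match.arg(diffusion_phase)
  stopifnot(inherits(scene, "phantom_scene"))
  if (!is.numeric(snr) || snr <= 0)
    stop("snr must be positive (use Inf for noiseless)", call. = FALSE)
  geom <- scene$geometry
  img <- scene$truth_image
  screen <- NULL
  if (diffusion_phase == "smooth_random") {
    screen <- .phase_screen(geom, seed)
    img <- img * exp(1i * screen)
  }
  b0 <- b0_map(scene$b0_true$delta_b0_hz, f0_offset_hz = f0_hz)
  mask <- acquired_lines(geom, polarity)
  if (exact) {
    times <- build_sample_times(geom, polarity, readout_dwell_s = readout_dwell_s)
    J <- scene$coils_true$n_coils
    yd <- array(0 + 0i, dim = c(geom$n_pe, geom$n_ro, J))
    for (j in seq_len(J)) {
      E <- encoding_matrix(scene$coils_true$maps[, , j], b0, times, geom,
                           sample_mask = mask)
      yd[, , j] <- matrix(E %*% as.vector(img), geom$n_pe, geom$n_ro)
    }
    y <- kspace(yd, polarity = polarity, sample_mask = mask)
  } else {
    times <- build_sample_times(geom, polarity)
    y <- forward_encode(img, scene$coils_true, b0, times, geom,
                        sample_mask = mask)
  }
  sigma_k <- 0
  if (is.finite(snr)) {
    obj <- scene$body_mask & Mod(scene$truth_image) > 0
    sos <- apply(abs(scene$coils_true$maps)^2, c(1, 2), sum)
    sigma_k <- mean(Mod(scene$truth_image)[obj] * sqrt(sos[obj])) / snr
    d <- y$data
    noise <- .with_seed(seed + 1L, {
      (rnorm(length(d)) + 1i * rnorm(length(d))) * sigma_k / sqrt(2)
    })
    d <- d + array(noise, dim = dim(d))
    y <- kspace(d, polarity = polarity, sample_mask = mask)
  }
  attr(y, "phase_screen") <- screen
  attr(y, "sigma_k") <- sigma_k
  y
}

#' Simulate a blip-up/blip-down pair
#'
#' Convenience wrapper calling [simulate_acquisition()] for both polarities.
#' With `diffusion_phase = "smooth_random"` the two shots receive
#' independent phase screens (they are separate excitations), seeded
#' deterministically from `seed`.
#'
#' @inheritParams simulate_acquisition
#' @return List with elements `up` and `down`.
#' @export
simulate_pair <- function(scene, f0_hz = 0, snr = Inf,
                          diffusion_phase = "none", seed = 1) {
  list(up = simulate_acquisition(scene, "blip_up", f0_hz = f0_hz, snr = snr,
                                 diffusion_phase = diffusion_phase,
                                 seed = seed),
       down = simulate_acquisition(scene, "blip_down", f0_hz = f0_hz,
                                   snr = snr,
                                   diffusion_phase = diffusion_phase,
                                   seed = seed + 1000003L))
}
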