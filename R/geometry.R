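#' EPI acquisition geometry
#'
#' Describes the image/k-space grid and the phase-encode (PE) timing of a
#' single-shot EPI acquisition. Exactly one of `echo_spacing_s` and
#' `bw_per_pixel_hz` may be given (the other is derived from the identity
#' `bw_per_pixel_hz * n_pe * echo_spacing_s = 1`); if both are given they must
#' agree. Image-only grids (e.g. the grid of a separately acquired B0 scan) may
#' omit both.
#'
#' @param n_pe Number of phase-encode lines (matrix size along PE).
#' @param n_ro Number of readout points.
#' @param pixel_mm Length-2 numeric, physical pixel spacing in mm (PE, RO).
#' @param pe_axis Which array dimension is phase-encode: `"row"` (default) or
#'   `"col"`.
#' @param echo_spacing_s Time between consecutive PE lines, in seconds.
#' @param bw_per_pixel_hz Phase-encode bandwidth per pixel in Hz
#'   (`1 / (n_pe * echo_spacing_s)`).
#' @param partial_fourier Half-scan factor in (0.5, 1]: fraction of PE lines
#'   acquired.
#' @return An object of class `grid_geometry`.
#' @examples
#' g <- grid_geometry(96, 96, bw_per_pixel_hz = 10.4)
#' g$echo_spacing_s * g$n_pe * g$bw_per_pixel_hz  # == 1
#' @export
grid_geometry <- function(n_pe, n_ro, pixel_mm = c(2, 2),
                          pe_axis = c("row", "col"),
                          echo_spacing_s = NULL, bw_per_pixel_hz = NULL,
                          partial_fourier = 1.0) {
  pe_axis <- match.arg(pe_axis)
  n_pe <- as.integer(n_pe); n_ro <- as.integer(n_ro)
  if (n_pe < 2L || n_ro < 2L)
    stop("invalid geometry: n_pe and n_ro must both be >= 2", call. = FALSE)
  if (length(pixel_mm) != 2L || any(!is.finite(pixel_mm)) || any(pixel_mm <= 0))
    stop("invalid geometry: pixel_mm must be two positive finite values", call. = FALSE)
  if (!is.numeric(partial_fourier) || partial_fourier <= 0.5 || partial_fourier > 1)
    stop("invalid geometry: partial_fourier must lie in (0.5, 1]", call. = FALSE)

  if (is.null(echo_spacing_s) && !is.null(bw_per_pixel_hz)) {
    if (bw_per_pixel_hz <= 0)
      stop("invalid geometry: bw_per_pixel_hz must be positive", call. = FALSE)
    echo_spacing_s <- 1 / (bw_per_pixel_hz * n_pe)
  } else if (!is.null(echo_spacing_s) && is.null(bw_per_pixel_hz)) {
    if (echo_spacing_s <= 0)
      stop("invalid geometry: echo_spacing_s must be positive", call. = FALSE)
    bw_per_pixel_hz <- 1 / (echo_spacing_s * n_pe)
  } else if (!is.null(echo_spacing_s) && !is.null(bw_per_pixel_hz)) {
    if (echo_spacing_s <= 0 || bw_per_pixel_hz <= 0)
      stop("invalid geometry: timing parameters must be positive", call. = FALSE)
    if (abs(bw_per_pixel_hz * n_pe * echo_spacing_s - 1) > 1e-9)
      stop("invalid geometry: bw_per_pixel_hz * n_pe * echo_spacing_s must equal 1",
           call. = FALSE)
  } else {
    echo_spacing_s <- NA_real_; bw_per_pixel_hz <- NA_real_
  }

  structure(list(n_pe = n_pe, n_ro = n_ro, pixel_mm = as.numeric(pixel_mm),
                 pe_axis = pe_axis, echo_spacing_s = echo_spacing_s,
                 bw_per_pixel_hz = bw_per_pixel_hz,
                 partial_fourier = partial_fourier),
            class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("EPI grid geometry: %d (PE) x %d (RO), pixel %.3g x %.3g mm, PE axis = %s\n",
              x$n_pe, x$n_ro, x$pixel_mm[1], x$pixel_mm[2], x$pe_axis))
  if (is.finite(x$echo_spacing_s))
    cat(sprintf("  echo spacing %.4g ms, PE bandwidth %.4g Hz/pixel, partial Fourier %.3g\n",
                1000 * x$echo_spacing_s, x$bw_per_pixel_hz, x$partial_fourier))
  invisible(x)
}

.check_timed <- function(geom) {
  if (!inherits(geom, "grid_geometry"))
    stop("geometry must be a grid_geometry object", call. = FALSE)
  if (!is.finite(geom$echo_spacing_s) || geom$echo_spacing_s <= 0)
    stop("invalid geometry: echo spacing is undefined or non-positive", call. = FALSE)
  invisible(geom)
}

#' Acquired phase-encode lines under partial Fourier
#'
#' Returns the logical acquired-line indicator for one blip polarity. The
#' omitted early-echo lines sit on opposite sides of k-space for the two
#' polarities because the PE traversal is reversed.
#'
#' @param geometry A [grid_geometry()].
#' @param polarity `"blip_up"` or `"blip_down"`.
#' @return Logical vector of length `n_pe`.
#' @export
acquired_lines <- function(geometry, polarity = c("blip_up", "blip_down")) {
  polarity <- match.arg(polarity)
  n <- geometry$n_pe
  n_skip <- round((1 - geometry$partial_fourier) * n)
  acq <- rep(TRUE, n)
  if (n_skip > 0) {
    if (polarity == "blip_up") acq[seq_len(n_skip)] <- FALSE
    else acq[n - seq_len(n_skip) + 1L] <- FALSE
  }
  acq
}

#' Per-sample acquisition times for one blip polarity
#'
#' Builds the k-space sample-time map `t(k, l)`. Time runs linearly with the
#' PE-line index, zero at the k-space-center line (0-based index
#' `floor(n_pe/2)`), positive traversal for blip-up and negated for blip-down.
#' The readout dwell time (microseconds) is negligible against the echo
#' spacing (milliseconds) and is zero by default; a nonzero `readout_dwell_s`
#' makes the map genuinely 2-D for exact-summation simulations (the fast
#' operators require the default per-line timing).
#'
#' @param geometry A [grid_geometry()] with defined PE timing.
#' @param polarity `"blip_up"` or `"blip_down"`.
#' @param readout_dwell_s Dwell time between readout samples in seconds.
#' @return An object of class `sample_time_map` with fields `times_s`
#'   (`n_pe x n_ro` matrix, seconds) and `polarity`.
#' @examples
#' g <- grid_geometry(4, 4, echo_spacing_s = 1e-3)
#' build_sample_times(g, "blip_up")$times_s[, 1]   # -2, -1, 0, 1 ms
#' @export
build_sample_times <- function(geometry, polarity = c("blip_up", "blip_down"),
                               readout_dwell_s = 0) {
  polarity <- match.arg(polarity)
  .check_timed(geometry)
  s <- if (polarity == "blip_up") 1 else -1
  k_echo <- floor(geometry$n_pe / 2)               # 0-based center line
  line_t <- s * ((seq_len(geometry$n_pe) - 1L) - k_echo) * geometry$echo_spacing_s
  ro_t <- s * ((seq_len(geometry$n_ro) - 1L) - floor(geometry$n_ro / 2)) * readout_dwell_s
  structure(list(times_s = outer(line_t, rep(1, geometry$n_ro)) +
                   outer(rep(1, geometry$n_pe), ro_t),
                 polarity = polarity),
            class = "sample_time_map")
}

.line_times <- function(times) {
  # fast operators assume per-line timing; verify before collapsing
  t <- times$times_s
  if (max(abs(t - t[, 1])) > 1e-12)
    stop("sample times vary along the readout; the fast operators require per-line timing",
         call. = FALSE)
  t[, 1]
}

#' B0 off-resonance field map
#'
#' @param delta_b0_hz Matrix of per-voxel off-resonance in Hz.
#' @param f0_offset_hz Scalar global center-frequency offset in Hz.
#' @return An object of class `b0_map`.
#' @export
b0_map <- function(delta_b0_hz, f0_offset_hz = 0) {
  delta_b0_hz <- as.matrix(delta_b0_hz)
  if (any(!is.finite(delta_b0_hz)))
    stop("B0 map must be finite everywhere", call. = FALSE)
  if (length(f0_offset_hz) != 1L || !is.finite(f0_offset_hz))
    stop("f0_offset_hz must be a finite scalar", call. = FALSE)
  structure(list(delta_b0_hz = delta_b0_hz, f0_offset_hz = as.numeric(f0_offset_hz)),
            class = "b0_map")
}

#' Effective off-resonance field (Hz)
#'
#' The field the encoding operators see: per-voxel B0 plus the global
#' center-frequency offset.
#'
#' @param b0 A [b0_map()].
#' @return Numeric matrix in Hz.
#' @export
effective_field <- function(b0) {
  stopifnot(inherits(b0, "b0_map"))
  b0$delta_b0_hz + b0$f0_offset_hz
}

#' Coil sensitivity maps
#'
#' @param maps Complex array `n_pe x n_ro x n_coils` (a matrix is treated as a
#'   single coil).
#' @return An object of class `coil_maps`.
#' @export
coil_maps <- function(maps) {
  if (is.matrix(maps)) maps <- array(maps, dim = c(dim(maps), 1L))
  if (length(dim(maps)) != 3L)
    stop("coil maps must be an n_pe x n_ro x n_coils array", call. = FALSE)
  storage.mode(maps) <- "complex"
  sos <- apply(abs(maps)^2, c(1, 2), sum)
  if (max(sos) <= 0)
    stop("coil maps have zero combined sensitivity everywhere", call. = FALSE)
  structure(list(maps = maps, n_coils = dim(maps)[3]), class = "coil_maps")
}

#' Multicoil k-space container
#'
#' @param data Complex array `n_pe x n_ro x n_coils`.
#' @param polarity `"blip_up"` or `"blip_down"`.
#' @param sample_mask Logical length-`n_pe` acquired-line indicator; unacquired
#'   lines must hold exact zeros.
#' @return An object of class `kspace`.
#' @export
kspace <- function(data, polarity = c("blip_up", "blip_down"), sample_mask = NULL) {
  polarity <- match.arg(polarity)
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (length(dim(data)) != 3L)
    stop("k-space must be an n_pe x n_ro x n_coils array", call. = FALSE)
  storage.mode(data) <- "complex"
  if (is.null(sample_mask)) sample_mask <- rep(TRUE, dim(data)[1])
  sample_mask <- as.logical(sample_mask)
  if (length(sample_mask) != dim(data)[1])
    stop("sample_mask length must equal the number of PE lines", call. = FALSE)
  if (any(!sample_mask)) data[!sample_mask, , ] <- 0 + 0i
  structure(list(data = data, polarity = polarity, sample_mask = sample_mask,
                 n_coils = dim(data)[3]),
            class = "kspace")
}
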