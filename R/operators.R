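# Off-resonance encoding operator E and adjoint E^H.
#
# E maps the undistorted image x to multicoil k-space:
#   Y_j(k,l) = sum_{m,n} C_j(m,n) x(m,n) F(k,m) F(l,n) exp(-i2pi (dB0(m,n)+df0) t(k,l))
# with F the centered unitary DFT kernel and t the polarity-signed sample-time
# map. Fast path (C++): per-PE-line evaluation, exact when t is constant along
# the readout. Reference path: explicit dense matrix (encoding_matrix), which
# also accepts fully 2-D time maps.

.pe_first_mat <- function(x, geom) if (geom$pe_axis == "col") t(x) else x

.pe_first_arr <- function(a, geom) {
  if (geom$pe_axis == "col") aperm(a, c(2, 1, 3)) else a
}

.check_img <- function(x, geom, what = "image") {
  x <- .pe_first_mat(as.matrix(x), geom)
  if (!all(dim(x) == c(geom$n_pe, geom$n_ro)))
    stop(sprintf("%s dimensions do not match the geometry", what), call. = FALSE)
  storage.mode(x) <- "complex"
  x
}

#' Apply the forward encoding operator E
#'
#' Simulates multicoil k-space from an image: coil weighting, centered unitary
#' Fourier encoding, and off-resonance phase accrual driven by the effective
#' field (per-voxel B0 plus global offset) and the polarity-signed sample
#' times. Unacquired partial-Fourier lines are zeroed.
#'
#' @param x Complex image matrix matching `geometry`.
#' @param coils A [coil_maps()].
#' @param b0 A [b0_map()].
#' @param times A [build_sample_times()] map (per-line timing).
#' @param geometry A [grid_geometry()].
#' @param sample_mask Optional logical acquired-line indicator; defaults to
#'   [acquired_lines()] for the map's polarity.
#' @return A [kspace()] object with the polarity of `times`.
#' @export
forward_encode <- function(x, coils, b0, times, geometry, sample_mask = NULL) {
  stopifnot(inherits(coils, "coil_maps"), inherits(b0, "b0_map"),
            inherits(times, "sample_time_map"))
  xm <- .check_img(x, geometry, "image")
  cm <- .pe_first_arr(coils$maps, geometry)
  fm <- .pe_first_mat(effective_field(b0), geometry)
  if (!all(dim(cm)[1:2] == dim(xm)) || !all(dim(fm) == dim(xm)))
    stop("coil map / B0 map dimensions do not match the geometry", call. = FALSE)
  if (is.null(sample_mask)) sample_mask <- acquired_lines(geometry, times$polarity)
  y <- forward_encode_cpp(xm, cm, fm, .line_times(times), as.integer(sample_mask))
  if (geometry$pe_axis == "col") y <- aperm(y, c(2, 1, 3))
  kspace(y, polarity = times$polarity, sample_mask = sample_mask)
}

#' Apply the adjoint encoding operator E^H (conjugate-phase reconstruction)
#'
#' Maps multicoil k-space back to a single image: each coil's data goes
#' through the conjugated Fourier/off-resonance kernel, is weighted by the
#' conjugate coil sensitivity, and the coils are summed. Applied to acquired
#' data this is the conjugate-phase reconstruction, a first-order distortion
#' correction.
#'
#' @param y A [kspace()] object.
#' @inheritParams forward_encode
#' @return Complex image matrix in the same layout as the input image grid.
#' @export
adjoint_encode <- function(y, coils, b0, times, geometry) {
  stopifnot(inherits(y, "kspace"), inherits(coils, "coil_maps"),
            inherits(b0, "b0_map"), inherits(times, "sample_time_map"))
  yd <- .pe_first_arr(y$data, geometry)
  cm <- .pe_first_arr(coils$maps, geometry)
  fm <- .pe_first_mat(effective_field(b0), geometry)
  if (!all(dim(yd)[1:2] == c(geometry$n_pe, geometry$n_ro)) ||
      !all(dim(cm)[1:2] == c(geometry$n_pe, geometry$n_ro)) ||
      dim(yd)[3] != dim(cm)[3])
    stop("k-space / coil map dimensions do not match the geometry", call. = FALSE)
  out <- adjoint_encode_cpp(yd, cm, fm, .line_times(times),
                            as.integer(y$sample_mask))
  if (geometry$pe_axis == "col") out <- t(out)
  out
}

#' Predicted phase-encode displacement in pixels
#'
#' Converts the effective off-resonance field to its first-order geometric
#' effect: a per-voxel displacement of `(dB0 + df0) / bw_per_pixel_hz` pixels
#' along the phase-encode axis, positive toward +PE for blip-up and negated
#' for blip-down.
#'
#' @inheritParams forward_encode
#' @param polarity Blip polarity the sign refers to.
#' @return Numeric matrix of displacements in pixels.
#' @examples
#' b0 <- b0_map(matrix(120, 4, 4))
#' g <- grid_geometry(4, 4, bw_per_pixel_hz = 15.80)
#' pixel_shift_map(b0, g)[1, 1]  # 7.59 pixels
#' @export
pixel_shift_map <- function(b0, geometry, polarity = c("blip_up", "blip_down")) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(b0, "b0_map"))
  .check_timed(geometry)
  if (!is.finite(geometry$bw_per_pixel_hz) || geometry$bw_per_pixel_hz <= 0)
    stop("invalid geometry: PE bandwidth per pixel must be positive", call. = FALSE)
  s <- if (polarity == "blip_up") 1 else -1
  s * effective_field(b0) / geometry$bw_per_pixel_hz
}

#' Dense encoding matrix (reference implementation)
#'
#' Explicitly builds the single-coil encoding matrix so that
#' `E %*% as.vector(x)` equals the flattened k-space (column-major, PE-first
#' layout). This is the exact O((MN)^2) evaluation of the model; it accepts
#' fully 2-D sample-time maps (nonzero readout dwell) and is intended for
#' small grids — operator verification and inverse-crime-breaking simulation.
#'
#' @param coil Complex sensitivity matrix of one coil (`n_pe x n_ro`,
#'   PE-first layout).
#' @inheritParams forward_encode
#' @param sample_mask Optional logical acquired-line indicator; masked rows of
#'   the matrix are zero.
#' @return Complex matrix of dimension `(n_pe*n_ro) x (n_pe*n_ro)`.
#' @export
encoding_matrix <- function(coil, b0, times, geometry, sample_mask = NULL) {
  stopifnot(inherits(b0, "b0_map"), inherits(times, "sample_time_map"))
  M <- geometry$n_pe; N <- geometry$n_ro
  coil <- as.matrix(coil)
  stopifnot(all(dim(coil) == c(M, N)))
  if (is.null(sample_mask)) sample_mask <- acquired_lines(geometry, times$polarity)
  fm <- effective_field(b0)
  W <- .dft_mat(M); V <- .dft_mat(N)
  E <- matrix(0 + 0i, M * N, M * N)
  for (l in seq_len(N)) {
    for (k in seq_len(M)) {
      if (!sample_mask[k]) next
      ph <- exp(-2i * pi * fm * times$times_s[k, l])
      E[(l - 1L) * M + k, ] <- as.vector(coil * ph * outer(W[k, ], V[l, ]))
    }
  }
  E
}

# centered unitary DFT helpers (dense; consistent with the C++ kernels)
.dft_mat <- function(n) {
  idx <- seq_len(n) - 1L - floor(n / 2)
  exp(-2i * pi * outer(idx, idx) / n) / sqrt(n)
}

.ft2c <- function(x) {
  W <- .dft_mat(nrow(x)); V <- .dft_mat(ncol(x))
  W %*% x %*% V          # V symmetric: right-multiplication == multiplying by t(V)
}

.ift2c <- function(y) {
  W <- Conj(.dft_mat(nrow(y))); V <- Conj(.dft_mat(ncol(y)))
  W %*% y %*% V
}
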