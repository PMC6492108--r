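# Diffusion-phase correction. Tissue motion during the diffusion gradients
# imprints a smooth, shot-to-shot random image phase; before blip-up and
# blip-down (or dynamic) data are combined complexly, the relative phase
# between their conjugate-phase reconstructions is estimated voxelwise and
# removed from one k-space set, the other serving as the phase reference.

#' Voxelwise relative phase between two reconstructions
#'
#' `dphi(m,n) = angle(xcp1(m,n) * conj(xcp2(m,n)))`, the phase of the
#' voxelwise Hermitian product. Voxels whose magnitude product falls below
#' `tau` times its maximum get `dphi = 0` — the angle of a near-zero complex
#' number is noise.
#'
#' @param xcp1,xcp2 Complex images of equal dimension (typically the blip-up
#'   and blip-down conjugate-phase reconstructions; `xcp2` is the reference).
#' @param tau Relative magnitude floor (default 1e-6).
#' @param smooth_sigma Optional Gaussian smoothing (pixels) applied to the
#'   complex product before taking the angle; 0 (default) uses the raw map.
#' @return An object of class `phase_map` with field `delta_phi_rad` in
#'   `(-pi, pi]`.
#' @export
compute_phase_map <- function(xcp1, xcp2, tau = 1e-6, smooth_sigma = 0) {
  xcp1 <- as.matrix(xcp1); xcp2 <- as.matrix(xcp2)
  if (!all(dim(xcp1) == dim(xcp2)))
    stop("images must have identical dimensions", call. = FALSE)
  p <- xcp1 * Conj(xcp2)
  if (smooth_sigma > 0)
    p <- EBImage::gblur(Re(p), sigma = smooth_sigma) +
      1i * EBImage::gblur(Im(p), sigma = smooth_sigma)
  mag <- Mod(p)
  phi <- Arg(p)
  phi[mag < tau * max(mag)] <- 0
  structure(list(delta_phi_rad = phi), class = "phase_map")
}

#' Apply a phase correction to multicoil k-space
#'
#' Each coil's k-space is brought to image space (centered unitary inverse
#' DFT), multiplied by `exp(-i * dphi)`, and transformed back. Unacquired
#' partial-Fourier lines are re-zeroed after the round trip so the sampling
#' mask stays valid. The reference polarity's data are never touched by this
#' step — correct only the non-reference set.
#'
#' @param y1 A [kspace()] object to correct.
#' @param phi A [compute_phase_map()] result matching the k-space grid.
#' @return A [kspace()] object with the same polarity and sample mask.
#' @export
apply_phase_to_kspace <- function(y1, phi) {
  stopifnot(inherits(y1, "kspace"), inherits(phi, "phase_map"))
  d <- y1$data
  if (!all(dim(d)[1:2] == dim(phi$delta_phi_rad)))
    stop("phase map dimensions do not match the k-space grid", call. = FALSE)
  mod <- exp(-1i * phi$delta_phi_rad)
  out <- d
  for (j in seq_len(dim(d)[3])) {
    img <- .ift2c(d[, , j]) * mod
    out[, , j] <- .ft2c(img)
  }
  kspace(out, polarity = y1$polarity, sample_mask = y1$sample_mask)
}
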