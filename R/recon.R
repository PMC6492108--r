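# Step 3: stack the blip-up and blip-down systems and solve the normal
# equations E^H E x = E^H Y by conjugate gradients with a normalized-residual
# stopping rule.

#' Reconstruction configuration
#'
#' @param epsilon Stopping threshold on the normalized residual
#'   `||E^H E x - E^H Y|| / ||E^H Y||` (default 0.0025).
#' @param max_iter CG iteration cap (default 30; convergence is typically
#'   reached in 10-15 iterations on well-posed joint systems).
#' @param use_phase_correction Remove the shot-to-shot diffusion phase before
#'   combining polarities.
#' @param use_offset_correction Calibrate the global center-frequency offset
#'   from the b = 0 pair before reconstruction.
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(epsilon = 0.0025, max_iter = 30,
                         use_phase_correction = TRUE,
                         use_offset_correction = TRUE) {
  if (!is.numeric(epsilon) || epsilon <= 0)
    stop("epsilon must be positive", call. = FALSE)
  if (max_iter < 1) stop("max_iter must be at least 1", call. = FALSE)
  structure(list(epsilon = epsilon, max_iter = as.integer(max_iter),
                 use_phase_correction = isTRUE(use_phase_correction),
                 use_offset_correction = isTRUE(use_offset_correction)),
            class = "recon_config")
}

# General stacked normal-equation system over a list of k-space sets, each
# with its own polarity-appropriate sample times and mask.
.stacked_system <- function(ys, coils, b0, geometry) {
  stopifnot(length(ys) >= 1)
  parts <- lapply(ys, function(y) {
    stopifnot(inherits(y, "kspace"))
    list(y = y, times = build_sample_times(geometry, y$polarity))
  })
  matvec <- function(x) {
    out <- matrix(0 + 0i, nrow(x), ncol(x))
    for (p in parts) {
      yk <- forward_encode(x, coils, b0, p$times, geometry,
                           sample_mask = p$y$sample_mask)
      out <- out + adjoint_encode(yk, coils, b0, p$times, geometry)
    }
    out
  }
  rhs <- Reduce(`+`, lapply(parts, function(p)
    adjoint_encode(p$y, coils, b0, p$times, geometry)))
  structure(list(matvec = matvec, rhs = rhs, geometry = geometry,
                 polarities = vapply(ys, `[[`, "", "polarity")),
            class = "joint_system")
}

#' Build the stacked blip-up/blip-down normal-equation system
#'
#' Exposes the matvec `x -> E^H E x = E1^H E1 x + E2^H E2 x` and right-hand
#' side `E^H Y = E1^H Y1 + E2^H Y2` of the joint inverse problem. Either
#' polarity may be omitted (`NULL`) to form a single-polarity system. Pass
#' the phase-corrected blip-up data when combining diffusion-weighted shots.
#'
#' @param y_up Blip-up [kspace()] data (or `NULL`).
#' @param y_down Blip-down [kspace()] data (or `NULL`).
#' @param coils A [coil_maps()].
#' @param b0 A [b0_map()], already offset-corrected.
#' @param geometry A [grid_geometry()].
#' @return An object of class `joint_system` with fields `matvec` and `rhs`.
#' @export
build_joint_system <- function(y_up = NULL, y_down = NULL, coils, b0, geometry) {
  if (is.null(y_up) && is.null(y_down))
    stop("at least one polarity's data must be supplied", call. = FALSE)
  if (!is.null(y_up) && y_up$polarity != "blip_up")
    stop("y_up does not carry blip_up polarity", call. = FALSE)
  if (!is.null(y_down) && y_down$polarity != "blip_down")
    stop("y_down does not carry blip_down polarity", call. = FALSE)
  ys <- Filter(Negate(is.null), list(y_up, y_down))
  .stacked_system(ys, coils, b0, geometry)
}

#' Build a stacked system from repeated same-polarity shots
#'
#' Stacks an arbitrary list of k-space sets (e.g. two dynamics of the same
#' slice acquired with identical blip polarity but different diffusion
#' phases, after phase correction) into one normal-equation system.
#'
#' @param ys List of [kspace()] objects.
#' @inheritParams build_joint_system
#' @return A `joint_system`.
#' @export
build_stacked_system <- function(ys, coils, b0, geometry) {
  .stacked_system(ys, coils, b0, geometry)
}

#' Conjugate-gradient solve of the stacked system
#'
#' Standard CG on the (Hermitian positive semidefinite) normal equations from
#' `x0 = 0`, recording after every iteration the normalized residual
#' `r = ||E^H E x - E^H Y||_2 / ||E^H Y||_2` and stopping once `r < epsilon`
#' or the iteration cap is reached. No preconditioner or regularization is
#' applied.
#'
#' @param system A [build_joint_system()] result.
#' @param config A [recon_config()].
#' @return An object of class `recon_result`: complex `image`, per-iteration
#'   `residuals`, `n_iter`, `converged`.
#' @export
cg_reconstruct <- function(system, config = recon_config()) {
  stopifnot(inherits(system, "joint_system"), inherits(config, "recon_config"))
  b <- system$rhs
  nb <- sqrt(sum(Mod(b)^2))
  if (nb == 0) {
    return(structure(list(image = matrix(0 + 0i, nrow(b), ncol(b)),
                          residuals = 0, n_iter = 0L, converged = TRUE),
                     class = "recon_result"))
  }
  x <- matrix(0 + 0i, nrow(b), ncol(b))
  r <- b
  p <- r
  rs <- Re(sum(Conj(r) * r))
  res_hist <- numeric(0)
  n_done <- 0L
  for (it in seq_len(config$max_iter)) {
    Ap <- system$matvec(p)
    alpha <- rs / Re(sum(Conj(p) * Ap))
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- Re(sum(Conj(r) * r))
    res_hist <- c(res_hist, sqrt(rs_new) / nb)
    n_done <- it
    if (sqrt(rs_new) / nb < config$epsilon) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  structure(list(image = x, residuals = res_hist, n_iter = n_done,
                 converged = res_hist[n_done] < config$epsilon),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("Model-based reconstruction: %d x %d image, %d CG iterations, %s\n",
              nrow(x$image), ncol(x$image), x$n_iter,
              if (x$converged) "converged" else "iteration cap reached"))
  cat(sprintf("  final normalized residual: %.3g\n", tail(x$residuals, 1)))
  invisible(x)
}

#' Reconstruct a full diffusion-weighted series
#'
#' Runs the three-step framework: (1) calibrate the center-frequency offset
#' from the b = 0 blip pair by mutual-information maximization and fold it
#' into the B0 map; (2) per diffusion direction, estimate the relative
#' diffusion phase between the blip-up and blip-down conjugate-phase
#' reconstructions and remove it from the blip-up k-space (blip-down is the
#' reference); (3) solve the stacked joint system by CG. Outputs per-direction
#' complex reconstructions, their magnitudes, and the magnitude average over
#' directions.
#'
#' @param b0_pair List with elements `up` and `down`: b = 0 [kspace()] data of
#'   opposite polarity (required when `config$use_offset_correction`).
#' @param directions List of direction-wise lists with elements `up` and
#'   `down`.
#' @param coils A [coil_maps()].
#' @param b0 A [b0_map()].
#' @param geometry A [grid_geometry()].
#' @param config A [recon_config()].
#' @return An object of class `dwi_recon`: `per_direction` (list of
#'   `recon_result`), `magnitudes`, `mag_avg`, `offset` (the
#'   `offset_estimate`, or `NULL`), `b0_used`.
#' @export
reconstruct_dwi_series <- function(b0_pair = NULL, directions, coils, b0,
                                   geometry, config = recon_config()) {
  offset <- NULL
  if (config$use_offset_correction) {
    if (is.null(b0_pair))
      stop("offset correction requested but no b = 0 blip pair supplied",
           call. = FALSE)
    offset <- estimate_frequency_offset(b0_pair$up, b0_pair$down, coils, b0,
                                        geometry)
    b0 <- b0_map(b0$delta_b0_hz, f0_offset_hz = offset$f0_hz)
  }
  t_up <- build_sample_times(geometry, "blip_up")
  t_down <- build_sample_times(geometry, "blip_down")
  per_dir <- lapply(directions, function(d) {
    y_up <- d$up
    if (config$use_phase_correction) {
      xcp1 <- adjoint_encode(d$up, coils, b0, t_up, geometry)
      xcp2 <- adjoint_encode(d$down, coils, b0, t_down, geometry)
      phi <- compute_phase_map(xcp1, xcp2)
      y_up <- apply_phase_to_kspace(d$up, phi)
    }
    sys <- build_joint_system(y_up, d$down, coils, b0, geometry)
    cg_reconstruct(sys, config)
  })
  mags <- lapply(per_dir, function(r) Mod(r$image))
  structure(list(per_direction = per_dir, magnitudes = mags,
                 mag_avg = Reduce(`+`, mags) / length(mags),
                 offset = offset, b0_used = b0),
            class = "dwi_recon")
}
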