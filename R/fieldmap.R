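# B0 field-map estimation from a dual-echo gradient-echo scan, robust
# penalized smoothing, and resampling onto the EPI grid.

#' Dual-echo gradient-echo image pair
#'
#' @param echo1,echo2 Complex image matrices at the two echo times.
#' @param te1_s,te2_s Echo times in seconds (`te2_s > te1_s`).
#' @return An object of class `dual_echo_set` with `delta_te_s` precomputed.
#' @export
dual_echo_set <- function(echo1, echo2, te1_s, te2_s) {
  echo1 <- as.matrix(echo1); echo2 <- as.matrix(echo2)
  if (!all(dim(echo1) == dim(echo2)))
    stop("echo images must have identical dimensions", call. = FALSE)
  dte <- te2_s - te1_s
  if (!is.finite(dte) || dte <= 0)
    stop("echo-time difference must be positive", call. = FALSE)
  storage.mode(echo1) <- "complex"; storage.mode(echo2) <- "complex"
  structure(list(echo1 = echo1, echo2 = echo2, te1_s = te1_s, te2_s = te2_s,
                 delta_te_s = dte),
            class = "dual_echo_set")
}

#' Estimate the B0 field from a dual-echo pair
#'
#' Per voxel, the off-resonance frequency is the phase evolved between the two
#' echoes divided by the echo-time difference:
#' `dB0 = angle(echo2 * conj(echo1)) / (2*pi*delta_TE)`, a weighted two-point
#' phase fit (the two-echo case of a least-squares fit of temporally unwrapped
#' phase over echo time). Values are confined to the principal interval
#' `+/- 1/(2*delta_TE)` Hz — larger true offsets alias. Magnitude weights
#' `|echo1 * echo2|` are attached for downstream smoothing.
#'
#' @param d A [dual_echo_set()].
#' @return A [b0_map()] with attribute `"weights"`.
#' @examples
#' e1 <- matrix(1 + 0i, 4, 4)
#' d <- dual_echo_set(e1, e1 * exp(1i * 0.65), 0.0046, 0.0069)
#' b0_from_dual_echo(d)$delta_b0_hz[1, 1]  # 0.65 / (2*pi*0.0023) ~ 44.98 Hz
#' @export
b0_from_dual_echo <- function(d) {
  stopifnot(inherits(d, "dual_echo_set"))
  prod21 <- d$echo2 * Conj(d$echo1)
  field <- Arg(prod21) / (2 * pi * d$delta_te_s)
  out <- b0_map(field, f0_offset_hz = 0)
  attr(out, "weights") <- Mod(prod21)
  out
}

# orthonormal DCT-II matrix and the Laplacian eigenvalues it diagonalizes
.dct_mat <- function(n) {
  k <- seq_len(n) - 1L; j <- seq_len(n) - 1L
  D <- sqrt(2 / n) * cos(pi * outer(k, 2 * j + 1) / (2 * n))
  D[1, ] <- D[1, ] / sqrt(2)
  D
}

.lap_eigen <- function(n) 2 - 2 * cos(pi * (seq_len(n) - 1L) / n)

#' Robust penalized smoothing of a B0 field
#'
#' Minimizes a weighted data-fidelity term plus a squared-second-difference
#' roughness penalty, solved in the 2-D DCT domain (the penalty is diagonal
#' there). With non-uniform weights the solution is obtained by fixed-point
#' iteration; robustness to outlier voxels comes from bisquare reweighting of
#' the residuals. The penalty strength is chosen by generalized
#' cross-validation when `strength = "auto"`. The output is clamped to the
#' input range, so smoothing never widens the field's `[min, max]`; constant
#' fields are exact fixed points and `strength = 0` returns the input.
#'
#' @param b0 A [b0_map()].
#' @param weights Optional non-negative per-voxel weights (e.g. the magnitude
#'   weights attached by [b0_from_dual_echo()]); rescaled to max 1.
#' @param strength `"auto"` (GCV) or a non-negative scalar penalty.
#' @param robust_iter Number of bisquare reweighting passes (0 disables).
#' @return A [b0_map()]; the chosen strength is attached as attribute
#'   `"strength"`.
#' @export
smooth_b0 <- function(b0, weights = NULL, strength = "auto", robust_iter = 2) {
  stopifnot(inherits(b0, "b0_map"))
  y <- b0$delta_b0_hz
  if (is.numeric(strength) && strength < 0)
    stop("smoothing strength must be non-negative", call. = FALSE)
  if (is.null(weights)) weights <- matrix(1, nrow(y), ncol(y))
  weights <- as.matrix(weights)
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and non-negative", call. = FALSE)
  if (max(weights) <= 0) stop("all-zero weights", call. = FALSE)
  weights <- weights / max(weights)
  if (is.numeric(strength) && strength == 0) {
    out <- b0_map(y, b0$f0_offset_hz); attr(out, "strength") <- 0
    return(out)
  }

  Dr <- .dct_mat(nrow(y)); Dc <- .dct_mat(ncol(y))
  lam2 <- outer(.lap_eigen(nrow(y)), .lap_eigen(ncol(y)), `+`)^2
  n <- length(y)
  dct2 <- function(x) Dr %*% x %*% t(Dc)
  idct2 <- function(x) t(Dr) %*% x %*% Dc

  solve_s <- function(s, w, z0) {
    gam <- 1 / (1 + s * lam2)
    z <- z0
    for (it in seq_len(200)) {
      zn <- idct2(gam * dct2(w * (y - z) + z))
      if (max(abs(zn - z)) <= 1e-9 * (max(abs(zn)) + 1e-12)) { z <- zn; break }
      z <- zn
    }
    z
  }
  gcv <- function(log10s, w, z0) {
    s <- 10^log10s
    z <- solve_s(s, w, z0)
    tr_h <- sum(1 / (1 + s * lam2))
    rss <- sum(w * (y - z)^2)
    rss / n / (1 - tr_h / n)^2
  }

  w <- weights
  z <- y
  auto <- identical(strength, "auto")
  s_used <- if (auto) NA_real_ else as.numeric(strength)
  for (pass in seq_len(robust_iter + 1L)) {
    if (auto) {
      opt <- optimize(gcv, interval = c(-6, 8), w = w, z0 = z, tol = 0.1)
      s_used <- 10^opt$minimum
    }
    z <- solve_s(s_used, w, z)
    if (pass > robust_iter) break
    r <- y - z
    sig <- 1.4826 * median(abs(r - median(r))) + 1e-12
    u <- pmin(abs(r) / (4.685 * sig), 1)
    w <- weights * (1 - u^2)^2
    if (max(w) <= 0) { w <- weights; break }
  }
  z <- pmin(pmax(z, min(y)), max(y))
  out <- b0_map(z, b0$f0_offset_hz)
  attr(out, "strength") <- s_used
  out
}

#' Resample a B0 map onto the EPI grid
#'
#' Bilinear interpolation in physical (mm) coordinates, assuming the two
#' fields of view share their center. Target voxels falling outside the
#' source field of view are filled with 0 Hz (no correction where no field
#' information exists).
#'
#' @param b0 A [b0_map()] on the source grid.
#' @param source_geom,target_geom [grid_geometry()] objects describing the two
#'   grids (timing may be undefined on the source).
#' @return A [b0_map()] with `target_geom` dimensions.
#' @export
resample_to_epi <- function(b0, source_geom, target_geom) {
  stopifnot(inherits(b0, "b0_map"), inherits(source_geom, "grid_geometry"),
            inherits(target_geom, "grid_geometry"))
  z <- b0$delta_b0_hz
  if (!all(dim(z) == c(source_geom$n_pe, source_geom$n_ro)))
    stop("B0 map dimensions do not match the source geometry", call. = FALSE)
  coords <- function(n, px) (seq_len(n) - 1 - (n - 1) / 2) * px
  sr <- coords(source_geom$n_pe, source_geom$pixel_mm[1])
  sc <- coords(source_geom$n_ro, source_geom$pixel_mm[2])
  tr <- coords(target_geom$n_pe, target_geom$pixel_mm[1])
  tc <- coords(target_geom$n_ro, target_geom$pixel_mm[2])
  inside_r <- tr >= min(sr) & tr <= max(sr)
  inside_c <- tc >= min(sc) & tc <= max(sc)
  if (!any(inside_r) || !any(inside_c))
    stop("source and target fields of view do not overlap", call. = FALSE)
  grid <- expand.grid(r = tr, c = tc)
  rq <- pmin(pmax(grid$r, min(sr)), max(sr))
  cq <- pmin(pmax(grid$c, min(sc)), max(sc))
  vals <- pracma::interp2(x = sc, y = sr, Z = z, xp = cq, yp = rq,
                          method = "linear")
  out <- matrix(vals, target_geom$n_pe, target_geom$n_ro)
  out[!inside_r, ] <- 0
  out[, !inside_c] <- 0
  b0_map(out, b0$f0_offset_hz)
}
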