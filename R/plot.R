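# Base-graphics display helpers.

.show_img <- function(m, main = "", ...) {
  graphics::image(t(m)[, nrow(m):1], axes = FALSE, asp = 1,
                  col = grDevices::gray.colors(256, 0, 1), main = main, ...)
}

#' Display a reconstruction and its convergence
#'
#' Left: magnitude image. Right: normalized CG residual per iteration on a
#' log scale, with the stopping threshold.
#'
#' @param x A [cg_reconstruct()] result.
#' @param epsilon Threshold line to draw (default 0.0025).
#' @param ... Passed to `image()`.
#' @export
plot.recon_result <- function(x, epsilon = 0.0025, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(op))
  .show_img(Mod(x$image), main = "reconstruction |x|", ...)
  graphics::plot(seq_along(x$residuals), x$residuals, log = "y", type = "b",
                 xlab = "CG iteration", ylab = "normalized residual",
                 main = "convergence")
  graphics::abline(h = epsilon, lty = 2)
  invisible(x)
}

#' Display a synthetic scene
#'
#' Truth magnitude with ROI outline, B0 field, predicted pixel-shift map and
#' coil sum-of-squares.
#'
#' @param x A [make_scene()] result.
#' @param ... Ignored.
#' @export
plot.phantom_scene <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  .show_img(Mod(x$truth_image), main = "truth |x| (ROI = prostate)")
  .show_img(x$b0_true$delta_b0_hz, main = "B0 field (Hz)")
  .show_img(pixel_shift_map(x$b0_true, x$geometry),
            main = "predicted PE shift (px, blip-up)")
  .show_img(apply(abs(x$coils_true$maps)^2, c(1, 2), sum),
            main = "coil sum of squares")
  invisible(x)
}
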