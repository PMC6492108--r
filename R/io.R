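# File-format glue for the command-line interface: NIfTI for images and
# fields (complex data split into real/imaginary volumes), an .rds container
# for multicoil k-space, and a structured run log.

#' Write a real or complex image to NIfTI
#'
#' Complex matrices/arrays are split into stacked real and imaginary volumes
#' (read back with [read_complex_nifti()]). The pixel spacing of `geometry`
#' is recorded; Hz-valued images should say so in `description`.
#'
#' @param x Numeric or complex matrix/array.
#' @param path Output file (`.nii` / `.nii.gz`).
#' @param geometry Optional [grid_geometry()] for pixel spacing.
#' @param description Free-text description stored in the header.
#' @return `path`, invisibly.
#' @export
write_image_nifti <- function(x, path, geometry = NULL, description = "") {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI output", call. = FALSE)
  if (is.complex(x)) {
    d <- dim(x); if (length(d) == 2) d <- c(d, 1L)
    x <- array(c(Re(x), Im(x)), dim = c(d[1], d[2], d[3] * 2L))
  }
  pixdim <- if (is.null(geometry)) c(1, 1, 1) else c(geometry$pixel_mm, 1)
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- pixdim[seq_len(min(3, length(dim(x))))]
  img$descrip <- description
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a complex image written by [write_image_nifti()]
#'
#' @param path NIfTI file whose third dimension stacks real then imaginary
#'   volumes.
#' @return Complex array (last dimension halved).
#' @export
read_complex_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI input", call. = FALSE)
  a <- as.array(RNifti::readNifti(path))
  if (length(dim(a)) == 2) return(a)
  h <- dim(a)[3] / 2
  re <- a[, , seq_len(h), drop = TRUE]
  im <- a[, , h + seq_len(h), drop = TRUE]
  re + 1i * im
}

#' Save a blip-up/blip-down k-space container
#'
#' Stores both polarities' multicoil k-space, the sample masks and the
#' acquisition geometry in one `.rds` file.
#'
#' @param pair List with [kspace()] elements `up` and `down` (either may be
#'   absent).
#' @param geometry A [grid_geometry()].
#' @param path Output `.rds` path.
#' @return `path`, invisibly.
#' @export
save_kspace <- function(pair, geometry, path) {
  saveRDS(list(kspace_up = pair$up, kspace_down = pair$down,
               geometry = geometry, format_version = 1L), path)
  invisible(path)
}

#' Load a k-space container written by [save_kspace()]
#'
#' @param path The `.rds` path.
#' @return List with `kspace_up`, `kspace_down`, `geometry`.
#' @export
load_kspace <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$geometry) || !inherits(obj$geometry, "grid_geometry"))
    stop("not a k-space container: missing geometry", call. = FALSE)
  obj
}

#' Append a structured entry to a run log
#'
#' One JSON object per line: timestamp, package version, command name and
#' the supplied parameter list.
#'
#' @param path Log file path.
#' @param command Name of the operation being logged.
#' @param params Named list of parameters/results (must be JSON-encodable).
#' @return `path`, invisibly.
#' @export
write_run_log <- function(path, command, params = list()) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("jsonlite is required for run logging", call. = FALSE)
  entry <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                package = "epiunwarp",
                version = as.character(utils::packageVersion("epiunwarp")),
                command = command, params = params)
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n", file = path,
      append = TRUE)
  invisible(path)
}
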