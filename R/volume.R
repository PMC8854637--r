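#' 3D scalar volume with voxel size and intensity semantics
#'
#' The central currency of the pipeline: a 3D numeric array together with its
#' voxel size in micrometres and a tag saying what the voxel values mean
#' (`"raw"` attenuation from the phantom generator, `"reconstructed"`
#' filter-backprojected values, or `"calibrated"` gray values on the
#' Hounsfield-like air = 500 / polystyrene = 1500 scale).
#'
#' @param data 3D numeric array, axis order (x, y, z).
#' @param voxel_size voxel edge length in micrometres; a scalar (isotropic) or
#'   a length-3 vector per axis.
#' @param semantics one of `"raw"`, `"reconstructed"`, `"calibrated"`.
#' @param provenance named list of processing metadata carried along the
#'   pipeline (filter settings, seeds, calibration coefficients, ...).
#'
#' @return An object of class `vh_volume`.
#' @export
vh_volume <- function(data, voxel_size, semantics = c("raw", "reconstructed", "calibrated"),
                      provenance = list()) {
  semantics <- match.arg(semantics)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("`voxel_size` must be a positive scalar or length-3 vector (um)", call. = FALSE)
  }
  structure(
    list(data = data, voxel_size = voxel_size, semantics = semantics,
         provenance = provenance),
    class = "vh_volume"
  )
}

#' @export
print.vh_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vh_volume> %d x %d x %d voxels, %s\n", d[1], d[2], d[3], x$semantics))
  cat(sprintf("  voxel size: %s um\n", paste(signif(x$voxel_size, 4), collapse = " x ")))
  cat(sprintf("  intensity range: [%.4g, %.4g]\n", min(x$data), max(x$data)))
  if (length(x$provenance)) {
    cat("  provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.vh_volume <- function(x) dim(x$data)

is_vh_volume <- function(x) inherits(x, "vh_volume")

stopifnot_volume <- function(x, semantics = NULL) {
  if (!is_vh_volume(x)) stop("expected a `vh_volume`", call. = FALSE)
  if (!is.null(semantics) && !(x$semantics %in% semantics)) {
    stop(sprintf("expected a %s volume, got %s",
                 paste(semantics, collapse = "/"), x$semantics), call. = FALSE)
  }
  invisible(x)
}

#' Per-voxel class labels aligned with a volume
#'
#' @param labels 3D integer array; 0 marks voxels outside the sample, positive
#'   codes index rows of `schema`.
#' @param voxel_size micrometres, as in [vh_volume()].
#' @param schema a [class_schema()] describing the positive codes.
#'
#' @return An object of class `vh_labels`.
#' @export
vh_labels <- function(labels, voxel_size, schema) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("`labels` must be a 3D array", call. = FALSE)
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  structure(list(labels = labels, voxel_size = voxel_size, schema = schema),
            class = "vh_labels")
}

#' @export
print.vh_labels <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<vh_labels> %d x %d x %d voxels, %d classes\n",
              d[1], d[2], d[3], nrow(x$schema)))
  tab <- tabulate(x$labels[x$labels > 0], nbins = max(x$schema$code))
  for (i in seq_len(nrow(x$schema))) {
    cat(sprintf("  %-4s %s: %d voxels\n", x$schema$class[i], x$schema$name[i],
                tab[x$schema$code[i]]))
  }
  invisible(x)
}

# Gaussian-smooth a 3D array (separable, replicate boundary); sigma in voxels.
gaussian_smooth3 <- function(a, sigma) {
  if (sigma <= 0) return(a)
  k <- gauss_kernel(sigma, order = 0L)
  a <- conv_axis_cpp(a, k, 0L)
  a <- conv_axis_cpp(a, k, 1L)
  conv_axis_cpp(a, k, 2L)
}

# Sampled Gaussian (derivative) kernel; order 0, 1 or 2.  Orientation is the
# correlation convention used by conv_axis_cpp, so that order-1 kernels return
# d/dx of the smoothed signal (positive slope -> positive response).
gauss_kernel <- function(sigma, order = 0L) {
  r <- max(1L, ceiling(4 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
    "0" = g,
    "1" = x / sigma^2 * g,
    "2" = {
      k <- (x^2 - sigma^2) / sigma^4 * g
      k - mean(k)          # sampled kernel must annihilate constants exactly
    },
    stop("order must be 0, 1 or 2")
  )
}
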