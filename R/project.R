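#' Parallel-beam acquisition geometry
#'
#' Desk-scale stand-in for the cone-beam scanner geometry: magnification is
#' folded into the effective voxel size, so only the number of projection
#' angles, the angular range and the detector pixel pitch remain.
#'
#' @param n_angles number of projection angles; default
#'   `max(180, ceiling(sqrt(2) * n_detector))`, set when the stack is created.
#' @param angular_range degrees covered by the scan (180 for parallel beam).
#' @param detector_pixel detector pixel pitch, um (defaults to the voxel size).
#' @return An object of class `vh_geometry`.
#' @export
vh_geometry <- function(n_angles = NULL, angular_range = 180, detector_pixel = NULL) {
  if (!is.null(n_angles) && n_angles < 1) stop("n_angles must be >= 1", call. = FALSE)
  if (angular_range <= 0 || angular_range > 360) {
    stop("angular_range must be in (0, 360]", call. = FALSE)
  }
  structure(list(n_angles = n_angles, angular_range = angular_range,
                 detector_pixel = detector_pixel),
            class = "vh_geometry")
}

new_projection_stack <- function(images, angles, pixel_size, kind, provenance = list()) {
  structure(list(images = images, angles = angles, pixel_size = pixel_size,
                 kind = kind, provenance = provenance),
            class = "vh_projections")
}

#' @export
print.vh_projections <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<vh_projections> %d angles, %d x %d pixels each, kind: %s\n",
              d[3], d[1], d[2], x$kind))
  cat(sprintf("  angular range: [%.2f, %.2f] deg, pixel %g um\n",
              min(x$angles), max(x$angles), x$pixel_size))
  invisible(x)
}

#' Forward-project a volume (parallel-beam Radon transform)
#'
#' Computes line integrals of the raw attenuation volume, slice by slice along
#' z, at equally spaced angles.  Projections are dimensionless optical
#' thicknesses (attenuation per um integrated over um).
#'
#' @param volume a raw [vh_volume()] with square x-y slices.
#' @param geometry a [vh_geometry()]; `NULL` takes the defaults.
#' @return A `vh_projections` stack of kind `"line_integral"` with images of
#'   shape (detector, z) per angle.
#' @export
forward_project <- function(volume, geometry = NULL) {
  stopifnot_volume(volume, "raw")
  d <- dim(volume$data)
  if (any(d == 0)) stop("empty volume", call. = FALSE)
  if (d[1] != d[2]) stop("x-y slices must be square for parallel-beam projection",
                         call. = FALSE)
  if (is.null(geometry)) geometry <- vh_geometry()
  n_angles <- geometry$n_angles
  if (is.null(n_angles)) n_angles <- max(180L, ceiling(sqrt(2) * d[1]))
  angles <- seq(0, geometry$angular_range, length.out = n_angles + 1)[seq_len(n_angles)]
  vs <- volume$voxel_size[1]
  images <- array(0, c(d[1], d[3], n_angles))
  rad <- angles * pi / 180
  for (k in seq_len(d[3])) {
    sino <- radon_forward_cpp(volume$data[, , k], rad)   # n_det x n_angles
    images[, k, ] <- sino * vs                           # physical path length
  }
  new_projection_stack(images, angles, vs, "line_integral",
                       provenance = c(volume$provenance,
                                      list(n_angles = n_angles,
                                           angular_range = geometry$angular_range)))
}

#' Emulate propagation edge enhancement and photon noise
#'
#' Converts line integrals to normalized intensities `exp(-p)`, sharpens each
#' projection with the exact frequency-domain inverse of the Paganin retrieval
#' low-pass (amplitude `1 + alpha f^2`), and Poisson-samples the result at a
#' mean of `photon_count` counts per unit intensity.  With `alpha = 0` and
#' noise disabled this is the plain `exp(-p)` transform, so a matched
#' retrieval recovers the input up to the exp/log round trip.
#'
#' @param stack a `vh_projections` of kind `"line_integral"`.
#' @param alpha propagation filter strength in (cycles/pixel)^-2, typically
#'   [alpha_from_cutoff()] of the retrieval configuration; `>= 0`.
#' @param photon_count mean photon count at unit intensity; `Inf` or
#'   `noise = FALSE` disables noise.
#' @param seed RNG seed for the Poisson draw.
#' @param noise logical; set `FALSE` for a noise-free propagation.
#' @return A `vh_projections` of kind `"intensity"`.
#' @export
apply_propagation_and_noise <- function(stack, alpha, photon_count = 1e5,
                                        seed = 1L, noise = TRUE) {
  stopifnot(inherits(stack, "vh_projections"))
  if (stack$kind != "line_integral") stop("stack must contain line integrals", call. = FALSE)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (noise && (!is.finite(photon_count) || photon_count <= 0) && !is.infinite(photon_count)) {
    stop("photon_count must be positive", call. = FALSE)
  }
  d <- dim(stack$images)
  out <- array(0, d)
  for (a in seq_len(d[3])) {
    I <- exp(-stack$images[, , a])
    if (alpha > 0) {
      I <- filter_freq2d(I, function(f2) 1 + alpha * f2)
      I[I < 1e-9] <- 1e-9                      # detector cannot see negative intensity
    }
    out[, , a] <- I
  }
  if (noise && is.finite(photon_count)) {
    set.seed(seed)
    counts <- rpois(length(out), lambda = as.numeric(out) * photon_count)
    out <- array(pmax(counts, 0.5) / photon_count, d)   # half-photon floor
  }
  new_projection_stack(out, stack$angles, stack$pixel_size, "intensity",
                       provenance = c(stack$provenance,
                                      list(propagation_alpha = alpha,
                                           photon_count = if (noise) photon_count else Inf)))
}

# Apply a radial frequency-domain transfer function gain(f^2) to a 2D image,
# f in cycles/pixel.  Pads to the next power of two with edge replication to
# curb wrap-around, unless pad = FALSE.
filter_freq2d <- function(img, gain, pad = TRUE) {
  d0 <- dim(img)
  if (pad) {
    dp <- 2^ceiling(log2(pmax(d0 * 1.5, 8)))
    img_p <- pad_edge2d(img, dp)
  } else {
    dp <- d0
    img_p <- img
  }
  fx <- fft_freq(dp[1]); fy <- fft_freq(dp[2])
  f2 <- outer(fx^2, fy^2, "+")
  out <- Re(fft(fft(img_p) * gain(f2), inverse = TRUE)) / prod(dp)
  out[seq_len(d0[1]), seq_len(d0[2])]
}

# DFT sample frequencies in cycles/sample (like the standard fftfreq layout)
fft_freq <- function(n) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / n
}

pad_edge2d <- function(img, dp) {
  d0 <- dim(img)
  out <- matrix(0, dp[1], dp[2])
  out[seq_len(d0[1]), seq_len(d0[2])] <- img
  if (dp[1] > d0[1]) out[(d0[1] + 1):dp[1], seq_len(d0[2])] <-
    matrix(img[d0[1], ], nrow = dp[1] - d0[1], ncol = d0[2], byrow = TRUE)
  if (dp[2] > d0[2]) out[, (d0[2] + 1):dp[2]] <- out[, d0[2]]
  out
}
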