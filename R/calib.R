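#' Two-point Hounsfield-like intensity calibration
#'
#' Fits the affine map that sends the mean reconstructed value of an air
#' reference region to 500 and of the polystyrene (Kapton tube) reference to
#' 1500, enabling inter-sample comparison of gray values the way Hounsfield
#' units do for clinical CT (with air/PS in place of air/water).
#'
#' @param volume a reconstructed [vh_volume()].
#' @param air_mask,ps_mask logical arrays (same shape as the volume) selecting
#'   the two reference materials; non-empty and disjoint, with
#'   `mean(ps) > mean(air)`.
#' @param targets calibrated gray values assigned to (air, PS);
#'   default `c(500, 1500)`.
#' @return An object of class `calibration_map` with slope `a`, offset `b` and
#'   the measured reference means.
#' @export
fit_two_point <- function(volume, air_mask, ps_mask, targets = c(500, 1500)) {
  stopifnot_volume(volume)
  if (!any(air_mask)) stop("air mask is empty", call. = FALSE)
  if (!any(ps_mask)) stop("PS mask is empty", call. = FALSE)
  if (any(air_mask & ps_mask)) stop("reference masks must be disjoint", call. = FALSE)
  m_air <- mean(volume$data[air_mask])
  m_ps <- mean(volume$data[ps_mask])
  if (m_ps <= m_air) {
    stop(sprintf("PS reference mean (%.6g) must exceed air mean (%.6g); masks swapped?",
                 m_ps, m_air), call. = FALSE)
  }
  a <- (targets[2] - targets[1]) / (m_ps - m_air)
  b <- targets[1] - a * m_air
  structure(list(a = a, b = b, m_air = m_air, m_ps = m_ps, targets = targets),
            class = "calibration_map")
}

#' @export
print.calibration_map <- function(x, ...) {
  cat("<calibration_map> calibrated = a * raw + b\n")
  cat(sprintf("  a = %.6g, b = %.6g\n", x$a, x$b))
  cat(sprintf("  air: %.6g -> %g, PS: %.6g -> %g\n",
              x$m_air, x$targets[1], x$m_ps, x$targets[2]))
  invisible(x)
}

#' Apply a fitted two-point calibration
#'
#' Voxel-wise affine map; strictly monotone (slope > 0), stored as floating
#' point with no clamping so hyperintense structures keep their full range.
#'
#' @param volume the [vh_volume()] the map was fitted on (or one from the same
#'   acquisition).
#' @param map a [fit_two_point()] result.
#' @return A calibrated [vh_volume()].
#' @export
apply_calibration <- function(volume, map) {
  stopifnot_volume(volume)
  stopifnot(inherits(map, "calibration_map"))
  vh_volume(map$a * volume$data + map$b, volume$voxel_size, "calibrated",
            provenance = c(volume$provenance,
                           list(calibration = list(a = map$a, b = map$b,
                                                   targets = map$targets))))
}

# Coarse air/material threshold: first threshold of a 3-class Otsu over the
# whole volume (a plain 2-class Otsu splits within the multimodal material
# range instead of at the air level).
air_material_threshold <- function(v) {
  auto_thresholds_values(as.numeric(v), k = 3)[1]
}

# Of the two largest material components, the tube annulus is the one whose
# voxels sit farther from the central (z) axis; the clot ball hugs the centre.
split_clot_tube <- function(lab, n_comp, d) {
  sizes <- tabulate(lab[lab > 0], nbins = n_comp)
  ord <- order(sizes, decreasing = TRUE)
  if (n_comp < 2 || sizes[ord[2]] < 0.01 * sizes[ord[1]]) {
    return(list(clot = ord[1], tube = NA_integer_))
  }
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  mean_rho <- function(code) {
    idx <- which(lab == code)
    co <- arrayInd(idx, d)
    mean(sqrt((co[, 1] - cx)^2 + (co[, 2] - cy)^2))
  }
  r1 <- mean_rho(ord[1]); r2 <- mean_rho(ord[2])
  if (r1 > r2) list(clot = ord[2], tube = ord[1]) else list(clot = ord[1], tube = ord[2])
}

#' Automatic air and tube reference masks
#'
#' Finds the two reference materials on a reconstructed volume without manual
#' ROIs.  Material voxels (above the coarse air/material threshold) are
#' grouped by 26-connectivity; of the two largest components the tube annulus
#' is recognised by its ring geometry (larger mean distance from the central
#' axis) and eroded by one voxel to avoid partial-volume rims.  Air is taken
#' from within the inscribed field-of-view cylinder (where the reconstruction
#' is quantitative), at least two voxels away from any material.
#'
#' @param volume a reconstructed [vh_volume()].
#' @return list with logical arrays `air`, `ps`, plus the `threshold` used.
#' @export
auto_reference_masks <- function(volume) {
  stopifnot_volume(volume)
  v <- volume$data
  d <- dim(v)
  thr <- air_material_threshold(v)
  material <- v > thr
  # open before labelling: blur tails can bridge the thin clot-tube air gap;
  # if erosion destroys a thin-walled tube instead, label the raw material
  core <- erode3(material, 1L)
  lab <- label3d_cpp(core)
  n_comp <- attr(lab, "n_components")
  if (n_comp < 2) {
    lab <- label3d_cpp(material)
    n_comp <- attr(lab, "n_components")
  }
  if (n_comp < 2) stop("could not separate clot and tube above the air threshold",
                       call. = FALSE)
  parts <- split_clot_tube(lab, n_comp, d)
  if (is.na(parts$tube)) stop("no tube annulus found", call. = FALSE)
  tube <- array(lab == parts$tube, d)
  tube_er <- erode3(tube, r = 1L)
  if (any(tube_er)) tube <- tube_er
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2
  rho2 <- outer((seq_len(d[1]) - cx)^2, (seq_len(d[2]) - cy)^2, "+")
  fov <- array(rho2 <= (0.95 * min(d[1:2]) / 2)^2, d)
  air <- fov & !dilate3(material, 2L)
  if (!any(air)) stop("no air voxels found inside the field of view", call. = FALSE)
  list(air = air, ps = tube, threshold = thr)
}

# binary erosion with a 3x3x3 cube repeated r times
erode3 <- function(mask, r = 1L) {
  k <- rep(1, 3)
  m <- mask * 1
  for (i in seq_len(r)) {
    m <- conv_axis_cpp(m, k, 0L)
    m <- conv_axis_cpp(m, k, 1L)
    m <- conv_axis_cpp(m, k, 2L)
    m <- (m >= 27 - 1e-6) * 1
  }
  array(m > 0, dim(mask))
}

# binary dilation with a 3x3x3 cube repeated r times
dilate3 <- function(mask, r = 1L) {
  k <- rep(1, 3)
  m <- mask * 1
  for (i in seq_len(r)) {
    m <- conv_axis_cpp(m, k, 0L)
    m <- conv_axis_cpp(m, k, 1L)
    m <- conv_axis_cpp(m, k, 2L)
    m <- (m > 1e-6) * 1
  }
  array(m > 0, dim(mask))
}
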