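#' Parameters of the multiscale Frangi blob/vessel filter
#'
#' @param scales Gaussian scales in voxels (default 1, 2, 3 — the range at
#'   which 4-7 um cells appear at ~1.2 um voxels).
#' @param alpha_f plate-vs-line discrimination weight (default 0.5).
#' @param beta_f blob discrimination weight (default 0.5).
#' @param c structureness weight; `NULL` (default) sets it per scale to half
#'   the maximum Frobenius norm of the Hessian over the masked volume.
#' @param rb_mode how the blobness ratio `R_B` gates the response:
#'   `"both"` (default) accepts bright tubular *and* spherical structures,
#'   `"tube"` is the classical vesselness gate, `"blob"` accepts spheres only.
#' @param noise_fraction noise-suppression threshold for detection, as a
#'   fraction of the maximum response: responses below
#'   `noise_fraction * max(response)` are zeroed (default 0.10, the lower 10%
#'   of the response range).  Set `noise_mode = "percentile"` to reinterpret
#'   it as the 10th percentile of non-zero responses.
#' @param noise_mode `"max"` (fraction of the maximum; default) or
#'   `"percentile"`.
#' @param min_diameter_um blobs with equivalent diameter below this are
#'   discarded as noise specks (default 2 um, half the smallest cell).
#' @return list of class `frangi_params`.
#' @export
frangi_params <- function(scales = c(1, 2, 3), alpha_f = 0.5, beta_f = 0.5,
                          c = NULL, rb_mode = c("both", "tube", "blob"),
                          noise_fraction = 0.10,
                          noise_mode = c("max", "percentile"),
                          min_diameter_um = 2) {
  rb_mode <- match.arg(rb_mode)
  noise_mode <- match.arg(noise_mode)
  if (any(scales <= 0)) stop("scales must be positive", call. = FALSE)
  if (noise_fraction <= 0 || noise_fraction >= 1) {
    stop("noise_fraction must be in (0, 1)", call. = FALSE)
  }
  structure(list(scales = scales, alpha_f = alpha_f, beta_f = beta_f, c = c,
                 rb_mode = rb_mode, noise_fraction = noise_fraction,
                 noise_mode = noise_mode, min_diameter_um = min_diameter_um),
            class = "frangi_params")
}

#' Scale-normalized Hessian eigenvalue fields
#'
#' Gaussian-derivative Hessian of the volume at scale `sigma` (voxels),
#' gamma-normalized by `sigma^2` for scale invariance, with eigenvalues
#' sorted per voxel by absolute value (`|l1| <= |l2| <= |l3|`).
#'
#' @param volume a [vh_volume()] or 3D array.
#' @param sigma Gaussian scale in voxels.
#' @return list of 3D arrays `l1`, `l2`, `l3`.
#' @export
hessian_eigen <- function(volume, sigma) {
  a <- if (is_vh_volume(volume)) volume$data else volume
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (2 * ceiling(4 * sigma) + 1 > min(dim(a))) {
    stop("sigma too large for the volume extent", call. = FALSE)
  }
  g0 <- gauss_kernel(sigma, 0L)
  g1 <- gauss_kernel(sigma, 1L)
  g2 <- gauss_kernel(sigma, 2L)
  conv3 <- function(x, kx, ky, kz) {
    x <- conv_axis_cpp(x, kx, 0L)
    x <- conv_axis_cpp(x, ky, 1L)
    conv_axis_cpp(x, kz, 2L)
  }
  s2 <- sigma^2
  h11 <- conv3(a, g2, g0, g0) * s2
  h22 <- conv3(a, g0, g2, g0) * s2
  h33 <- conv3(a, g0, g0, g2) * s2
  h12 <- conv3(a, g1, g1, g0) * s2
  h13 <- conv3(a, g1, g0, g1) * s2
  h23 <- conv3(a, g0, g1, g1) * s2
  ev <- eig_sym3(h11, h22, h33, h12, h13, h23)
  d <- dim(a)
  list(l1 = array(ev$l1, d), l2 = array(ev$l2, d), l3 = array(ev$l3, d))
}

# Vectorised eigenvalues of symmetric 3x3 matrices (trigonometric/Cardano
# form), returned sorted by |lambda|: |l1| <= |l2| <= |l3|.
eig_sym3 <- function(a11, a22, a33, a12, a13, a23) {
  p1 <- a12^2 + a13^2 + a23^2
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  safe <- p > 0
  pp <- ifelse(safe, p, 1)
  b11 <- (a11 - q) / pp; b22 <- (a22 - q) / pp; b33 <- (a33 - q) / pp
  b12 <- a12 / pp; b13 <- a13 / pp; b23 <- a23 / pp
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detB / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  e1[!safe] <- q[!safe]; e2[!safe] <- q[!safe]; e3[!safe] <- q[!safe]
  # sort the triple by absolute value, per element
  E <- cbind(as.numeric(e1), as.numeric(e2), as.numeric(e3))
  A <- abs(E)
  o1 <- max.col(-A, ties.method = "first")             # smallest |.|
  o3 <- max.col(A, ties.method = "last")               # largest |.|
  n <- nrow(E)
  idx <- seq_len(n)
  l1 <- E[cbind(idx, o1)]
  l3 <- E[cbind(idx, o3)]
  l2 <- rowSums(E) - l1 - l3
  # degenerate case where o1 == o3 (all equal magnitudes handled fine above)
  same <- o1 == o3
  if (any(same)) { l1[same] <- E[same, 1]; l3[same] <- E[same, 1]; l2[same] <- E[same, 1] }
  list(l1 = l1, l2 = l2, l3 = l3)
}

#' Single-scale Frangi response from Hessian eigenvalues
#'
#' Bright-polarity Frangi measure: zero wherever `l2 > 0` or `l3 > 0`, else
#' `V = gate(R_A) * gate(R_B) * (1 - exp(-S^2 / 2c^2))` with
#' `R_A = |l2|/|l3|`, `R_B = |l1|/sqrt(|l2 l3|)` and
#' `S = sqrt(l1^2 + l2^2 + l3^2)`.  The `R_B` gate depends on `rb_mode`:
#' the classical `exp(-R_B^2/2beta^2)` (tubes), its complement
#' `1 - exp(-R_B^2/2beta^2)` (blobs, where `R_B -> 1`), or their pointwise
#' maximum (default, accepting both tubular and spherical bright structures).
#'
#' @param eigs eigenvalue fields from [hessian_eigen()].
#' @param params a [frangi_params()].
#' @return 3D array of responses in `[0, 1]`.
#' @export
frangi_response <- function(eigs, params = frangi_params(), c_value = NULL) {
  l1 <- eigs$l1; l2 <- eigs$l2; l3 <- eigs$l3
  S2 <- l1^2 + l2^2 + l3^2
  cc <- if (!is.null(c_value)) c_value else params$c
  if (is.null(cc)) cc <- 0.5 * sqrt(max(S2))
  cc <- cc[1]
  if (cc <= 0) return(array(0, dim(l1)))
  al3 <- abs(l3); al2 <- abs(l2)
  ra2 <- ifelse(al3 > 0, (al2 / al3)^2, 0)
  rb2 <- ifelse(al2 * al3 > 0, l1^2 / (al2 * al3), 0)
  g_ra <- 1 - exp(-ra2 / (2 * params$alpha_f^2))
  g_tube <- exp(-rb2 / (2 * params$beta_f^2))
  g_blob <- 1 - g_tube
  g_rb <- switch(params$rb_mode,
                 tube = g_tube, blob = g_blob, both = pmax(g_tube, g_blob))
  v <- g_ra * g_rb * (1 - exp(-S2 / (2 * cc^2)))
  v[l2 > 0 | l3 > 0] <- 0
  array(pmin(pmax(v, 0), 1), dim(l1))
}

#' Multiscale Frangi detection of hyperintense RBC blobs
#'
#' Computes the per-voxel maximum Frangi response over the configured scales
#' (recording the argmax scale), suppresses noise by zeroing responses below
#' the configured fraction of the maximum, groups the surviving voxels by
#' 26-connectivity into blobs, discards sub-cellular specks, and reports blob
#' centroids, sizes and mean intensities.  Blobs whose equivalent diameter
#' falls within `single_cell_range` are flagged as single-RBC candidates.
#'
#' @param volume a calibrated [vh_volume()].
#' @param mask logical sample mask (`NULL` = whole volume).
#' @param params a [frangi_params()].  `params$c` may be a per-scale numeric
#'   vector (e.g. the `c_used` of a previous detection) to re-apply a detector
#'   calibrated on one acquisition to another -- the appropriate design for
#'   control/specificity runs, since the automatic `c` re-adapts to whatever
#'   the volume contains.
#' @param single_cell_range diameter range (um) flagged as single cells
#'   (default 4-7 um).
#' @param threshold absolute noise threshold on the response; `NULL` (default)
#'   derives it from `params$noise_fraction` and this volume's maximum
#'   response.  Pass the `threshold_used` of a calibration run to hold the
#'   detector fixed across volumes.
#' @return list of class `vh_blobset`: `response` (3D array in `[0, 1]`),
#'   `scale` (argmax scale per voxel), `blobs` (tibble: blob, x, y, z voxel
#'   centroid, x_um, y_um, z_um, n_voxels, diameter_um, mean_intensity,
#'   single_cell), `params`, `c_used` (per scale), `threshold_used`.
#' @export
multiscale_detect <- function(volume, mask = NULL, params = frangi_params(),
                              single_cell_range = c(4, 7), threshold = NULL) {
  stopifnot_volume(volume)
  d <- dim(volume$data)
  if (is.null(mask)) mask <- array(TRUE, d)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  resp <- array(0, d)
  sc_arg <- array(0, d)
  c_in <- params$c
  if (!is.null(c_in)) c_in <- rep_len(c_in, length(params$scales))
  c_used <- numeric(length(params$scales))
  for (i in seq_along(params$scales)) {
    s <- params$scales[i]
    eigs <- hessian_eigen(volume, s)
    if (is.null(c_in)) {
      S2 <- eigs$l1^2 + eigs$l2^2 + eigs$l3^2
      c_used[i] <- 0.5 * sqrt(max(S2))
    } else {
      c_used[i] <- c_in[i]
    }
    v <- frangi_response(eigs, params, c_value = c_used[i])
    upd <- v > resp
    resp[upd] <- v[upd]
    sc_arg[upd] <- s
  }
  resp[!mask] <- 0
  sc_arg[resp == 0] <- 0
  mx <- max(resp)
  if (is.null(threshold) && mx > 0) {
    threshold <- if (params$noise_mode == "max") {
      params$noise_fraction * mx
    } else {
      quantile(resp[resp > 0], probs = params$noise_fraction, names = FALSE)
    }
  }
  if (!is.null(threshold)) {
    resp[resp < threshold] <- 0
    sc_arg[resp == 0] <- 0
  }
  comp <- label3d_cpp(array(resp > 0, d))
  n_comp <- attr(comp, "n_components")
  vs <- exp(mean(log(volume$voxel_size)))
  min_vox <- max(1, pi / 6 * (params$min_diameter_um / vs)^3)
  if (n_comp > 0) {
    sizes <- tabulate(comp[comp > 0], nbins = n_comp)
    keep <- which(sizes >= min_vox)
  } else {
    sizes <- integer(0); keep <- integer(0)
  }
  if (length(keep)) {
    idx <- which(comp > 0)
    cl <- comp[idx]
    sel <- cl %in% keep
    idx <- idx[sel]; cl <- cl[sel]
    coord <- arrayInd(idx, d)
    cx <- tapply(coord[, 1], cl, mean)
    cy <- tapply(coord[, 2], cl, mean)
    cz <- tapply(coord[, 3], cl, mean)
    mi <- tapply(volume$data[idx], cl, mean)
    ks <- as.integer(names(cx))
    n_vox <- sizes[ks]
    d_um <- (6 * n_vox / pi)^(1 / 3) * vs
    blobs <- tibble::tibble(
      blob = seq_along(ks),
      x = as.numeric(cx), y = as.numeric(cy), z = as.numeric(cz),
      x_um = as.numeric(cx) * volume$voxel_size[1],
      y_um = as.numeric(cy) * volume$voxel_size[2],
      z_um = as.numeric(cz) * volume$voxel_size[3],
      n_voxels = as.integer(n_vox),
      diameter_um = d_um,
      mean_intensity = as.numeric(mi),
      single_cell = d_um >= single_cell_range[1] & d_um <= single_cell_range[2]
    )
  } else {
    blobs <- tibble::tibble(blob = integer(0), x = numeric(0), y = numeric(0),
                            z = numeric(0), x_um = numeric(0), y_um = numeric(0),
                            z_um = numeric(0), n_voxels = integer(0),
                            diameter_um = numeric(0), mean_intensity = numeric(0),
                            single_cell = logical(0))
  }
  structure(list(response = resp, scale = sc_arg, blobs = blobs, params = params,
                 c_used = c_used, threshold_used = threshold),
            class = "vh_blobset")
}

#' @export
print.vh_blobset <- function(x, ...) {
  cat(sprintf("<vh_blobset> %d blobs (%d single-cell candidates)\n",
              nrow(x$blobs), sum(x$blobs$single_cell)))
  if (nrow(x$blobs)) {
    cat(sprintf("  diameters: %.2f - %.2f um\n",
                min(x$blobs$diameter_um), max(x$blobs$diameter_um)))
  }
  invisible(x)
}
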