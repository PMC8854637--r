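#' XRD peak list
#'
#' A tidy per-peak table of Bragg angle and observed width, tagged with the
#' radiation wavelength and whether it describes the sample or the
#' instrumental reference (e.g. polycrystalline silicon).
#'
#' @param two_theta_deg scattering angles 2-theta in degrees (0 < 2theta < 180).
#' @param fwhm_deg observed full widths at half maximum, degrees (> 0).
#' @param hkl optional reflection labels.
#' @param wavelength radiation wavelength in Angstrom (default Cu-K-alpha,
#'   1.5406 A).
#' @param source `"sample"` or `"reference"`.
#' @return tibble of class `peak_list` with attributes `wavelength`, `source`.
#' @export
peak_list <- function(two_theta_deg, fwhm_deg, hkl = NA_character_,
                      wavelength = 1.5406, source = c("sample", "reference")) {
  source <- match.arg(source)
  if (any(two_theta_deg <= 0 | two_theta_deg >= 180)) {
    stop("2-theta must lie in (0, 180) degrees", call. = FALSE)
  }
  if (any(fwhm_deg <= 0)) stop("FWHM must be positive", call. = FALSE)
  out <- tibble::tibble(two_theta_deg = as.numeric(two_theta_deg),
                        fwhm_deg = as.numeric(fwhm_deg),
                        hkl = as.character(hkl))
  attr(out, "wavelength") <- wavelength
  attr(out, "source") <- source
  class(out) <- c("peak_list", class(out))
  out
}

#' Read a peak list from CSV
#'
#' Expects columns `two_theta_deg`, `fwhm_deg` and optionally `hkl`.
#'
#' @param path CSV file path.
#' @inheritParams peak_list
#' @return a [peak_list()].
#' @export
read_peaks <- function(path, wavelength = 1.5406, source = c("sample", "reference")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("two_theta_deg", "fwhm_deg") %in% names(df))) {
    stop("CSV must have columns two_theta_deg and fwhm_deg", call. = FALSE)
  }
  peak_list(df$two_theta_deg, df$fwhm_deg,
            hkl = if ("hkl" %in% names(df)) df$hkl else NA_character_,
            wavelength = wavelength, source = source)
}

#' Simulate peak widths for a known size/strain state
#'
#' Generates the FWHM values that a crystallite size `D` and microstrain
#' `epsilon` produce under the Williamson-Hall model
#' `beta cos(theta) = K lambda / D + 4 epsilon sin(theta)`; used to build
#' synthetic recovery tests.
#'
#' @param two_theta_deg Bragg angles 2-theta in degrees.
#' @param size_nm crystallite size D in nm.
#' @param strain dimensionless microstrain epsilon.
#' @param wavelength Angstrom.
#' @param K Scherrer constant (default 0.9).
#' @return a sample [peak_list()].
#' @export
simulate_wh_peaks <- function(two_theta_deg, size_nm, strain = 0,
                              wavelength = 1.5406, K = 0.9) {
  theta <- two_theta_deg / 2 * pi / 180
  D_A <- size_nm * 10                      # nm -> Angstrom
  beta_rad <- K * wavelength / (D_A * cos(theta)) + 4 * strain * tan(theta)
  peak_list(two_theta_deg, beta_rad * 180 / pi, wavelength = wavelength,
            source = "sample")
}

#' Instrumental broadening correction
#'
#' Subtracts the instrumental width (from a reference material such as
#' polycrystalline Si) from the observed sample widths, peak by peak, with
#' the instrumental FWHM linearly interpolated in 2-theta.  Gaussian
#' quadrature subtraction `beta = sqrt(beta_obs^2 - beta_instr^2)` by default;
#' `mode = "lorentzian"` uses the linear difference.
#'
#' @param sample,reference [peak_list()] objects.
#' @param mode `"gaussian"` (default) or `"lorentzian"`.
#' @return the corrected sample [peak_list()] (extra column
#'   `fwhm_instr_deg`).
#' @export
correct_instrumental <- function(sample, reference, mode = c("gaussian", "lorentzian")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sample, "peak_list"), inherits(reference, "peak_list"))
  ref_i <- approx(reference$two_theta_deg, reference$fwhm_deg,
                  xout = sample$two_theta_deg, rule = 1)$y
  if (any(is.na(ref_i))) {
    stop("reference peaks do not span the sample 2-theta range", call. = FALSE)
  }
  bad <- which(ref_i >= sample$fwhm_deg)
  if (length(bad)) {
    stop(sprintf("instrumental width >= observed width at 2-theta = %s deg",
                 paste(signif(sample$two_theta_deg[bad], 5), collapse = ", ")),
         call. = FALSE)
  }
  beta <- switch(mode,
                 gaussian = sqrt(sample$fwhm_deg^2 - ref_i^2),
                 lorentzian = sample$fwhm_deg - ref_i)
  out <- sample
  out$fwhm_deg <- beta
  out$fwhm_instr_deg <- ref_i
  attr(out, "corrected") <- mode
  out
}

#' Williamson-Hall size/strain fit
#'
#' Ordinary least-squares line through `y = beta cos(theta)` versus
#' `x = 4 sin(theta)` (beta in radians): the intercept gives the crystallite
#' size `D = K lambda / intercept` and the slope the microstrain `epsilon`,
#' with uncertainties propagated from the regression covariance.
#'
#' @param peaks a (corrected) [peak_list()] with at least 2 peaks.
#' @param K Scherrer constant (default 0.9; FWHM convention for beta).
#' @param wavelength optional override of the peak list's wavelength
#'   (Angstrom).
#' @return object of class `wh_fit`: size `D_nm` (NA, flagged, when the
#'   intercept is not positive), `D_se_nm`, `strain`, `strain_se`, intercept
#'   and slope with SEs, the underlying `lm` fit and the plotting data.
#' @export
williamson_hall_fit <- function(peaks, K = 0.9, wavelength = NULL) {
  stopifnot(inherits(peaks, "peak_list"))
  if (nrow(peaks) < 2) stop("need at least 2 peaks for a Williamson-Hall fit",
                            call. = FALSE)
  lambda <- if (is.null(wavelength)) attr(peaks, "wavelength") else wavelength
  theta <- peaks$two_theta_deg / 2 * pi / 180
  beta <- peaks$fwhm_deg * pi / 180
  df <- data.frame(x = 4 * sin(theta), y = beta * cos(theta))
  fit <- lm(y ~ x, data = df)
  co <- coef(fit)
  se <- sqrt(diag(suppressWarnings(vcov(fit))))
  intercept <- unname(co[1]); slope <- unname(co[2])
  size_defined <- is.finite(intercept) && intercept > 0
  D_A <- if (size_defined) K * lambda / intercept else NA_real_
  D_se <- if (size_defined) K * lambda / intercept^2 * se[1] else NA_real_
  structure(
    list(D_nm = D_A / 10, D_se_nm = D_se / 10,
         strain = slope, strain_se = unname(se[2]),
         intercept = intercept, intercept_se = unname(se[1]),
         slope = slope, slope_se = unname(se[2]),
         size_defined = size_defined,
         K = K, wavelength = lambda,
         sigma = suppressWarnings(summary(fit)$sigma), n_peaks = nrow(peaks),
         data = df, fit = fit),
    class = "wh_fit"
  )
}

#' @export
print.wh_fit <- function(x, ...) {
  cat("<wh_fit> Williamson-Hall size/strain analysis\n")
  if (x$size_defined) {
    cat(sprintf("  crystallite size D = %.2f +/- %.2f nm (K = %g, lambda = %g A)\n",
                x$D_nm, x$D_se_nm, x$K, x$wavelength))
  } else {
    cat("  crystallite size undefined (intercept <= 0; strain-only broadening)\n")
  }
  cat(sprintf("  microstrain = %.3e +/- %.3e\n", x$strain, x$strain_se))
  cat(sprintf("  %d peaks, residual SE %.3e\n", x$n_peaks, x$sigma))
  invisible(x)
}

#' @rdname williamson_hall_fit
#' @param x a `wh_fit`.
#' @param ... unused.
#' @export
tidy.wh_fit <- function(x, ...) {
  tibble::tibble(
    term = c("size_nm", "strain", "intercept", "slope"),
    estimate = c(x$D_nm, x$strain, x$intercept, x$slope),
    std.error = c(x$D_se_nm, x$strain_se, x$intercept_se, x$slope_se)
  )
}

#' @rdname williamson_hall_fit
#' @export
glance.wh_fit <- function(x, ...) {
  tibble::tibble(D_nm = x$D_nm, D_se_nm = x$D_se_nm, strain = x$strain,
                 strain_se = x$strain_se, size_defined = x$size_defined,
                 n_peaks = x$n_peaks, sigma = x$sigma,
                 r.squared = suppressWarnings(summary(x$fit)$r.squared))
}

#' @rdname williamson_hall_fit
#' @param object a `wh_fit`.
#' @export
autoplot.wh_fit <- function(object, ...) {
  df <- object$data
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(
      x = expression(4 * sin(theta)),
      y = expression(beta * cos(theta) ~ "(rad)"),
      title = "Williamson-Hall plot",
      subtitle = if (object$size_defined) {
        sprintf("D = %.1f nm, strain = %.2e", object$D_nm, object$strain)
      } else {
        "size undefined (strain-only broadening)"
      }
    ) +
    ggplot2::theme_minimal()
}
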