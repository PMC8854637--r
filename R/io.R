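sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Write a volume as a multi-page TIFF stack with a JSON sidecar
#'
#' Slices along z become TIFF pages.  Because TIFF float storage is defined on
#' `[0, 1]`, values are affine-mapped to that range and the original range is
#' recorded in the sidecar, together with voxel size, intensity semantics and
#' provenance.  8/16-bit integer grids round-trip exactly; 32-bit float grids
#' round-trip at single precision.
#'
#' @param volume a [vh_volume()].
#' @param path output TIFF path (`.tif`); the sidecar goes to the same path
#'   with extension `.json`.
#' @param bits 8, 16 or 32 (32 = float).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, bits = 32L) {
  stopifnot_volume(volume)
  v <- volume$data
  rng <- range(v)
  span <- diff(rng)
  if (span == 0) span <- 1
  if (bits %in% c(8L, 16L)) {
    levels <- 2^bits - 1
    # integer-valued grids that fit the bit depth get a unit quantisation
    # step so they round-trip exactly
    if (all(v == round(v)) && span <= levels) {
      span <- levels
      rng <- c(rng[1], rng[1] + levels)
    }
    vn <- round((v - rng[1]) / span * levels) / levels
  } else if (bits == 32L) {
    vn <- (v - rng[1]) / span
  } else stop("bits must be 8, 16 or 32", call. = FALSE)
  pages <- lapply(seq_len(dim(v)[3]), function(k) vn[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  meta <- list(kind = "volume", voxel_size = volume$voxel_size,
               semantics = volume$semantics, range = rng, bits = bits,
               dim = dim(v), provenance = volume$provenance)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path TIFF path; the sidecar is looked up next to it.
#' @param voxel_size required if no sidecar is present (um).
#' @return a [vh_volume()].
#' @export
read_volume <- function(path, voxel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(dim(pages[[1]]), length(pages))
  v <- array(0, d)
  for (k in seq_along(pages)) v[, , k] <- pages[[k]]
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    rng <- meta$range
    v <- v * (rng[2] - rng[1]) + rng[1]
    if (!is.null(meta$dim) && !all(meta$dim == d)) {
      stop("TIFF shape does not match its sidecar", call. = FALSE)
    }
    vh_volume(v, meta$voxel_size, meta$semantics,
              provenance = as.list(meta$provenance))
  } else {
    if (is.null(voxel_size)) {
      stop("no sidecar found; voxel_size must be given", call. = FALSE)
    }
    vh_volume(v, voxel_size, "raw")
  }
}

#' Write / read a label volume (8-bit TIFF + JSON class table)
#'
#' @param labels a [vh_labels()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  stopifnot(inherits(labels, "vh_labels"))
  lab <- labels$labels
  if (max(lab) > 255) stop("more than 255 label codes", call. = FALSE)
  pages <- lapply(seq_len(dim(lab)[3]), function(k) lab[, , k] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  meta <- list(kind = "labels", voxel_size = labels$voxel_size,
               dim = dim(lab),
               schema = as.data.frame(labels$schema),
               tube_code = attr(lab, "tube_code"))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(dim(pages[[1]]), length(pages))
  lab <- array(0L, d)
  for (k in seq_along(pages)) lab[, , k] <- as.integer(pages[[k]])
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  schema <- class_schema(meta$schema$class,
                         thresholds = if (all(is.finite(meta$schema$threshold[-1]))) {
                           meta$schema$threshold[-1]
                         } else NULL)
  if (!is.null(meta$tube_code)) attr(lab, "tube_code") <- meta$tube_code
  vh_labels(lab, meta$voxel_size, schema)
}

#' Write a composition or porosity report as CSV (fixed column order)
#'
#' @param report a `vh_composition`, `vh_porosity` or blob tibble.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a composition report as JSON (volume-fraction table layout)
#'
#' @param report a `vh_composition`.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_composition_json <- function(report, path) {
  payload <- list(
    total_voxels = attr(report, "total_voxels"),
    total_volume_um3 = attr(report, "total_volume_um3"),
    classes = as.data.frame(report)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
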