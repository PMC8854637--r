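#' Default pipeline configuration
#'
#' Nested stage blocks mirroring the module parameters: `phantom` (passed to
#' [phantom_spec()]), `geometry` ([vh_geometry()] fields), `propagation`
#' (photon_count, noise, alpha `NULL` = matched to the retrieval filter),
#' `pbct` (cutoff_fraction), `calib` (targets), `segmentation` (thresholds
#' `NULL` = multi-Otsu with `k` classes taken from the phantom schema),
#' `frangi` (enabled, [frangi_params()] fields), plus a global `seed` and
#' `out_dir`.
#'
#' @param seed global RNG seed; stage seeds are derived from it.
#' @param out_dir output directory for artifacts (`NULL`: nothing written).
#' @return nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = NULL) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    phantom = list(),
    geometry = list(n_angles = NULL, angular_range = 180),
    propagation = list(alpha = NULL, photon_count = 1e5, noise = TRUE),
    pbct = list(cutoff_fraction = 0.16),
    calib = list(targets = c(500, 1500)),
    segmentation = list(thresholds = NULL),
    frangi = list(enabled = FALSE),
    porosity = list(min_diameter = 2)
  ), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror [pipeline_config()]; unknown keys are rejected.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- pipeline_config(seed = raw$seed %||% 1L, out_dir = raw$out_dir)
  for (block in c("phantom", "geometry", "propagation", "pbct", "calib",
                  "segmentation", "frangi", "porosity")) {
    if (!is.null(raw[[block]])) {
      unknown <- setdiff(names(raw[[block]]),
                         union(names(cfg[[block]]), names(formals(phantom_spec))))
      if (block != "phantom" && length(setdiff(names(raw[[block]]), names(cfg[[block]])))) {
        stop(sprintf("unknown key(s) in config block '%s': %s", block,
                     paste(setdiff(names(raw[[block]]), names(cfg[[block]])),
                           collapse = ", ")), call. = FALSE)
      }
      if (block == "phantom" && length(unknown)) {
        stop(sprintf("unknown key(s) in config block 'phantom': %s",
                     paste(unknown, collapse = ", ")), call. = FALSE)
      }
      cfg[[block]] <- utils::modifyList(cfg[[block]], raw[[block]])
    }
  }
  extra <- setdiff(names(raw), c("seed", "out_dir", "phantom", "geometry",
                                 "propagation", "pbct", "calib", "segmentation",
                                 "frangi", "porosity"))
  if (length(extra)) {
    stop("unknown top-level config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full virtual-histology pipeline on a synthetic clot
#'
#' simulate -> forward-project -> propagate/noise -> retrieve -> reconstruct
#' -> calibrate -> mask -> segment -> quantify (-> RBC detection), validating
#' every stage block before any stage runs.  Re-running with an identical
#' configuration reproduces all reports exactly; artifacts and a provenance
#' record are written to `config$out_dir` when set.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @return list of class `vh_run`: phantom, projections (propagated),
#'   retrieved, recon, calibration, calibrated, mask, thresholds, labels,
#'   composition, porosity, blobs (or NULL), config.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))

  # ---- validate every stage block up front --------------------------------
  ph_args <- config$phantom
  ph_args$seed <- ph_args$seed %||% config$seed
  spec <- do.call(phantom_spec, ph_args)             # errors on bad fractions etc.
  geom <- vh_geometry(n_angles = config$geometry$n_angles,
                      angular_range = config$geometry$angular_range %||% 180)
  pag <- paganin_config(config$pbct$cutoff_fraction %||% 0.16)
  alpha <- config$propagation$alpha %||% pag$alpha
  if (alpha < 0) stop("propagation alpha must be >= 0", call. = FALSE)
  photons <- config$propagation$photon_count %||% 1e4
  if (photons <= 0) stop("photon_count must be positive", call. = FALSE)
  targets <- config$calib$targets %||% c(500, 1500)
  fr <- NULL
  if (isTRUE(config$frangi$enabled)) {
    fr_args <- config$frangi[setdiff(names(config$frangi), "enabled")]
    fr <- do.call(frangi_params, fr_args)
  }

  # ---- execute ------------------------------------------------------------
  phantom <- generate_clot_phantom(spec)
  stack <- forward_project(phantom$volume, geom)
  stack <- apply_propagation_and_noise(stack, alpha = alpha,
                                       photon_count = photons,
                                       seed = config$seed + 1L,
                                       noise = isTRUE(config$propagation$noise))
  retrieved <- paganin_retrieve(stack, pag)
  recon <- fbp_reconstruct(retrieved)
  refs <- auto_reference_masks(recon)
  cal <- fit_two_point(recon, refs$air, refs$ps, targets = targets)
  calibrated <- apply_calibration(recon, cal)
  mask <- extract_sample_mask(calibrated)
  thresholds <- config$segmentation$thresholds
  if (is.null(thresholds)) {
    thresholds <- auto_thresholds(calibrated, mask, k = nrow(phantom$schema))
  }
  schema <- set_thresholds(phantom$schema, thresholds)
  labels <- segment_composition(calibrated, mask, schema)
  composition <- quantify_composition(labels, calibrated)
  porosity <- if ("P" %in% schema$class) {
    quantify_porosity(labels, min_diameter = config$porosity$min_diameter %||% 2)
  } else NULL
  blobs <- if (!is.null(fr)) multiscale_detect(calibrated, mask, fr) else NULL

  run <- structure(
    list(phantom = phantom, projections = stack, retrieved = retrieved,
         recon = recon, calibration = cal, calibrated = calibrated,
         mask = mask, thresholds = thresholds, labels = labels,
         composition = composition, porosity = porosity, blobs = blobs,
         config = config),
    class = "vh_run"
  )
  if (!is.null(config$out_dir)) write_run_artifacts(run, config$out_dir)
  run
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_volume(run$phantom$volume, p("phantom_raw.tif"), bits = 16L)
  write_labels(run$phantom$labels, p("truth_labels.tif"))
  write_volume(run$recon, p("recon.tif"))
  write_volume(run$calibrated, p("calibrated.tif"))
  write_labels(run$labels, p("labels.tif"))
  write_report_csv(run$composition, p("composition.csv"))
  write_composition_json(run$composition, p("composition.json"))
  if (!is.null(run$porosity)) write_report_csv(run$porosity, p("porosity.csv"))
  if (!is.null(run$blobs)) write_report_csv(run$blobs$blobs, p("blobs.csv"))
  cfg <- run$config
  prov <- list(
    config = cfg,
    config_hash = rlang::hash(cfg),
    seed = cfg$seed,
    calibration = list(a = run$calibration$a, b = run$calibration$b,
                       m_air = run$calibration$m_air, m_ps = run$calibration$m_ps),
    thresholds = run$thresholds,
    package_version = as.character(utils::packageVersion("clotvh")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(prov, p("provenance.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")
  invisible(out_dir)
}

#' @export
print.vh_run <- function(x, ...) {
  cat("<vh_run> virtual-histology pipeline result\n")
  cat(sprintf("  calibration: a = %.4g, b = %.4g\n", x$calibration$a, x$calibration$b))
  cat(sprintf("  thresholds: %s\n", paste(signif(x$thresholds, 5), collapse = ", ")))
  cat("  composition:\n")
  print(as.data.frame(x$composition), row.names = FALSE)
  invisible(x)
}
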