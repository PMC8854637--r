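#' Specification of a synthetic clot phantom
#'
#' Describes a ~2 mm clot held in a Kapton (polystyrene) tube in air, with an
#' ordered catalogue of internal composition classes: P (porosity, air-level
#' intensity), LFP (loose, porous fibrin/platelets), CFP (compact
#' fibrin/platelets), CA (nano-calcification "glassy opacity", optional) and
#' RBC (red blood cell masses).  Raw class attenuations are free parameters of
#' the generator; the defaults are chosen so that after the two-point air/PS
#' calibration the class means land near the values typical of reconstructed
#' clot scans (P just above air at ~507, LFP ~975, CFP ~1404, CA between CFP
#' and RBC at ~1650, RBC ~1925 calibrated units), preserving the strict
#' ordering P < LFP < CFP < CA < RBC.
#'
#' @param grid_shape voxels per axis (x, y, z); cubic grids recommended.
#' @param voxel_size voxel edge length in micrometres.
#' @param clot_radius radius of the spherical clot, um.
#' @param tube_inner_radius,tube_outer_radius Kapton tube annulus radii, um.
#' @param class_fractions named percentages of the clot volume per class, in
#'   the order P, LFP, CFP, CA, RBC (CA may be omitted); must sum to 100.
#' @param class_means named raw linear attenuation means per class (per um),
#'   strictly increasing in class order.
#' @param class_sds per-class raw intensity standard deviations.
#' @param tube_mean,tube_sd raw attenuation of the polystyrene tube wall.
#' @param air_sd raw intensity spread of air (mean 0).
#' @param rbc_diameter_range single-cell diameter range, um (default 4-7).
#' @param rbc_aggregate_fraction fraction of RBC volume placed as large
#'   (>= 100 um) compact aggregates; the remainder is placed as single cells,
#'   or as few-cell clusters where a single cell is below voxel resolution.
#' @param pore_radius_range pore blob radius range, um.
#' @param ca_radius_range calcification blob radius range, um.
#' @param rbc_shell_thickness thickness of the low-intensity porous boundary
#'   painted around RBC aggregates, um (labelled LFP).
#' @param texture_length correlation length (um) of the random field that
#'   splits the remaining clot matrix into loose vs compact fibrin/platelets;
#'   the default 450 um gives the marbled, hundreds-of-micrometre regions seen
#'   in reconstructed clot slices.
#' @param edge_sigma partial-volume softening of material interfaces applied
#'   to the noise-free mean-intensity field, in voxels.
#' @param seed RNG seed (mandatory; the generator is fully deterministic).
#'
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(128L, 128L, 128L),
                         voxel_size = 16,
                         clot_radius = 800,
                         tube_inner_radius = 900,
                         tube_outer_radius = 1000,
                         class_fractions = c(P = 10, LFP = 38, CFP = 40, CA = 2, RBC = 10),
                         class_means = c(P = 5e-6, LFP = 3.8e-4, CFP = 7.2e-4,
                                         CA = 9.2e-4, RBC = 1.14e-3),
                         class_sds = c(P = 5e-6, LFP = 3e-5, CFP = 3e-5,
                                       CA = 3e-5, RBC = 3e-5),
                         tube_mean = 8e-4, tube_sd = 1e-5, air_sd = 2e-6,
                         rbc_diameter_range = c(4, 7),
                         rbc_aggregate_fraction = 0.9,
                         pore_radius_range = c(100, 300),
                         ca_radius_range = c(150, 280),
                         rbc_shell_thickness = 24,
                         texture_length = 450,
                         edge_sigma = 0.4,
                         seed) {
  if (missing(seed)) stop("`seed` is mandatory for phantom generation", call. = FALSE)
  canonical <- c("P", "LFP", "CFP", "CA", "RBC")
  cls <- names(class_fractions)
  if (is.null(cls) || !all(cls %in% canonical)) {
    stop("class_fractions must be named with classes among P, LFP, CFP, CA, RBC",
         call. = FALSE)
  }
  cls <- canonical[canonical %in% cls]
  class_fractions <- class_fractions[cls]
  if (any(class_fractions < 0)) stop("class fractions must be non-negative", call. = FALSE)
  if (abs(sum(class_fractions) - 100) > 0.01) {
    stop(sprintf("class fractions must sum to 100 (got %.4f)", sum(class_fractions)),
         call. = FALSE)
  }
  if (!all(cls %in% names(class_means)) || !all(cls %in% names(class_sds))) {
    stop("class_means/class_sds must cover every class in class_fractions", call. = FALSE)
  }
  class_means <- class_means[cls]; class_sds <- class_sds[cls]
  if (any(diff(class_means) <= 0)) {
    stop("class_means must be strictly increasing in class order P < LFP < CFP < CA < RBC",
         call. = FALSE)
  }
  if (!(clot_radius < tube_inner_radius && tube_inner_radius < tube_outer_radius)) {
    stop("need clot_radius < tube_inner_radius < tube_outer_radius", call. = FALSE)
  }
  half_extent <- min(grid_shape[1:2]) / 2 * voxel_size
  if (tube_outer_radius > half_extent) {
    stop(sprintf("tube (outer radius %g um) does not fit in the grid (half extent %g um)",
                 tube_outer_radius, half_extent), call. = FALSE)
  }
  if (clot_radius > grid_shape[3] / 2 * voxel_size) {
    stop("clot does not fit in the grid along z", call. = FALSE)
  }
  structure(
    list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
         clot_radius = clot_radius, tube_inner_radius = tube_inner_radius,
         tube_outer_radius = tube_outer_radius,
         class_fractions = class_fractions, class_means = class_means,
         class_sds = class_sds, tube_mean = tube_mean, tube_sd = tube_sd,
         air_sd = air_sd, rbc_diameter_range = rbc_diameter_range,
         rbc_aggregate_fraction = rbc_aggregate_fraction,
         pore_radius_range = pore_radius_range, ca_radius_range = ca_radius_range,
         rbc_shell_thickness = rbc_shell_thickness, texture_length = texture_length,
         edge_sigma = edge_sigma, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# voxel-centre coordinates (um) along one axis, centred on the grid
axis_coords <- function(n, voxel) (seq_len(n) - (n + 1) / 2) * voxel

#' Generate a ground-truthed synthetic clot volume
#'
#' Rasterises the clot sphere, tube annulus and internal composition classes
#' onto the grid, draws per-voxel raw intensities (class mean + Gaussian
#' spread, with partial-volume softened interfaces) and returns the raw volume
#' together with the ground-truth label volume.  Pores and calcifications are
#' random spherical blobs; RBC content is placed as large aggregates (unions
#' of overlapping spheres with a thin low-intensity porous boundary shell)
#' plus single cells / small clusters; the remaining clot voxels are split
#' into loose vs compact fibrin/platelets along a smooth random texture field
#' so that the realized per-class volume fractions match the requested ones to
#' within one percentage point.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `vh_phantom` with elements `volume` (raw
#'   [vh_volume()]), `labels` ([vh_labels()]; tube voxels carry the extra code
#'   `attr(labels$labels, "tube_code")`), `schema`, `realized_fractions`
#'   (tibble) and `spec`.
#' @export
generate_clot_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$grid_shape; vs <- spec$voxel_size
  X <- axis_coords(d[1], vs); Y <- axis_coords(d[2], vs); Z <- axis_coords(d[3], vs)
  r2_xy <- outer(X^2, Y^2, "+")                       # d1 x d2
  rho <- sqrt(r2_xy)
  clot <- array(FALSE, d)
  for (k in seq_len(d[3])) clot[, , k] <- r2_xy + Z[k]^2 <= spec$clot_radius^2
  tube2d <- rho >= spec$tube_inner_radius & rho <= spec$tube_outer_radius
  cls <- names(spec$class_fractions)
  K <- length(cls)
  tube_code <- K + 1L
  labels <- array(0L, d)
  labels[array(tube2d, d)] <- tube_code

  n_clot <- sum(clot)
  targets <- round(spec$class_fractions / 100 * n_clot)
  counts <- setNames(integer(K), cls)
  avail <- clot                                        # not-yet-assigned clot voxels

  code_of <- setNames(seq_len(K), cls)

  # paint one ellipsoid (semi-axes um, um centre) into `labels` where `avail`
  paint <- function(center, semi, code) {
    i <- which(X >= center[1] - semi[1] - vs & X <= center[1] + semi[1] + vs)
    j <- which(Y >= center[2] - semi[2] - vs & Y <= center[2] + semi[2] + vs)
    k <- which(Z >= center[3] - semi[3] - vs & Z <= center[3] + semi[3] + vs)
    if (!length(i) || !length(j) || !length(k)) return(0L)
    ex <- ((X[i] - center[1]) / semi[1])^2
    ey <- ((Y[j] - center[2]) / semi[2])^2
    ez <- ((Z[k] - center[3]) / semi[3])^2
    inside <- outer(outer(ex, ey, "+"), ez, "+") <= 1
    sel <- inside & avail[i, j, k]
    n_new <- sum(sel)
    if (n_new > 0) {
      sub <- labels[i, j, k]; sub[sel] <- code; labels[i, j, k] <<- sub
      sub <- avail[i, j, k]; sub[sel] <- FALSE; avail[i, j, k] <<- sub
    }
    n_new
  }

  rand_center <- function(margin) {
    # uniform in the sphere of radius clot_radius - margin
    repeat {
      p <- runif(3, -1, 1) * (spec$clot_radius - margin)
      if (sum(p^2) <= (spec$clot_radius - margin)^2) return(p)
    }
  }

  # cap a drawn blob radius to the remaining voxel budget of its class, so a
  # single large blob cannot overshoot the target fraction
  cap_radius <- function(r, need) {
    r_need <- (3 * need * vs^3 / (4 * pi))^(1 / 3) * 1.05
    min(r, max(r_need, 2 * vs))
  }
  interior_margin <- 4 * vs   # keep blobs clear of the clot surface so
                              # enclosed pores stay holes of the sample mask

  # smooth random texture that later splits loose vs compact fibrin/platelets;
  # computed up front so pores can be seeded inside the future loose (porous)
  # regions -- porosity belongs to the loose, porous fibrin matrix
  tex <- gaussian_smooth3(array(rnorm(prod(d)), d),
                          sigma = spec$texture_length / vs)
  dist_c <- array(0, d)
  for (k in seq_len(d[3])) dist_c[, , k] <- sqrt(r2_xy + Z[k]^2)
  tex_q30 <- quantile(tex[clot], 0.3)

  loose_center <- function(margin) {
    pool <- which(clot & tex <= tex_q30 & dist_c <= spec$clot_radius - margin)
    if (!length(pool)) {
      pool <- which(clot & dist_c <= spec$clot_radius - margin)
    }
    if (!length(pool)) return(rand_center(margin))
    co <- arrayInd(sample(pool, 1), d)
    c(X[co[1]], Y[co[2]], Z[co[3]])
  }

  # --- pores (seeded in loose regions) -------------------------------------
  if ("P" %in% cls && targets[["P"]] > 0) {
    tries <- 0L
    while (counts[["P"]] < targets[["P"]] && tries < 10000L) {
      tries <- tries + 1L
      r <- runif(1, spec$pore_radius_range[1], spec$pore_radius_range[2])
      r <- cap_radius(r, targets[["P"]] - counts[["P"]])
      counts[["P"]] <- counts[["P"]] +
        paint(loose_center(r + interior_margin), rep(r, 3), code_of[["P"]])
    }
  }

  # --- calcifications ------------------------------------------------------
  if ("CA" %in% cls && targets[["CA"]] > 0) {
    tries <- 0L
    while (counts[["CA"]] < targets[["CA"]] && tries < 10000L) {
      tries <- tries + 1L
      r <- runif(1, spec$ca_radius_range[1], spec$ca_radius_range[2])
      r <- cap_radius(r, targets[["CA"]] - counts[["CA"]])
      semi <- r * runif(3, 0.7, 1.3)
      counts[["CA"]] <- counts[["CA"]] +
        paint(rand_center(max(semi) + interior_margin), semi, code_of[["CA"]])
    }
  }

  # --- RBC: aggregates with porous (loose fibrin) boundary shells ----------
  rbc_centers <- NULL
  if ("RBC" %in% cls && targets[["RBC"]] > 0) {
    target_rbc <- targets[["RBC"]]
    target_agg <- round(spec$rbc_aggregate_fraction * target_rbc)
    shell <- spec$rbc_shell_thickness
    shell_code <- if ("LFP" %in% cls) code_of[["LFP"]] else code_of[["CFP"]]
    # compact aggregates as smooth ellipsoids, hundreds of micrometres across,
    # each wrapped in a porous (loose fibrin) boundary shell
    attempts <- 0L
    while (counts[["RBC"]] < target_agg && attempts < 200L) {
      attempts <- attempts + 1L
      r <- runif(1, 300, 400)
      r <- cap_radius(r, target_agg - counts[["RBC"]])
      semi <- r * runif(3, 0.85, 1.18)
      ctr <- rand_center(max(semi) + shell + interior_margin)
      if (shell > 0) paint(ctr, semi + shell, shell_code)
      nn <- paint_over(ctr, semi, code_of[["RBC"]], shell_code,
                       X, Y, Z, vs, labels, avail, clot)
      labels <- nn$labels; avail <- nn$avail
      counts[["RBC"]] <- counts[["RBC"]] + nn$n
    }
    if ("LFP" %in% cls) counts[["LFP"]] <- sum(labels == code_of[["LFP"]])
    if ("CFP" %in% cls) counts[["CFP"]] <- sum(labels == code_of[["CFP"]])
    # singles / small clusters for the remaining RBC volume
    mean_d <- mean(spec$rbc_diameter_range)
    if (mean_d >= 2 * vs) {
      tries <- 0L
      while (counts[["RBC"]] < target_rbc && tries < 100000L) {
        tries <- tries + 1L
        dd <- runif(1, spec$rbc_diameter_range[1], spec$rbc_diameter_range[2])
        semi <- c(dd, dd, 0.75 * dd) / 2          # mildly oblate single cell
        ctr <- rand_center(dd)
        n_new <- paint(ctr, semi, code_of[["RBC"]])
        counts[["RBC"]] <- counts[["RBC"]] + n_new
        if (n_new > 0) rbc_centers <- rbind(rbc_centers, ctr)
      }
    } else {
      # single cells are below voxel resolution and could not survive the
      # reconstruction point spread; the remaining RBC volume is placed as the
      # smallest resolvable clusters of tightly packed cells (~4 voxels radius)
      cluster_r <- 4 * vs
      tries <- 0L
      while (counts[["RBC"]] < target_rbc && tries < 10000L) {
        tries <- tries + 1L
        r <- cap_radius(runif(1, 0.8, 1.2) * cluster_r,
                        target_rbc - counts[["RBC"]])
        ctr <- rand_center(r + interior_margin)
        n_new <- paint(ctr, rep(r, 3), code_of[["RBC"]])
        counts[["RBC"]] <- counts[["RBC"]] + n_new
        if (n_new > 0) rbc_centers <- rbind(rbc_centers, ctr)
      }
    }
  }

  # --- loose/compact fibrin-platelet split over the remainder --------------
  rem_idx <- which(avail)
  n_rem <- length(rem_idx)
  need_l <- if ("LFP" %in% cls) max(0L, targets[["LFP"]] - counts[["LFP"]]) else 0L
  need_l <- min(need_l, n_rem)
  if ("LFP" %in% cls || "CFP" %in% cls) {
    o <- order(tex[rem_idx])                       # low texture -> loose
    if (need_l > 0) labels[rem_idx[o[seq_len(need_l)]]] <- code_of[["LFP"]]
    if ("CFP" %in% cls && n_rem > need_l) {
      labels[rem_idx[o[(need_l + 1):n_rem]]] <- code_of[["CFP"]]
    }
    if ("LFP" %in% cls) counts[["LFP"]] <- sum(labels == code_of[["LFP"]])
    if ("CFP" %in% cls) counts[["CFP"]] <- sum(labels == code_of[["CFP"]])
  }

  # --- raw intensity synthesis --------------------------------------------
  mean_field <- array(0, d)
  for (ci in seq_len(K)) mean_field[labels == ci] <- spec$class_means[[ci]]
  mean_field[labels == tube_code] <- spec$tube_mean
  if (spec$edge_sigma > 0) mean_field <- gaussian_smooth3(mean_field, spec$edge_sigma)
  sd_field <- array(spec$air_sd, d)
  for (ci in seq_len(K)) sd_field[labels == ci] <- spec$class_sds[[ci]]
  sd_field[labels == tube_code] <- spec$tube_sd
  vol <- mean_field + rnorm(prod(d)) * sd_field

  realized <- tibble::tibble(
    class = cls,
    target_pct = as.numeric(spec$class_fractions),
    realized_pct = as.numeric(counts[cls]) / n_clot * 100,
    n_voxels = as.integer(counts[cls])
  )
  schema <- class_schema(cls)
  lab <- array(as.integer(labels), d)
  attr(lab, "tube_code") <- tube_code
  structure(
    list(
      volume = vh_volume(vol, vs, "raw",
                         provenance = list(generator = "clot_phantom", seed = spec$seed)),
      labels = vh_labels(lab, vs, schema),
      schema = schema,
      realized_fractions = realized,
      rbc_centers = rbc_centers,
      spec = spec
    ),
    class = "vh_phantom"
  )
}

# paint an ellipsoid with `code`, claiming voxels that are available OR carry
# `over_code` (used to let an aggregate core overwrite its own shell)
paint_over <- function(center, semi, code, over_code, X, Y, Z, vs, labels, avail, clot) {
  i <- which(X >= center[1] - semi[1] - vs & X <= center[1] + semi[1] + vs)
  j <- which(Y >= center[2] - semi[2] - vs & Y <= center[2] + semi[2] + vs)
  k <- which(Z >= center[3] - semi[3] - vs & Z <= center[3] + semi[3] + vs)
  if (!length(i) || !length(j) || !length(k)) {
    return(list(labels = labels, avail = avail, n = 0L))
  }
  ex <- ((X[i] - center[1]) / semi[1])^2
  ey <- ((Y[j] - center[2]) / semi[2])^2
  ez <- ((Z[k] - center[3]) / semi[3])^2
  inside <- outer(outer(ex, ey, "+"), ez, "+") <= 1
  lab_sub <- labels[i, j, k]
  av_sub <- avail[i, j, k]
  cl_sub <- clot[i, j, k]
  sel <- inside & cl_sub & (av_sub | lab_sub == over_code) & lab_sub != code
  n_new <- sum(sel)
  if (n_new > 0) {
    lab_sub[sel] <- code; av_sub[sel] <- FALSE
    labels[i, j, k] <- lab_sub; avail[i, j, k] <- av_sub
  }
  list(labels = labels, avail = avail, n = n_new)
}

#' @export
print.vh_phantom <- function(x, ...) {
  cat("<vh_phantom>\n")
  print(x$volume)
  cat("realized class fractions (%):\n")
  print(as.data.frame(x$realized_fractions), row.names = FALSE)
  invisible(x)
}

#' Generate a fine-voxel phantom of seeded red blood cells
#'
#' A flat fibrin/platelet background with `n_cells` bright, mildly oblate RBC
#' ellipsoids (diameters drawn from `diameter_range`) at non-overlapping random
#' positions, plus Gaussian noise.  Used to exercise and regression-test the
#' multiscale Frangi blob detector at the voxel size where single cells are
#' resolvable.
#'
#' @param n_cells number of cells to seed (0 gives a pure-noise volume).
#' @param grid_shape voxels per axis.
#' @param voxel_size um (default 1.23, a typical effective microCT voxel).
#' @param diameter_range cell diameter range in um (default 4-7).
#' @param oblateness ratio of the short (z) to long semi-axes.
#' @param background,cell_intensity,noise_sd calibrated-scale intensities.
#' @param seed RNG seed.
#'
#' @return list of class `vh_rbc_phantom`: `volume` (calibrated [vh_volume()]),
#'   `cells` (tibble: centre voxel coordinates, diameter um), `mask` (all-TRUE
#'   interior mask).
#' @export
generate_rbc_phantom <- function(n_cells = 50, grid_shape = c(96L, 96L, 96L),
                                 voxel_size = 1.23, diameter_range = c(4, 7),
                                 oblateness = 0.75,
                                 background = 1400, cell_intensity = 1925,
                                 noise_sd = 40, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  set.seed(seed)
  d <- as.integer(grid_shape)
  vol <- array(background, d)
  cells <- NULL
  if (n_cells > 0) {
    max_r_vox <- diameter_range[2] / 2 / voxel_size
    margin <- ceiling(max_r_vox) + 2
    placed <- matrix(numeric(0), ncol = 4)  # x, y, z (voxels), radius (voxels)
    tries <- 0
    while (nrow(placed) < n_cells && tries < 20000) {
      tries <- tries + 1
      dd <- runif(1, diameter_range[1], diameter_range[2])
      r_vox <- dd / 2 / voxel_size
      ctr <- runif(3, margin + 1, d - margin)
      if (nrow(placed) > 0) {
        sep <- sqrt(colSums((t(placed[, 1:3, drop = FALSE]) - ctr)^2))
        if (any(sep < (placed[, 4] + r_vox + 6))) next
      }
      placed <- rbind(placed, c(ctr, r_vox))
    }
    if (nrow(placed) < n_cells) {
      stop("could not place all cells without overlap; reduce n_cells or enlarge grid",
           call. = FALSE)
    }
    for (m in seq_len(nrow(placed))) {
      ctr <- placed[m, 1:3]; r <- placed[m, 4]
      semi <- c(r, r, oblateness * r)
      i <- max(1, floor(ctr[1] - semi[1] - 1)):min(d[1], ceiling(ctr[1] + semi[1] + 1))
      j <- max(1, floor(ctr[2] - semi[2] - 1)):min(d[2], ceiling(ctr[2] + semi[2] + 1))
      k <- max(1, floor(ctr[3] - semi[3] - 1)):min(d[3], ceiling(ctr[3] + semi[3] + 1))
      e <- outer(outer(((i - ctr[1]) / semi[1])^2, ((j - ctr[2]) / semi[2])^2, "+"),
                 ((k - ctr[3]) / semi[3])^2, "+")
      sub <- vol[i, j, k]
      # soft partial-volume edge over ~half a voxel
      w <- pmin(1, pmax(0, (1.15 - sqrt(e)) / 0.3))
      sub <- sub + (cell_intensity - background) * w
      vol[i, j, k] <- pmin(sub, cell_intensity + 0)
    }
    cells <- tibble::tibble(
      x = placed[, 1], y = placed[, 2], z = placed[, 3],
      diameter_um = placed[, 4] * 2 * voxel_size
    )
  } else {
    cells <- tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                            diameter_um = numeric(0))
  }
  vol <- vol + rnorm(prod(d), sd = noise_sd)
  structure(
    list(volume = vh_volume(vol, voxel_size, "calibrated",
                            provenance = list(generator = "rbc_phantom", seed = seed)),
         cells = cells,
         mask = array(TRUE, d)),
    class = "vh_rbc_phantom"
  )
}
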