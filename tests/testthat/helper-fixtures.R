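# Shared fixtures, built lazily and cached for the whole test run.

# A small (96^3) clot phantom with the default class mix.
small_clot_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_clot_phantom(
        phantom_spec(grid_shape = c(96L, 96L, 96L), voxel_size = 21.4, seed = 101)
      )
    }
    cache
  }
})

# A uniform-disk volume (a few z-slices) with known attenuation, for
# projection and FBP oracles.  Disk radius in voxels, value per um.
disk_volume <- function(n = 64L, radius = 20, mu = 0.002, voxel = 10, nz = 3L) {
  xs <- seq_len(n) - (n + 1) / 2
  r2 <- outer(xs^2, xs^2, "+")
  a <- array(0, c(n, n, nz))
  for (k in seq_len(nz)) a[, , k] <- mu * (r2 <= radius^2)
  vh_volume(a, voxel, "raw")
}

# A smooth multi-blob volume whose projections have no sharp edges; used for
# the propagation/retrieval filter-pair checks where clamping must not occur.
smooth_volume <- function(n = 64L, nz = 4L, voxel = 10) {
  xs <- seq_len(n) - (n + 1) / 2
  sl <- 0.001 * exp(-outer(xs^2, xs^2, "+") / (2 * 64)) +
    0.0005 * exp(-outer((xs - 10)^2, (xs + 8)^2, "+") / (2 * 36))
  a <- array(0, c(n, n, nz))
  for (k in seq_len(nz)) a[, , k] <- sl
  vh_volume(a, voxel, "raw")
}

# Euclidean matching of detected blob centroids to seeded cell centres.
match_blobs <- function(cells, blobs, tol = 2) {
  if (nrow(blobs) == 0) {
    return(list(recall = 0, precision = NA_real_))
  }
  s <- as.matrix(cells[, c("x", "y", "z")])
  b <- as.matrix(blobs[, c("x", "y", "z")])
  dmat <- sqrt(outer(s[, 1], b[, 1], "-")^2 +
               outer(s[, 2], b[, 2], "-")^2 +
               outer(s[, 3], b[, 3], "-")^2)
  list(recall = mean(apply(dmat, 1, min) <= tol),
       precision = mean(apply(dmat, 2, min) <= tol))
}

# Rasterise a digital ball of nominal diameter d (voxels) around a centre.
ball_voxels <- function(center, d_nominal) {
  r <- d_nominal / 2
  rng <- (-ceiling(r)):ceiling(r)
  offs <- expand.grid(x = rng, y = rng, z = rng)
  offs <- offs[offs$x^2 + offs$y^2 + offs$z^2 <= r^2 + 1e-9, ]
  cbind(center[1] + offs$x, center[2] + offs$y, center[3] + offs$z)
}
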