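test_that("class schema enforces ordering and mode rules", {
  sc <- class_schema()
  expect_equal(sc$class, c("P", "LFP", "CFP", "CA", "RBC"))
  expect_error(class_schema(c("P")), "at least 2")
  expect_error(class_schema(c("P", "FP", "LFP", "RBC")), "cannot be combined")
  expect_error(class_schema(c("P", "CA", "RBC")), "only permitted")
  sc4 <- class_schema(c("P", "FP", "CA", "RBC"))          # merged-fibrin mode
  expect_equal(sc4$class, c("P", "FP", "CA", "RBC"))
  expect_error(class_schema(c("P", "RBC"), thresholds = c(Inf)), "finite")
  expect_error(set_thresholds(class_schema(c("P", "LFP", "RBC")), c(900, 800)),
               "strictly increasing")
})

test_that("sample mask recovers the clot, excludes the tube, keeps pores", {
  n <- 64
  xs <- seq_len(n) - 32.5
  r2 <- outer(xs^2, xs^2, "+")
  a <- array(0, c(n, n, n))
  truth <- array(FALSE, c(n, n, n))
  set.seed(5)
  for (k in seq_len(n)) {
    ball <- r2 + (xs[k])^2 <= 22^2
    a[, , k] <- 1000 * ball + 1500 * (r2 >= 28^2 & r2 <= 31^2) + 10 * rnorm(n * n)
    truth[, , k] <- ball
  }
  # carve an internal pore (air-level) inside the ball
  pore_idx <- which(outer(outer((xs - 3)^2, (xs + 2)^2, "+"), xs^2, "+") <= 5^2)
  a[pore_idx] <- rnorm(length(pore_idx), 0, 10)
  v <- vh_volume(a, 10, "calibrated")
  mask <- extract_sample_mask(v)
  expect_equal(sum(mask) / sum(truth), 1, tolerance = 0.02)
  ring <- array(r2 >= 28^2 & r2 <= 31^2, dim(a))
  expect_equal(sum(mask & ring), 0)
  expect_true(all(mask[pore_idx]))             # pore belongs to the sample
  expect_error(extract_sample_mask(vh_volume(array(0, c(8, 8, 8)), 1, "calibrated")),
               "constant")
})

test_that("auto thresholds split a two-Gaussian mixture near the valley", {
  set.seed(31)
  x <- c(rnorm(6000, 800, 60), rnorm(6000, 1900, 60))
  v <- vh_volume(array(x, c(20, 30, 20)), 1, "calibrated")
  mask <- array(TRUE, c(20, 30, 20))
  thr_v <- auto_thresholds(v, mask, k = 2, method = "valley")
  expect_length(thr_v, 1)
  expect_gt(thr_v, 1100)
  expect_lt(thr_v, 1600)
  # the Otsu objective is flat across the empty gap between the modes, so
  # assert the substantive property: the cut separates the two populations
  thr_o <- auto_thresholds(v, mask, k = 2, method = "otsu")
  expect_gt(thr_o, 980)
  expect_lt(thr_o, 1720)
  expect_equal(mean(x < thr_o), 0.5, tolerance = 0.01)
  expect_error(auto_thresholds(vh_volume(array(1, c(4, 4, 4)), 1, "calibrated"),
                               array(TRUE, c(4, 4, 4)), k = 2),
               "degenerate")
})

test_that("multi-level Otsu matches an exhaustive search oracle", {
  set.seed(32)
  x <- c(rnorm(2000, 10, 1), rnorm(3000, 20, 1.5), rnorm(1500, 32, 2))
  bins <- 64L
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  cnt <- tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = bins)
  p <- cnt / sum(cnt)
  mid <- (edges[-1] + edges[-(bins + 1)]) / 2
  score <- function(cut1, cut2) {
    groups <- list(1:cut1, (cut1 + 1):cut2, (cut2 + 1):bins)
    sum(vapply(groups, function(g) {
      w <- sum(p[g]); if (w == 0) 0 else sum(p[g] * mid[g])^2 / w
    }, numeric(1)))
  }
  best <- -Inf; best_cuts <- c(NA, NA)
  for (c1 in 1:(bins - 2)) for (c2 in (c1 + 1):(bins - 1)) {
    s <- score(c1, c2)
    if (s > best) { best <- s; best_cuts <- c(c1, c2) }
  }
  oracle <- edges[best_cuts + 1]
  dp <- clotvh:::auto_thresholds_values(x, k = 3, bins = bins)
  expect_equal(dp, oracle, tolerance = 1e-12)
})

test_that("thresholds come back strictly ascending on the phantom", {
  ph <- small_clot_phantom()
  v <- vh_volume(ph$volume$data * 1e6, ph$volume$voxel_size, "calibrated")
  lab <- ph$labels$labels
  mask <- array(lab >= 1 & lab <= 5, dim(lab))
  thr <- auto_thresholds(v, mask, k = 4)
  expect_length(thr, 3)
  expect_true(all(diff(thr) > 0))
})

test_that("ordered segmentation matches an exhaustive per-voxel oracle", {
  set.seed(33)
  d <- c(12L, 12L, 12L)
  v <- vh_volume(array(runif(prod(d), 0, 2000), d), 5, "calibrated")
  mask <- array(runif(prod(d)) > 0.2, d)
  schema <- class_schema(c("P", "LFP", "CFP", "RBC"),
                         thresholds = c(600, 1200, 1700))
  labels <- segment_composition(v, mask, schema)
  thr <- c(600, 1200, 1700)
  oracle <- array(0L, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!mask[i, j, k]) next
    val <- v$data[i, j, k]
    cls <- 1L
    for (t in seq_along(thr)) if (val >= thr[t]) cls <- t + 1L
    oracle[i, j, k] <- cls
  }
  expect_identical(labels$labels, oracle)
})

test_that("a voxel exactly on a threshold goes to the upper class", {
  v <- vh_volume(array(c(599.9999, 600, 600.0001, 100, 1200, 9),
                       c(3, 2, 1)), 1, "calibrated")
  mask <- array(TRUE, c(3, 2, 1))
  schema <- class_schema(c("P", "LFP", "RBC"), thresholds = c(600, 1200))
  lab <- segment_composition(v, mask, schema)$labels
  expect_equal(as.integer(lab), c(1L, 2L, 2L, 1L, 3L, 1L))
})

test_that("composition quantification is exact arithmetic", {
  d <- c(10L, 10L, 1L)
  lab_arr <- array(0L, d)
  lab_arr[1:50] <- 1L; lab_arr[51:80] <- 2L; lab_arr[81:100] <- 3L
  set.seed(34)
  vals <- array(rnorm(prod(d), 1000, 100), d)
  schema <- class_schema(c("P", "LFP", "RBC"), thresholds = c(500, 1500))
  labels <- vh_labels(lab_arr, 2, schema)
  rep <- quantify_composition(labels, vh_volume(vals, 2, "calibrated"))
  expect_equal(rep$vol_pct, c(50, 30, 20))
  expect_equal(rep$mean_intensity[2], mean(vals[51:80]))
  expect_equal(sum(rep$vol_pct), 100, tolerance = 1e-10)
  expect_equal(attr(rep, "total_volume_um3"), 100 * 8)
  # empty class reports 0% and NA intensity
  lab_arr2 <- lab_arr; lab_arr2[lab_arr2 == 3L] <- 2L
  rep2 <- quantify_composition(vh_labels(lab_arr2, 2, schema),
                               vh_volume(vals, 2, "calibrated"))
  expect_equal(rep2$vol_pct[3], 0)
  expect_true(is.na(rep2$mean_intensity[3]))
})

test_that("segmentation partitions the mask exactly", {
  ph <- small_clot_phantom()
  v <- vh_volume(ph$volume$data * 1e6 + 500, ph$volume$voxel_size, "calibrated")
  mask <- array(ph$labels$labels >= 1 & ph$labels$labels <= 5, dim(v$data))
  schema <- set_thresholds(ph$schema, c(650, 1050, 1350, 1600))
  labels <- segment_composition(v, mask, schema)
  rep <- quantify_composition(labels, v)
  expect_identical(sum(rep$n_voxels), sum(mask))
  expect_equal(sum(rep$vol_pct), 100, tolerance = 1e-9)
})

test_that("pore sizing applies the two-voxel floor and closed-form diameters", {
  d <- c(24L, 24L, 24L)
  lab_arr <- array(0L, d)
  lab_arr[2:23, 2:23, 2:23] <- 2L                       # fibrin matrix
  schema <- class_schema(c("P", "CFP"), thresholds = c(700))
  p_code <- 1L
  balls <- list(ball_voxels(c(6, 6, 6), 1),             # nominal diameter 1
                ball_voxels(c(14, 6, 6), 2),            # nominal diameter 2
                ball_voxels(c(6, 16, 16), 3))           # nominal diameter 3
  for (b in balls) lab_arr[b] <- p_code
  labels <- vh_labels(lab_arr, 4, schema)
  rep <- quantify_porosity(labels, min_diameter = 2)
  expect_equal(nrow(rep), 3)
  expect_equal(sum(rep$retained), 2)
  discarded <- rep[!rep$retained, ]
  expect_equal(discarded$n_voxels, 1)                   # the nominal-1 pore
  expect_true(all(rep$diameter_vox[rep$retained] >= 2))
  # smallest retained pore is the nominal-diameter-2 ball (7 voxels)
  expect_equal(min(rep$n_voxels[rep$retained]), 7)
  expect_equal(min(rep$diameter_vox[rep$retained]), (6 * 7 / pi)^(1 / 3))
})

test_that("a cubic pore has the closed-form equivalent diameter", {
  d <- c(12L, 12L, 12L)
  lab_arr <- array(2L, d)
  lab_arr[5:7, 5:7, 5:7] <- 1L
  schema <- class_schema(c("P", "CFP"), thresholds = c(700))
  rep <- quantify_porosity(vh_labels(lab_arr, 3, schema))
  expect_equal(rep$diameter_vox, (6 * 27 / pi)^(1 / 3), tolerance = 1e-12)
  expect_equal(rep$diameter_um, 3 * (6 * 27 / pi)^(1 / 3), tolerance = 1e-12)
})

test_that("porosity reports zero cleanly when no pores exist", {
  lab_arr <- array(2L, c(6, 6, 6))
  schema <- class_schema(c("P", "CFP"), thresholds = c(700))
  rep <- quantify_porosity(vh_labels(lab_arr, 1, schema))
  expect_equal(nrow(rep), 0)
  expect_equal(attr(rep, "retained_porosity_pct"), 0)
  schema2 <- class_schema(c("LFP", "CFP"), thresholds = c(1200))
  expect_error(quantify_porosity(vh_labels(lab_arr, 1, schema2)), "no porosity")
})
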