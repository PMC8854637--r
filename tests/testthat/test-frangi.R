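test_that("Hessian eigenvalues vanish on a constant volume", {
  e <- hessian_eigen(array(7, c(16, 16, 16)), sigma = 1)
  expect_lt(max(abs(e$l1), abs(e$l2), abs(e$l3)), 1e-10)
  expect_error(hessian_eigen(array(0, c(8, 8, 8)), sigma = 4), "too large")
})

test_that("a matched bright Gaussian blob has three equal negative eigenvalues", {
  # analytic: blob sd s_b smoothed at sigma gives, gamma-normalized,
  # lambda_i = -sigma^2 * (s_b^2/(s_b^2+sigma^2))^(3/2) / (s_b^2+sigma^2)
  d <- c(33L, 33L, 33L)
  xs <- seq_len(33) - 17
  blob <- exp(-outer(outer(xs^2, xs^2, "+"), xs^2, "+") / (2 * 4))
  e <- hessian_eigen(blob, sigma = 2)
  ctr <- c(17, 17, 17)
  analytic <- -4 * (4 / 8)^(3 / 2) / 8
  for (l in list(e$l1, e$l2, e$l3)) {
    expect_equal(l[17, 17, 17], analytic, tolerance = 0.02)
    expect_lt(l[17, 17, 17], 0)
  }
})

test_that("a bright filament along z has one near-zero and two negative eigenvalues", {
  d <- c(33L, 33L, 33L)
  fil <- array(0, d); fil[17, 17, ] <- 1
  fil <- clotvh:::gaussian_smooth3(fil, 1.5)
  e <- hessian_eigen(fil, sigma = 2)
  expect_lt(abs(e$l1[17, 17, 17]), 1e-4)
  expect_lt(e$l3[17, 17, 17], 0)
  expect_equal(e$l2[17, 17, 17], e$l3[17, 17, 17], tolerance = 1e-6)
})

test_that("the Frangi response gates polarity and uniform fields", {
  d <- c(25L, 25L, 25L)
  xs <- seq_len(25) - 13
  blob <- exp(-outer(outer(xs^2, xs^2, "+"), xs^2, "+") / (2 * 4))
  # dark blob under bright polarity -> 0 at the centre
  e_dark <- hessian_eigen(1 - blob, sigma = 2)
  v_dark <- frangi_response(e_dark, frangi_params())
  expect_equal(v_dark[13, 13, 13], 0)
  # uniform field -> 0 everywhere (c must be supplied; S = 0)
  e_flat <- hessian_eigen(array(1, d), sigma = 2)
  v_flat <- frangi_response(e_flat, frangi_params(c = 1))
  expect_equal(max(v_flat), 0)
  # bright blob -> bounded positive response peaking at the centre
  e_b <- hessian_eigen(blob, sigma = 2)
  v_b <- frangi_response(e_b, frangi_params())
  expect_true(all(v_b >= 0 & v_b <= 1))
  expect_gt(v_b[13, 13, 13], 0.5)
})

test_that("the global response maximum sits at a seeded bright sphere", {
  d <- c(32L, 32L, 32L)
  xs_list <- lapply(1:3, function(i) seq_len(32))
  a <- array(0, d)
  ctr <- c(20, 14, 17)
  for (k in seq_len(32)) {
    a[, , k] <- 1000 + 900 * (outer((seq_len(32) - ctr[1])^2,
                                    (seq_len(32) - ctr[2])^2, "+") +
                              (k - ctr[3])^2 <= 9)
  }
  v <- vh_volume(a, 1.23, "calibrated")
  det <- multiscale_detect(v, params = frangi_params())
  peak <- arrayInd(which.max(det$response), d)
  expect_lte(sqrt(sum((peak - ctr)^2)), 1)
})

test_that("response is invariant to adding a constant to the volume", {
  ph <- generate_rbc_phantom(n_cells = 6, grid_shape = c(40L, 40L, 40L), seed = 12)
  det1 <- multiscale_detect(ph$volume, params = frangi_params())
  v2 <- vh_volume(ph$volume$data + 250, ph$volume$voxel_size, "calibrated")
  det2 <- multiscale_detect(v2, params = frangi_params())
  expect_equal(det1$response, det2$response, tolerance = 1e-8)
})

test_that("max over scales dominates each single-scale response", {
  ph <- generate_rbc_phantom(n_cells = 6, grid_shape = c(40L, 40L, 40L), seed = 13)
  multi <- multiscale_detect(ph$volume, params = frangi_params(noise_fraction = 0.001))
  single <- multiscale_detect(ph$volume,
                              params = frangi_params(scales = 2, c = multi$c_used[2],
                                                     noise_fraction = 0.001),
                              threshold = multi$threshold_used)
  on <- multi$response > 0 & single$response > 0
  expect_true(all(multi$response[on] >= single$response[on] - 1e-12))
})

test_that("a single-scale run reports that scale for every blob voxel", {
  ph <- generate_rbc_phantom(n_cells = 6, grid_shape = c(40L, 40L, 40L), seed = 14)
  det <- multiscale_detect(ph$volume, params = frangi_params(scales = 1))
  expect_true(all(det$scale[det$response > 0] == 1))
})

test_that("seeded cells are detected with high recall and precision", {
  ph <- generate_rbc_phantom(n_cells = 50, seed = 5)
  det <- multiscale_detect(ph$volume, params = frangi_params())
  m <- match_blobs(ph$cells, det$blobs)
  expect_gte(m$recall, 0.9)
  expect_gte(m$precision, 0.8)
  expect_gt(sum(det$blobs$single_cell), 0)
})

test_that("the calibrated detector stays quiet on a cell-free volume", {
  ph <- generate_rbc_phantom(n_cells = 50, seed = 5)
  det <- multiscale_detect(ph$volume, params = frangi_params())
  params0 <- frangi_params()
  params0$c <- det$c_used
  ph0 <- generate_rbc_phantom(n_cells = 0, seed = 6)
  det0 <- multiscale_detect(ph0$volume, params = params0,
                            threshold = det$threshold_used)
  expect_lte(nrow(det0$blobs), 0.05 * nrow(det$blobs))
})
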