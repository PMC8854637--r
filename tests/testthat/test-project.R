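test_that("central ray through a uniform disk matches the analytic chord", {
  vol <- disk_volume(n = 64, radius = 20, mu = 0.002, voxel = 10)
  st <- forward_project(vol, vh_geometry(n_angles = 8))
  # detector is centred between elements 32 and 33 for even n
  central <- st$images[32:33, 2, 1]
  analytic <- 2 * 20 * 10 * 0.002
  expect_true(all(abs(central / analytic - 1) < 0.01))
})

test_that("all-zero volumes project to all-zero stacks and empty ones error", {
  vol <- vh_volume(array(0, c(16, 16, 2)), 5, "raw")
  st <- forward_project(vol, vh_geometry(n_angles = 4))
  expect_equal(max(abs(st$images)), 0)
  expect_error(forward_project(vh_volume(array(0, c(0, 0, 0)), 5, "raw")),
               "empty")
})

test_that("parallel-beam projections mirror between theta and theta + 180", {
  vol <- disk_volume(n = 32, radius = 9, mu = 0.001, voxel = 8, nz = 2)
  vol$data[10:14, 5:9, ] <- 0.003     # break symmetry of the object
  st <- forward_project(vol, vh_geometry(n_angles = 8, angular_range = 360))
  p0 <- st$images[, 1, 1]
  p180 <- st$images[, 1, 5]           # angle index 5 is theta + 180
  expect_equal(p0, rev(p180), tolerance = 1e-10)
})

test_that("the Radon transform is linear", {
  set.seed(11)
  a1 <- array(runif(16 * 16 * 2), c(16, 16, 2))
  a2 <- array(runif(16 * 16 * 2), c(16, 16, 2))
  g <- vh_geometry(n_angles = 6)
  p1 <- forward_project(vh_volume(a1, 5, "raw"), g)$images
  p2 <- forward_project(vh_volume(a2, 5, "raw"), g)$images
  p12 <- forward_project(vh_volume(2 * a1 + 3 * a2, 5, "raw"), g)$images
  expect_equal(p12, 2 * p1 + 3 * p2, tolerance = 1e-10)
})

test_that("propagation with alpha 0 and no noise is the exp transform only", {
  vol <- smooth_volume()
  st <- forward_project(vol, vh_geometry(n_angles = 6))
  out <- apply_propagation_and_noise(st, alpha = 0, noise = FALSE)
  expect_equal(out$images, exp(-st$images), tolerance = 1e-12)
  expect_equal(out$kind, "intensity")
})

test_that("the propagation filter preserves each projection's mean", {
  vol <- smooth_volume()
  st <- forward_project(vol, vh_geometry(n_angles = 6))
  alpha <- alpha_from_cutoff(0.16)
  out <- apply_propagation_and_noise(st, alpha = alpha, noise = FALSE)
  m0 <- apply(exp(-st$images), 3, mean)
  m1 <- apply(out$images, 3, mean)
  expect_true(all(abs(m1 / m0 - 1) < 1e-3))
})

test_that("propagate-then-retrieve with matched alpha recovers projections", {
  vol <- smooth_volume()
  st <- forward_project(vol, vh_geometry(n_angles = 6))
  cfg <- paganin_config(0.16)
  prop <- apply_propagation_and_noise(st, alpha = cfg$alpha, noise = FALSE)
  ret <- paganin_retrieve(prop, cfg)
  rel_rms <- sqrt(mean((ret$images - st$images)^2)) / sqrt(mean(st$images^2))
  expect_lt(rel_rms, 0.01)
})

test_that("propagation rejects invalid noise settings and is seed-stable", {
  vol <- smooth_volume()
  st <- forward_project(vol, vh_geometry(n_angles = 4))
  expect_error(apply_propagation_and_noise(st, alpha = 1, photon_count = -5),
               "photon_count")
  expect_error(apply_propagation_and_noise(st, alpha = -1), "alpha")
  n1 <- apply_propagation_and_noise(st, alpha = 0, photon_count = 1e3, seed = 9)
  n2 <- apply_propagation_and_noise(st, alpha = 0, photon_count = 1e3, seed = 9)
  expect_identical(n1$images, n2$images)
  expect_true(all(n1$images > 0))
})
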