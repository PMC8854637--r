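test_that("alpha_from_cutoff solves the -6 dB condition in closed form", {
  # 1/(1 + alpha f_c^2) = 10^(-6/20) at f_c = fraction * 0.5 cycles/pixel
  expect_equal(alpha_from_cutoff(0.16), (10^0.3 - 1) / 0.08^2, tolerance = 1e-12)
  expect_equal(alpha_from_cutoff(0.16), 155.51, tolerance = 1e-4)
  expect_equal(alpha_from_cutoff(1.0), (10^0.3 - 1) / 0.25, tolerance = 1e-12)
  expect_equal(alpha_from_cutoff(1.0), 3.981, tolerance = 1e-4)
  # the filter tends to the identity as the cutoff moves out
  expect_lt(alpha_from_cutoff(100), 1e-3)
  expect_error(alpha_from_cutoff(0), "positive")
})

test_that("the retrieval filter response is 1 at DC and strictly decreasing", {
  cfg <- paganin_config(0.16)
  f <- seq(0, 0.5, length.out = 101)
  H <- paganin_response(f, cfg)
  expect_equal(H[1], 1)
  expect_true(all(diff(H) < 0))
})

test_that("a constant projection retrieves to -log of the constant", {
  cfg <- paganin_config(0.16)
  out <- paganin_retrieve(matrix(0.37, 32, 32), cfg)
  expect_equal(out, matrix(-log(0.37), 32, 32), tolerance = 1e-10)
  expect_error(paganin_retrieve(matrix(c(0.5, -0.1, 0.5, 0.5), 2, 2), cfg),
               "positive")
})

test_that("the measured amplitude response crosses -6 dB at the configured cutoff", {
  cfg <- paganin_config(0.16)
  # response at exactly f_c, measured through the public retrieval path
  n <- 250L                                  # f_c = 0.08 cyc/px = 20 cycles
  cfg_np <- paganin_config(0.16, pad = FALSE)
  xs <- seq_len(n)
  a <- 1e-5
  probe <- 1 + a * matrix(sin(2 * pi * 0.08 * xs), n, n)
  ret <- paganin_retrieve(probe, cfg_np)
  s <- sin(2 * pi * 0.08 * xs)
  amp_out <- mean(apply(ret, 2, function(r) sum(r * s) / sum(s * s)))
  amp_ref <- mean(apply(-log(probe), 2, function(r) sum(r * s) / sum(s * s)))
  expect_equal(amp_out / amp_ref, 10^(-6 / 20), tolerance = 1e-6)
  # and the numerically solved crossing frequency
  expect_equal(measure_cutoff_fraction(cfg), 0.16, tolerance = 1e-3)
})

test_that("retrieval reduces the variance of white noise", {
  cfg <- paganin_config(0.16)
  set.seed(21)
  p <- 0.01 * matrix(rnorm(96 * 96), 96)
  ret <- paganin_retrieve(exp(-p - 0.5), cfg)
  expect_lt(var(as.numeric(ret)), var(as.numeric(p)))
})

test_that("FBP reconstructs a uniform disk within 2% inside and clean air", {
  vol <- disk_volume(n = 64, radius = 20, mu = 0.002, voxel = 10)
  st <- forward_project(vol, vh_geometry(n_angles = 180))
  rec <- fbp_reconstruct(st)
  xs <- seq_len(64) - 32.5
  r2 <- outer(xs^2, xs^2, "+")
  sl <- rec$data[, , 2]
  expect_equal(mean(sl[r2 <= 15^2]) / 0.002, 1, tolerance = 0.02)
  air_ring <- r2 >= 26^2 & r2 <= 31^2
  expect_lt(abs(mean(sl[air_ring])) / 0.002, 0.02)
})

test_that("FBP is linear and maps zero to zero", {
  vol <- disk_volume(n = 32, radius = 9, mu = 0.001, voxel = 8, nz = 2)
  st <- forward_project(vol, vh_geometry(n_angles = 48))
  rec1 <- fbp_reconstruct(st)
  st3 <- st; st3$images <- 3 * st$images
  rec3 <- fbp_reconstruct(st3)
  expect_equal(rec3$data, 3 * rec1$data, tolerance = 1e-10)
  st0 <- st; st0$images[] <- 0
  expect_equal(max(abs(fbp_reconstruct(st0)$data)), 0)
})

test_that("a short angular scan warns but still reconstructs", {
  vol <- disk_volume(n = 32, radius = 9, mu = 0.001, voxel = 8, nz = 2)
  st <- forward_project(vol, vh_geometry(n_angles = 16, angular_range = 90))
  expect_warning(rec <- fbp_reconstruct(st), "angular range")
  expect_true(rec$provenance$short_scan)
})

test_that("end-to-end simulation preserves the per-class mean ordering", {
  ph <- small_clot_phantom()
  cfg <- paganin_config(0.16)
  st <- forward_project(ph$volume)
  st <- apply_propagation_and_noise(st, alpha = cfg$alpha, photon_count = 1e5,
                                    seed = 55)
  rec <- fbp_reconstruct(paganin_retrieve(st, cfg))
  lab <- ph$labels$labels
  means <- vapply(seq_len(nrow(ph$schema)), function(ci) mean(rec$data[lab == ci]),
                  numeric(1))
  expect_true(all(diff(means) > 0))
})
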