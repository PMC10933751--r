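# Simulation framework: phantom, coil maps, phase model, k-space synthesis,
# noise calibration.

test_that("phantom is deterministic with unit max magnitude and interior support", {
  ph <- make_phantom(48, 48)
  expect_equal(max(Mod(ph)), 1)
  expect_true(all(Im(ph) == 0))                     # zero baseline phase
  expect_identical(ph, make_phantom(48, 48))
  supp <- attr(ph, "support")
  expect_false(any(supp[1, ]) || any(supp[, 1]))    # strictly inside grid
  ph2 <- make_phantom(48, 48, baseline_phase = c(0.1, 0.3, -0.2, 0.1))
  expect_equal(Mod(ph2), Mod(ph), tolerance = 1e-12)
  expect_gt(max(abs(Arg(ph2[supp]))), 0.05)
  blobs <- make_phantom(40, 40, structure = "smooth_blobs", seed = 7)
  expect_equal(max(Mod(blobs)), 1)
  expect_identical(blobs, make_phantom(40, 40, structure = "smooth_blobs",
                                       seed = 7))
})

test_that("coil maps are smooth, deterministic, and RSS-normalized", {
  maps <- make_coil_maps(8, c(48, 48), seed = 3)
  rss <- sqrt(rowSums(Mod(maps)^2, dims = 2))
  supp <- attr(fixture_phantom(), "support")
  expect_true(all(rss[supp] > 0.99 & rss[supp] <= 1 + 1e-12))
  expect_true(all(rss <= 1 + 1e-12))
  expect_identical(maps, make_coil_maps(8, c(48, 48), seed = 3))
  one <- make_coil_maps(1, c(16, 16))
  expect_equal(Mod(one[, , 1]), matrix(1, 16, 16), tolerance = 1e-12)
  expect_error(make_coil_maps(0, c(8, 8)), "positive integer")
})

test_that("phase maps live exactly in the 6-map second-order basis", {
  grid <- c(32, 32)
  zero <- phase_model(amplitudes = rep(0, 6))
  expect_true(all(phase_map_at(2.3, zero, grid) == 0))
  # constant-term-only model: spatially uniform a * trace(t)
  m1 <- phase_model(amplitudes = c(0.7, 0, 0, 0, 0, 0), drift = 0)
  pm <- phase_map_at(1.1, m1, grid)
  expect_equal(max(pm) - min(pm), 0)
  expect_equal(pm[1, 1], 0.7 * sin(2 * pi * 0.25 * 1.1), tolerance = 1e-12)
  # least-squares refit onto the basis reproduces any model map exactly
  mod <- phase_model(jitter_sd = 0.1)
  map <- phase_map_at(3.7, mod, grid)
  B <- harmonic_basis(grid)
  A <- matrix(B, prod(grid), 6)
  coef <- qr.solve(A, as.vector(map))
  expect_lt(max(abs(as.vector(map) - A %*% coef)), 1e-10)
})

test_that("noiseless zero-phase full sampling reproduces the phantom", {
  ph <- fixture_phantom(); maps <- fixture_maps()
  sched <- fixture_schedule_g2()
  sim <- simulate_timeseries(ph, maps, sched, phase_model(amplitudes = rep(0, 6)),
                             noise_spec(0), 1)
  v <- sim$volumes[[1]]
  ksum <- v$kspace[, , , 1] + v$kspace[, , , 2]
  rec <- ifft2c(coil_combine_kspace(ksum, maps))
  relerr <- sqrt(sum(Mod(rec - ph)^2) / sum(Mod(ph)^2))
  expect_lt(relerr, 1e-8)
})

test_that("reference pairing uses identical noise draws", {
  ph <- fixture_phantom(); maps <- fixture_maps(4)
  sched <- fixture_schedule_g2()
  ns <- noise_spec(0.01, seed = 5)
  a <- simulate_timeseries(ph, maps, sched, phase_model(amplitudes = rep(0, 6)),
                           ns, 2)
  b <- simulate_timeseries(ph, maps, sched, phase_model(), ns, 2,
                           reference = TRUE)
  expect_identical(a$volumes[[2]]$kspace, b$volumes[[2]]$kspace)
  # corrupted series with the same seed differs only on acquired samples
  cc <- simulate_timeseries(ph, maps, sched, phase_model(), ns, 2)
  diffmask <- Mod(cc$volumes[[1]]$kspace - b$volumes[[1]]$kspace) > 0
  for (g in 1:2) for (cl in 1:4)
    expect_true(all(diffmask[, , cl, g] <= b$volumes[[1]]$masks[, , g]))
})

test_that("noise-only image SNR matches the closed-form prediction", {
  ph <- fixture_phantom(); maps <- fixture_maps(4)
  sched <- fixture_schedule_g2()
  target <- 40
  supp <- support_mask(Mod(ph))
  bg <- Mod(ph) < 0.01
  snrs <- sapply(1:20, function(s) {
    ns <- snr_calibrate(target, ph, seed = 100 + s)
    sim <- simulate_timeseries(ph, maps, sched,
                               phase_model(amplitudes = rep(0, 6)), ns, 1)
    v <- sim$volumes[[1]]
    img <- ifft2c(coil_combine_kspace(v$kspace[, , , 1] + v$kspace[, , , 2],
                                      maps))
    mean(Mod(img)[supp]) / sqrt(mean(Mod(img[bg])^2))
  })
  expect_lt(abs(mean(snrs) - target) / target, 0.05)
})

test_that("noise calibration is linear and supports the noiseless limit", {
  ph <- fixture_phantom()
  expect_equal(snr_calibrate(40, ph)$sd, 2 * snr_calibrate(80, ph)$sd,
               tolerance = 1e-12)
  expect_equal(snr_calibrate(Inf, ph)$sd, 0)
})

test_that("respiration causes kz ghosting in the conventional recon", {
  ph <- fixture_phantom(); maps <- fixture_maps(4)
  sched <- fixture_schedule_g2()
  bg <- Mod(ph) < 0.01
  energy <- function(model) {
    sim <- simulate_timeseries(ph, maps, sched, model, noise_spec(0), 1)
    v <- sim$volumes[[1]]
    img <- ifft2c(coil_combine_kspace(v$kspace[, , , 1] + v$kspace[, , , 2],
                                      maps))
    sum(Mod(img[bg])^2)
  }
  e_phase <- energy(phase_model(resp_phase = pi / 2))  # max phase spread
  e_zero <- energy(phase_model(amplitudes = rep(0, 6)))
  expect_gt(e_phase, 5 * max(e_zero, 1e-20))
})

test_that("within-group phase spread is small relative to across-volume spread", {
  # premise: shot TR well below the respiratory period makes shots of one
  # group temporally coherent.  3-shot groups, shot TR = 0.1 s, 4 s period.
  sched <- build_schedule(trajectory_config(12, 12, 3, 2, "seg_caipi",
                                            width = 4, dkz = 1))
  model <- phase_model(shot_TR = 0.1)
  grid <- c(12, 12)
  n_vol <- 30
  S <- sched$n_shots
  shot_maps <- function(v)
    lapply(seq_len(S) - 1, function(o)
      phase_map_at(((v - 1) * S + o) * model$shot_TR, model, grid))
  rms <- function(a, b) sqrt(mean((a - b)^2))
  max_pair <- function(maps_list) {
    mx <- 0
    for (i in seq_along(maps_list)) for (j in seq_len(i - 1))
      mx <- max(mx, rms(maps_list[[i]], maps_list[[j]]))
    mx
  }
  within <- 0
  vol_means <- list()
  for (v in seq_len(n_vol)) {
    sm <- shot_maps(v)
    for (g in unique(sched$shots$group)) {
      idx <- which(sched$shots$group == g)
      within <- max(within, max_pair(sm[idx]))
    }
    vol_means[[v]] <- Reduce(`+`, sm) / S
  }
  across <- max_pair(vol_means)
  expect_lt(within, 0.2 * across)
})

test_that("simulation errors on geometry mismatch", {
  expect_error(simulate_timeseries(make_phantom(32, 32), fixture_maps(2),
                                   fixture_schedule_g2(), phase_model(),
                                   noise_spec(0), 1),
               "does not match")
})
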