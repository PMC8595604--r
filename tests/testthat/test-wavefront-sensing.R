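test_that("the default segment grid tiles the pupil into 25 segments", {
  cfg <- cfg_small(192)
  seg <- segment_grid(cfg)
  expect_equal(nrow(seg), 25)
  # the four extreme corner tiles barely overlap the disk and are dropped
  expect_true(all(!seg$valid[seg$frac_inside < 0.25]))
  expect_gte(sum(seg$valid), 21)
  # tiles are disjoint and cover the disk
  masks <- lapply(seg$tile, function(t) besselao:::tile_mask(seg, t))
  total <- Reduce(`+`, masks)
  disk <- besselao:::pupil_disk_mask(cfg)
  expect_true(all(total[disk] == 1))
  expect_true(all(total[!disk] == 0))
})

test_that("segment images sit at the reference for a flat wavefront and shift together under tilt", {
  cfg <- cfg_small(192)
  sim0 <- simulate_segment_images(zero_wavefront(cfg), cfg,
                                  bead_diameter_um = 1)
  sh0 <- estimate_shifts(sim0)
  expect_true(all(abs(sh0$shift_x_um[sh0$valid]) < 1e-6))
  expect_true(all(abs(sh0$shift_y_um[sh0$valid]) < 1e-6))
  # global tilt displaces every beamlet by the same calibrated amount
  g <- besselao:::na_grids(cfg)
  waves_per_na <- 0.8 / cfg$na_objective
  simt <- simulate_segment_images(g$x * waves_per_na, cfg,
                                  bead_diameter_um = 1)
  sht <- estimate_shifts(simt)
  expected <- besselao:::shift_per_gradient(cfg) * waves_per_na
  expect_lt(max(abs(sht$shift_x_um[sht$valid] - expected)),
            0.15 * abs(expected))
  expect_lt(max(abs(sht$shift_y_um[sht$valid])), 0.1 * abs(expected))
})

test_that("shift localization is exact for integer shifts and sub-pixel accurate", {
  set.seed(3)
  n <- 96
  base <- matrix(0, n, n)
  xs <- (seq_len(n) - (n / 2 + 1))
  base <- exp(-(outer(xs^2, xs^2, "+")) / (2 * 4^2))
  shift_img <- function(img, dx) img[((seq_len(n) - 1 - dx) %% n) + 1, ]
  s <- besselao:::xcorr_shift(shift_img(base, 3), base)
  expect_equal(s[1], 3, tolerance = 1e-6)
  # half-pixel synthetic shift via Fourier translation
  sh <- c((n / 2 + 1):n, 1:(n / 2))
  f <- fft(base[sh, sh])
  ph <- exp(-2i * pi * 0.5 * (c(0:(n / 2 - 1), -(n / 2):-1)) / n)
  g <- Re(fft(f * matrix(ph, n, n), inverse = TRUE)) / n^2
  g <- g[sh, sh]
  s2 <- besselao:::xcorr_shift(g, base)
  expect_lt(abs(s2[1] - 0.5), 0.1)
  expect_lt(abs(s2[2]), 0.1)
})

test_that("blank tiles are flagged invalid and excluded", {
  cfg <- cfg_small(192)
  sim <- simulate_segment_images(zero_wavefront(cfg), cfg,
                                 bead_diameter_um = 1)
  sim$images[[13]] <- matrix(0, cfg$grid_n, cfg$grid_n) # centre tile blanked
  sh <- estimate_shifts(sim)
  expect_false(sh$valid[sh$tile == 13])
  expect_equal(sh$confidence[sh$tile == 13], 0)
})

test_that("tile shifts equal the analytic local wavefront gradient", {
  cfg <- cfg_small(192)
  seg <- segment_grid(cfg)
  w <- 1 * zernike_surface(2, 2, cfg)
  sim <- simulate_segment_images(w, cfg, bead_diameter_um = 1)
  sh <- estimate_shifts(sim)
  cal <- besselao:::shift_per_gradient(cfg)
  grads <- besselao:::tile_mode_gradients(seg, data.frame(n = 2, m = 2))
  ok <- sh$valid & seg$frac_inside > 0.9 # interior tiles: clean gradients
  expect_gt(sum(ok), 5)
  expect_lt(max(abs(sh$shift_x_um[ok] - cal * grads$gx[ok, 1])),
            0.15 * max(abs(cal * grads$gx[ok, 1])))
})

test_that("reconstruction recovers modal wavefronts and has the right null space", {
  cfg <- cfg_small(192)
  # zero shifts -> zero wavefront
  sim0 <- simulate_segment_images(zero_wavefront(cfg), cfg,
                                  bead_diameter_um = 1)
  rec0 <- reconstruct_wavefront(estimate_shifts(sim0))
  expect_lt(max(abs(rec0$coefficients$waves)), 1e-6)
  # 1 wave defocus + 0.5 wave astigmatism round trip within 5%
  w <- zernike_surface(2, 0, cfg) + 0.5 * zernike_surface(2, 2, cfg)
  rec <- reconstruct_wavefront(
    estimate_shifts(simulate_segment_images(w, cfg, bead_diameter_um = 1)))
  co <- rec$coefficients
  expect_lt(abs(co$waves[co$n == 2 & co$m == 0] - 1), 0.05)
  expect_lt(abs(co$waves[co$n == 2 & co$m == 2] - 0.5), 0.05 * 0.5)
  disk <- besselao:::pupil_disk_mask(cfg)
  expect_lt(sqrt(mean((rec$wavefront - w)[disk]^2)), 0.1) # < lambda/10
  # tip/tilt-only input reconstructs to (near) zero
  g <- besselao:::na_grids(cfg)
  wt <- 0.6 * g$x / cfg$na_objective + 0.3 * g$y / cfg$na_objective
  rect <- reconstruct_wavefront(
    estimate_shifts(simulate_segment_images(wt, cfg, bead_diameter_um = 1)))
  expect_lt(max(abs(rect$coefficients$waves)), 0.02)
})

test_that("reconstruction is linear in the shifts and degrades gracefully", {
  cfg <- cfg_small(192)
  w <- 0.7 * zernike_surface(3, 1, cfg)
  sh <- estimate_shifts(simulate_segment_images(w, cfg, bead_diameter_um = 1))
  rec1 <- reconstruct_wavefront(sh)
  sh2 <- sh
  sh2$shift_x_um <- 2 * sh2$shift_x_um
  sh2$shift_y_um <- 2 * sh2$shift_y_um
  attributes(sh2) <- attributes(sh)
  sh2$shift_x_um <- 2 * sh$shift_x_um
  sh2$shift_y_um <- 2 * sh$shift_y_um
  rec2 <- reconstruct_wavefront(sh2)
  expect_equal(rec2$coefficients$waves, 2 * rec1$coefficients$waves,
               tolerance = 1e-8)
  # asking for more modes than tiles support reduces the order, warning
  few <- sh[sh$tile %in% c(7, 8, 9, 12, 13, 14, 17), ]
  attr(few, "config") <- attr(sh, "config")
  attr(few, "segments") <- attr(sh, "segments")
  expect_warning(reconstruct_wavefront(few, n_max = 9), "reducing")
  expect_error(reconstruct_wavefront(few[1:2, ]), "at least 3")
})

test_that("Poisson noise at a realistic photon budget leaves reconstruction usable", {
  cfg <- cfg_small(192)
  w <- 0.8 * zernike_surface(2, -2, cfg)
  sim <- simulate_segment_images(w, cfg, bead_diameter_um = 1,
                                 photons = 1e5, seed = 21)
  rec <- reconstruct_wavefront(estimate_shifts(sim))
  co <- rec$coefficients
  expect_lt(abs(co$waves[co$n == 2 & co$m == -2] - 0.8), 0.08)
})
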