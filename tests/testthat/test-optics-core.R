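test_that("pupil grid covers the NA disk with the right area and energy", {
  cfg <- cfg_small()
  p <- make_pupil_grid(cfg)
  r_px <- cfg$grid_n / (2 * cfg$pupil_oversampling) # disk radius in pixels
  n_nonzero <- sum(Mod(p$values) > 0)
  expect_lt(abs(n_nonzero - pi * r_px^2) / (pi * r_px^2), 0.01)
  # unit amplitude inside: energy equals pixel count
  expect_equal(field_energy(p), n_nonzero)
  # heavy padding shrinks the disk: support stays centred and compact
  tiny <- optical_config(grid_n = 64, pupil_oversampling = 8)
  pt <- make_pupil_grid(tiny)
  idx <- which(Mod(pt$values) > 0, arr.ind = TRUE)
  expect_true(all(abs(idx - 33) <= 4 + 1e-9)) # disk radius = 4 px
  # under-sampled disk is refused
  expect_error(make_pupil_grid(optical_config(grid_n = 16,
                                              pupil_oversampling = 4)),
               "too small")
})

test_that("propagate is unitary and a double forward transform is a parity flip", {
  cfg <- cfg_small()
  p <- make_pupil_grid(cfg)
  set.seed(1)
  p$values <- p$values * exp(2i * pi * matrix(runif(cfg$grid_n^2),
                                              cfg$grid_n, cfg$grid_n))
  f <- propagate(p)
  expect_equal(field_energy(f), field_energy(p), tolerance = 1e-12)
  back <- propagate(f)
  expect_lt(max(Mod(back$values - p$values)), 1e-10)
  expect_identical(back$plane, "pupil")
  # forward twice = parity flip (index reversal about the centre)
  ff <- propagate(f, "pupil_to_focal")
  n <- cfg$grid_n
  # parity map: index i -> 2*(n/2+1) - i, wrapping modulo n
  idx <- ((n / 2 + 1) - (seq_len(n) - (n / 2 + 1))) %% n
  idx[idx == 0] <- n
  expect_lt(max(Mod(ff$values - p$values[idx, idx])), 1e-9)
})

test_that("a uniform disk pupil transforms to an Airy pattern", {
  cfg <- optical_config(grid_n = 512, pupil_oversampling = 8)
  f <- propagate(make_pupil_grid(cfg))
  n <- cfg$grid_n
  prof <- Mod(f$values[, n / 2 + 1])^2
  x <- (seq_len(n) - (n / 2 + 1)) * focal_pitch(cfg)
  right <- prof[(n / 2 + 1):n]
  i <- which(diff(right) > 0)[1] # first upturn after the peak
  # parabolic refinement of the minimum position
  ym <- right[i - 1]; y0 <- right[i]; yp <- right[i + 1]
  sub <- 0.5 * (ym - yp) / (ym - 2 * y0 + yp)
  r_zero <- x[n / 2 + i] + sub * focal_pitch(cfg)
  expect_lt(abs(r_zero - 0.61 * cfg$wavelength / cfg$na_objective) /
              (0.61 * cfg$wavelength / cfg$na_objective), 0.02)
})

test_that("Zernike surfaces follow the Born-Wolf convention and are orthogonal", {
  cfg <- cfg_mid()
  disk <- besselao:::pupil_disk_mask(cfg)
  piston <- zernike_surface(0, 0, cfg)
  expect_true(all(piston[disk] == 1))
  defocus <- zernike_surface(2, 0, cfg)
  centre <- cfg$grid_n / 2 + 1
  expect_equal(defocus[centre, centre], -1) # 2 rho^2 - 1 at rho = 0
  expect_error(zernike_surface(2, 1, cfg), "not a valid")
  # numerical-quadrature orthogonality between distinct modes
  z22 <- zernike_surface(2, 2, cfg)
  z31 <- zernike_surface(3, 1, cfg)
  inner <- sum(z22[disk] * z31[disk]) /
    sqrt(sum(z22[disk]^2) * sum(z31[disk]^2))
  expect_lt(abs(inner), 1e-3)
  # all leading modes mutually orthogonal at grid 256 under
  # quadrature-accurate (edge-coverage-weighted) disk integrals
  cover <- besselao:::disk_coverage(cfg)
  sel <- cover > 0
  X <- besselao:::zernike_design(cfg, 15, sel) * sqrt(cover[sel])
  G <- crossprod(X)
  offdiag <- abs(G[upper.tri(G)]) / sqrt(diag(G)[row(G)[upper.tri(G)]] *
                                           diag(G)[col(G)[upper.tri(G)]])
  expect_lt(max(offdiag), 1e-3)
})

test_that("fit_zernike recovers basis members exactly and round-trips random wavefronts", {
  cfg <- cfg_small()
  w <- zernike_surface(2, 2, cfg)
  fit <- fit_zernike(w, cfg, n_modes = 15)
  expect_equal(fit$coefficients$waves[fit$coefficients$n == 2 &
                                        fit$coefficients$m == 2], 1,
               tolerance = 1e-10)
  expect_lt(fit$residual_rms, 1e-10)
  expect_lt(max(abs(fit$coefficients$waves[!(fit$coefficients$n == 2 &
                                               fit$coefficients$m == 2)])),
            1e-10)
  # zero in, zero out
  fit0 <- fit_zernike(zero_wavefront(cfg), cfg, n_modes = 15)
  expect_true(all(fit0$coefficients$waves == 0))
  # 55-coefficient round trip
  set.seed(42)
  truth <- zernike_index_table(55)
  truth$waves <- rnorm(55, 0, 0.2)
  w55 <- zernike_reconstruct(truth, cfg)
  fit55 <- fit_zernike(w55, cfg, n_modes = 55)
  expect_lt(sqrt(mean((fit55$coefficients$waves - truth$waves)^2)), 1e-6)
  # idempotence: refitting the reconstruction changes nothing
  refit <- fit_zernike(zernike_reconstruct(fit55, cfg), cfg, 55)
  expect_equal(refit$coefficients$waves, fit55$coefficients$waves,
               tolerance = 1e-9)
  expect_error(fit_zernike(w, cfg, n_modes = 1e6), "fewer valid")
})

test_that("remove_modes zeroes exactly the listed modes", {
  coefs <- zernike_index_table(10)
  coefs$waves <- 0
  coefs$waves[coefs$label == "tip"] <- 0.5
  coefs$waves[coefs$label == "defocus"] <- 0.3
  coefs$waves[coefs$n == 2 & coefs$m == 2] <- 0.2
  out <- remove_modes(coefs)
  expect_equal(sum(out$waves != 0), 1)
  expect_equal(out$waves[out$n == 2 & out$m == 2], 0.2)
  # removing nothing is the identity; removing absent modes is a no-op
  expect_equal(remove_modes(coefs, character(0)), coefs)
  expect_equal(remove_modes(coefs, list(c(9, 9))), coefs)
  # pair syntax
  out2 <- remove_modes(coefs, list(c(1, 1), c(2, 0)))
  expect_equal(sum(out2$waves != 0), 1)
  # reconstruction of the edited set is orthogonal to the removed surfaces
  cfg <- cfg_small()
  disk <- besselao:::pupil_disk_mask(cfg)
  recon <- zernike_reconstruct(out, cfg)
  for (nm in list(c(1, 1), c(1, -1), c(2, 0))) {
    z <- zernike_surface(nm[1], nm[2], cfg)
    expect_lt(abs(sum(recon[disk] * z[disk])) / sum(z[disk]^2), 1e-8)
  }
})

test_that("mode ordering lists 55 modes through radial order 9", {
  tab <- zernike_index_table(55)
  expect_equal(nrow(tab), 55)
  expect_equal(max(tab$n), 9)
  expect_true(all(diff(tab$n) >= 0))
  expect_true(all(besselao:::is_valid_zernike(tab$n, tab$m)))
})

test_that("phase wrapping lands in (-pi, pi] and SLM export is 8-bit exact", {
  x <- c(-pi, pi, 3 * pi, -3 * pi, 0, 2 * pi - 1e-9)
  w <- wrap_phase(x)
  expect_true(all(w > -pi & w <= pi + 1e-12))
  expect_equal(wrap_phase(0.3), 0.3)
  lev <- slm_export(matrix(seq(0, 2 * pi - 1e-9, length.out = 256), 16, 16))
  expect_true(all(lev >= 0 & lev <= 255))
})
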