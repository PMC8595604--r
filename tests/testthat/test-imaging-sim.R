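test_that("phantoms are reproducible and their catalogs are consistent", {
  p1 <- make_phantom("dendrites", extent_um = c(16, 16, 8), pitch_um = 0.2,
                     n_spines = 12, seed = 5)
  p2 <- make_phantom("dendrites", extent_um = c(16, 16, 8), pitch_um = 0.2,
                     n_spines = 12, seed = 5)
  expect_identical(p1$density, p2$density)
  expect_identical(p1$catalog, p2$catalog)
  spines <- p1$catalog[p1$catalog$kind == "spine", ]
  expect_equal(nrow(spines), 12)
  expect_true(all(spines$parent == 1L))
  expect_true(all(spines$diameter >= 0.5 & spines$diameter <= 1.5))
  # rendered density is positive at every spine centre
  d <- dim(p1$density)
  for (i in seq_len(nrow(spines))) {
    vox <- round(c(spines$x[i], spines$y[i], spines$z[i]) / 0.2 +
                   (d + 1) / 2)
    expect_gt(p1$density[vox[1], vox[2], vox[3]], 0.5)
  }
  expect_true(all(p1$density >= 0))
})

test_that("a single small bead renders as one compact object", {
  ph <- make_phantom("beads", extent_um = c(2, 2, 2), pitch_um = 0.1,
                     beads = data.frame(x = 0, y = 0, z = 0, diameter = 0.3))
  on <- which(ph$density > 0.5, arr.ind = TRUE)
  expect_gt(nrow(on), 0)
  expect_lt(max(dist(on)) * 0.1, 0.5) # all lit voxels within the bead
})

test_that("imaging a point-like bead reproduces the PSF axial width", {
  cfg <- cfg_mid()
  pitch <- focal_pitch(cfg)
  zs <- seq(-2.4, 2.4, by = pitch)
  psf <- compute_psf(make_pupil_grid(cfg), zs, crop_px = 64)
  ph <- make_phantom("beads",
                     extent_um = c(64 * pitch, 64 * pitch, 4.8 + pitch),
                     pitch_um = pitch,
                     beads = data.frame(x = 0, y = 0, z = 0, diameter = 0.1))
  img <- image_phantom(ph, psf, "gaussian_stack")
  d <- dim(img$values)
  pk <- arrayInd(which.max(img$values), d)
  prof <- img$values[pk[1], pk[2], ]
  zax <- (seq_len(d[3]) - pk[3]) * pitch
  prof_ref <- axial_profile(make_pupil_grid(cfg), seq(-2.4, 2.4, 0.02))
  f_ref <- fwhm(prof_ref$z, prof_ref$two_photon)
  expect_lt(abs(fwhm(zax, prof) - f_ref) / f_ref, 0.15)
})

test_that("a Bessel projection collapses the volume that a Gaussian stack separates", {
  cfg <- cfg_mid()
  pitch <- 0.25
  mask <- hw_mask(cfg)
  bess <- apply_annulus(make_pupil_grid(cfg), mask)
  zs <- seq(-30, 30, by = 1)
  psf_b <- compute_psf(bess, zs, crop_px = 64)
  psf_g <- compute_psf(make_pupil_grid(cfg), seq(-2, 2, by = 0.25),
                       crop_px = 64)
  ph <- make_phantom("beads", extent_um = c(12, 12, 50), pitch_um = pitch,
                     beads = data.frame(x = c(-2, 2), y = c(-2, 2),
                                        z = c(-10, 10), diameter = 1))
  proj <- image_phantom(ph, psf_b, "bessel_projection")
  expect_length(dim(proj$values), 2)
  # both beads visible in the single projection frame
  ctr <- (dim(proj$values) + 1) / 2
  at <- function(x, y) proj$values[round(ctr[1] + x / pitch),
                                   round(ctr[2] + y / pitch)]
  bg <- median(proj$values)
  expect_gt(at(-2, -2), 5 * bg)
  expect_gt(at(2, 2), 5 * bg)
  # the Gaussian stack separates them: each bead only in its own plane
  stack <- suppressWarnings(image_phantom(ph, psf_g, "gaussian_stack"))
  d <- dim(stack$values)
  z_of <- function(zum) round((d[3] + 1) / 2 + zum / pitch)
  a_plane <- stack$values[, , z_of(-10)]
  b_plane <- stack$values[, , z_of(10)]
  i1 <- round(ctr[1] - 2 / pitch); i2 <- round(ctr[2] - 2 / pitch)
  j1 <- round(ctr[1] + 2 / pitch); j2 <- round(ctr[2] + 2 / pitch)
  expect_gt(a_plane[i1, i2] / (b_plane[i1, i2] + 1e-12), 50)
  expect_gt(b_plane[j1, j2] / (a_plane[j1, j2] + 1e-12), 50)
})

test_that("the Bessel projection matches the axially weighted sum of plane images", {
  # grid chosen so the focal pitch equals the phantom pitch exactly and
  # the PSF z-planes coincide with the phantom planes
  pitch <- 0.25
  cfg <- optical_config(grid_n = 192,
                        pupil_oversampling = 0.94 / (2 * pitch * 1.05))
  bess <- apply_annulus(make_pupil_grid(cfg), hw_mask(cfg))
  zs <- seq(-20, 20, by = pitch)
  psf_b <- compute_psf(bess, zs, crop_px = 64)
  set.seed(9)
  ph <- make_phantom("beads", extent_um = c(12, 12, 30.25), pitch_um = pitch,
                     beads = 6, bead_diameter_um = 0.8)
  proj <- image_phantom(ph, psf_b, "bessel_projection")$values
  # oracle: sum of per-plane 2-D convolutions with the PSF plane at the
  # matching axial offset
  ker2 <- psf_b$values[, , ] # lateral pitch == phantom pitch here
  d <- dim(ph$density)
  acc <- matrix(0, d[1], d[2])
  for (iz in seq_len(d[3])) {
    z_off <- (iz - (d[3] + 1) / 2) * pitch
    kz <- which.min(abs(psf_b$z_planes - z_off))
    if (abs(psf_b$z_planes[kz] - z_off) > pitch / 4) next
    plane <- ph$density[, , iz]
    if (all(plane == 0)) next
    kk <- ker2[, , kz]
    if (dim(kk)[1] > d[1]) { # centre-crop the kernel to the plane size
      ctr <- dim(kk)[1] / 2 + 1
      sel <- seq(ctr - d[1] / 2, length.out = d[1])
      kk <- kk[sel, sel]
    }
    big <- matrix(0, d[1], d[2])
    off <- (d[1] - dim(kk)[1]) / 2
    big[off + seq_len(dim(kk)[1]), off + seq_len(dim(kk)[2])] <- kk
    acc <- acc + besselao:::conv2_centered(plane, big)
  }
  expect_lt(sqrt(mean((acc - proj)^2)) / max(proj), 0.05)
})

test_that("Richardson-Lucy deconvolution conserves flux and sharpens a two-point object", {
  cfg <- optical_config(grid_n = 256, pupil_oversampling = 4)
  pitch <- focal_pitch(cfg)
  psf <- compute_psf(make_pupil_grid(cfg), seq(-1, 1, by = 0.25),
                     crop_px = 64)
  lat_fwhm <- measure_fwhm(psf)$fwhm_x
  sep <- round(1.2 * lat_fwhm / pitch) * pitch # snapped to the voxel grid
  ph <- make_phantom("beads",
                     extent_um = c(96 * pitch, 96 * pitch, 2 + pitch),
                     pitch_um = pitch,
                     beads = data.frame(x = c(-sep / 2, sep / 2), y = 0,
                                        z = 0, diameter = 0.1))
  img <- image_phantom(ph, psf, "gaussian_stack")
  expect_identical(deconvolve(img, psf, 0)$values, img$values)
  dec <- deconvolve(img, psf, 10)
  expect_lt(abs(sum(dec$values) - sum(img$values)) / sum(img$values), 1e-3)
  expect_true(all(dec$values >= 0))
  # contrast dip between the two peaks deepens monotonically
  d <- dim(img$values)
  zc <- (d[3] + 1) / 2
  yc <- (d[2] + 1) / 2
  dip <- function(v) {
    prof <- v[, yc, zc]
    pks <- range(which(prof > 0.5 * max(prof)))
    valley <- min(prof[pks[1]:pks[2]])
    1 - valley / max(prof)
  }
  dips <- vapply(c(1, 3, 6, 10),
                 function(it) dip(deconvolve(img, psf, it)$values), 0)
  expect_true(all(diff(dips) > -1e-9)) # deepens monotonically
  expect_gt(dips[4], dip(img$values)) # and beats the blurred image
})

test_that("aberration correction makes more catalog spines resolvable in Bessel projections", {
  cfg <- cfg_mid()
  mask <- hw_mask(cfg)
  pitch <- 0.25
  ph <- make_phantom("dendrites", extent_um = c(16, 16, 30), pitch_um = pitch,
                     n_spines = 15, seed = 8)
  zs <- seq(-24, 24, by = 1)
  good <- apply_annulus(make_pupil_grid(cfg), mask)
  bad <- apply_wavefront(good, 1 * zernike_surface(3, 3, cfg,
                                                   na_scale = 0.5))
  psf_good <- compute_psf(good, zs, crop_px = 64)
  psf_bad <- compute_psf(bad, zs, crop_px = 64, normalize = FALSE)
  psf_bad$values <- psf_bad$values / max(psf_good$values[] * 0 + 1) # keep scale
  img_good <- image_phantom(ph, psf_good, "bessel_projection")
  img_bad <- image_phantom(ph, psf_bad, "bessel_projection")
  n_good <- sum(detect_spines(img_good, ph)$detected)
  n_bad <- sum(detect_spines(img_bad, ph)$detected)
  expect_gt(n_good, n_bad)
  expect_gt(n_good, 7) # corrected imaging resolves most of the catalog
})
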