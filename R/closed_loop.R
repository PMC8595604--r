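#' Random smooth aberration as a Zernike coefficient table
#'
#' Draws coefficients for radial orders 2..`n_max` (tip/tilt excluded;
#' they only translate the focus) and scales the surface so its RMS over
#' the pupil disk equals `rms_waves`.
#'
#' @param config An [optical_config()].
#' @param rms_waves Target wavefront RMS in waves.
#' @param n_max Highest radial order (default 4).
#' @param seed Optional RNG seed.
#' @return List with `coefficients` (55-mode tibble) and `wavefront`
#'   (matrix in waves).
#' @export
random_smooth_aberration <- function(config, rms_waves = 1, n_max = 4,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  coefs <- zernike_index_table(55)
  coefs$waves <- 0
  pick <- coefs$n >= 2 & coefs$n <= n_max
  coefs$waves[pick] <- rnorm(sum(pick)) / coefs$n[pick] # mild spectral rolloff
  w <- zernike_reconstruct(coefs, config)
  disk <- pupil_disk_mask(config)
  rms <- sqrt(mean(w[disk]^2))
  scale <- if (rms > 0) rms_waves / rms else 0
  coefs$waves <- coefs$waves * scale
  list(coefficients = coefs, wavefront = w * scale)
}

# Two-photon Bessel peak obtained by displaying `focal_phase` on the
# focal-plane SLM while the system suffers `aberration` (waves) at the
# pupil: uniform-amplitude phase-only field at the focal plane is
# back-propagated, clipped by the physical annular mask, aberrated, and
# focused.
bessel_peak_with_pattern <- function(focal_phase, mask, config,
                                     aberration = NULL, z_planes = NULL) {
  field <- new_pupil_field(exp(1i * focal_phase), config, plane = "focal")
  pupil <- propagate(field, "focal_to_pupil")
  pupil <- apply_annulus(pupil, mask)
  if (!is.null(aberration)) pupil <- apply_wavefront(pupil, aberration)
  if (is.null(z_planes)) z_planes <- z_search_grid(pupil)
  peak_two_photon(pupil, z_planes)
}

#' Closed-loop adaptive-optics recovery simulation
#'
#' Runs the full loop on a known aberration: simulate the 25 pupil-segment
#' bead images, localize their displacements, reconstruct the wavefront,
#' derive the focal-plane corrective pattern, and measure the two-photon
#' Bessel peak under the true aberration with and without the correction,
#' both normalized to the unaberrated ideal pattern.
#'
#' @param true_wavefront Real matrix (waves) - the aberration to correct.
#' @param config An [optical_config()].
#' @param mask An [annular_mask()] (default: hardware mask).
#' @param bead_diameter_um Guide-bead diameter for sensing (default 2).
#' @param photons Optional photon budget for the sensing images.
#' @param seed Optional seed for sensing noise.
#' @param recon_n_max Radial order for the modal reconstruction (default 4).
#' @return One-row tibble: `peak_corrected`, `peak_uncorrected` (fractions
#'   of the unaberrated peak), `wavefront_rms_error` (waves, piston/tip/
#'   tilt/defocus excluded), `n_valid_tiles`.
#' @export
ao_closed_loop <- function(true_wavefront, config,
                           mask = annular_mask(config = config),
                           bead_diameter_um = 2, photons = NULL, seed = NULL,
                           recon_n_max = 4) {
  mask <- derive_annulus_na(mask, config)
  sim <- simulate_segment_images(true_wavefront, config,
                                 bead_diameter_um = bead_diameter_um,
                                 photons = photons, seed = seed)
  shifts <- estimate_shifts(sim)
  rec <- reconstruct_wavefront(shifts, n_max = recon_n_max)

  # the corrective wavefront cancels the measured aberration
  corr <- compute_focal_correction(-rec$wavefront, mask, config)
  ideal <- compute_focal_correction(matrix(0, config$grid_n, config$grid_n),
                                    mask, config)

  pupil_ref <- apply_annulus(make_pupil_grid(config), mask)
  zs <- z_search_grid(pupil_ref)
  ref <- bessel_peak_with_pattern(ideal$focal_phase, mask, config,
                                  aberration = NULL, z_planes = zs)
  corrected <- bessel_peak_with_pattern(corr$focal_phase, mask, config,
                                        aberration = true_wavefront,
                                        z_planes = zs)
  uncorrected <- bessel_peak_with_pattern(ideal$focal_phase, mask, config,
                                          aberration = true_wavefront,
                                          z_planes = zs)

  # residual wavefront error, ignoring modes the pipeline discards anyway
  fit_true <- fit_zernike(true_wavefront, config)
  cmp_true <- remove_modes(fit_true, c("piston", "tip", "tilt", "defocus"))
  cmp_rec <- remove_modes(rec$coefficients, c("piston", "tip", "tilt", "defocus"))
  derr <- zernike_reconstruct(
    dplyr::mutate(cmp_true, waves = .data$waves - cmp_rec$waves), config)
  disk <- pupil_disk_mask(config)

  tibble(peak_corrected = corrected / ref,
         peak_uncorrected = uncorrected / ref,
         wavefront_rms_error = sqrt(mean(derr[disk]^2)),
         n_valid_tiles = rec$n_valid)
}
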