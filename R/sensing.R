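#' Partition of the pupil disk into square segments
#'
#' The back pupil's bounding square is divided into `k` x `k` tiles
#' (default 5 x 5 = 25). A tile is valid when at least `min_inside` of its
#' area overlaps the pupil disk; its reconstruction weight is proportional
#' to the overlapping area. Area fractions are computed on the pixel grid
#' of `config`.
#'
#' @param config An [optical_config()].
#' @param k Tiles per side (default 5).
#' @param min_inside Minimum inside-disk area fraction for a valid tile
#'   (default 0.25).
#' @return An object of class `segment_grid`: tibble with columns `tile`,
#'   `ix`, `iy`, `cx`, `cy` (tile-centre NA coordinates), `frac_inside`,
#'   `valid`; attributes `k`, `config`.
#' @examples
#' sum(segment_grid(optical_config(grid_n = 64))$valid)
#' @export
segment_grid <- function(config, k = 5, min_inside = 0.25) {
  g <- na_grids(config)
  na_obj <- config$na_objective
  edges <- seq(-na_obj, na_obj, length.out = k + 1)
  disk <- pupil_disk_mask(config)
  rows <- list()
  t <- 0L
  hi <- function(v, edge, last) if (last) v <= edge + 1e-12 else v < edge
  for (iy in seq_len(k)) {
    for (ix in seq_len(k)) {
      t <- t + 1L
      in_tile <- g$x >= edges[ix] & hi(g$x, edges[ix + 1], ix == k) &
                 g$y >= edges[iy] & hi(g$y, edges[iy + 1], iy == k)
      n_tile <- sum(in_tile)
      frac <- if (n_tile > 0) sum(in_tile & disk) / n_tile else 0
      rows[[t]] <- tibble(
        tile = t, ix = ix, iy = iy,
        cx = (edges[ix] + edges[ix + 1]) / 2,
        cy = (edges[iy] + edges[iy + 1]) / 2,
        frac_inside = frac, valid = frac >= min_inside)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "k") <- k
  attr(out, "config") <- config
  attr(out, "edges") <- edges
  class(out) <- c("segment_grid", class(out))
  out
}

# Logical pixel mask of one tile intersected with the pupil disk
tile_mask <- function(segments, tile) {
  config <- attr(segments, "config")
  edges <- attr(segments, "edges")
  k <- attr(segments, "k")
  g <- na_grids(config)
  row <- segments[segments$tile == tile, ]
  hi <- function(v, edge, last) if (last) v <= edge + 1e-12 else v < edge
  g$x >= edges[row$ix] & hi(g$x, edges[row$ix + 1], row$ix == k) &
    g$y >= edges[row$iy] & hi(g$y, edges[row$iy + 1], row$iy == k) &
    pupil_disk_mask(config)
}

# 2-D projection of a uniformly fluorescent sphere (chord-length kernel),
# normalized to unit sum, on the focal pixel grid.
bead_projection_kernel <- function(diameter_um, config) {
  n <- config$grid_n
  dx <- focal_pitch(config)
  ax <- (seq_len(n) - (n / 2 + 1)) * dx
  r2 <- outer(ax^2, ax^2, "+")
  rad <- diameter_um / 2
  ker <- matrix(0, n, n)
  inside <- r2 < rad^2
  ker[inside] <- 2 * sqrt(rad^2 - r2[inside])
  if (sum(ker) == 0) { # sub-pixel bead: delta kernel
    ker[n / 2 + 1, n / 2 + 1] <- 1
  }
  ker / sum(ker)
}

# Circular FFT correlation-based 2-D convolution on the centred grid
conv2_centered <- function(a, kernel) {
  n <- nrow(a)
  sh <- c((n / 2 + 1):n, 1:(n / 2))
  Re(fft(fft(a[sh, sh]) * fft(kernel[sh, sh]), inverse = TRUE))[sh, sh] / n^2
}
# (inverse FFT of an n x n matrix needs division by n^2 elements)

#' Simulate pupil-segmentation bead images
#'
#' Emulates indirect wavefront sensing: each pupil tile is illuminated in
#' turn and a two-photon image of an isolated fluorescent bead is formed
#' by the tile-restricted, aberrated pupil field. The displacement of each
#' beamlet image encodes the mean wavefront gradient over its tile. A
#' full-pupil image is included as the localization reference.
#'
#' @param true_wavefront Real matrix (waves) on the pupil grid - the
#'   aberration to sense.
#' @param config An [optical_config()].
#' @param segments A [segment_grid()]; default 5 x 5 on `config`.
#' @param bead_diameter_um Guide-bead diameter (default 2).
#' @param photons Optional expected photon count per image (total); when
#'   given, Poisson noise is applied.
#' @param seed Optional RNG seed used for the noise.
#' @return An object of class `segment_images`: list with `images` (list of
#'   matrices, one per tile; invalid tiles `NULL`), `calibration`
#'   (noiseless unaberrated per-tile images - the per-segment reference
#'   positions a system calibration provides), `reference` (the aberrated
#'   full-pupil image), `segments`, `config`, `bead_diameter_um`.
#' @export
simulate_segment_images <- function(true_wavefront, config,
                                    segments = segment_grid(config),
                                    bead_diameter_um = 2,
                                    photons = NULL, seed = NULL) {
  stopifnot(all(dim(true_wavefront) == c(config$grid_n, config$grid_n)))
  if (!is.null(seed)) set.seed(seed)
  ker <- debye_kernels(config)
  bead <- bead_projection_kernel(bead_diameter_um, config)
  phase <- exp(2i * pi * true_wavefront)
  image_of <- function(mask, aberrated = TRUE, noisy = TRUE) {
    pv <- matrix(0 + 0i, config$grid_n, config$grid_n)
    pv[mask] <- (if (aberrated) phase[mask] else 1) * ker$apod[mask]
    inten2p <- Mod(fft2_centered(pv))^4
    img <- conv2_centered(inten2p, bead)
    img[img < 0] <- 0
    if (noisy && !is.null(photons) && sum(img) > 0) {
      img <- matrix(rpois(length(img), img / sum(img) * photons),
                    nrow(img), ncol(img))
    }
    img
  }
  imgs <- vector("list", nrow(segments))
  cal <- vector("list", nrow(segments))
  for (t in segments$tile) {
    if (!segments$valid[segments$tile == t]) next
    m <- tile_mask(segments, t)
    if (!any(m)) next
    imgs[[t]] <- image_of(m)
    cal[[t]] <- image_of(m, aberrated = FALSE, noisy = FALSE)
  }
  structure(
    list(images = imgs,
         calibration = cal,
         reference = image_of(pupil_disk_mask(config)),
         segments = segments, config = config,
         bead_diameter_um = bead_diameter_um),
    class = "segment_images"
  )
}

# Sub-pixel displacement of `img` relative to `ref` by FFT
# cross-correlation with separable parabolic peak refinement.
# Returns c(dx_px, dy_px, confidence). Positive dx means `img` features
# sit at larger row coordinate than in `ref`.
xcorr_shift <- function(img, ref) {
  n <- nrow(img)
  sh <- c((n / 2 + 1):n, 1:(n / 2))
  C <- Re(fft(fft(img[sh, sh]) * Conj(fft(ref[sh, sh])), inverse = TRUE)) / n^2
  C <- C[sh, sh]
  pk <- arrayInd(which.max(C), dim(C))
  sub <- function(axis) {
    i <- pk[axis]
    if (i <= 1 || i >= n) return(0)
    ym <- if (axis == 1) C[i - 1, pk[2]] else C[pk[1], i - 1]
    y0 <- C[pk[1], pk[2]]
    yp <- if (axis == 1) C[i + 1, pk[2]] else C[pk[1], i + 1]
    den <- ym - 2 * y0 + yp
    if (den >= 0) 0 else 0.5 * (ym - yp) / den
  }
  dx <- (pk[1] - (n / 2 + 1)) + sub(1)
  dy <- (pk[2] - (n / 2 + 1)) + sub(2)
  conf <- max(C) / sqrt(sum(img^2) * sum(ref^2))
  c(dx, dy, conf)
}

# Intensity-centroid displacement relative to the grid centre
centroid_shift <- function(img) {
  n <- nrow(img)
  ax <- seq_len(n) - (n / 2 + 1)
  s <- sum(img)
  c(sum(matrix(ax, n, n) * img) / s, sum(t(matrix(ax, n, n)) * img) / s, 1)
}

#' Localize per-segment bead displacements
#'
#' Measures the sub-pixel 2-D displacement of each tile's bead image
#' relative to its reference position. The default localization
#' cross-correlates each tile image against that tile's own calibration
#' (unaberrated) image, which is shape-matched and therefore unbiased;
#' the `"centroid"` method instead takes the intensity centroid relative
#' to the grid centre. Tiles whose image energy is below `snr_min` times
#' the strongest tile are marked invalid.
#'
#' @param sim A `segment_images` object from [simulate_segment_images()].
#' @param reference Optional single reference image used for every tile in
#'   place of the per-tile calibration images.
#' @param method `"xcorr"` (default) or `"centroid"`.
#' @param snr_min Relative energy threshold for validity (default 1e-3).
#' @return An object of class `segment_shifts`: tibble with columns
#'   `tile`, `cx`, `cy`, `shift_x_um`, `shift_y_um`, `confidence`,
#'   `valid`; attribute `config`.
#' @export
estimate_shifts <- function(sim, reference = NULL,
                            method = c("xcorr", "centroid"),
                            snr_min = 1e-3) {
  method <- match.arg(method)
  segments <- sim$segments
  config <- sim$config
  dx_um <- focal_pitch(config)
  energies <- vapply(sim$images, function(im) if (is.null(im)) 0 else sum(im), 0)
  e_max <- max(energies)
  rows <- lapply(segments$tile, function(t) {
    seg <- segments[segments$tile == t, ]
    im <- sim$images[[t]]
    ok <- !is.null(im) && energies[t] > snr_min * e_max && seg$valid
    if (!ok) {
      return(tibble(tile = t, cx = seg$cx, cy = seg$cy,
                    shift_x_um = NA_real_, shift_y_um = NA_real_,
                    confidence = 0, valid = FALSE))
    }
    ref_t <- reference %||% sim$calibration[[t]] %||% sim$reference
    s <- if (method == "xcorr") xcorr_shift(im, ref_t) else centroid_shift(im)
    tibble(tile = t, cx = seg$cx, cy = seg$cy,
           shift_x_um = s[1] * dx_um, shift_y_um = s[2] * dx_um,
           confidence = s[3], valid = TRUE)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  attr(out, "segments") <- segments
  class(out) <- c("segment_shifts", class(out))
  out
}

# Mean analytic Zernike gradient over each tile (waves per NA unit).
# Returns list(gx, gy): matrices tiles x modes.
tile_mode_gradients <- function(segments, modes) {
  config <- attr(segments, "config")
  g <- na_grids(config)
  gx <- matrix(0, nrow(segments), nrow(modes))
  gy <- matrix(0, nrow(segments), nrow(modes))
  for (t in seq_len(nrow(segments))) {
    if (!segments$valid[t]) next
    m <- tile_mask(segments, segments$tile[t])
    if (!any(m)) next
    xs <- g$x[m]; ys <- g$y[m]
    for (j in seq_len(nrow(modes))) {
      gr <- zernike_gradient(modes$n[j], modes$m[j], xs, ys, config$na_objective)
      gx[t, j] <- mean(gr$dx)
      gy[t, j] <- mean(gr$dy)
    }
  }
  list(gx = gx, gy = gy)
}

# Calibration between focal-plane displacement and pupil wavefront
# gradient: a wavefront tilt of g waves per NA unit displaces the focus by
# `shift_sign * wavelength * g` micrometres. The sign matches the FFT
# conventions of `propagate()`/`fft2_centered()` and is shared by the
# forward simulator and the reconstructor.
shift_per_gradient <- function(config) config$wavelength

#' Modal wavefront reconstruction from segment displacements
#'
#' Converts per-tile displacements into mean wavefront gradients with the
#' system's displacement calibration and solves a weighted least-squares
#' problem for Zernike coefficients (modal reconstruction). Tip and tilt
#' are included in the solve - so a uniform displacement component cannot
#' alias into higher modes - but are zeroed in the output along with
#' piston, which slope data cannot constrain. If the valid tiles
#' under-determine the requested modes, the radial order is reduced with a
#' warning.
#'
#' @param shifts A `segment_shifts` tibble from [estimate_shifts()].
#' @param n_max Maximum radial order to reconstruct (default 4).
#' @param n_modes_out Length of the padded output coefficient table
#'   (default 55).
#' @return List with `coefficients` (tibble padded to `n_modes_out`),
#'   `wavefront` (matrix, waves), `residual_rms_gradient`, `n_valid`.
#' @export
reconstruct_wavefront <- function(shifts, n_max = 4, n_modes_out = 55) {
  config <- attr(shifts, "config")
  segments <- attr(shifts, "segments")
  ok <- shifts$valid
  if (sum(ok) < 3) stop("need at least 3 valid tiles", call. = FALSE)
  n_eq <- 2 * sum(ok)
  n_req <- n_max
  n_modes_for <- function(nm) (nm + 1) * (nm + 2) / 2 - 1 # piston dropped
  while (n_modes_for(n_max) > n_eq && n_max > 1) n_max <- n_max - 1
  if (n_max < n_req) {
    warning("valid tiles under-determine requested modes; reducing radial order to ",
            n_max)
  }
  modes <- zernike_index_table((n_max + 1) * (n_max + 2) / 2)
  modes <- modes[modes$n >= 1, ] # piston has no slope signal
  gr <- tile_mode_gradients(segments, modes)
  cal <- shift_per_gradient(config)
  seg_row <- match(shifts$tile, segments$tile) # shifts may be a subset
  gx_meas <- shifts$shift_x_um[ok] / cal
  gy_meas <- shifts$shift_y_um[ok] / cal
  w <- sqrt(segments$frac_inside[seg_row][ok] *
              pmax(shifts$confidence[ok], 1e-6))
  A <- rbind(gr$gx[seg_row, , drop = FALSE][ok, , drop = FALSE] * w,
             gr$gy[seg_row, , drop = FALSE][ok, , drop = FALSE] * w)
  b <- c(gx_meas * w, gy_meas * w)
  beta <- qr.coef(qr(A), b)
  beta[is.na(beta)] <- 0
  resid <- sqrt(mean((A %*% beta - b)^2))
  coefs <- zernike_index_table(n_modes_out)
  coefs$waves <- 0
  key_fit <- paste(modes$n, modes$m)
  key_out <- paste(coefs$n, coefs$m)
  coefs$waves[match(key_fit, key_out)] <- as.numeric(beta)
  coefs$waves[coefs$label %in% c("piston", "tip", "tilt")] <- 0
  list(coefficients = coefs,
       wavefront = zernike_reconstruct(coefs, config),
       residual_rms_gradient = resid,
       n_valid = sum(ok))
}
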