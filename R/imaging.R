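# 3-D circular correlation/convolution via FFT. `kernel` is given on a
# centred grid and is zero-padded (objects are compactly supported) to the
# data size. With correlate = TRUE this matches a scanning microscope:
# image(r) = sum_r' density(r') kernel(r' - r).
fft3_filter <- function(a, kernel, correlate = TRUE) {
  d <- dim(a)
  kd <- dim(kernel)
  if (any(kd > d)) { # crop oversized kernel axes symmetrically
    idx <- lapply(seq_len(3), function(i) {
      if (kd[i] <= d[i]) return(seq_len(kd[i]))
      ctr <- floor(kd[i] / 2) + 1
      seq(ctr - floor(d[i] / 2), length.out = d[i])
    })
    kernel <- kernel[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    kd <- dim(kernel)
  }
  kpad <- array(0, dim = d)
  off <- floor(d / 2) - floor(kd / 2)
  kpad[off[1] + seq_len(kd[1]), off[2] + seq_len(kd[2]), off[3] + seq_len(kd[3])] <- kernel
  # move kernel centre (floor(d/2)+1) to the origin
  sh <- lapply(d, function(n) c((floor(n / 2) + 1):n, seq_len(floor(n / 2))))
  kpad <- kpad[sh[[1]], sh[[2]], sh[[3]]]
  K <- fft(kpad)
  if (correlate) K <- Conj(K)
  Re(fft(fft(a) * K, inverse = TRUE)) / prod(d)
}

# Resample a PSF volume onto the phantom's voxel grid (separable linear
# interpolation), returning a plain array.
psf_on_grid <- function(psf, pitch_um) {
  v <- psf$values
  d <- dim(v)
  ax_l <- (seq_len(d[1]) - (d[1] %/% 2 + 1)) * psf$pitch_lateral
  ax_z <- psf$z_planes
  same_l <- abs(psf$pitch_lateral - pitch_um) < 1e-9 * pitch_um
  dz <- if (length(ax_z) > 1) diff(ax_z[1:2]) else pitch_um
  same_z <- abs(dz - pitch_um) < 1e-9 * pitch_um
  if (same_l && same_z) return(v)
  interp_axis <- function(arr, axis, old, new) {
    ap <- aperm(arr, c(axis, setdiff(1:3, axis)))
    dm <- dim(ap)
    flat <- matrix(ap, dm[1], dm[2] * dm[3])
    out <- apply(flat, 2, function(col) approx(old, col, xout = new, rule = 2)$y)
    out <- array(out, c(length(new), dm[2], dm[3]))
    aperm(out, order(c(axis, setdiff(1:3, axis))))
  }
  new_l1 <- seq(min(ax_l), max(ax_l), by = pitch_um)
  new_z <- seq(min(ax_z), max(ax_z), by = pitch_um)
  v <- interp_axis(v, 1, ax_l, new_l1)
  v <- interp_axis(v, 2, ax_l, new_l1)
  v <- interp_axis(v, 3, ax_z, new_z)
  v
}

#' Forward imaging of a phantom
#'
#' Images a [make_phantom()] volume with a simulated two-photon PSF.
#' `"gaussian_stack"` produces the plane-by-plane 3-D image stack
#' (3-D correlation of density and PSF); `"bessel_projection"` produces
#' the single 2-D sweep of the axially extended Bessel focus held at the
#' volume midplane, so all structures within the PSF's axial extent
#' project into one frame. Optional Poisson noise is parameterized by the
#' expected photon count at the brightest pixel.
#'
#' @param phantom A `phantom`.
#' @param psf A `psf_volume` (two-photon). Resampled onto the phantom grid
#'   if pitches differ. A warning is issued in Bessel mode when the PSF's
#'   axial support does not cover the phantom depth.
#' @param mode `"gaussian_stack"` or `"bessel_projection"`.
#' @param photon_budget Expected photons at the brightest pixel (NULL =
#'   noiseless).
#' @param seed RNG seed for the noise.
#' @return An object of class `simulated_image`: list with `values` (3-D
#'   array or 2-D matrix), `mode`, `pitch_um`, `noise` descriptor.
#' @export
image_phantom <- function(phantom, psf,
                          mode = c("gaussian_stack", "bessel_projection"),
                          photon_budget = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (psf$excitation != "two") {
    warning("PSF is one-photon; two-photon imaging expects excitation = 'two'")
  }
  ker <- psf_on_grid(psf, phantom$pitch_um)
  if (mode == "bessel_projection") {
    z_support <- diff(range(psf$z_planes))
    depth <- dim(phantom$density)[3] * phantom$pitch_um
    if (z_support < depth) {
      warning(sprintf(
        "Bessel PSF axial support (%.3g um) smaller than phantom depth (%.3g um): partial-volume coverage",
        z_support, depth))
    }
  }
  img <- fft3_filter(phantom$density, ker, correlate = TRUE)
  img[img < 0] <- 0
  if (mode == "bessel_projection") {
    img <- img[, , floor(dim(img)[3] / 2) + 1]
  }
  if (!is.null(photon_budget)) {
    if (!is.null(seed)) set.seed(seed)
    scale <- photon_budget / max(img)
    img <- array(rpois(length(img), img * scale), dim = dim(img) %||% length(img))
    if (is.null(dim(img))) dim(img) <- dim(phantom$density)[1:2]
  }
  structure(
    list(values = img, mode = mode, pitch_um = phantom$pitch_um,
         noise = list(photon_budget = photon_budget, seed = seed)),
    class = "simulated_image"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.simulated_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<simulated_image> %s, %s voxels at %.3g um\n",
              x$mode, paste(d, collapse = " x "), x$pitch_um))
  invisible(x)
}

#' Richardson-Lucy deconvolution
#'
#' Standard multiplicative Richardson-Lucy iterations with FFT
#' convolutions. Nonnegativity is preserved by construction and total flux
#' is conserved. `iterations <= 0` returns the input unchanged.
#'
#' @param image A `simulated_image` or a numeric 2-D/3-D array.
#' @param psf A `psf_volume` or array on the same pixel pitch.
#' @param iterations Number of iterations.
#' @return Same type as `image`.
#' @export
deconvolve <- function(image, psf, iterations = 10) {
  vals <- if (inherits(image, "simulated_image")) image$values else image
  pitch <- if (inherits(image, "simulated_image")) image$pitch_um else NULL
  ker <- if (inherits(psf, "psf_volume")) {
    psf_on_grid(psf, pitch %||% psf$pitch_lateral)
  } else psf
  two_d <- length(dim(vals)) == 2
  if (two_d) {
    # 2-D image: collapse the PSF axially (projection imaging kernel)
    if (length(dim(ker)) == 3) ker <- apply(ker, c(1, 2), sum)
    dim(vals) <- c(dim(vals), 1L)
    dim(ker) <- c(dim(ker), 1L)
  }
  ker <- ker / sum(ker)
  est <- vals
  if (iterations > 0) {
    for (i in seq_len(iterations)) {
      blur <- fft3_filter(est, ker, correlate = FALSE)
      blur[blur < 1e-12] <- 1e-12
      est <- est * fft3_filter(vals / blur, ker, correlate = TRUE)
      est[est < 0] <- 0
    }
    # guard against drift from the circular boundary
    if (sum(est) > 0) est <- est * sum(vals) / sum(est)
  }
  if (two_d) est <- est[, , 1]
  if (inherits(image, "simulated_image")) {
    image$values <- est
    image
  } else est
}

#' Count catalog spines resolvable in an image
#'
#' A spine is "resolvable" when a local intensity maximum lies within
#' `radius_um` of its catalog position and exceeds the image background
#' (median of nonzero pixels) by `factor`.
#'
#' @param image A `simulated_image` (2-D Bessel projection or 3-D stack).
#' @param phantom The `phantom` whose catalog is checked.
#' @param radius_um Matching radius (default 0.5).
#' @param factor Peak-above-background factor (default 2).
#' @return Tibble: one row per catalog spine with `object`, `detected`.
#' @export
detect_spines <- function(image, phantom, radius_um = 0.5, factor = 2) {
  spines <- phantom$catalog[phantom$catalog$kind == "spine", ]
  v <- image$values
  two_d <- length(dim(v)) == 2
  bg <- median(v[v > 0])
  d <- dim(v)
  ctr <- (d + 1) / 2
  detected <- vapply(seq_len(nrow(spines)), function(i) {
    pos <- c(spines$x[i], spines$y[i], spines$z[i]) / image$pitch_um + ctr[1:3]
    rad <- ceiling(radius_um / image$pitch_um)
    ix <- max(1, round(pos[1]) - rad):min(d[1], round(pos[1]) + rad)
    iy <- max(1, round(pos[2]) - rad):min(d[2], round(pos[2]) + rad)
    if (two_d) {
      patch <- v[ix, iy]
      lo <- v[max(1, min(ix) - 1):min(d[1], max(ix) + 1),
              max(1, min(iy) - 1):min(d[2], max(iy) + 1)]
    } else {
      iz <- max(1, round(pos[3]) - rad):min(d[3], round(pos[3]) + rad)
      patch <- v[ix, iy, iz]
      lo <- patch
    }
    m <- max(patch)
    m >= factor * bg && m >= max(lo) - 1e-12
  }, logical(1))
  tibble(object = spines$object, detected = detected)
}
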