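#' Zernike mode bookkeeping
#'
#' Modes are indexed by radial order `n >= 0` and azimuthal index `m` with
#' `|m| <= n` and `n - |m|` even. The package uses the Born-Wolf
#' (unnormalised) convention: radial polynomials with `R_n^{|m|}(1) = 1`,
#' azimuthal factor `cos(m theta)` for `m > 0`, `sin(|m| theta)` for
#' `m < 0`, and 1 for `m = 0`. An amplitude of "1 wave" therefore means the
#' polynomial's peak value on the unit disk is one wavelength of path
#' difference. The deterministic ordering sorts by `n` then by `m`
#' ascending; the first 55 modes are exactly radial orders 0 through 9.
#'
#' @param n_modes Number of leading modes.
#' @return `zernike_index_table()`: a tibble with columns `mode`, `n`, `m`,
#'   and `label` (named for the classic aberrations where one exists).
#' @examples
#' zernike_index_table(10)
#' @export
zernike_index_table <- function(n_modes = 55) {
  stopifnot(n_modes >= 1)
  n <- integer(0); m <- integer(0); order <- 0L
  while (length(n) < n_modes) {
    mm <- seq(-order, order, by = 2L)
    n <- c(n, rep(order, length(mm)))
    m <- c(m, mm)
    order <- order + 1L
  }
  n <- n[seq_len(n_modes)]
  m <- m[seq_len(n_modes)]
  tibble(mode = seq_len(n_modes), n = n, m = m,
         label = zernike_label(n, m))
}

zernike_label <- function(n, m) {
  key <- paste(n, m)
  nm <- c("0 0" = "piston", "1 -1" = "tilt", "1 1" = "tip",
          "2 0" = "defocus", "2 -2" = "oblique astigmatism",
          "2 2" = "vertical astigmatism", "3 -1" = "vertical coma",
          "3 1" = "horizontal coma", "3 -3" = "oblique trefoil",
          "3 3" = "horizontal trefoil", "4 0" = "primary spherical")
  out <- unname(nm[key])
  out[is.na(out)] <- ""
  out
}

is_valid_zernike <- function(n, m) {
  n >= 0 & abs(m) <= n & (n - abs(m)) %% 2 == 0
}

# Radial polynomial R_n^{|m|}(rho); exact integer coefficients (n <= ~20)
zernike_radial <- function(n, m, rho) {
  m <- abs(m)
  s_max <- (n - m) / 2
  out <- numeric(length(rho))
  for (s in 0:s_max) {
    cf <- (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s))
    out <- out + cf * rho^(n - 2 * s)
  }
  out
}

#' Evaluate a Zernike surface on the pupil grid
#'
#' Returns the mode `Z_n^m` evaluated over the pupil disk of `config`
#' (radial coordinate scaled so the disk edge is `rho = 1`), zero outside
#' the disk. Born-Wolf convention; see [zernike_index_table()].
#'
#' @param n,m Radial order and azimuthal index (a valid pair).
#' @param config An [optical_config()] defining the grid.
#' @param na_scale Numerical aperture at which the polynomial's unit-disk
#'   edge sits (default `na_objective`). Sensitivity studies can scale the
#'   mode to the annular-footprint region instead; the surface is zero
#'   outside `na_scale`.
#' @return A real `grid_n` x `grid_n` matrix in waves per unit amplitude.
#' @examples
#' z <- zernike_surface(2, 0, optical_config(grid_n = 64))
#' range(z) # defocus spans [-1, 1] on the disk
#' @export
zernike_surface <- function(n, m, config, na_scale = config$na_objective) {
  if (!is_valid_zernike(n, m)) {
    stop(sprintf("(%d, %d) is not a valid Zernike index pair", n, m),
         call. = FALSE)
  }
  g <- na_grids(config)
  rho <- g$r / na_scale
  inside <- rho <= 1 + 1e-12
  az <- if (m > 0) cos(m * g$theta) else if (m < 0) sin(-m * g$theta) else 1
  out <- zernike_radial(n, m, pmin(rho, 1)) * az
  out[!inside] <- 0
  out
}

# Design matrix: one column per mode, rows = pixels selected by `mask`
zernike_design <- function(config, n_modes, mask = pupil_disk_mask(config)) {
  tab <- zernike_index_table(n_modes)
  g <- na_grids(config)
  rho <- pmin(g$r[mask] / config$na_objective, 1)
  theta <- g$theta[mask]
  mat <- matrix(0, sum(mask), n_modes)
  for (j in seq_len(n_modes)) {
    az <- if (tab$m[j] > 0) cos(tab$m[j] * theta)
          else if (tab$m[j] < 0) sin(-tab$m[j] * theta) else 1
    mat[, j] <- zernike_radial(tab$n[j], tab$m[j], rho) * az
  }
  mat
}

#' Least-squares Zernike decomposition of a wavefront
#'
#' Projects a wavefront map (waves, defined on the pupil disk) onto the
#' first `n_modes` Zernike modes in the package's fixed ordering and
#' reports the residual. Pixels outside the disk are ignored.
#'
#' @param wavefront Real matrix (`grid_n` x `grid_n`), in waves.
#' @param config An [optical_config()].
#' @param n_modes Number of leading modes to fit (default 55 = radial
#'   orders 0-9).
#' @return An object of class `zernike_fit`: list with `coefficients` (a
#'   tibble `mode, n, m, label, waves`), `residual` (matrix, zero outside
#'   the disk), `residual_rms` (waves, over the disk), and `config`.
#' @examples
#' cfg <- optical_config(grid_n = 64)
#' w <- 0.3 * zernike_surface(2, 2, cfg)
#' fit <- fit_zernike(w, cfg, n_modes = 15)
#' fit$coefficients[fit$coefficients$waves > 1e-6, ]
#' @export
fit_zernike <- function(wavefront, config, n_modes = 55) {
  stopifnot(all(dim(wavefront) == c(config$grid_n, config$grid_n)))
  mask <- pupil_disk_mask(config)
  if (sum(mask) < n_modes) {
    stop("fewer valid pupil pixels than modes requested", call. = FALSE)
  }
  X <- zernike_design(config, n_modes, mask)
  qrX <- qr(X)
  if (qrX$rank < n_modes) {
    warning("rank-deficient Zernike sampling; coefficients not unique")
  }
  beta <- qr.coef(qrX, wavefront[mask])
  beta[is.na(beta)] <- 0
  recon <- as.vector(X %*% beta)
  residual <- matrix(0, config$grid_n, config$grid_n)
  residual[mask] <- wavefront[mask] - recon
  coefs <- zernike_index_table(n_modes)
  coefs$waves <- as.numeric(beta)
  structure(
    list(coefficients = coefs,
         residual = residual,
         residual_rms = sqrt(mean(residual[mask]^2)),
         config = config),
    class = "zernike_fit"
  )
}

#' @export
print.zernike_fit <- function(x, ...) {
  cat(sprintf("<zernike_fit> %d modes, residual RMS %.3g waves\n",
              nrow(x$coefficients), x$residual_rms))
  top <- dplyr::arrange(x$coefficients, dplyr::desc(abs(.data$waves)))
  print(utils::head(top, 5))
  invisible(x)
}

#' @export
tidy.zernike_fit <- function(x, ...) x$coefficients

#' @export
glance.zernike_fit <- function(x, ...) {
  tibble(n_modes = nrow(x$coefficients),
         residual_rms = x$residual_rms,
         wavefront_rms = sqrt(x$residual_rms^2 +
                                mean(zernike_reconstruct(x$coefficients, x$config)[
                                  pupil_disk_mask(x$config)]^2)))
}

#' Zero selected modes of a Zernike coefficient table
#'
#' Removes (zeroes) listed modes; all other coefficients are unchanged and
#' removing an absent mode is a no-op. Modes are named by label
#' (`"piston"`, `"tip"`, `"tilt"`, `"defocus"`, ...) or given as a
#' two-column matrix / list of `c(n, m)` pairs.
#'
#' @param coefficients A coefficient tibble as produced by [fit_zernike()]
#'   (columns `n`, `m`, `waves`), or a `zernike_fit`.
#' @param modes Character vector of labels or list/matrix of `(n, m)` pairs.
#'   Default removes tip, tilt and defocus.
#' @return The coefficient tibble with listed modes zeroed.
#' @export
remove_modes <- function(coefficients, modes = c("tip", "tilt", "defocus")) {
  if (inherits(coefficients, "zernike_fit")) {
    coefficients <- coefficients$coefficients
  }
  if (is.character(modes)) {
    drop <- coefficients$label %in% modes
  } else {
    if (is.list(modes)) modes <- do.call(rbind, modes)
    modes <- matrix(as.numeric(modes), ncol = 2)
    key <- paste(coefficients$n, coefficients$m)
    drop <- key %in% paste(modes[, 1], modes[, 2])
  }
  coefficients$waves[drop] <- 0
  coefficients
}

#' Rebuild a wavefront map from Zernike coefficients
#'
#' @param coefficients Coefficient tibble (columns `n`, `m`, `waves`) or a
#'   `zernike_fit`.
#' @param config An [optical_config()].
#' @return Real matrix in waves, zero outside the pupil disk.
#' @export
zernike_reconstruct <- function(coefficients, config) {
  if (inherits(coefficients, "zernike_fit")) {
    coefficients <- coefficients$coefficients
  }
  out <- matrix(0, config$grid_n, config$grid_n)
  nz <- which(coefficients$waves != 0)
  for (j in nz) {
    out <- out + coefficients$waves[j] *
      zernike_surface(coefficients$n[j], coefficients$m[j], config)
  }
  out
}

# Analytic gradient of Z_n^m w.r.t. NA-units coordinates, evaluated at
# (x, y) in NA units. Used by the wavefront-sensing forward model and the
# modal reconstructor. Returns list(dx, dy) in waves per NA unit.
zernike_gradient <- function(n, m, x, y, na_objective) {
  h <- 1e-4 * na_objective
  f <- function(xx, yy) {
    rho <- pmin(sqrt(xx^2 + yy^2) / na_objective, 1)
    th <- atan2(yy, xx)
    az <- if (m > 0) cos(m * th) else if (m < 0) sin(-m * th) else 1
    zernike_radial(n, m, rho) * az
  }
  list(
    dx = (f(x + h, y) - f(x - h, y)) / (2 * h),
    dy = (f(x, y + h) - f(x, y - h)) / (2 * h)
  )
}
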