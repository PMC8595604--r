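#' Bimodal (two-peaked) Gaussian direction-tuning curve
#'
#' The standard direction-tuning model: a constant offset plus Gaussian
#' peaks at the preferred direction and at the opposite direction
#' (180 degrees away), with shared width `sigma`. Angular differences are
#' wrapped to (-180, 180].
#'
#' @param theta Grating directions in degrees.
#' @param r_offset,r_pref,r_oppo Offset and peak responses (dF/F0 units).
#' @param theta_pref Preferred direction in degrees.
#' @param sigma Tuning width in degrees (> 0).
#' @return Responses at `theta`.
#' @examples
#' tuning_curve(seq(0, 330, 30), 0, 1, 0.5, 90, 30)
#' @export
tuning_curve <- function(theta, r_offset, r_pref, r_oppo, theta_pref, sigma) {
  r_offset +
    r_pref * exp(-ang_wrap(theta - theta_pref)^2 / (2 * sigma^2)) +
    r_oppo * exp(-ang_wrap(theta - theta_pref + 180)^2 / (2 * sigma^2))
}

#' Wrap an angular difference to (-180, 180] degrees
#'
#' @param x Angles in degrees.
#' @return Wrapped angles.
#' @export
ang_wrap <- function(x) {
  out <- (x + 180) %% 360 - 180
  out[out == -180] <- 180
  out
}

#' Generate a synthetic trial-structured fluorescence session
#'
#' Produces per-ROI fluorescence traces aligned to a [stimulus_schedule()]:
#' baseline x (1 + tuned transient) + Gaussian noise. The transient kernel
#' rises and decays exponentially with indicator-specific time constants
#' (slow calcium vs fast glutamate) and is normalized so its mean over the
#' grating epoch is 1, making the evoked-response estimator unbiased for
#' the ground-truth tuning amplitude. Trial-to-trial amplitude jitter is
#' multiplicative. Fully reproducible by seed.
#'
#' @param truth Tibble, one row per ROI, with columns `roi`, `r_offset`,
#'   `r_pref`, `r_oppo`, `theta_pref`, `sigma`, and optionally `baseline`
#'   (default 100) and `responsive` (default TRUE; non-responsive ROIs get
#'   a flat zero-amplitude tuning).
#' @param schedule A [stimulus_schedule()].
#' @param noise_sd Additive Gaussian noise SD in dF/F0 units (default 0.1).
#' @param trial_jitter_sd SD of multiplicative trial amplitude jitter
#'   (default 0.1).
#' @param indicator `"calcium"` (rise 0.1 s, decay 1.5 s) or `"glutamate"`
#'   (rise 0.01 s, decay 0.15 s), or a list `list(rise_s=, decay_s=)`.
#' @param seed RNG seed.
#' @return A long tibble of class `roi_traces`: `roi`, `frame`, `time`,
#'   `value` (raw fluorescence); attributes `schedule`, `truth`.
#' @export
generate_session <- function(truth, schedule, noise_sd = 0.1,
                             trial_jitter_sd = 0.1,
                             indicator = "calcium", seed = 1) {
  set.seed(seed)
  if (is.character(indicator)) {
    indicator <- switch(match.arg(indicator, c("calcium", "glutamate")),
                        calcium = list(rise_s = 0.1, decay_s = 1.5),
                        glutamate = list(rise_s = 0.01, decay_s = 0.15))
  }
  truth <- as_tibble(truth)
  if (!"baseline" %in% names(truth)) truth$baseline <- 100
  if (!"responsive" %in% names(truth)) truth$responsive <- TRUE
  fmap <- schedule_frame_map(schedule)
  ep <- attr(schedule, "epochs_s")
  trial_dur <- sum(ep)
  # transient kernel evaluated at time-since-grating-onset, normalized so
  # its mean over the grating epoch is 1
  kern <- function(t_on) {
    k <- ifelse(t_on < 0, 0,
                (1 - exp(-t_on / indicator$rise_s)) *
                  exp(-pmax(t_on - ep[2], 0) / indicator$decay_s))
    k
  }
  tt <- seq(0, ep[2], length.out = 200)
  k_norm <- mean(kern(tt))
  t_on <- fmap$time - (fmap$trial - 1) * trial_dur - ep[1]
  base_kernel <- kern(t_on) / k_norm

  out <- lapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    amp_dir <- if (isTRUE(tr$responsive)) {
      tuning_curve(schedule$direction, tr$r_offset, tr$r_pref, tr$r_oppo,
                   tr$theta_pref, tr$sigma)
    } else rep(0, nrow(schedule))
    jitter <- pmax(rnorm(nrow(schedule), 1, trial_jitter_sd), 0)
    dff <- base_kernel * (amp_dir * jitter)[fmap$trial]
    value <- tr$baseline * (1 + dff) +
      tr$baseline * rnorm(length(dff), 0, noise_sd)
    tibble(roi = tr$roi, frame = fmap$frame, time = fmap$time, value = value)
  })
  out <- dplyr::bind_rows(out)
  attr(out, "schedule") <- schedule
  attr(out, "truth") <- truth
  class(out) <- c("roi_traces", class(out))
  out
}

#' Random ground-truth tuning table for synthetic sessions
#'
#' @param n_roi Number of ROIs.
#' @param responsive_fraction Fraction with true visually evoked tuning.
#' @param seed RNG seed.
#' @return Truth tibble for [generate_session()].
#' @export
random_tuning_truth <- function(n_roi = 91, responsive_fraction = 0.58,
                                seed = 1) {
  set.seed(seed)
  tibble(
    roi = seq_len(n_roi),
    r_offset = runif(n_roi, 0, 0.05),
    r_pref = runif(n_roi, 0.4, 1.2),
    r_oppo = runif(n_roi, 0.05, 0.6),
    theta_pref = runif(n_roi, 0, 360),
    sigma = runif(n_roi, 20, 45),
    baseline = 100,
    responsive = runif(n_roi) < responsive_fraction
  )
}
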