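#' Drifting-grating stimulus schedule
#'
#' Trial-structured schedule of full-field drifting gratings: 12
#' directions (0-330 degrees in 30-degree steps) by default, each repeated
#' `n_trials` times in a seeded pseudorandom order. Each trial is
#' blank / grating / blank; Gaussian-mode sessions default to (2, 4, 2) s
#' epochs sampled at 3.3 Hz and Bessel-mode sessions to (4, 6, 2) s at
#' 1.5 Hz.
#'
#' @param mode `"gaussian"` or `"bessel"` (sets epoch/frame-rate defaults).
#' @param directions Grating drift directions in degrees.
#' @param n_trials Repetitions per direction.
#' @param epochs_s Length-3 numeric: blank-pre, grating, blank-post (s).
#' @param frame_rate_hz Imaging frame rate (Hz).
#' @param seed Seed for the pseudorandom presentation order.
#' @return An object of class `stimulus_schedule`: tibble with one row per
#'   trial (`trial`, `direction`, `t_start`, `t_grating_on`,
#'   `t_grating_off`, `t_end` in seconds); attributes `frame_rate_hz`,
#'   `epochs_s`, `n_frames`.
#' @examples
#' sched <- stimulus_schedule("bessel", n_trials = 2, seed = 1)
#' attr(sched, "frame_rate_hz")
#' @export
stimulus_schedule <- function(mode = c("gaussian", "bessel"),
                              directions = seq(0, 330, by = 30),
                              n_trials = 10,
                              epochs_s = NULL, frame_rate_hz = NULL,
                              seed = 1) {
  mode <- match.arg(mode)
  if (is.null(epochs_s)) {
    epochs_s <- if (mode == "gaussian") c(2, 4, 2) else c(4, 6, 2)
  }
  if (is.null(frame_rate_hz)) {
    frame_rate_hz <- if (mode == "gaussian") 3.3 else 1.5
  }
  stopifnot(length(epochs_s) == 3, all(epochs_s > 0), frame_rate_hz > 0)
  set.seed(seed)
  order <- as.vector(vapply(seq_len(n_trials),
                            function(i) sample(directions), directions))
  trial_dur <- sum(epochs_s)
  n <- length(order)
  out <- tibble(
    trial = seq_len(n),
    direction = order,
    t_start = (seq_len(n) - 1) * trial_dur,
    t_grating_on = (seq_len(n) - 1) * trial_dur + epochs_s[1],
    t_grating_off = (seq_len(n) - 1) * trial_dur + epochs_s[1] + epochs_s[2],
    t_end = seq_len(n) * trial_dur
  )
  attr(out, "mode") <- mode
  attr(out, "frame_rate_hz") <- frame_rate_hz
  attr(out, "epochs_s") <- epochs_s
  attr(out, "n_frames") <- floor(n * trial_dur * frame_rate_hz)
  class(out) <- c("stimulus_schedule", class(out))
  out
}

# Frame mid-times (s) of a schedule's full session
schedule_frame_times <- function(schedule) {
  fr <- attr(schedule, "frame_rate_hz")
  (seq_len(attr(schedule, "n_frames")) - 0.5) / fr
}

# Long tibble mapping every frame to its trial and epoch
schedule_frame_map <- function(schedule) {
  t <- schedule_frame_times(schedule)
  trial_dur <- sum(attr(schedule, "epochs_s"))
  ep <- attr(schedule, "epochs_s")
  trial <- pmin(floor(t / trial_dur) + 1, nrow(schedule))
  t_in <- t - (trial - 1) * trial_dur
  epoch <- ifelse(t_in < ep[1], "blank_pre",
                  ifelse(t_in < ep[1] + ep[2], "grating", "blank_post"))
  tibble(frame = seq_along(t), time = t, trial = trial,
         direction = schedule$direction[trial], epoch = epoch)
}
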