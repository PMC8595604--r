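#' Per-trial dF/F0 from raw ROI traces
#'
#' The baseline F0 of each trial is the mean raw fluorescence over that
#' trial's pre-stimulus blank epoch; dF/F0 = (F - F0) / F0 frame by frame.
#' ROIs whose baseline is not positive in some trial are flagged and
#' excluded.
#'
#' @param traces Long tibble (`roi`, `frame`, `value`), e.g. from
#'   [generate_session()] or [read_traces_csv()].
#' @param schedule The session's [stimulus_schedule()] (taken from the
#'   traces' attribute when omitted).
#' @return Long tibble: `roi`, `trial`, `direction`, `frame`, `time`,
#'   `epoch`, `dff`; excluded ROIs recorded in attribute `excluded_rois`.
#' @export
compute_dff <- function(traces, schedule = attr(traces, "schedule")) {
  stopifnot(!is.null(schedule))
  fmap <- schedule_frame_map(schedule)
  df <- dplyr::inner_join(as_tibble(traces)[c("roi", "frame", "value")],
                          fmap, by = "frame")
  f0 <- df |>
    dplyr::filter(.data$epoch == "blank_pre") |>
    dplyr::group_by(.data$roi, .data$trial) |>
    dplyr::summarise(f0 = mean(.data$value), .groups = "drop")
  bad <- unique(f0$roi[f0$f0 <= 0])
  if (length(bad) > 0) {
    warning("excluding ", length(bad), " ROI(s) with non-positive baseline")
  }
  out <- df |>
    dplyr::inner_join(f0, by = c("roi", "trial")) |>
    dplyr::filter(!(.data$roi %in% bad)) |>
    dplyr::mutate(dff = (.data$value - .data$f0) / .data$f0) |>
    dplyr::select("roi", "trial", "direction", "frame", "time", "epoch", "dff")
  attr(out, "schedule") <- schedule
  attr(out, "excluded_rois") <- bad
  out
}

#' Evoked responses per trial and direction
#'
#' The response R of a trial is the mean dF/F0 over the grating epoch. A
#' trial is classified as a transient when R exceeds `threshold` (0.20 for
#' calcium; glutamate responses are conventionally thresholded at 0.10 or
#' 0.05 - configurable).
#'
#' @param dff Output of [compute_dff()].
#' @param threshold Transient threshold in dF/F0 units (default 0.2).
#' @return Tibble: `roi`, `trial`, `direction`, `response`, `transient`.
#'   An unbalanced design (missing trials for some direction) is flagged
#'   with a warning.
#' @export
evoked_response <- function(dff, threshold = 0.2) {
  out <- dff |>
    dplyr::filter(.data$epoch == "grating") |>
    dplyr::group_by(.data$roi, .data$trial, .data$direction) |>
    dplyr::summarise(response = mean(.data$dff), .groups = "drop") |>
    dplyr::mutate(transient = .data$response > threshold)
  counts <- out |>
    dplyr::count(.data$roi, .data$direction)
  if (length(unique(counts$n)) > 1) {
    warning("unbalanced design: unequal trial counts across directions")
  }
  out
}

#' One-way-ANOVA orientation-selectivity test
#'
#' An ROI is orientation-selective when its per-trial responses differ
#' significantly across the grating directions (one-way ANOVA,
#' p < `alpha`). Degenerate inputs are handled: all responses identical is
#' non-selective; zero within-group variance with between-group differences
#' is selective with p ~ 0.
#'
#' @param responses Tibble with columns `direction` and `response` (one
#'   ROI), or grouped per-ROI via [selectivity_table()].
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble: `p_value`, `selective`.
#' @export
selectivity_test <- function(responses, alpha = 0.05) {
  r <- responses$response
  g <- factor(responses$direction)
  if (length(unique(g)) < 2 || min(table(g)) < 2) {
    stop("need >= 2 trials for each of >= 2 directions", call. = FALSE)
  }
  if (var(r) == 0) {
    return(tibble(p_value = 1, selective = FALSE))
  }
  p <- summary(aov(r ~ g))[[1]][["Pr(>F)"]][1]
  if (is.na(p)) { # zero residual variance but group differences
    p <- 0
  }
  tibble(p_value = p, selective = p < alpha)
}

#' @rdname selectivity_test
#' @param responses_all Tibble from [evoked_response()] covering many ROIs.
#' @export
selectivity_table <- function(responses_all, alpha = 0.05) {
  responses_all |>
    dplyr::group_by(.data$roi) |>
    dplyr::group_modify(~ selectivity_test(.x, alpha = alpha)) |>
    dplyr::ungroup()
}

#' Fit the bimodal Gaussian tuning model to per-direction mean responses
#'
#' Nonlinear least squares of [tuning_curve()] against the direction-mean
#' responses, multi-started over a grid of preferred directions (the 12
#' stimulus directions); the best residual wins, ties resolved toward the
#' smaller width. The returned fit is canonicalized so
#' `r_pref >= r_oppo` and `theta_pref` lies in [0, 360). Meant to be run
#' only on ROIs that pass [selectivity_test()].
#'
#' @param responses Tibble with `direction` and `response` (per-trial rows
#'   are averaged per direction first).
#' @param sigma_start Starting width (degrees).
#' @return An object of class `tuning_fit`: list with `estimate` (tibble:
#'   `r_offset`, `r_pref`, `r_oppo`, `theta_pref`, `sigma`), `residual_rms`,
#'   `converged`, `data` (per-direction means), `gosi`.
#' @export
fit_tuning <- function(responses, sigma_start = 30) {
  means <- responses |>
    dplyr::group_by(.data$direction) |>
    dplyr::summarise(response = mean(.data$response), .groups = "drop")
  th <- means$direction
  y <- means$response
  best <- NULL
  for (th0 in th) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ tuning_curve(th, r_offset, r_pref, r_oppo, theta_pref, sigma),
        start = list(r_offset = min(y), r_pref = max(y) - min(y),
                     r_oppo = (max(y) - min(y)) / 2, theta_pref = th0,
                     sigma = sigma_start),
        lower = c(-Inf, 0, 0, -Inf, 5),
        upper = c(Inf, Inf, Inf, Inf, 180),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    sg <- coef(fit)[["sigma"]]
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 && sg < best$sigma)) {
      best <- list(fit = fit, rss = rss, sigma = sg)
    }
  }
  if (is.null(best)) {
    return(structure(list(estimate = NULL, residual_rms = NA_real_,
                          converged = FALSE, data = means,
                          gosi = gosi(means)),
                     class = "tuning_fit"))
  }
  cf <- as.list(coef(best$fit))
  if (cf$r_oppo > cf$r_pref) { # canonical orientation: stronger peak leads
    tmp <- cf$r_pref; cf$r_pref <- cf$r_oppo; cf$r_oppo <- tmp
    cf$theta_pref <- cf$theta_pref + 180
  }
  cf$theta_pref <- cf$theta_pref %% 360
  structure(
    list(estimate = tibble(r_offset = cf$r_offset, r_pref = cf$r_pref,
                           r_oppo = cf$r_oppo, theta_pref = cf$theta_pref,
                           sigma = cf$sigma),
         residual_rms = sqrt(best$rss / length(y)),
         converged = TRUE,
         data = means,
         gosi = gosi(means)),
    class = "tuning_fit"
  )
}

#' @export
print.tuning_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<tuning_fit> fit failed\n")
    return(invisible(x))
  }
  e <- x$estimate
  cat(sprintf(
    "<tuning_fit> theta_pref %.1f deg, sigma %.1f deg, R_pref %.3f, R_oppo %.3f, offset %.3f\n",
    e$theta_pref, e$sigma, e$r_pref, e$r_oppo, e$r_offset))
  cat(sprintf("  residual RMS %.4g, gOSI %.3f\n", x$residual_rms, x$gosi))
  invisible(x)
}

#' @export
tidy.tuning_fit <- function(x, ...) {
  if (!x$converged) return(tibble())
  tidyr::pivot_longer(x$estimate, dplyr::everything(),
                      names_to = "term", values_to = "estimate")
}

#' @export
glance.tuning_fit <- function(x, ...) {
  tibble(converged = x$converged, residual_rms = x$residual_rms,
         gosi = x$gosi, n_directions = nrow(x$data))
}

#' Global orientation-selectivity index
#'
#' `gOSI = | sum_k R(theta_k) exp(2 i theta_k) | / sum_k R(theta_k)`, the
#' modulus of the orientation (2-theta) phasor mean of the per-direction
#' responses. Negative mean responses are floored at zero before the sums
#' so the index stays in [0, 1]. Responses uniform across direction give
#' 0; a single responsive direction gives 1; equal responses 180 degrees
#' apart give 1 and 90 degrees apart give 0.
#'
#' @param responses Tibble with `direction` (degrees) and `response`
#'   columns (per-direction means, or per-trial rows which are averaged),
#'   or a numeric vector of responses with directions in `directions`.
#' @param directions Directions (degrees) when `responses` is a vector.
#' @return Scalar in [0, 1]; `NA` (with a warning) if all responses are 0.
#' @examples
#' gosi(c(1, rep(0, 11)), seq(0, 330, 30)) # 1
#' gosi(rep(1, 12), seq(0, 330, 30))       # 0
#' @export
gosi <- function(responses, directions = NULL) {
  if (is.data.frame(responses)) {
    means <- responses |>
      dplyr::group_by(.data$direction) |>
      dplyr::summarise(response = mean(.data$response), .groups = "drop")
    r <- means$response
    th <- means$direction
  } else {
    r <- responses
    th <- directions
  }
  stopifnot(length(r) == length(th))
  r <- pmax(r, 0)
  if (sum(r) == 0) {
    warning("all responses are zero; gOSI undefined")
    return(NA_real_)
  }
  Mod(sum(r * exp(2i * th * pi / 180))) / sum(r)
}

#' Dominant orientation of a population of preferred directions
#'
#' Folds preferred directions into the 0-180 degree orientation domain,
#' histograms them, and fits a wrapped-Gaussian-plus-offset to the bin
#' counts by least squares (multi-started over bin centres). Reports the
#' peak centre and FWHM. If the Gaussian explains less than
#' `min_gain` of the flat model's residual sum of squares, the histogram
#' is declared to have no dominant peak.
#'
#' @param theta_pref Preferred directions in degrees (any range).
#' @param bin_width Histogram bin width in degrees (default 15).
#' @param min_gain Minimum fractional RSS reduction vs the flat model
#'   (default 0.3).
#' @return One-row tibble: `center`, `fwhm`, `dominant` (logical),
#'   `n`.
#' @export
dominant_orientation <- function(theta_pref, bin_width = 15, min_gain = 0.3) {
  stopifnot(length(theta_pref) >= 5)
  ori <- theta_pref %% 180
  breaks <- seq(0, 180, by = bin_width)
  counts <- as.vector(table(cut(ori, breaks, include.lowest = TRUE)))
  centers <- breaks[-1] - bin_width / 2
  rss_flat <- sum((counts - mean(counts))^2)
  if (rss_flat == 0) {
    return(tibble(center = NA_real_, fwhm = NA_real_, dominant = FALSE,
                  n = length(ori)))
  }
  wrap90 <- function(x) { # orientation domain wraps at 180
    out <- (x + 90) %% 180 - 90
    out
  }
  best <- NULL
  for (c0 in centers) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        counts ~ a + b * exp(-wrap90(centers - c0f)^2 / (2 * s^2)),
        start = list(a = min(counts), b = max(counts) - min(counts),
                     c0f = c0, s = 25),
        lower = c(0, 0, -Inf, bin_width / 2.355),
        upper = c(Inf, Inf, Inf, 90),
        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best) || (1 - best$rss / rss_flat) < min_gain) {
    return(tibble(center = NA_real_, fwhm = NA_real_, dominant = FALSE,
                  n = length(ori)))
  }
  cf <- coef(best$fit)
  tibble(center = cf[["c0f"]] %% 180,
         fwhm = 2 * sqrt(2 * log(2)) * cf[["s"]],
         dominant = TRUE, n = length(ori))
}

#' End-to-end tuning analysis of a session
#'
#' Convenience pipeline: dF/F0, evoked responses, selectivity test per
#' ROI, Eq.-style tuning fits for selective ROIs, and gOSI for every ROI.
#'
#' @param traces `roi_traces` from [generate_session()] or read from file.
#' @param schedule The session's schedule (default: traces attribute).
#' @param threshold Transient threshold (default 0.2).
#' @param alpha Selectivity significance level (default 0.05).
#' @return Tibble, one row per ROI: `roi`, `p_value`, `selective`,
#'   `responsive` (any transient), `gosi`, and fit columns (`theta_pref`,
#'   `sigma`, `r_pref`, `r_oppo`, `r_offset`; NA when not fitted).
#' @export
analyze_session <- function(traces, schedule = attr(traces, "schedule"),
                            threshold = 0.2, alpha = 0.05) {
  dff <- compute_dff(traces, schedule)
  resp <- evoked_response(dff, threshold = threshold)
  sel <- selectivity_table(resp, alpha = alpha)
  per_roi <- resp |>
    dplyr::group_by(.data$roi) |>
    dplyr::summarise(responsive = any(.data$transient), .groups = "drop") |>
    dplyr::inner_join(sel, by = "roi")
  fits <- lapply(per_roi$roi, function(id) {
    rr <- resp[resp$roi == id, ]
    g <- gosi(rr)
    if (!per_roi$selective[per_roi$roi == id]) {
      return(tibble(roi = id, gosi = g, theta_pref = NA_real_,
                    sigma = NA_real_, r_pref = NA_real_, r_oppo = NA_real_,
                    r_offset = NA_real_))
    }
    ft <- fit_tuning(rr)
    if (!ft$converged) {
      return(tibble(roi = id, gosi = g, theta_pref = NA_real_,
                    sigma = NA_real_, r_pref = NA_real_, r_oppo = NA_real_,
                    r_offset = NA_real_))
    }
    tibble(roi = id, gosi = g, theta_pref = ft$estimate$theta_pref,
           sigma = ft$estimate$sigma, r_pref = ft$estimate$r_pref,
           r_oppo = ft$estimate$r_oppo, r_offset = ft$estimate$r_offset)
  })
  dplyr::inner_join(per_roi, dplyr::bind_rows(fits), by = "roi")
}
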