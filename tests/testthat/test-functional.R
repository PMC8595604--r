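dirs12 <- seq(0, 330, by = 30)

test_that("schedules encode the epoch structure at both frame rates", {
  sg <- stimulus_schedule("gaussian", n_trials = 2, seed = 1)
  sb <- stimulus_schedule("bessel", n_trials = 2, seed = 1)
  expect_equal(attr(sg, "frame_rate_hz"), 3.3)
  expect_equal(attr(sb, "frame_rate_hz"), 1.5)
  expect_equal(attr(sg, "epochs_s"), c(2, 4, 2))
  expect_equal(attr(sb, "epochs_s"), c(4, 6, 2))
  expect_equal(nrow(sg), 24)
  expect_setequal(unique(sg$direction), dirs12)
  # every direction exactly once per repetition block
  expect_equal(as.vector(table(sg$direction[1:12])), rep(1, 12))
  fmap <- besselao:::schedule_frame_map(sb)
  expect_equal(nrow(fmap), attr(sb, "n_frames"))
  expect_setequal(unique(fmap$epoch), c("blank_pre", "grating", "blank_post"))
})

test_that("dF/F0 is exact for step traces and flags bad baselines", {
  sched <- stimulus_schedule("gaussian", n_trials = 2, seed = 2)
  fmap <- besselao:::schedule_frame_map(sched)
  f0 <- 100
  val <- ifelse(fmap$epoch == "grating", 1.2 * f0, f0)
  traces <- tibble::tibble(roi = 1L, frame = fmap$frame, value = val)
  dff <- compute_dff(traces, sched)
  expect_equal(unique(round(dff$dff[dff$epoch == "grating"], 10)), 0.2)
  expect_equal(unique(round(dff$dff[dff$epoch == "blank_pre"], 10)), 0)
  # constant trace -> dff identically zero
  tr0 <- tibble::tibble(roi = 1L, frame = fmap$frame, value = f0)
  expect_true(all(compute_dff(tr0, sched)$dff == 0))
  # non-positive baseline excluded with a warning
  trbad <- dplyr::bind_rows(
    tibble::tibble(roi = 1L, frame = fmap$frame, value = val),
    tibble::tibble(roi = 2L, frame = fmap$frame, value = 0))
  expect_warning(dffb <- compute_dff(trbad, sched), "non-positive")
  expect_false(2L %in% dffb$roi)
})

test_that("evoked responses average the grating window and classify transients", {
  sched <- stimulus_schedule("gaussian", n_trials = 2, seed = 2)
  fmap <- besselao:::schedule_frame_map(sched)
  f0 <- 100
  # one direction responds with a 0.3 plateau
  hot <- sched$trial[sched$direction == 90]
  val <- ifelse(fmap$epoch == "grating" & fmap$trial %in% hot,
                1.3 * f0, f0)
  traces <- tibble::tibble(roi = 1L, frame = fmap$frame, value = val)
  resp <- evoked_response(compute_dff(traces, sched))
  r90 <- resp$response[resp$direction == 90]
  expect_equal(r90, rep(0.3, 2), tolerance = 1e-10)
  expect_true(all(resp$transient[resp$direction == 90]))
  expect_true(all(!resp$transient[resp$direction != 90]))
  # all-zero responses: no transients
  resp0 <- evoked_response(compute_dff(
    tibble::tibble(roi = 1L, frame = fmap$frame, value = f0), sched))
  expect_true(all(resp0$response == 0))
  expect_false(any(resp0$transient))
})

test_that("the ANOVA selectivity test handles degenerate and strong cases", {
  set.seed(5)
  flat <- tibble::tibble(direction = rep(dirs12, each = 5),
                         response = 0.2)
  out <- selectivity_test(flat)
  expect_false(out$selective)
  # one direction elevated by 10 pooled SDs
  r <- rnorm(60, 0.2, 0.05)
  r[rep(dirs12, each = 5) == 90] <- r[rep(dirs12, each = 5) == 90] + 0.5
  strong <- tibble::tibble(direction = rep(dirs12, each = 5), response = r)
  outs <- selectivity_test(strong)
  expect_true(outs$selective)
  expect_lt(outs$p_value, 1e-3)
  expect_error(selectivity_test(flat[seq(1, 60, by = 5), ]), "2 trials")
})

test_that("gOSI analytic values are exact and invariances hold", {
  expect_equal(gosi(c(1, rep(0, 11)), dirs12), 1)
  expect_equal(gosi(rep(1, 12), dirs12), 0, tolerance = 1e-12)
  expect_equal(gosi(as.numeric(dirs12 %in% c(30, 210)), dirs12), 1)
  expect_equal(gosi(as.numeric(dirs12 %in% c(0, 90)), dirs12), 0,
               tolerance = 1e-12)
  # scale invariance and 180-degree-pair invariance
  set.seed(6)
  r <- runif(12)
  expect_equal(gosi(r, dirs12), gosi(7.3 * r, dirs12))
  ropp <- r + r[c(7:12, 1:6)] # add the 180-degree partner proportionally
  expect_equal(Arg(sum(pmax(r, 0) * exp(2i * dirs12 * pi / 180))),
               Arg(sum(pmax(ropp, 0) * exp(2i * dirs12 * pi / 180))),
               tolerance = 1e-9)
  # negative responses floored, all-zero flagged
  expect_warning(g0 <- gosi(rep(0, 12), dirs12), "undefined")
  expect_true(is.na(g0))
})

test_that("tuning fits recover noiseless parameters to under 1%", {
  truth <- list(r_offset = 0, r_pref = 1, r_oppo = 0.5,
                theta_pref = 90, sigma = 30)
  resp <- tibble::tibble(
    direction = dirs12,
    response = tuning_curve(dirs12, truth$r_offset, truth$r_pref,
                            truth$r_oppo, truth$theta_pref, truth$sigma))
  ft <- fit_tuning(resp)
  expect_true(ft$converged)
  expect_lt(abs(ft$estimate$theta_pref - 90), 0.9)
  expect_lt(abs(ft$estimate$sigma - 30) / 30, 0.01)
  expect_lt(abs(ft$estimate$r_pref - 1), 0.01)
  expect_lt(abs(ft$estimate$r_oppo - 0.5) / 0.5, 0.01)
  # canonical form even when generated with swapped peaks
  resp2 <- tibble::tibble(
    direction = dirs12,
    response = tuning_curve(dirs12, 0, 0.4, 0.9, 45, 25))
  ft2 <- fit_tuning(resp2)
  expect_gt(ft2$estimate$r_pref, ft2$estimate$r_oppo)
  expect_lt(abs(besselao::ang_wrap(ft2$estimate$theta_pref - 225)), 1)
  # tidy/glance interfaces
  expect_setequal(tidy(ft)$term,
                  c("r_offset", "r_pref", "r_oppo", "theta_pref", "sigma"))
  expect_true(glance(ft)$converged)
})

test_that("dominant orientation finds concentrated peaks and rejects flat histograms", {
  expect_error(dominant_orientation(c(10, 20)), "length")
  conc <- dominant_orientation(rep(144, 40))
  expect_true(conc$dominant)
  expect_equal(conc$center, 144, tolerance = 8)
  set.seed(8)
  # sample from a wrapped Gaussian, centre 63, FWHM 46
  th <- (rnorm(40, 63, 46 / 2.3548)) %% 180
  samp <- dominant_orientation(th)
  expect_true(samp$dominant)
  expect_lt(abs(samp$center - 63), 10)
  flat <- dominant_orientation(seq(0.1, 179.9, length.out = 120))
  expect_false(flat$dominant)
})

test_that("generated sessions are reproducible and analyzable end to end", {
  sched <- stimulus_schedule("bessel", n_trials = 8, seed = 4)
  truth <- random_tuning_truth(n_roi = 24, responsive_fraction = 0.6,
                               seed = 9)
  s1 <- generate_session(truth, sched, seed = 10)
  s2 <- generate_session(truth, sched, seed = 10)
  expect_identical(s1$value, s2$value)
  # zero-noise, zero-tuning traces are flat
  flat_truth <- tibble::tibble(roi = 1, r_offset = 0, r_pref = 0,
                               r_oppo = 0, theta_pref = 0, sigma = 30)
  flat <- generate_session(flat_truth, sched, noise_sd = 0,
                           trial_jitter_sd = 0, seed = 1)
  expect_equal(var(flat$value), 0)
  # full pipeline: responsive fraction near truth, tuned ROIs selective
  out <- analyze_session(s1)
  frac <- mean(out$responsive)
  p_true <- mean(truth$responsive)
  ci <- qbinom(c(0.005, 0.995), nrow(truth), p_true) / nrow(truth)
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
  tuned <- out[out$roi %in% truth$roi[truth$responsive], ]
  expect_gt(mean(tuned$selective), 0.8)
  # recovered preferred directions match the ground truth
  ok <- !is.na(out$theta_pref) & truth$responsive
  err <- abs(besselao::ang_wrap(out$theta_pref[ok] - truth$theta_pref[ok]))
  expect_lt(median(err), 10)
})

test_that("lower SNR monotonically suppresses transient detection and gOSI", {
  sched <- stimulus_schedule("bessel", n_trials = 8, seed = 4)
  truth <- random_tuning_truth(n_roi = 20, responsive_fraction = 1, seed = 2)
  stats <- lapply(c(1, 0.4, 0.15), function(gain) {
    tr <- truth
    tr$r_pref <- tr$r_pref * gain
    tr$r_oppo <- tr$r_oppo * gain
    tr$r_offset <- tr$r_offset * gain
    out <- analyze_session(generate_session(tr, sched, seed = 11))
    c(frac = mean(out$responsive), gosi = median(out$gosi, na.rm = TRUE))
  })
  fracs <- vapply(stats, `[[`, 0, "frac")
  gosis <- vapply(stats, `[[`, 0, "gosi")
  expect_true(all(diff(fracs) <= 0))
  expect_lt(gosis[3], gosis[1])
})
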