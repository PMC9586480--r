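# Baseline/noise model, LOESS smoothing, maxima detection, peak/front
# tracking and time-zero conventions.

test_that("baseline model encodes the noise-band formulas", {
  bm <- baseline_model(100, 5)
  expect_equal(bm$noise_upper, 109.8)
  expect_equal(bm$noise_lower, 90.2)
  expect_equal(bm$front_threshold, 105)
  bm0 <- baseline_model(80, 0)
  expect_equal(bm0$noise_upper, 80)
  expect_equal(bm0$noise_lower, 80)
})

test_that("estimate_baseline recovers generator parameters", {
  p <- small_local_params(noise_sd = 6, baseline = 120, seed = 9L)
  g <- gen_local_wave_stack(p)
  geom <- scan_geometry("radial_point", points = p$origin, n_lines = 40,
                        line_length = 120)
  ps <- scan_stack(g$stack, geom)
  bl <- estimate_baseline(ps, pre_frames = 1)
  expect_equal(bl$baseline, 120, tolerance = 0.01)
  # zero-noise input under the pre-frames scope collapses the band
  p0 <- small_local_params(baseline = 100)
  ps0 <- scan_stack(gen_local_wave_stack(p0)$stack, geom)
  bl0 <- estimate_baseline(ps0, pre_frames = 1, sd_scope = "pre_frames")
  expect_equal(bl0$noise_upper, bl0$baseline, tolerance = 1e-9)
  expect_error(estimate_baseline(ps, pre_frames = integer(0)), "non-empty")
  expect_error(estimate_baseline(ps, pre_frames = 1,
                                 distance_range = c(1e5, 2e5)),
               "empty pre-response region")
})

test_that("smooth_profile reproduces polynomials and respects noise", {
  d <- seq(0, 100, by = 1)
  y <- 3 + 0.5 * d
  sm <- smooth_profile(d, y, span = 0.5)
  expect_equal(sm$fitted, y, tolerance = 1e-6)
  # span = 1 on quadratic data: near-global quadratic fit
  yq <- 2 + 0.1 * d^2
  smq <- smooth_profile(d, yq, span = 1)
  expect_equal(smq$fitted, yq, tolerance = 1e-6)
  # pure noise around a constant stays within the noise band
  set.seed(31)
  yn <- 50 + stats::rnorm(length(d), sd = 2)
  smn <- smooth_profile(d, yn, span = 0.75)
  expect_true(all(abs(smn$fitted - 50) < 2 * 1.96))
  expect_error(smooth_profile(d[1:5], y[1:5]), "at least 10")
  expect_error(smooth_profile(d, y, span = 0), "span")
})

test_that("find_local_maxima honours window and boundary rules", {
  d <- seq(0, 400, by = 2)
  y <- gauss_profile(d, 200, 10, 20)
  mx <- find_local_maxima(d, y, window = 5)
  expect_equal(nrow(mx), 1L)
  expect_equal(mx$distance, 200, tolerance = 2)
  # monotone curve: no interior maxima
  expect_equal(nrow(find_local_maxima(d, rev(sort(y)), window = 5)), 0L)
  # two equal bumps are both returned
  y2 <- gauss_profile(d, 100, 10, 15) + gauss_profile(d, 300, 10, 15)
  mx2 <- find_local_maxima(d, y2, window = 5)
  expect_equal(nrow(mx2), 2L)
  expect_equal(mx2$distance, c(100, 300), tolerance = 2)
  expect_error(find_local_maxima(d, y, window = 0), "window")
})

test_that("track_peak applies intensity + monotone-progression selection", {
  d <- seq(0, 400, by = 2)
  bl <- baseline_model(0, 1)
  # frame 1: single bump at 200; frame 2: brighter bump behind (at 100)
  # and dimmer bump ahead (at 300) -> the outer one must win
  prof <- cbind(gauss_profile(d, 200, 50, 20),
                gauss_profile(d, 100, 80, 20) + gauss_profile(d, 300, 40, 20))
  ps <- make_profile_set(prof, distances = d, times = c(0, 1),
                         pixel_size = 2)
  tk <- track_peak(ps, bl, span = 0.15, window = 5)
  expect_equal(tk$peak_um, c(200, 300), tolerance = 4)
  expect_equal(tk$snr, tk$peak_intensity / bl$noise_upper)
  # a constant stack yields an empty track with a warning
  psc <- make_profile_set(matrix(5, 60, 3))
  blc <- baseline_model(5, 0)
  expect_warning(tkc <- track_peak(psc, blc), "empty track")
  expect_true(all(is.na(tkc$peak_um)))
})

test_that("peak distances are nondecreasing on tracked synthetic waves", {
  p <- small_local_params(noise_sd = 10, seed = 17L, D = 60)
  g <- gen_local_wave_stack(p)
  geom <- scan_geometry("radial_point", points = p$origin, n_lines = 60,
                        line_length = 120)
  ps <- scan_stack(g$stack, geom)
  bl <- estimate_baseline(ps, pre_frames = 1)
  tk <- track_wave(ps, bl, span = 0.15)
  pk <- tk$peak_um[is.finite(tk$peak_um)]
  expect_gt(length(pk), 10)
  expect_true(all(diff(pk) >= -1e-9))
  # front >= peak wherever both are defined
  both <- is.finite(tk$peak_um) & is.finite(tk$front_um)
  expect_true(all(tk$front_um[both] >= tk$peak_um[both] - 1e-9))
})

test_that("track_front finds the outermost threshold crossing", {
  d <- seq(0, 400, by = 2)
  bl <- baseline_model(10, 1)
  step <- ifelse(d <= 300, 10 + 10 * 1, 10)  # step of height 10 sd ending 300
  ps <- make_profile_set(cbind(step), distances = d, times = 0)
  fr <- track_front(ps, bl)
  expect_equal(fr, 300, tolerance = 2)
  # interior dip below threshold does not truncate the outermost crossing
  dip <- step; dip[d > 100 & d < 140] <- 10
  expect_equal(track_front(make_profile_set(cbind(dip), distances = d,
                                            times = 0), bl), 300,
               tolerance = 2)
  # all-below-threshold profile is missing
  ps0 <- make_profile_set(cbind(rep(10, length(d))), distances = d, times = 0)
  expect_true(is.na(track_front(ps0, bl)))
})

test_that("tracking is invariant to a constant intensity shift after re-estimation", {
  p <- small_local_params(noise_sd = 5, seed = 23L)
  g <- gen_local_wave_stack(p)
  geom <- scan_geometry("radial_point", points = p$origin, n_lines = 40,
                        line_length = 120)
  ps <- scan_stack(g$stack, geom)
  ps_shift <- ps
  ps_shift$intensity <- ps$intensity + 500
  bl <- estimate_baseline(ps, pre_frames = 1)
  bls <- estimate_baseline(ps_shift, pre_frames = 1)
  tk <- track_wave(ps, bl, span = 0.15)
  tks <- track_wave(ps_shift, bls, span = 0.15)
  expect_equal(tk$peak_um, tks$peak_um)
  expect_equal(tk$front_um, tks$front_um)
})

test_that("set_time_zero implements both conventions", {
  tk <- structure(
    data.frame(t_s = seq(0, 18, by = 2),
               peak_um = c(rep(20, 5), 30, 45, 60, 80, 100),
               peak_intensity = 1, snr = 1),
    class = c("wave_track", "data.frame"))
  # stimulus frame 1 is the identity
  expect_equal(set_time_zero(tk, "stimulus_frame", stimulus_frame = 1)$t_s,
               tk$t_s)
  z <- set_time_zero(tk, "stimulus_frame", stimulus_frame = 3)
  expect_equal(z$t_s[1], 0)
  expect_equal(nrow(z), 8)
  # first progression: stationary for 5 frames, then advances at frame 6
  fp <- set_time_zero(tk, "first_progression")
  expect_equal(fp$t_s[1], 0)
  expect_equal(fp$peak_um[1], 30)
  flat <- tk; flat$peak_um <- rep(20, 10)
  expect_error(set_time_zero(flat, "first_progression"), "never progresses")
  expect_error(set_time_zero(tk, "stimulus_frame", stimulus_frame = 99),
               "outside")
})

test_that("noiseless front obeys Einstein-Smoluchowski scaling", {
  # front must not saturate at the scan-line end, hence the modest D
  p <- small_local_params(D = 40)
  g <- gen_local_wave_stack(p)
  geom <- scan_geometry("radial_point", points = p$origin, n_lines = 60,
                        line_length = 120)
  ps <- scan_stack(g$stack, geom)
  bl <- estimate_baseline(ps, pre_frames = 1)
  fr <- track_front(ps, bl)
  tt <- ps$times
  ok <- is.finite(fr) & tt > 2 & fr > 0
  slope <- stats::coef(stats::lm(log(fr[ok]) ~ log(tt[ok])))[2]
  expect_gt(unname(slope), 0.45)
  expect_lt(unname(slope), 0.55)
})

test_that("wave tracks round-trip through CSV", {
  p <- small_local_params()
  g <- gen_local_wave_stack(p)
  geom <- scan_geometry("radial_point", points = p$origin, n_lines = 20,
                        line_length = 100)
  ps <- scan_stack(g$stack, geom)
  tk <- track_wave(ps, estimate_baseline(ps, pre_frames = 1), span = 0.3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_wave_track(tk, f)
  tk2 <- read_wave_track(f)
  expect_equal(tk2$peak_um, tk$peak_um)
  expect_equal(tk2$front_um, tk$front_um)
})
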