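# Traveling-peak and front tracking on distance-resolved intensity profiles:
# LOESS smoothing, baseline/noise estimation, local-maxima detection with a
# monotone-progression selection rule, and threshold-crossing fronts.

#' LOESS-smooth an intensity profile
#'
#' Locally weighted polynomial regression (tricube weights, local degree 2 by
#' default) on a single distance profile. `surface = "direct"` is used so
#' that smooth inputs are reproduced to numerical precision.
#'
#' @param distances,intensities numeric vectors (>= 10 points).
#' @param span smoothing span, in (0, 1].
#' @param degree local polynomial degree (1 or 2).
#' @return `list(fitted, fun)`: fitted values on the input grid and a
#'   function evaluable at any distance inside the data range.
#' @export
smooth_profile <- function(distances, intensities, span = 0.75, degree = 2) {
  ok <- is.finite(distances) & is.finite(intensities)
  x <- distances[ok]; y <- intensities[ok]
  if (length(x) < 10) stop("need at least 10 finite points")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (span * length(x) < degree + 2) {
    stop("span covers fewer points than the local fit requires")
  }
  fit <- stats::loess(y ~ x, span = span, degree = degree,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  fitted_full <- rep(NA_real_, length(distances))
  fitted_full[ok] <- fit$fitted
  list(fitted = fitted_full,
       fun = function(newd) stats::predict(fit, data.frame(x = newd)),
       residual_sd = stats::sd(fit$residuals),
       loess = fit)
}

#' Baseline noise model
#'
#' Encodes the noise-band formulas: `noise = baseline +/- 1.96 * sd_bar` and
#' the front threshold `baseline + sd_bar`, where `sd_bar` is the average SD
#' of the averaged intensity profile.
#'
#' @param baseline mean pre-response intensity, a.u.
#' @param sd_bar average SD of the averaged profile, a.u. (>= 0).
#' @param noise_multiplier width of the noise band in SDs (default 1.96).
#' @return a `baseline_model`.
#' @export
baseline_model <- function(baseline, sd_bar, noise_multiplier = 1.96) {
  if (sd_bar < 0) stop("sd_bar must be >= 0")
  structure(list(baseline = baseline, sd_bar = sd_bar,
                 noise_multiplier = noise_multiplier,
                 noise_upper = baseline + noise_multiplier * sd_bar,
                 noise_lower = baseline - noise_multiplier * sd_bar,
                 front_threshold = baseline + sd_bar),
            class = "baseline_model")
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf(
    "<baseline_model> baseline %.4g, sd_bar %.4g, noise [%.4g, %.4g], front threshold %.4g\n",
    x$baseline, x$sd_bar, x$noise_lower, x$noise_upper, x$front_threshold))
  invisible(x)
}

#' Estimate the baseline noise model from a profile set
#'
#' The baseline is the mean intensity over a pre-response region (frames
#' before the wave arrives, optionally restricted in distance); `sd_bar` is
#' the mean over time points of the SD across distance of the averaged
#' profile. With the default `sd_scope = "all_frames"` ("across the whole
#' dataset") every time point contributes, signal frames included, which
#' puts the front threshold well above the noise floor; because the wave
#' foot is temporally sharp this raised threshold still crosses within
#' about a pixel of the low-threshold front, and it makes the
#' outermost-crossing rule robust to noise. `sd_scope = "pre_frames"`
#' restricts the SD to the pre-response frames (a pure noise band).
#'
#' @param ps a `profile_set`.
#' @param pre_frames indices of pre-response time points (1-based).
#' @param distance_range optional `c(min, max)` um restriction.
#' @param sd_scope `"all_frames"` (default) or `"pre_frames"`.
#' @param noise_multiplier see [baseline_model()].
#' @return a [baseline_model()].
#' @export
estimate_baseline <- function(ps, pre_frames, distance_range = NULL,
                              sd_scope = c("all_frames", "pre_frames"),
                              noise_multiplier = 1.96) {
  sd_scope <- match.arg(sd_scope)
  stopifnot(inherits(ps, "profile_set"))
  if (length(pre_frames) < 1 ||
      any(pre_frames < 1 | pre_frames > ncol(ps$intensity))) {
    stop("pre_frames must be a non-empty set of valid frame indices")
  }
  drows <- if (is.null(distance_range)) {
    seq_along(ps$distances)
  } else {
    which(ps$distances >= distance_range[1] & ps$distances <= distance_range[2])
  }
  if (length(drows) == 0) stop("empty pre-response region")
  sub <- ps$intensity[drows, pre_frames, drop = FALSE]
  baseline <- mean(sub, na.rm = TRUE)
  sd_cols <- if (sd_scope == "pre_frames") {
    sub
  } else {
    ps$intensity[drows, , drop = FALSE]
  }
  sd_bar <- mean(apply(sd_cols, 2, stats::sd, na.rm = TRUE), na.rm = TRUE)
  baseline_model(baseline, sd_bar, noise_multiplier)
}

#' Local maxima of a curve on a grid
#'
#' A point is a maximum when strictly greater than every neighbour within
#' `window` grid steps; boundary points (within `window` of either end) are
#' never maxima. Exact ties (symmetric plateaus) are broken by a negligible
#' deterministic ramp added before comparison, which also keeps
#' numerical-precision wiggles on flat curves from qualifying.
#'
#' @param x grid positions. @param y curve values. @param window half-width
#'   in grid steps (>= 1).
#' @return `data.frame(index, distance, intensity)` (possibly empty).
#' @export
find_local_maxima <- function(x, y, window = 5) {
  if (window < 1) stop("window must be >= 1")
  n <- length(y)
  idx <- integer(0)
  rng <- diff(range(y, finite = TRUE))
  yr <- y + seq_len(n) * 1e-9 * max(1, rng) / n  # tie-breaking ramp
  if (n >= 2 * window + 1) {
    for (i in (window + 1):(n - window)) {
      nb <- yr[max(1, i - window):min(n, i + window)]
      if (all(is.finite(nb)) && yr[i] > max(nb[-(window + 1)])) {
        idx <- c(idx, i)
      }
    }
  }
  data.frame(index = idx, distance = x[idx], intensity = y[idx])
}

new_wave_track <- function(df, time_zero_rule = "acquisition_start") {
  structure(df, class = c("wave_track", "data.frame"),
            time_zero_rule = time_zero_rule)
}

#' Track the traveling peak across time points
#'
#' Per time point the averaged profile is LOESS-smoothed; among local maxima
#' whose intensity exceeds the upper noise band, the selected peak maximizes
#' intensity subject to its distance being no less than the previously
#' selected peak distance (ties broken toward the smaller distance). Time
#' points with no qualifying maximum yield missing entries. The
#' signal-to-noise ratio is peak intensity / upper noise value.
#'
#' @param ps a `profile_set`. @param baseline a [baseline_model()].
#' @param span LOESS span. @param window maxima window (grid steps).
#' @return a `wave_track` data frame with columns `t_s`, `peak_um`,
#'   `peak_intensity`, `snr`.
#' @export
track_peak <- function(ps, baseline, span = 0.75, window = 5) {
  stopifnot(inherits(ps, "profile_set"), inherits(baseline, "baseline_model"))
  nt <- length(ps$times)
  peak_um <- peak_int <- rep(NA_real_, nt)
  prev <- -Inf
  for (ti in seq_len(nt)) {
    y <- ps$intensity[, ti]
    if (sum(is.finite(y)) < 10) next
    sm <- smooth_profile(ps$distances, y, span = span)
    mx <- find_local_maxima(ps$distances, sm$fitted, window = window)
    # strict exceedance with a relative margin so numerical wiggles on flat
    # profiles never qualify when the noise band collapses (sd_bar = 0)
    eps <- 1e-6 * max(1, abs(baseline$noise_upper))
    mx <- mx[mx$intensity > baseline$noise_upper + eps &
               mx$distance >= prev - 1e-9, , drop = FALSE]
    if (nrow(mx) == 0) next
    best <- mx[order(-mx$intensity, mx$distance)[1], ]
    peak_um[ti] <- best$distance
    peak_int[ti] <- best$intensity
    prev <- best$distance
  }
  if (all(is.na(peak_um))) {
    warning("no time point has a peak above the noise band; empty track")
  }
  new_wave_track(data.frame(
    t_s = ps$times, peak_um = peak_um, peak_intensity = peak_int,
    snr = peak_int / baseline$noise_upper))
}

#' Track the wave front across time points
#'
#' The front at each time point is the outermost distance at which the
#' profile still exceeds the front threshold (`baseline + sd_bar`), so
#' interior noise dips do not truncate it; missing when the profile never
#' exceeds the threshold. By default the raw averaged profile is used (the
#' front definition refers to the average profile); `smooth_span` switches
#' to the LOESS curve.
#'
#' @param ps a `profile_set`. @param baseline a [baseline_model()].
#' @param smooth_span `NULL` for the raw profile, else a LOESS span.
#' @return numeric vector of front distances (um), one per time point.
#' @export
track_front <- function(ps, baseline, smooth_span = NULL) {
  stopifnot(inherits(ps, "profile_set"), inherits(baseline, "baseline_model"))
  thr <- baseline$front_threshold + 1e-9 * max(1, abs(baseline$front_threshold))
  vapply(seq_along(ps$times), function(ti) {
    y <- ps$intensity[, ti]
    if (!is.null(smooth_span) && sum(is.finite(y)) >= 10) {
      y <- smooth_profile(ps$distances, y, span = smooth_span)$fitted
    }
    above <- which(is.finite(y) & y > thr)
    if (length(above) == 0) NA_real_ else ps$distances[max(above)]
  }, numeric(1))
}

#' Track peak and front together
#'
#' Convenience wrapper producing the full wave track (peak, SNR and front
#' per time point).
#'
#' @inheritParams track_peak
#' @param front_smooth_span passed to [track_front()] as `smooth_span`.
#' @return a `wave_track` with columns `t_s`, `peak_um`, `peak_intensity`,
#'   `snr`, `front_um`.
#' @export
track_wave <- function(ps, baseline, span = 0.75, window = 5,
                       front_smooth_span = NULL) {
  tk <- track_peak(ps, baseline, span = span, window = window)
  tk$front_um <- track_front(ps, baseline, smooth_span = front_smooth_span)
  tk
}

#' Re-express track times relative to a time-zero convention
#'
#' `"stimulus_frame"` sets zero at the acquisition time of a given frame
#' (the frame where the needle hits); `"first_progression"` sets zero at the
#' first time point where the tracked peak (or front) moves forward from its
#' initial position. Entries before zero are dropped.
#'
#' @param track a `wave_track`.
#' @param rule `"stimulus_frame"` or `"first_progression"`.
#' @param stimulus_frame 1-based frame index for `"stimulus_frame"`.
#' @param on column watched by `"first_progression"` (`"peak_um"` or
#'   `"front_um"`).
#' @param tol minimum forward movement (um) counting as progression.
#' @return the shifted `wave_track`.
#' @export
set_time_zero <- function(track, rule = c("stimulus_frame",
                                          "first_progression"),
                          stimulus_frame = 1L, on = "peak_um", tol = 1e-9) {
  rule <- match.arg(rule)
  stopifnot(inherits(track, "wave_track"))
  if (rule == "stimulus_frame") {
    if (stimulus_frame < 1 || stimulus_frame > nrow(track)) {
      stop("stimulus_frame outside the track")
    }
    t0 <- track$t_s[stimulus_frame]
  } else {
    d <- track[[on]]
    idx <- which(is.finite(d))
    if (length(idx) < 2) stop("track too short to find progression")
    adv <- idx[-1][diff(d[idx]) > tol]
    if (length(adv) == 0) stop("track never progresses forward")
    t0 <- track$t_s[adv[1]]
  }
  out <- track[track$t_s >= t0, , drop = FALSE]
  out$t_s <- out$t_s - t0
  rownames(out) <- NULL
  new_wave_track(as.data.frame(out), time_zero_rule = rule)
}

#' Write / read a wave track CSV
#'
#' Columns `t_s`, `peak_um`, `peak_intensity`, `snr` and (when present)
#' `front_um`.
#'
#' @param track a `wave_track`. @param path file path.
#' @export
write_wave_track <- function(track, path) {
  utils::write.csv(as.data.frame(track), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_wave_track
#' @export
read_wave_track <- function(path) {
  new_wave_track(utils::read.csv(path))
}
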