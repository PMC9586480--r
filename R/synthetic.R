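# Synthetic fluorescence waves with known ground truth.
#
# The generators emulate the acquisition regime the analysis targets:
# frames every 2 s, 16-bit grayscale, a wave of indicator fluorescence that
# travels outward from a point (wound), from a line (vein), or along the
# vasculature, on top of a constant baseline with additive Gaussian noise.

#' Parameters for a locally propagating (radial) wave
#'
#' Describes a diffusion-driven wave of a channel-activating agonist released
#' at a wound point at t = 0. Each pixel "activates" when the local agonist
#' concentration first exceeds `activation_threshold`; its fluorescence then
#' follows a rise/decay response, producing a traveling peak behind an
#' advancing front.
#'
#' Two front conventions are available. `front_mode = "sqrt"` (default)
#' prescribes the activation time directly from the mean-squared-displacement
#' law, `t_act(r) = r^2 / (front_coef * D)`, so the true front is exactly
#' `r(t) = sqrt(front_coef * D * t)` — the form every downstream fit assumes.
#' `front_mode = "kernel"` derives activation from the 2D instantaneous
#' point-source kernel (see [agonist_concentration()]); its threshold-crossing
#' front is `sqrt(4 D t log(K/t))`, which is not a pure power law.
#'
#' @param D diffusion coefficient, um^2/s (default 116, the glutamate value
#'   the package's fits are designed to recover).
#' @param source_mass released amount, a.u. (kernel mode only).
#' @param activation_threshold concentration triggering the response, a.u.
#' @param rise,decay fluorescence response time constants, s.
#' @param amplitude peak fluorescence response above baseline, a.u.
#' @param baseline resting intensity, a.u.
#' @param noise_sd additive Gaussian noise SD per pixel per frame, a.u.
#' @param pixel_size um/px. @param frame_interval s (default 2).
#' @param n_frames number of frames. @param image_size side length, px.
#' @param origin wave origin `(x, y)` in 0-based px; default image centre.
#' @param front_mode `"sqrt"` or `"kernel"` (see Details).
#' @param front_coef coefficient c in `r = sqrt(c * D * t)` for sqrt mode
#'   (default 6, the 3D MSD convention used by the diffusion fits).
#' @param seed integer RNG seed; all randomness flows from it.
#' @return a validated parameter list of class `local_wave_params`.
#' @export
local_wave_params <- function(D = 116, source_mass = 8.7e5,
                              activation_threshold = 1,
                              rise = 2, decay = 20, amplitude = 500,
                              baseline = 100, noise_sd = 0,
                              pixel_size = 4, frame_interval = 2,
                              n_frames = 120, image_size = 256,
                              origin = NULL,
                              front_mode = c("sqrt", "kernel"),
                              front_coef = 6, seed = 1L) {
  front_mode <- match.arg(front_mode)
  assert_scalar_pos(D, "D")
  assert_scalar_pos(frame_interval, "frame_interval")
  assert_scalar_pos(pixel_size, "pixel_size")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (decay <= rise) stop("decay must exceed rise")
  origin <- origin %||% rep((image_size - 1) / 2, 2)
  if (any(origin < 0) || any(origin > image_size - 1)) {
    stop("origin must lie inside the image")
  }
  structure(list(
    D = D, source_mass = source_mass,
    activation_threshold = activation_threshold,
    rise = rise, decay = decay, amplitude = amplitude,
    baseline = baseline, noise_sd = noise_sd,
    pixel_size = pixel_size, frame_interval = frame_interval,
    n_frames = as.integer(n_frames), image_size = as.integer(image_size),
    origin = origin, front_mode = front_mode, front_coef = front_coef,
    seed = as.integer(seed)), class = "local_wave_params")
}

#' Agonist concentration after an instantaneous point release
#'
#' 2D instantaneous point-source diffusion kernel in the tissue plane:
#' `C(r, t) = M / (4 pi D t) * exp(-r^2 / (4 D t))`.
#'
#' @param r distance from the release point, um (>= 0).
#' @param t time since release, s (> 0).
#' @param params a [local_wave_params()] supplying `D` and `source_mass`.
#' @return concentration, a.u.
#' @export
agonist_concentration <- function(r, t, params) {
  if (any(t <= 0)) stop("t must be > 0")
  if (any(r < 0)) stop("r must be >= 0")
  M <- params$source_mass
  D <- params$D
  M / (4 * pi * D * t) * exp(-r^2 / (4 * D * t))
}

# Normalized difference-of-exponentials fluorescence response; peak value 1
# at tau_peak = log(decay/rise) * rise * decay / (decay - rise).
wave_response <- function(tau, rise, decay) {
  tpk <- log(decay / rise) * rise * decay / (decay - rise)
  nrm <- exp(-tpk / decay) - exp(-tpk / rise)
  out <- numeric(length(tau))
  pos <- which(tau > 0)
  out[pos] <- (exp(-tau[pos] / decay) - exp(-tau[pos] / rise)) / nrm
  dim(out) <- dim(tau)
  out
}

response_peak_delay <- function(rise, decay) {
  log(decay / rise) * rise * decay / (decay - rise)
}

# Activation time as a function of radial distance (um), per front_mode.
# Returns list(t_act = function(r), front_law = function(t)).
.front_laws <- function(params, kernel_dim = 2L) {
  D <- params$D
  if (params$front_mode == "sqrt") {
    cf <- params$front_coef
    list(t_act = function(r) r^2 / (cf * D),
         front_law = function(t) sqrt(cf * D * pmax(t, 0)))
  } else {
    theta <- params$activation_threshold
    M <- params$source_mass
    t_max <- params$n_frames * params$frame_interval
    tg <- seq(params$frame_interval / 50, t_max,
              by = params$frame_interval / 50)
    r2 <- if (kernel_dim == 2L) {
      4 * D * tg * log(M / (4 * pi * D * tg * theta))
    } else {
      4 * D * tg * log(M / (theta * sqrt(4 * pi * D * tg)))
    }
    rg <- cummax(sqrt(pmax(r2, 0)))  # farthest radius ever activated
    front <- stats::approxfun(c(0, tg), c(0, rg), rule = 2)
    r_max <- max(rg)
    t_act <- function(r) {
      out <- rep(Inf, length(r))
      ok <- r <= r_max
      # first time the front reaches r
      out[ok] <- vapply(r[ok], function(ri) tg[which(rg >= ri)[1L]], 0)
      out[r <= 0] <- 0
      out
    }
    list(t_act = t_act, front_law = front)
  }
}

new_ground_truth <- function(front_law, peak_law, params) {
  structure(list(front_law = front_law, peak_law = peak_law,
                 params_used = params), class = "ground_truth")
}

#' Generate a radially propagating local-wave image stack
#'
#' Pixel intensity is `baseline + amplitude * f(t - t_act(r)) + noise`, where
#' `f` is the normalized rise/decay response and `t_act(r)` the activation
#' time at radial distance `r` from the origin (see [local_wave_params()]).
#' The true front law (threshold-crossing radius) and peak law (front law
#' delayed by the response peak time) are returned alongside the stack.
#'
#' @param params a [local_wave_params()].
#' @return `list(stack = image_stack, truth = ground_truth)`.
#' @export
gen_local_wave_stack <- function(params) {
  stopifnot(inherits(params, "local_wave_params"))
  n <- params$image_size
  laws <- .front_laws(params, kernel_dim = 2L)
  xs <- (0:(n - 1)) - params$origin[1]
  ys <- (0:(n - 1)) - params$origin[2]
  r_um <- sqrt(outer(ys^2, xs^2, "+")) * params$pixel_size  # [y, x]
  t_act <- laws$t_act(as.vector(r_um))
  times <- (seq_len(params$n_frames) - 1L) * params$frame_interval
  arr <- array(0, dim = c(n, n, params$n_frames))
  for (i in seq_along(times)) {
    arr[, , i] <- params$baseline +
      params$amplitude * wave_response(times[i] - t_act,
                                       params$rise, params$decay)
  }
  if (params$noise_sd > 0) {
    arr <- arr + with_seed(params$seed,
      array(stats::rnorm(length(arr), sd = params$noise_sd), dim = dim(arr)))
  }
  tpk <- response_peak_delay(params$rise, params$decay)
  truth <- new_ground_truth(
    front_law = laws$front_law,
    peak_law = function(t) laws$front_law(pmax(t - tpk, 0)),
    params = params)
  list(stack = image_stack(arr, params$pixel_size, params$frame_interval),
       truth = truth)
}

#' Generate a distal-wave stack: diffusion away from a bright vein
#'
#' A straight horizontal vein (static Gaussian ridge of brightness) crosses
#' the image; the wave propagates perpendicular to it with a 1D line-source
#' geometry, so intensity is constant along any line parallel to the vein
#' (before noise). Activation uses the same conventions as
#' [gen_local_wave_stack()] with the 1D kernel in `"kernel"` mode.
#'
#' @param params a [local_wave_params()].
#' @param vein_y vein row, 0-based px; default image centre row.
#' @param vein_height,vein_sigma brightness (a.u.) and Gaussian half-width
#'   (um) of the static vein ridge.
#' @return `list(stack, truth)` as for [gen_local_wave_stack()].
#' @export
gen_distal_wave_stack <- function(params, vein_y = NULL,
                                  vein_height = 300, vein_sigma = 12) {
  stopifnot(inherits(params, "local_wave_params"))
  n <- params$image_size
  vein_y <- vein_y %||% ((n - 1) / 2)
  laws <- .front_laws(params, kernel_dim = 1L)
  dy_um <- abs((0:(n - 1)) - vein_y) * params$pixel_size
  t_act_col <- laws$t_act(dy_um)
  ridge_col <- vein_height * exp(-dy_um^2 / (2 * vein_sigma^2))
  times <- (seq_len(params$n_frames) - 1L) * params$frame_interval
  arr <- array(0, dim = c(n, n, params$n_frames))
  for (i in seq_along(times)) {
    col <- params$baseline + ridge_col +
      params$amplitude * wave_response(times[i] - t_act_col,
                                       params$rise, params$decay)
    arr[, , i] <- matrix(col, nrow = n, ncol = n)  # constant along x
  }
  if (params$noise_sd > 0) {
    arr <- arr + with_seed(params$seed,
      array(stats::rnorm(length(arr), sd = params$noise_sd), dim = dim(arr)))
  }
  tpk <- response_peak_delay(params$rise, params$decay)
  truth <- new_ground_truth(
    front_law = laws$front_law,
    peak_law = function(t) laws$front_law(pmax(t - tpk, 0)),
    params = params)
  list(stack = image_stack(arr, params$pixel_size, params$frame_interval),
       truth = truth)
}

#' Parameters for a vascular (bulk-flow) wave
#'
#' The tracer front travels at the xylem flow speed `u`; the calcium-wave
#' front is the activation-threshold crossing of the advected, Taylor-
#' dispersed agonist profile and leads bulk flow for `theta < 0.5` (see
#' [predict_wave_front()]).
#'
#' @param u flow speed, um/s (default 500). @param Dm molecular diffusion
#'   coefficient, um^2/s (default 100, i.e. 1e-6 cm^2/s). @param radius
#'   xylem radius, um (default 10). @param theta activation threshold as a
#'   fraction of source concentration, in (0, 1).
#' @param t_max latest time, s (default 10, the constant-flow window).
#' @param sample_times sampling times, s.
#' @param noise_sd additive Gaussian noise SD on distances, um.
#' @param seed integer RNG seed.
#' @export
vascular_wave_params <- function(u = 500, Dm = 100, radius = 10,
                                 theta = 0.25, t_max = 10,
                                 sample_times = seq(0.5, 10, by = 0.5),
                                 noise_sd = 0, seed = 1L) {
  if (u < 0) stop("u must be >= 0")
  assert_scalar_pos(Dm, "Dm")
  assert_scalar_pos(radius, "radius")
  if (theta <= 0 || theta >= 1) stop("theta must be in (0, 1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(u = u, Dm = Dm, radius = radius, theta = theta,
                 t_max = t_max, sample_times = sample_times,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "vascular_wave_params")
}

#' Generate paired tracer and calcium distance-time tables
#'
#' The tracer table is the bulk-flow front `d = u t`; the calcium table adds
#' the Taylor-dispersion lead `2 sqrt(D_eff t) erfcinv(2 theta)`. Gaussian
#' noise of SD `noise_sd` is added to the distances of both tables.
#'
#' @param params a [vascular_wave_params()].
#' @return `list(tracer, calcium, truth)`; the tables are data frames with
#'   columns `t_s`, `distance_um`.
#' @export
gen_vascular_tables <- function(params) {
  stopifnot(inherits(params, "vascular_wave_params"))
  t <- params$sample_times
  Deff <- taylor_Deff(params$u, params$Dm, params$radius)
  lead <- 2 * sqrt(Deff * t) * erfcinv(2 * params$theta)
  tracer_d <- params$u * t
  calcium_d <- tracer_d + lead
  if (params$noise_sd > 0) {
    noise <- with_seed(params$seed,
                       stats::rnorm(2 * length(t), sd = params$noise_sd))
    tracer_d <- tracer_d + noise[seq_along(t)]
    calcium_d <- calcium_d + noise[length(t) + seq_along(t)]
  }
  truth <- new_ground_truth(
    front_law = function(t) params$u * t,
    peak_law = function(t) params$u * t +
      2 * sqrt(Deff * pmax(t, 0)) * erfcinv(2 * params$theta),
    params = params)
  list(tracer = data.frame(t_s = t, distance_um = tracer_d),
       calcium = data.frame(t_s = t, distance_um = calcium_d),
       truth = truth)
}

#' Generate a single-frame vein image for peak-width analysis
#'
#' Parallel straight veins are drawn as Gaussian ridges (cross-sectional SD
#' `ridge_sigma` um) on a constant baseline; the analytic peak width at the
#' base-crossing definition (curve exceeding valley + 2 sd_resid, with
#' sd_resid = `sd_resid_frac * peak height`) is recorded per ridge:
#' `width = 2 sigma sqrt(2 log(1 / (2 sd_resid_frac)))`.
#'
#' @param n_veins number of equally spaced vertical veins (0 allowed).
#' @param ridge_sigma Gaussian ridge SD, um; recycled to `n_veins`.
#' @param peak_height ridge brightness above baseline, a.u.
#' @param baseline,noise_sd background level and noise SD, a.u.
#' @param image_size px. @param pixel_size um/px.
#' @param sd_resid_frac residual SD used by the analytic width, as a fraction
#'   of `peak_height`; must be < 0.5.
#' @param seed integer RNG seed.
#' @return `list(stack, true_widths, sd_resid)`; widths in um.
#' @export
gen_cf_vein_image <- function(n_veins = 3, ridge_sigma = 20,
                              peak_height = 500, baseline = 100,
                              noise_sd = 0, image_size = 256,
                              pixel_size = 2, sd_resid_frac = 0.1,
                              seed = 1L) {
  if (any(ridge_sigma <= 0)) stop("ridge_sigma must be > 0")
  if (sd_resid_frac <= 0 || sd_resid_frac >= 0.5) {
    stop("sd_resid_frac must be in (0, 0.5)")
  }
  n <- as.integer(image_size)
  sig <- rep_len(ridge_sigma, max(n_veins, 1L))
  img <- matrix(baseline, n, n)
  widths <- numeric(0)
  if (n_veins > 0) {
    x_um <- (0:(n - 1)) * pixel_size
    centers <- (seq_len(n_veins) - 0.5) / n_veins * (n - 1) * pixel_size
    row <- rep(0, n)
    for (k in seq_len(n_veins)) {
      row <- row + peak_height * exp(-(x_um - centers[k])^2 / (2 * sig[k]^2))
    }
    img <- img + matrix(row, nrow = n, ncol = n, byrow = TRUE)
    widths <- 2 * sig[seq_len(n_veins)] *
      sqrt(2 * log(1 / (2 * sd_resid_frac)))
  }
  if (noise_sd > 0) {
    img <- img + with_seed(seed,
      matrix(stats::rnorm(n * n, sd = noise_sd), n, n))
  }
  list(stack = image_stack(img, pixel_size, 1),
       true_widths = widths,
       sd_resid = sd_resid_frac * peak_height)
}
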