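# Physical transport-model inference: power-law and diffusion fits of front
# trajectories, Taylor (shear-enhanced) dispersion in xylem bulk flow with a
# channel-activation threshold, and the paired lag sign test.

.as_track_xy <- function(track, t, distance) {
  if (is.data.frame(track)) {
    tc <- track[["t_s"]] %||% track[[1]]
    dc <- track[["distance_um"]] %||% track[["front_um"]] %||% track[[2]]
    list(t = as.numeric(tc), d = as.numeric(dc))
  } else {
    list(t = as.numeric(track), d = as.numeric(t))
  }
}

#' Power-law fit of a front trajectory
#'
#' Nonlinear least squares of `r(t) = a t^b`, initialized at `b = 0.8` (the
#' conventional starting value for these fits) with `a` initialized from the
#' first data point. A diffusive front has `b = 0.5`
#' (Einstein-Smoluchowski: `r^2` grows linearly with time).
#'
#' @param track data frame with columns `t_s` and `distance_um` (or
#'   `front_um`); alternatively pass `t` and `distance` vectors.
#' @param t,distance numeric vectors when `track` is a vector of times.
#' @param b_init initial exponent (default 0.8).
#' @return a `power_law_fit`: `a`, `b`, standard errors, residual SD.
#' @export
fit_power_law <- function(track, t = NULL, distance = NULL, b_init = 0.8) {
  xy <- .as_track_xy(track, t, distance)
  ok <- is.finite(xy$t) & is.finite(xy$d) & xy$t > 0
  tt <- xy$t[ok]; rr <- xy$d[ok]
  if (length(tt) < 4) stop("need at least 4 points with t > 0")
  a0 <- max(rr[1] / tt[1]^b_init, 1e-6)
  fit <- tryCatch(
    stats::nls(rr ~ a * tt^b, start = list(a = a0, b = b_init),
               algorithm = "port", lower = c(a = 1e-12, b = -Inf),
               control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
    error = function(e) stop("power-law fit did not converge: ",
                             conditionMessage(e)))
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(a = NA_real_, b = NA_real_))
  structure(list(a = unname(est["a"]), b = unname(est["b"]),
                 se_a = unname(se["a"]), se_b = unname(se["b"]),
                 residual_sd = stats::sigma(fit), n = length(tt), fit = fit),
            class = "power_law_fit")
}

#' Diffusion fit of a front trajectory
#'
#' Nonlinear least squares of `r(t) = sqrt(6 D t)` initialized at
#' `D = 60` um^2/s.
#'
#' @inheritParams fit_power_law
#' @param D_init initial diffusion coefficient (um^2/s).
#' @return a `diffusion_fit`: `D`, standard error, residual SD.
#' @export
fit_diffusion <- function(track, t = NULL, distance = NULL, D_init = 60) {
  xy <- .as_track_xy(track, t, distance)
  ok <- is.finite(xy$t) & is.finite(xy$d) & xy$t > 0
  tt <- xy$t[ok]; rr <- xy$d[ok]
  if (length(tt) < 2) stop("need at least 2 points with t > 0")
  fit <- tryCatch(
    stats::nls(rr ~ sqrt(6 * D * tt), start = list(D = D_init),
               algorithm = "port", lower = c(D = 1e-12),
               control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
    error = function(e) stop("diffusion fit did not converge: ",
                             conditionMessage(e)))
  structure(list(D = unname(stats::coef(fit)["D"]),
                 se_D = tryCatch(summary(fit)$coefficients["D", "Std. Error"],
                                 error = function(e) NA_real_),
                 residual_sd = stats::sigma(fit), n = length(tt), fit = fit),
            class = "diffusion_fit")
}

#' Taylor (Aris) effective dispersion coefficient in a cylindrical tube
#'
#' `D_eff = Dm (1 + Pe^2 / 48)` with Péclet number `Pe = u radius / Dm`.
#' Shear across the tube radius enhances axial spreading of a solute carried
#' by bulk flow.
#'
#' @param u flow speed, um/s (>= 0). @param Dm molecular diffusion
#'   coefficient, um^2/s. @param radius tube radius, um.
#' @return effective dispersion coefficient, um^2/s.
#' @export
taylor_Deff <- function(u, Dm, radius) {
  if (any(u < 0)) stop("u must be >= 0")
  assert_scalar_pos(Dm, "Dm")
  assert_scalar_pos(radius, "radius")
  Pe <- u * radius / Dm
  Dm * (1 + Pe^2 / 48)
}

#' Dispersion model for the vascular calcium wave
#'
#' Bundles the bulk-flow and Taylor-dispersion parameters with the
#' channel-activation threshold `theta` (fraction of source concentration).
#' The advected, dispersed concentration is
#' `c(x, t) = 1/2 erfc((x - u t) / (2 sqrt(D_eff t)))`; the wave front is
#' where `c` crosses `theta`.
#'
#' @param u flow speed um/s (default 500). @param Dm molecular diffusivity
#'   um^2/s (default 100 = 1e-6 cm^2/s). @param radius xylem radius um
#'   (default 10). @param theta activation threshold in (0, 1).
#' @param t_limit latest time (s) at which the constant-flow assumption is
#'   trusted (default 10); predictions beyond warn.
#' @return a `dispersion_model` with derived `Pe` and `D_eff`.
#' @export
dispersion_model <- function(u = 500, Dm = 100, radius = 10, theta = 0.25,
                             t_limit = 10) {
  if (theta <= 0 || theta >= 1) stop("theta must be in (0, 1)")
  Deff <- taylor_Deff(u, Dm, radius)
  structure(list(u = u, Dm = Dm, radius = radius,
                 Pe = u * radius / Dm, D_eff = Deff,
                 theta = theta, t_limit = t_limit),
            class = "dispersion_model")
}

#' Predicted wave-front position under bulk flow plus Taylor dispersion
#'
#' Threshold crossing of the erfc concentration profile:
#' `x(t) = u t + 2 sqrt(D_eff t) erfcinv(2 theta)`. For `theta < 0.5` the
#' wave leads bulk flow by a gap growing as `sqrt(t)`.
#'
#' @param model a [dispersion_model()]. @param t times (s, >= 0).
#' @return front positions (um).
#' @export
predict_wave_front <- function(model, t) {
  stopifnot(inherits(model, "dispersion_model"))
  if (any(t < 0)) stop("t must be >= 0")
  if (any(t > model$t_limit)) {
    warning(sprintf(
      "prediction beyond t_limit = %g s: constant-flow assumption only holds early",
      model$t_limit))
  }
  model$u * t + 2 * sqrt(model$D_eff * t) * erfcinv(2 * model$theta)
}

#' Fit the channel-activation threshold from paired tracer/calcium tracks
#'
#' Given a GP fit of the tracer (bulk-flow) distance-time data, finds the
#' `theta` minimizing the squared distance between the calcium track and
#' `gp mean + 2 sqrt(D_eff t) erfcinv(2 theta)`. The flow speed enters only
#' through `D_eff`; it is a stated parameter, not re-fit. Solved in closed
#' form: the optimal `g = erfcinv(2 theta)` is the weighted least-squares
#' slope of the calcium-minus-tracer gap on `2 sqrt(D_eff t)`.
#'
#' @param calcium data frame `t_s, distance_um` (calcium-front track).
#' @param gp_tracer a [gp_fit()] of the tracer track.
#' @param u,Dm,radius dispersion parameters (defaults 500, 100, 10).
#' @param t_limit analysis window (s); calcium points beyond it are dropped
#'   with a warning.
#' @return a [dispersion_model()] with the fitted `theta`, plus `rss` and
#'   `n` attributes.
#' @export
fit_theta <- function(calcium, gp_tracer, u = 500, Dm = 100, radius = 10,
                      t_limit = 10) {
  stopifnot(inherits(gp_tracer, "gp_fit"))
  tt <- as.numeric(calcium$t_s)
  dd <- as.numeric(calcium$distance_um %||% calcium[[2]])
  keep <- is.finite(tt) & is.finite(dd) & tt > 0
  if (any(tt[keep] > t_limit)) {
    warning("calcium points beyond t_limit dropped from the theta fit")
    keep <- keep & tt <= t_limit
  }
  tt <- tt[keep]; dd <- dd[keep]
  if (length(tt) < 1) stop("no calcium points within t_limit")
  Deff <- taylor_Deff(u, Dm, radius)
  gm <- gp_predict(gp_tracer, tt)$mean
  w <- 2 * sqrt(Deff * tt)
  g <- sum(w * (dd - gm)) / sum(w^2)
  g_max <- erfcinv(2e-8)  # clamp just inside (0, 1)
  if (abs(g) >= g_max) {
    warning("theta estimate at the boundary of (0, 1)")
    g <- sign(g) * g_max
  }
  theta <- erfc(g) / 2
  if (theta > 0.5) {
    warning("calcium lags the tracer: theta > 0.5 is unphysical under the model")
  }
  model <- dispersion_model(u = u, Dm = Dm, radius = radius, theta = theta,
                            t_limit = t_limit)
  model$rss <- sum((dd - (gm + w * g))^2)
  model$n <- length(tt)
  model
}

#' Exact paired sign test for tracer-vs-calcium lags
#'
#' Two-sided exact binomial test of the per-replicate sign of
#' (calcium front - tracer front) against p = 0.5: the smaller binomial
#' tail is doubled and capped at 1. Zero lags (ties) are excluded from `n`
#' and reported.
#'
#' @param lags numeric per-replicate lags, or their signs.
#' @return `list(n_pos, n, n_ties, p_value)`.
#' @export
lag_sign_test <- function(lags) {
  if (length(lags) < 1) stop("need at least one paired replicate")
  sgn <- sign(lags)
  n_ties <- sum(sgn == 0)
  sgn <- sgn[sgn != 0]
  n <- length(sgn)
  k <- sum(sgn > 0)
  if (n == 0) {
    return(list(n_pos = 0L, n = 0L, n_ties = n_ties, p_value = 1))
  }
  lower <- stats::pbinom(k, n, 0.5)
  upper <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)
  list(n_pos = k, n = n, n_ties = n_ties,
       p_value = min(1, 2 * min(lower, upper)))
}

#' Write a transport fit report as JSON
#'
#' @param fit a `power_law_fit`, `diffusion_fit` or `dispersion_model`.
#' @param path output path.
#' @export
write_fit_report <- function(fit, path) {
  drop_cl <- function(x) x[!vapply(x, function(e)
    inherits(e, c("nls", "gp_fit")), TRUE)]
  jsonlite::write_json(c(list(class = class(fit)[1]),
                         drop_cl(unclass(fit))),
                       path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
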