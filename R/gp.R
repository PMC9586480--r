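# Gaussian-process regression of distance-time data (tracer bulk flow).
# Squared-exponential kernel, hyperparameters by marginal-likelihood
# maximization over a small deterministic multi-start, nugget floored at
# 1e-8 of the signal variance.

.sqexp_K <- function(t1, t2, ell, sf2) {
  sf2 * exp(-0.5 * outer(t1, t2, "-")^2 / ell^2)
}

.gp_nll <- function(par, t, yc) {
  ell <- exp(par[1]); sf2 <- exp(par[2]); sn2 <- exp(par[3])
  n <- length(t)
  K <- .sqexp_K(t, t, ell, sf2)
  diag(K) <- diag(K) + sn2 + 1e-10 * sf2
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  z <- forwardsolve(t(L), yc)
  0.5 * drop(crossprod(z)) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
}

#' Fit a Gaussian process to a distance-time track
#'
#' Zero-mean (after centring) GP with squared-exponential kernel
#' `k(t, t') = sf2 exp(-(t - t')^2 / (2 ell^2)) + sn2 1(t = t')`.
#' Hyperparameters maximize the log marginal likelihood from a fixed grid of
#' starting points; the noise variance is floored at `1e-8 * sf2` so that
#' noiseless data are interpolated.
#'
#' @param t times (s), not all equal (>= 3 points).
#' @param distance distances (um).
#' @return a `gp_fit` with elements `ell`, `sf2`, `sn2`, `log_marginal`,
#'   and the training data.
#' @export
gp_fit <- function(t, distance) {
  ok <- is.finite(t) & is.finite(distance)
  t <- as.numeric(t[ok]); y <- as.numeric(distance[ok])
  if (length(t) < 3) stop("need at least 3 points")
  if (diff(range(t)) == 0) stop("all times equal; GP undefined")
  ybar <- mean(y)
  yc <- y - ybar
  vy <- max(stats::var(yc), 1e-12)
  tr <- diff(range(t))
  starts <- expand.grid(ell = c(tr / 10, tr / 2, tr * 2),
                        sn_frac = c(1e-6, 1e-3, 1e-1))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    par0 <- log(c(starts$ell[k], vy, starts$sn_frac[k] * vy))
    opt <- tryCatch(
      stats::optim(par0, .gp_nll, t = t, yc = yc, method = "Nelder-Mead",
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
      best <- opt
    }
  }
  if (is.null(best)) stop("GP hyperparameter optimization failed")
  ell <- exp(best$par[1]); sf2 <- exp(best$par[2])
  sn2 <- max(exp(best$par[3]), 1e-8 * sf2)
  K <- .sqexp_K(t, t, ell, sf2)
  diag(K) <- diag(K) + sn2 + 1e-10 * sf2
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), yc))
  structure(list(ell = ell, sf2 = sf2, sn2 = sn2,
                 log_marginal = -best$value,
                 t = t, y = y, ybar = ybar, L = L, alpha = alpha),
            class = "gp_fit")
}

#' Posterior mean and variance of a fitted GP
#'
#' @param fit a `gp_fit`. @param t prediction times (s).
#' @return `list(mean, var)`; `var` is the posterior variance of the latent
#'   function (>= 0, ~nugget-level at training points).
#' @export
gp_predict <- function(fit, t) {
  ks <- .sqexp_K(fit$t, as.numeric(t), fit$ell, fit$sf2)
  mean <- fit$ybar + drop(crossprod(ks, fit$alpha))
  v <- forwardsolve(t(fit$L), ks)
  var <- pmax(fit$sf2 - colSums(v^2), 0)
  list(mean = mean, var = var)
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf(
    "<gp_fit> n = %d, lengthscale %.4g s, signal var %.4g, noise var %.4g\n",
    length(x$t), x$ell, x$sf2, x$sn2))
  invisible(x)
}
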