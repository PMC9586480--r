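# Kinematic summaries across replicates: through-origin degree-6 polynomial
# fits of distance over time, analytic velocities, through-origin vascular
# speed fits, and the per-time-point / pairwise group comparisons.

#' Through-origin degree-6 polynomial fit of distance over time
#'
#' Least squares over the six monomials `t, t^2, ..., t^6` (no intercept, so
#' the fitted curve passes exactly through the origin). Times are rescaled
#' to `[0, 1]` internally for conditioning and the coefficients mapped back.
#'
#' @param t,distance numeric vectors (>= 7 points).
#' @param replicate optional replicate id stored with the fit.
#' @return a `poly_fit` with `coefficients` c1..c6 (um s^-k).
#' @export
fit_poly6_origin <- function(t, distance, replicate = NA) {
  ok <- is.finite(t) & is.finite(distance)
  t <- t[ok]; distance <- distance[ok]
  if (length(t) < 7) stop("need at least 7 points for a degree-6 fit")
  t_scale <- max(abs(t))
  if (t_scale == 0) stop("all times are zero")
  s <- t / t_scale
  X <- outer(s, 1:6, "^")
  qrX <- qr(X)
  if (qrX$rank < 6) stop("rank-deficient design (times too few or repeated)")
  beta <- qr.coef(qrX, distance)
  coefs <- beta / t_scale^(1:6)
  structure(list(coefficients = unname(coefs), replicate = replicate,
                 t_scale = t_scale),
            class = "poly_fit")
}

#' Evaluate a through-origin polynomial fit
#' @param fit a `poly_fit`. @param t times (s).
#' @return fitted distances (um).
#' @export
predict_poly <- function(fit, t) {
  drop(outer(t, 1:6, "^") %*% fit$coefficients)
}

#' Coefficient-wise mean polynomial across replicates
#'
#' Because the fits share the monomial basis, averaging coefficients equals
#' averaging the fitted curves pointwise.
#'
#' @param fits list of `poly_fit` objects.
#' @return a `poly_fit`.
#' @export
mean_curve <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "poly_fit")))
  cm <- rowMeans(vapply(fits, function(f) f$coefficients, numeric(6)))
  structure(list(coefficients = cm, replicate = "mean", t_scale = NA),
            class = "poly_fit")
}

#' Wave velocity from a polynomial fit
#'
#' Analytic first derivative `c1 + 2 c2 t + ... + 6 c6 t^5` (um/s).
#'
#' @param fit a `poly_fit`. @param t times (s).
#' @export
velocity <- function(fit, t) {
  drop(outer(t, 0:5, "^") %*% (fit$coefficients * (1:6)))
}

#' Through-origin linear fit of a vascular track
#'
#' The wave speed of a replicate is the slope of the straight line through
#' the origin, `slope = sum(t d) / sum(t^2)`.
#'
#' @param t,distance numeric vectors (>= 2 points).
#' @param replicate optional id.
#' @return a `speed_fit` with `slope` (um/s) and its standard error.
#' @export
fit_vascular_speed <- function(t, distance, replicate = NA) {
  ok <- is.finite(t) & is.finite(distance)
  t <- t[ok]; distance <- distance[ok]
  if (length(t) < 2) stop("need at least 2 points")
  if (sum(t^2) == 0) stop("all times are zero")
  slope <- sum(t * distance) / sum(t^2)
  resid <- distance - slope * t
  se <- if (length(t) > 1) {
    sqrt(sum(resid^2) / (length(t) - 1) / sum(t^2))
  } else NA_real_
  structure(list(slope = slope, se = se, n = length(t),
                 replicate = replicate),
            class = "speed_fit")
}

#' Per-time-point two-sample t tests between two groups of tracks
#'
#' At each time point shared by at least two replicates per group, the
#' tracked distances are compared with a two-sample t test
#' (pooled-variance Student by default, as in the summary statistics this
#' reproduces; `var_equal = FALSE` gives Welch). Time points with
#' insufficient replication are skipped. Groups whose members are all
#' identical give t = 0 and p = 1 when the means agree.
#'
#' @param groupA,groupB lists of `wave_track` data frames (or any data frame
#'   with `t_s` and the value column).
#' @param value column compared (default `"peak_um"`).
#' @param var_equal pooled-variance Student t (default `TRUE`).
#' @return data frame `t_s, n_A, n_B, mean_A, mean_B, t_stat, p`.
#' @export
compare_tracks_pointwise <- function(groupA, groupB, value = "peak_um",
                                     var_equal = TRUE) {
  pull <- function(group) {
    do.call(rbind, lapply(seq_along(group), function(i) {
      tr <- group[[i]]
      data.frame(t_s = tr$t_s, v = tr[[value]], rep = i)
    }))
  }
  a <- pull(groupA); b <- pull(groupB)
  a <- a[is.finite(a$v), ]; b <- b[is.finite(b$v), ]
  times <- sort(intersect(unique(a$t_s), unique(b$t_s)))
  rows <- lapply(times, function(tt) {
    xa <- a$v[a$t_s == tt]; xb <- b$v[b$t_s == tt]
    if (length(xa) < 2 || length(xb) < 2) return(NULL)
    dmean <- mean(xa) - mean(xb)
    if (var_equal) {
      df <- length(xa) + length(xb) - 2
      sp2 <- ((length(xa) - 1) * stats::var(xa) +
                (length(xb) - 1) * stats::var(xb)) / df
      sed <- sqrt(sp2 * (1 / length(xa) + 1 / length(xb)))
    } else {
      va <- stats::var(xa) / length(xa); vb <- stats::var(xb) / length(xb)
      sed <- sqrt(va + vb)
      df <- (va + vb)^2 / (va^2 / (length(xa) - 1) + vb^2 / (length(xb) - 1))
    }
    tstat <- if (sed == 0) {
      if (dmean == 0) 0 else sign(dmean) * Inf
    } else dmean / sed
    p <- if (is.infinite(tstat)) 0 else
      2 * stats::pt(-abs(tstat), df = max(df, 1))
    data.frame(t_s = tt, n_A = length(xa), n_B = length(xb),
               mean_A = mean(xa), mean_B = mean(xb),
               t_stat = tstat, p = p)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(t_s = numeric(0), n_A = integer(0), n_B = integer(0),
                      mean_A = numeric(0), mean_B = numeric(0),
                      t_stat = numeric(0), p = numeric(0))
  }
  out
}

#' Pairwise rank-sum comparison of replicate speeds across groups
#'
#' Wilcoxon rank sum test for every pair of groups; exact when both group
#' sizes are <= 10 (and ties allow), normal approximation otherwise.
#' Bonferroni correction multiplies p by the number of pairwise comparisons,
#' capped at 1.
#'
#' @param groups named list of numeric speed vectors, or of lists of
#'   `speed_fit` objects.
#' @param correction `"none"` or `"bonferroni"`.
#' @return data frame `group1, group2, W, p, p_adj`.
#' @export
compare_speeds <- function(groups, correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  groups <- lapply(groups, function(g) {
    if (is.numeric(g)) g else vapply(g, function(f) f$slope, 0)
  })
  if (length(groups) < 2) stop("need at least two groups")
  nm <- names(groups) %||% as.character(seq_along(groups))
  pairs <- utils::combn(length(groups), 2)
  n_cmp <- ncol(pairs)
  rows <- lapply(seq_len(n_cmp), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    exact <- length(groups[[i]]) <= 10 && length(groups[[j]]) <= 10
    wt <- suppressWarnings(
      stats::wilcox.test(groups[[i]], groups[[j]], exact = exact))
    data.frame(group1 = nm[i], group2 = nm[j],
               W = unname(wt$statistic), p = wt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (correction == "bonferroni") pmin(out$p * n_cmp, 1) else out$p
  out
}
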