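# Vein-unloading quantification: mean peak width along grid scan lines.
# Each image is scanned by equidistant horizontal and vertical lines; peaks
# of the LOESS-smoothed line profiles are measured from base to base, where
# a base is the outermost point at which the curve still exceeds the
# neighbouring valley minimum + 2 x SD of the LOESS residuals.

#' Grid line profiles of an image
#'
#' `n_lines_per_axis` equidistant full-length horizontal lines (rows) plus
#' the same number of vertical lines (columns), sampled at pixel steps.
#'
#' @param image an [image_stack()] (first frame used) or a matrix.
#' @param n_lines_per_axis lines per axis (default 50).
#' @param pixel_size um/px; taken from the stack when available.
#' @return list of profiles `list(axis, index, distance, intensity)`.
#' @export
grid_profiles <- function(image, n_lines_per_axis = 50, pixel_size = NULL) {
  if (inherits(image, "image_stack")) {
    pixel_size <- pixel_size %||% image$pixel_size
    image <- image$data[, , 1]
  }
  pixel_size <- pixel_size %||% 1
  if (n_lines_per_axis < 1) stop("n_lines_per_axis must be >= 1")
  h <- nrow(image); w <- ncol(image)
  pick <- function(extent, n) {
    unique(round((2 * seq_len(n) - 1) / (2 * n) * (extent - 1) + 1))
  }
  out <- list()
  for (r in pick(h, n_lines_per_axis)) {
    out[[length(out) + 1L]] <- list(
      axis = "horizontal", index = r,
      distance = (0:(w - 1)) * pixel_size, intensity = image[r, ])
  }
  for (cc in pick(w, n_lines_per_axis)) {
    out[[length(out) + 1L]] <- list(
      axis = "vertical", index = cc,
      distance = (0:(h - 1)) * pixel_size, intensity = image[, cc])
  }
  out
}

#' Peaks and valleys of a smoothed line profile
#'
#' LOESS smoothing (shared with the wave-tracking module) followed by
#' alternating extrema extraction; profile ends count as valleys for base
#' finding.
#'
#' @param distance,intensity the line profile.
#' @param span LOESS span. @param window extrema window in grid steps.
#' @return `list(distance, curve, maxima, minima, sd_resid)`; `maxima` and
#'   `minima` are index vectors into the grid.
#' @export
detect_peaks_valleys <- function(distance, intensity, span = 0.1,
                                 window = 3) {
  sm <- smooth_profile(distance, intensity, span = span)
  curve <- sm$fitted
  maxima <- find_local_maxima(distance, curve, window = window)$index
  minima <- find_local_maxima(distance, -curve, window = window)$index
  list(distance = distance, curve = curve,
       maxima = maxima, minima = minima,
       sd_resid = sm$residual_sd)
}

#' Base positions of a peak
#'
#' Walking outward from the peak on each side, the base is the outermost
#' grid position at which the curve still exceeds
#' `valley_level + 2 * sd_resid`. With `valley_rule = "lower"` (default) the
#' lower of the two flanking valley values is used for both sides;
#' `"per_side"` uses each side's own valley. A peak not exceeding its base
#' level is discarded (`NULL`).
#'
#' @param distance,curve the smoothed profile grid.
#' @param peak_index index of the peak on the grid.
#' @param valley_indices indices of the flanking valleys (profile ends are
#'   used when a side has none).
#' @param sd_resid SD of the LOESS residuals.
#' @param valley_rule `"lower"` or `"per_side"`.
#' @return `list(left_base, right_base, width)` in distance units, or `NULL`.
#' @export
peak_bases <- function(distance, curve, peak_index, valley_indices,
                       sd_resid, valley_rule = c("lower", "per_side")) {
  valley_rule <- match.arg(valley_rule)
  n <- length(curve)
  left_v <- valley_indices[valley_indices < peak_index]
  right_v <- valley_indices[valley_indices > peak_index]
  li <- if (length(left_v)) max(left_v) else 1L
  ri <- if (length(right_v)) min(right_v) else n
  lev_l <- curve[li]; lev_r <- curve[ri]
  if (valley_rule == "lower") lev_l <- lev_r <- min(lev_l, lev_r)
  thr_l <- lev_l + 2 * sd_resid
  thr_r <- lev_r + 2 * sd_resid
  if (curve[peak_index] <= max(thr_l, thr_r)) return(NULL)
  run <- function(idx, thr) {
    # outermost index (walking outward) still above thr
    last <- peak_index
    for (i in idx) {
      if (!is.finite(curve[i]) || curve[i] <= thr) break
      last <- i
    }
    last
  }
  lb <- run(rev(seq_len(peak_index - 1L)), thr_l)
  rb <- run(if (peak_index < n) (peak_index + 1L):n else integer(0), thr_r)
  list(left_base = distance[lb], right_base = distance[rb],
       width = distance[rb] - distance[lb])
}

#' Mean peak width of a vein image
#'
#' Full grid-line pipeline: grid profiles, LOESS peak/valley detection, base
#' finding, and the simple mean of all retained peak widths of the image
#' (one value per projection).
#'
#' @param image an [image_stack()] or matrix (single projection).
#' @param n_lines_per_axis lines per axis (default 50).
#' @param span,window smoothing and extrema parameters.
#' @param sd_resid fixed residual SD; `NULL` (default) estimates it per line
#'   from the LOESS residuals.
#' @param valley_rule see [peak_bases()].
#' @param pixel_size um/px override for plain matrices.
#' @return `list(mean_width, records)`; `records` is a data frame of
#'   per-peak measurements (`axis, line, peak_um, left_um, right_um,
#'   width_um`). `mean_width` is `NA` with a warning when no peak survives.
#' @export
mean_peak_width <- function(image, n_lines_per_axis = 50, span = 0.1,
                            window = 3, sd_resid = NULL,
                            valley_rule = c("lower", "per_side"),
                            pixel_size = NULL) {
  valley_rule <- match.arg(valley_rule)
  profiles <- grid_profiles(image, n_lines_per_axis, pixel_size = pixel_size)
  rows <- list()
  for (pr in profiles) {
    pv <- tryCatch(
      detect_peaks_valleys(pr$distance, pr$intensity, span = span,
                           window = window),
      error = function(e) NULL)
    if (is.null(pv) || length(pv$maxima) == 0) next
    sdr <- sd_resid %||% pv$sd_resid
    for (pk in pv$maxima) {
      b <- peak_bases(pv$distance, pv$curve, pk, pv$minima, sdr,
                      valley_rule = valley_rule)
      if (is.null(b)) next
      rows[[length(rows) + 1L]] <- data.frame(
        axis = pr$axis, line = pr$index,
        peak_um = pv$distance[pk],
        left_um = b$left_base, right_um = b$right_base,
        width_um = b$width)
    }
  }
  records <- if (length(rows)) do.call(rbind, rows) else
    data.frame(axis = character(0), line = integer(0), peak_um = numeric(0),
               left_um = numeric(0), right_um = numeric(0),
               width_um = numeric(0))
  if (nrow(records) == 0) {
    warning("no peaks detected; mean width is NA")
    return(list(mean_width = NA_real_, records = records))
  }
  list(mean_width = mean(records$width_um), records = records)
}
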