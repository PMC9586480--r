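# Geometric fluorescence scanning: convert an image stack plus geometry
# annotations into distance-resolved intensity profiles, one per time point.
# Coordinates are 0-based pixel centres, origin top-left, x right, y down.

#' Scan geometry
#'
#' Three modes mirror the acquisition geometries of the assays:
#' \describe{
#'   \item{`radial_point`}{`n_lines` radii (default 100) depart equiangularly
#'     from a wound point.}
#'   \item{`arc_circle`}{three points on the edge of a droplet or trichome
#'     base define a circle; radii (default 700 um long) start on the arc
#'     spanned by the first two points (the arc not containing the third)
#'     and point radially outward.}
#'   \item{`vein_transects`}{`n_lines` (default 10) equidistant transects of
#'     default length 500 um depart perpendicular to a vein segment.}
#' }
#'
#' @param mode one of `"radial_point"`, `"arc_circle"`, `"vein_transects"`.
#' @param points geometry anchor, px: a single `(x, y)` point
#'   (radial_point), a list/matrix of three edge points (arc_circle), or the
#'   two segment endpoints (vein_transects).
#' @param n_lines number of scan lines; defaults by mode (100 / 100 / 10).
#' @param line_length line length in um; defaults by mode (NULL = clip to
#'   image / 700 / 500).
#' @param transect_side `+1` or `-1`: which normal of the vein segment the
#'   transects follow.
#' @return a `scan_geometry` object.
#' @export
scan_geometry <- function(mode = c("radial_point", "arc_circle",
                                   "vein_transects"),
                          points, n_lines = NULL, line_length = NULL,
                          transect_side = 1) {
  mode <- match.arg(mode)
  pts <- if (is.matrix(points)) {
    points
  } else if (is.numeric(points)) {
    matrix(points, ncol = 2, byrow = TRUE)
  } else {
    do.call(rbind, lapply(points, as.numeric))
  }
  storage.mode(pts) <- "double"
  need <- c(radial_point = 1L, arc_circle = 3L, vein_transects = 2L)[[mode]]
  if (nrow(pts) != need) {
    stop_config(mode, " needs ", need, " point(s), got ", nrow(pts))
  }
  n_lines <- n_lines %||%
    c(radial_point = 100L, arc_circle = 100L, vein_transects = 10L)[[mode]]
  if (n_lines < 1) stop_config("n_lines must be >= 1")
  line_length <- line_length %||%
    switch(mode, radial_point = NULL, arc_circle = 700, vein_transects = 500)
  if (!is.null(line_length) && line_length <= 0) {
    stop_config("line_length must be > 0")
  }
  if (mode == "arc_circle") {
    d <- as.matrix(stats::dist(pts))
    if (any(d[upper.tri(d)] < 1e-9)) stop_config("arc points must be distinct")
  }
  if (mode == "vein_transects" &&
      sqrt(sum((pts[1, ] - pts[2, ])^2)) < 1e-9) {
    stop_config("vein segment endpoints coincide")
  }
  structure(list(mode = mode, points = pts, n_lines = as.integer(n_lines),
                 line_length = line_length,
                 transect_side = sign(transect_side)),
            class = "scan_geometry")
}

#' Circle through three points
#'
#' Perpendicular-bisector solution for the circle anchored on three edge
#' points (droplet or trichome base).
#'
#' @param p1,p2,p3 points `(x, y)` in px, pairwise distinct.
#' @return `list(center = c(x, y), radius)`.
#' @export
circle_from_three_points <- function(p1, p2, p3) {
  P <- rbind(p1, p2, p3)
  if (any(as.matrix(stats::dist(P))[upper.tri(diag(3))] < 1e-12)) {
    stop("points must be pairwise distinct")
  }
  # 2 * (p_i - p_j) . c = |p_i|^2 - |p_j|^2
  A <- 2 * rbind(P[1, ] - P[2, ], P[1, ] - P[3, ])
  b <- c(sum(P[1, ]^2) - sum(P[2, ]^2), sum(P[1, ]^2) - sum(P[3, ]^2))
  det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  # collinearity: twice the signed triangle area
  area2 <- (P[2, 1] - P[1, 1]) * (P[3, 2] - P[1, 2]) -
    (P[3, 1] - P[1, 1]) * (P[2, 2] - P[1, 2])
  scale <- max(abs(P)) + 1
  if (abs(area2) < 1e-9 * scale^2) stop("points are collinear")
  center <- c(A[2, 2] * b[1] - A[1, 2] * b[2],
              -A[2, 1] * b[1] + A[1, 1] * b[2]) / det
  list(center = center, radius = sqrt(sum((P[1, ] - center)^2)))
}

# Normalize an angle to [0, 2*pi)
.wrap_angle <- function(a) a %% (2 * pi)

#' Build sampling lines from a scan geometry
#'
#' Each line is a start point plus a unit direction (px units) and a length.
#' Lines leaving the image are clipped: `length_px` records the per-line
#' usable extent and samples beyond it are excluded from profile means, not
#' zero-filled.
#'
#' @param geometry a [scan_geometry()].
#' @param pixel_size um/px.
#' @param image_dim `c(width, height)` in px, used for clipping; `NULL`
#'   skips clipping.
#' @return list of lines: `list(start, dir, length_px)`.
#' @export
build_lines <- function(geometry, pixel_size, image_dim = NULL) {
  stopifnot(inherits(geometry, "scan_geometry"))
  n <- geometry$n_lines
  len_px <- if (!is.null(geometry$line_length)) {
    geometry$line_length / pixel_size
  } else if (!is.null(image_dim)) {
    sqrt(sum(image_dim^2))  # clipping will trim
  } else {
    stop_config("line_length or image_dim required")
  }
  lines <- switch(geometry$mode,
    radial_point = {
      ang <- 2 * pi * (seq_len(n) - 1) / n
      lapply(ang, function(a) {
        list(start = geometry$points[1, ], dir = c(cos(a), sin(a)),
             length_px = len_px)
      })
    },
    arc_circle = {
      circ <- circle_from_three_points(geometry$points[1, ],
                                       geometry$points[2, ],
                                       geometry$points[3, ])
      a1 <- .wrap_angle(atan2(geometry$points[1, 2] - circ$center[2],
                              geometry$points[1, 1] - circ$center[1]))
      a2 <- .wrap_angle(atan2(geometry$points[2, 2] - circ$center[2],
                              geometry$points[2, 1] - circ$center[1]))
      a3 <- .wrap_angle(atan2(geometry$points[3, 2] - circ$center[2],
                              geometry$points[3, 1] - circ$center[1]))
      # sweep from a1 to a2 through the side not containing a3
      ccw <- .wrap_angle(a2 - a1)        # CCW sweep width a1 -> a2
      pos3 <- .wrap_angle(a3 - a1)
      angles <- if (pos3 < ccw) {
        # a3 inside the CCW arc: go clockwise instead
        a1 - seq(0, .wrap_angle(a1 - a2), length.out = max(n, 2))
      } else {
        a1 + seq(0, ccw, length.out = max(n, 2))
      }
      if (n == 1) angles <- angles[1]
      lapply(angles, function(a) {
        u <- c(cos(a), sin(a))
        list(start = circ$center + circ$radius * u, dir = u,
             length_px = len_px)
      })
    },
    vein_transects = {
      p <- geometry$points
      seg <- p[2, ] - p[1, ]
      u <- seg / sqrt(sum(seg^2))
      normal <- geometry$transect_side * c(-u[2], u[1])
      fr <- if (n == 1) 0.5 else (seq_len(n) - 1) / (n - 1)
      lapply(fr, function(f) {
        list(start = p[1, ] + f * seg, dir = normal, length_px = len_px)
      })
    })
  if (!is.null(image_dim)) {
    w <- image_dim[1]; h <- image_dim[2]
    lines <- lapply(lines, function(ln) {
      # longest s in [0, length] with start + s*dir inside [0, w-1]x[0, h-1]
      smax <- ln$length_px
      for (k in 1:2) {
        lim <- c(w - 1, h - 1)[k]
        if (abs(ln$dir[k]) > 1e-12) {
          bounds <- sort((c(0, lim) - ln$start[k]) / ln$dir[k])
          smax <- min(smax, bounds[2])
        } else if (ln$start[k] < 0 || ln$start[k] > lim) {
          smax <- -1
        }
      }
      ln$length_px <- max(smax, -1)
      ln
    })
  }
  lines
}

# Bilinear interpolation of frame values at 0-based (x, y); NA outside.
bilinear_sample <- function(frame, x, y) {
  h <- nrow(frame); w <- ncol(frame)
  out <- rep(NA_real_, length(x))
  ok <- x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1
  if (!any(ok)) return(out)
  xo <- x[ok]; yo <- y[ok]
  x0 <- pmin(floor(xo), w - 2); y0 <- pmin(floor(yo), h - 2)
  fx <- xo - x0; fy <- yo - y0
  i00 <- y0 + 1 + h * x0  # linear index of (row y0+1, col x0+1)
  v <- (1 - fx) * (1 - fy) * frame[i00] +
    fx * (1 - fy) * frame[i00 + h] +
    (1 - fx) * fy * frame[i00 + 1] +
    fx * fy * frame[i00 + h + 1]
  out[ok] <- v
  out
}

#' Scan an image stack along a geometry
#'
#' Samples every line at one-pixel steps by bilinear interpolation and
#' averages across lines at each distance, per frame. Distances are measured
#' in um from each line's start (the anchor); samples clipped off the image
#' are excluded from the mean.
#'
#' @param stack an [image_stack()].
#' @param geometry a [scan_geometry()].
#' @return a `profile_set`: `distances` (um), `times` (s), `intensity`
#'   matrix `[distance, time]`, `n_lines_used` per distance.
#' @export
scan_stack <- function(stack, geometry) {
  stopifnot(inherits(stack, "image_stack"))
  if (n_frames(stack) < 1) stop_data("empty stack")
  d <- dim(stack$data)
  lines <- build_lines(geometry, stack$pixel_size,
                       image_dim = c(d[2], d[1]))
  max_len <- max(vapply(lines, function(l) l$length_px, 0))
  if (max_len < 0) stop_data("all scan lines fall outside the image")
  steps <- 0:floor(max_len)                 # 1 px sampling step
  xs <- vapply(lines, function(l) l$start[1] + steps * l$dir[1],
               numeric(length(steps)))
  ys <- vapply(lines, function(l) l$start[2] + steps * l$dir[2],
               numeric(length(steps)))
  valid <- vapply(lines, function(l) steps <= l$length_px + 1e-9,
                  logical(length(steps)))
  dim(valid) <- dim(xs) <- dim(ys) <- c(length(steps), length(lines))
  nt <- n_frames(stack)
  intensity <- matrix(NA_real_, nrow = length(steps), ncol = nt)
  n_used <- rowSums(valid)
  for (ti in seq_len(nt)) {
    vals <- bilinear_sample(stack$data[, , ti], as.vector(xs), as.vector(ys))
    dim(vals) <- dim(xs)
    vals[!valid] <- NA_real_
    intensity[, ti] <- rowMeans(vals, na.rm = TRUE)
  }
  intensity[n_used == 0, ] <- NA_real_
  structure(list(distances = steps * stack$pixel_size,
                 times = frame_times(stack),
                 intensity = intensity,
                 n_lines_used = n_used,
                 pixel_size = stack$pixel_size),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  cat(sprintf("<profile_set> %d distances x %d time points, step %.3g um\n",
              length(x$distances), length(x$times),
              if (length(x$distances) > 1) diff(x$distances[1:2]) else NA))
  invisible(x)
}

#' Serialize / read a profile set as a CSV matrix
#'
#' Rows are distances (first column `distance_um`), remaining columns the
#' frame times prefixed `t`.
#'
#' @param ps a `profile_set`. @param path file path.
#' @export
write_profile_set <- function(ps, path) {
  df <- data.frame(distance_um = ps$distances, ps$intensity,
                   check.names = FALSE)
  names(df)[-1] <- paste0("t", ps$times)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_set
#' @export
read_profile_set <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  times <- as.numeric(sub("^t", "", names(df)[-1]))
  structure(list(distances = df[[1]],
                 times = times,
                 intensity = as.matrix(df[, -1, drop = FALSE]),
                 n_lines_used = rep(NA_integer_, nrow(df)),
                 pixel_size = if (nrow(df) > 1) diff(df[[1]][1:2]) else NA),
            class = "profile_set")
}
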