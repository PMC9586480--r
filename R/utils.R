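#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Complementary error function and its inverse
#'
#' `erfc(x) = 2/sqrt(pi) * integral_x^Inf exp(-s^2) ds`, computed through the
#' normal CDF; `erfcinv()` inverts it on (0, 2). Used by the Taylor-dispersion
#' front model, where the activation-threshold crossing of an erfc-shaped
#' concentration profile appears in closed form.
#'
#' @param x numeric vector.
#' @param y numeric vector in (0, 2).
#' @return numeric vector.
#' @examples
#' erfc(0)          # 1
#' erfcinv(1)       # 0
#' erfc(erfcinv(0.5))
#' @export
erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))

#' @rdname erfc
#' @export
erfcinv <- function(y) {
  if (any(y <= 0 | y >= 2)) stop("erfcinv() is defined on (0, 2)")
  -stats::qnorm(y / 2) / sqrt(2)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  force(code)
}

stop_config <- function(...) {
  stop(structure(class = c("pw_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("pw_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(name, " must be a positive finite scalar")
  }
  invisible(x)
}
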