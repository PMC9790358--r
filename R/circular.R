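#' Signed circular difference between two angles
#'
#' Computes `a - b` on a 360-degree ring, mapped into the half-open interval
#' (-180, 180]. This is the signed angular distance used throughout the
#' package for prediction errors and bucket updates: positive values mean
#' `a` lies counter-clockwise of `b` by less than half a turn. At the exact
#' antipode the convention is +180 for both orders.
#'
#' @param a,b numeric vectors of angles in degrees (any finite values;
#'   recycled to a common length).
#' @return numeric vector of signed differences in (-180, 180].
#' @examples
#' circ_diff(10, 350)   # +20, wraps across 0
#' circ_diff(0, 180)    # +180 by convention
#' @export
circ_diff <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || anyNA(a) || anyNA(b) ||
      any(!is.finite(a)) || any(!is.finite(b))) {
    stop("circ_diff() requires finite numeric angles")
  }
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Wrap angles to [0, 360)
#'
#' @param x numeric vector of angles in degrees.
#' @return angles reduced modulo 360 into [0, 360).
#' @export
wrap_angle <- function(x) x %% 360

# Signed difference under the selected geometry. "linear" treats the 0-360
# scale as a line (no wrap), which some legacy analyses of this task used.
signed_diff <- function(a, b, geometry = "circular") {
  if (geometry == "linear") a - b else circ_diff(a, b)
}
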