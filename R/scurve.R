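#' Two-anchor S-curve of the EPIC family
#'
#' Monotone increasing sigmoid `f(x) = x / (x + exp(b1 - b2 * x))` with the
#' shape coefficients `(b1, b2)` solved so the curve passes through two anchor
#' points. This is the convention used throughout EPIC-style models to encode
#' process response functions as two (x, y) pairs, with y conventionally given
#' in percent.
#'
#' @param x numeric vector of evaluation points (x > 0 for non-trivial values;
#'   `f(0) = 0` and x < 0 is clamped to 0).
#' @param anchor1,anchor2 numeric length-2 vectors `c(x, y)`; `y` is a
#'   fraction in (0, 1) when `y_percent = FALSE` (default) or in percent.
#' @param y_percent logical; divide anchor y values by 100 first.
#' @return values in (0, 1), same length as `x`.
#' @examples
#' scurve_from_anchors(0.5, c(0.2, 0.1), c(0.9, 0.95))
#' @export
scurve_from_anchors <- function(x, anchor1, anchor2, y_percent = FALSE) {
  ab <- scurve_coef(anchor1, anchor2, y_percent)
  xx <- pmax(x, 0)
  unname(xx / (xx + exp(ab[[1]] - ab[[2]] * xx)))
}

# solve (b1, b2) from the two anchors; shared by the R and C++ engines
scurve_coef <- function(anchor1, anchor2, y_percent = FALSE) {
  x1 <- anchor1[1]; y1 <- anchor1[2]
  x2 <- anchor2[1]; y2 <- anchor2[2]
  if (y_percent) { y1 <- y1 / 100; y2 <- y2 / 100 }
  if (!(x1 < x2) || !(y1 > 0 && y1 < 1) || !(y2 > 0 && y2 < 1) || !(y1 < y2))
    stop("degenerate S-curve anchors: need x1 < x2 and 0 < y1 < y2 < 1")
  # x/(x + exp(b1 - b2 x)) = y  =>  b1 - b2 x = log(x (1 - y) / y)
  r1 <- log(x1 * (1 - y1) / y1)
  r2 <- log(x2 * (1 - y2) / y2)
  b2 <- (r1 - r2) / (x2 - x1)
  b1 <- r1 + b2 * x1
  c(b1 = b1, b2 = b2)
}
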