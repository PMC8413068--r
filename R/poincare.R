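#' Second-order difference Poincare plot
#'
#' Builds the scatter of consecutive first differences of a sequence x:
#' `X(t) = x(t+1) - x(t)` plotted against `Y(t) = x(t+2) - x(t+1)`. No
#' normalisation or detrending is applied. The plot's dispersion tracks
#' short-term variability of x: a constant or linearly drifting signal
#' collapses to a single point, an oscillatory mode spreads into an
#' ellipse-like cloud.
#'
#' @param x numeric vector, length at least 3.
#' @return A [PoincarePlot-class] with `length(x) - 2` points.
#' @examples
#' pp <- poincarePlot(c(1, 2, 4, 8))
#' length(pp)  # 2 points: (1,2) and (2,4)
#' @export
poincarePlot <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 3L)
    stop("a Poincare plot needs at least 3 samples, got ", length(x))
  d <- diff(x)
  n <- length(d)
  new("PoincarePlot", X = d[-n], Y = d[-1])
}

#' Fitted-ellipse descriptor of a Poincare plot
#'
#' Second-moment ellipse of the plot: with `SX = sqrt(mean(X^2))`,
#' `SY = sqrt(mean(Y^2))` and `SXY = mean(X * Y)` (raw moments about the
#' origin, not centred), the radii are the square roots of the
#' eigenvalues of the 2x2 second-moment matrix
#' `[[SX^2, SXY], [SXY, SY^2]]`, i.e. `lambda = ((SX^2 + SY^2) +/- D)/2`
#' with `D = sqrt((SX^2 - SY^2)^2 + 4 * SXY^2)`, and the area is
#' `pi * a * b`. Eigenvalues that round off to tiny negatives are clamped
#' by absolute value so the radii stay real.
#'
#' @param pp a [PoincarePlot-class] with at least 2 points.
#' @return list with elements `SX`, `SY`, `SXY`, `D`, `a` (major
#'   radius), `b` (minor radius, `a >= b >= 0`) and `area`.
#' @examples
#' pp <- poincarePlot(cumsum(rnorm(100)))
#' ellipseDescriptor(pp)$area
#' @export
ellipseDescriptor <- function(pp) {
  stopifnot(is(pp, "PoincarePlot"))
  n <- length(pp)
  if (n < 2L)
    stop("ellipse descriptor needs at least 2 points, got ", n)
  X <- pp@X; Y <- pp@Y
  sx2 <- mean(X^2)
  sy2 <- mean(Y^2)
  sxy <- mean(X * Y)
  D <- sqrt((sx2 - sy2)^2 + 4 * sxy^2)
  lam1 <- (sx2 + sy2 + D) / 2
  lam2 <- (sx2 + sy2 - D) / 2
  a <- sqrt(abs(lam1))
  b <- sqrt(abs(lam2))
  list(SX = sqrt(sx2), SY = sqrt(sy2), SXY = sxy, D = D,
       a = a, b = b, area = pi * a * b)
}

#' Mean radial distance of a Poincare plot
#'
#' Average Euclidean distance of the plot points from the origin,
#' `mean(sqrt(X^2 + Y^2))`. Reported in feature tables under the column
#' `m`; the radius parameter attached to that column is metadata only
#' (the mean distance itself does not depend on it).
#'
#' @param pp a [PoincarePlot-class] with at least 1 point.
#' @return nonnegative number.
#' @export
meanDistance <- function(pp) {
  stopifnot(is(pp, "PoincarePlot"))
  if (length(pp) < 1L) stop("mean distance of an empty Poincare plot is undefined")
  mean(sqrt(pp@X^2 + pp@Y^2))
}

#' Central tendency measure of a Poincare plot
#'
#' Fraction of plot points falling strictly inside the circle of radius
#' `r` around the origin. High CTM means the differences concentrate
#' near zero (low short-term variability).
#'
#' @param pp a [PoincarePlot-class] with at least 1 point.
#' @param r radius (> 0); feature tables conventionally use `r = 0.5`.
#' @return value in `[0, 1]`.
#' @export
ctm <- function(pp, r = 0.5) {
  stopifnot(is(pp, "PoincarePlot"))
  if (length(pp) < 1L) stop("CTM of an empty Poincare plot is undefined")
  if (!is.numeric(r) || length(r) != 1L || r <= 0)
    stop("radius r must be a single positive number")
  mean(sqrt(pp@X^2 + pp@Y^2) < r)
}

#' All three Poincare descriptors of a mode signal
#'
#' Convenience wrapper: builds the second-order difference plot of `x`
#' and returns ellipse area, mean radial distance and CTM at radius `r`.
#'
#' @param x numeric mode signal (length >= 4 so the plot has >= 2 points).
#' @param r CTM radius, default 0.5.
#' @return list with `area`, `m`, `ctm`, `r`.
#' @export
ppFeatures <- function(x, r = 0.5) {
  pp <- poincarePlot(x)
  list(area = ellipseDescriptor(pp)$area,
       m = meanDistance(pp),
       ctm = ctm(pp, r),
       r = r)
}
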