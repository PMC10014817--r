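#' Degree-5 interpolating B-spline
#'
#' Fits the quintic B-spline that passes exactly through every sample,
#' parameterised by gait-cycle progress (0--100 %). The knot vector uses
#' full-multiplicity end knots and de Boor averaging of interior parameters,
#' which guarantees the Schoenberg--Whitney conditions and a well-conditioned
#' collocation system.
#'
#' @param x Strictly increasing sample parameters (percent of cycle, or any
#'   strictly increasing abscissa). At least 6 values.
#' @param y Sample values (degrees for angle curves).
#' @return An object of class `quintic_spline` with elements `knots`,
#'   `coef`, `range`.
#' @export
#' @examples
#' s <- fit_spline(seq(0, 100, by = 5), sin(seq(0, 100, by = 5) / 10))
#' eval_spline(s, c(2.5, 97.5))
fit_spline <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 6)
    stop("degree-5 interpolation needs at least 6 samples; supply a denser ",
         "trajectory (no degree fallback is applied)", call. = FALSE)
  if (any(diff(x) <= 0)) stop("parameters must be strictly increasing",
                              call. = FALSE)
  if (any(!is.finite(y))) stop("non-finite sample values", call. = FALSE)
  ord <- 6L
  n <- length(x)
  interior <- if (n > ord) {
    # de Boor averaging: t_i = mean(x[i+1], ..., x[i+5])
    vapply(seq_len(n - ord), function(i) mean(x[(i + 1):(i + ord - 1)]),
           numeric(1))
  } else numeric(0)
  knots <- c(rep(x[1], ord), interior, rep(x[n], ord))
  B <- splines::splineDesign(knots, x, ord = ord)
  coef <- solve(B, y)
  structure(list(knots = knots, coef = coef, range = c(x[1], x[n]), ord = ord),
            class = "quintic_spline")
}

#' Evaluate a quintic spline (or a derivative)
#'
#' @param spline A [fit_spline()] object.
#' @param s Evaluation parameters, inside the fitted range.
#' @param deriv Derivative order (0 = value, 1 = first derivative, ...).
#' @return Numeric vector of values.
#' @export
eval_spline <- function(spline, s, deriv = 0L) {
  stopifnot(inherits(spline, "quintic_spline"))
  if (any(s < spline$range[1] - 1e-9 | s > spline$range[2] + 1e-9))
    stop("evaluation outside the fitted parameter range", call. = FALSE)
  s <- pmin(pmax(s, spline$range[1]), spline$range[2])
  B <- splines::splineDesign(spline$knots, s, ord = spline$ord,
                             derivs = rep(as.integer(deriv), length(s)))
  drop(B %*% spline$coef)
}

#' @export
print.quintic_spline <- function(x, ...) {
  cat("<quintic_spline> ", length(x$coef), " coefficients on [",
      x$range[1], ", ", x$range[2], "]\n", sep = "")
  invisible(x)
}

cycle_grid <- function() 0:100

#' Normalised angular velocity of an angle curve
#'
#' The normalised angular velocity (NAV) is the slope of the tangent to the
#' plot of a physiological angle against gait-cycle progress, in degrees per
#' percent of cycle. It is obtained analytically as the first derivative of
#' the quintic interpolating spline of the angle.
#'
#' @param spline A [fit_spline()] object of an angle in degrees over 0--100.
#' @param grid Evaluation grid in percent of cycle (default the canonical
#'   101-point grid `0:100`).
#' @return Tibble with columns `pct` and `nav` (degrees/%).
#' @export
#' @examples
#' pct <- seq(0, 100, by = 2)
#' sp <- fit_spline(pct, 0.5 * pct)     # steady 0.5 deg/% ramp
#' nav_from_angle(sp)$nav[1:3]
nav_from_angle <- function(spline, grid = cycle_grid()) {
  tibble::tibble(pct = grid, nav = eval_spline(spline, grid, deriv = 1L))
}

#' Angular velocity from a quaternion orientation trajectory
#'
#' Fits quintic splines to the four components of a hemisphere-aligned unit
#' quaternion trajectory (scalar-first) parameterised by gait-cycle progress,
#' and maps the spline derivatives to the body-independent (space-frame)
#' angular velocity: `omega(s) = 2 * qdot(s) * conj(q(s))` (vector part),
#' converted to degrees per percent of cycle. The interpolated quaternion is
#' renormalised before the product, so `omega` is tangent-exact for unit
#' trajectories.
#'
#' @param pct Sample parameters in percent of cycle (strictly increasing,
#'   >= 6 samples).
#' @param quat Numeric matrix `length(pct) x 4`, columns `w, x, y, z`;
#'   rows must be unit quaternions, hemisphere-aligned.
#' @param grid Evaluation grid (default `0:100`).
#' @return Tibble with columns `pct`, `wx`, `wy`, `wz` (degrees/%).
#' @export
nav_from_orientation <- function(pct, quat, grid = cycle_grid()) {
  quat <- as.matrix(quat)
  stopifnot(ncol(quat) == 4, nrow(quat) == length(pct))
  comps <- lapply(1:4, function(j) fit_spline(pct, quat[, j]))
  q <- vapply(comps, eval_spline, numeric(length(grid)), s = grid)
  qd <- vapply(comps, eval_spline, numeric(length(grid)), s = grid,
               deriv = 1L)
  if (length(grid) == 1) { q <- matrix(q, 1); qd <- matrix(qd, 1) }
  nrm <- sqrt(rowSums(q^2))
  if (any(nrm < 0.5))
    stop("interpolated quaternion norm fell below 0.5; the orientation ",
         "trajectory is too sparse or ill-conditioned", call. = FALSE)
  # renormalise and project the derivative onto the unit sphere's tangent
  qn <- q / nrm
  qdn <- (qd - qn * rowSums(qd * qn)) / nrm
  w <- 2 * quat_mul(qdn, quat_conj(qn))
  tibble::tibble(pct = grid,
                 wx = w[, 2] * 180 / pi,
                 wy = w[, 3] * 180 / pi,
                 wz = w[, 4] * 180 / pi)
}

# rowwise Hamilton product of scalar-first quaternion matrices
quat_mul <- function(a, b) {
  cbind(a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
        a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
        a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
        a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1])
}

quat_conj <- function(q) cbind(q[, 1], -q[, 2], -q[, 3], -q[, 4])
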