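#' One wall-corrected experimental drag observation
#'
#' @param Re Measured Reynolds number, positive.
#' @param C_D Wall-corrected (unbounded-domain) drag coefficient, positive.
#' @param S Scale factor of the model that produced the point (provenance).
#' @param experiment_id Free-text identifier.
#' @return A one-row data.frame; rows from several experiments can be
#'   `rbind`-ed and passed to [fit_drag_spline()].
#' @export
drag_data_point <- function(Re, C_D, S = NA_real_, experiment_id = NA_character_) {
  check_positive_scalar(Re, "Re")
  check_positive_scalar(C_D, "C_D")
  data.frame(Re = Re, C_D = C_D, S = as.numeric(S),
             experiment_id = as.character(experiment_id),
             stringsAsFactors = FALSE)
}

#' Fit the empirical drag curve C_D^E(Re)
#'
#' Fits a shape-constrained spline through experimental (Re, C_D) points. The
#' fit is performed on (log10 Re, log10 C_D), where drag curves are close to
#' power laws, using three spline knots: the two ends of the data range plus
#' one interior knot whose position is chosen by least squares over a small
#' candidate grid (falling back to the log-range midpoint). The curve is
#' constrained to be monotonically decreasing and concave-up within the limits
#' of the data, matching the expected behaviour of drag on compact particles
#' at low to moderate Re; the constraints are enforced on a dense grid of at
#' least 200 points across the data range. A convex decreasing curve in
#' log-log coordinates is automatically convex and decreasing in linear
#' coordinates as well.
#'
#' With three data points the cubic fit effectively interpolates (a tiny
#' curvature penalty selects the smoothest interpolant); as points accumulate
#' it becomes a constrained least-squares fit. If the data are incompatible
#' with the constraints beyond noise, the best feasible fit is returned with a
#' warning.
#'
#' @param points data.frame with columns `Re` and `C_D` (rows from
#'   [drag_data_point()], or any data.frame with those columns); at least 3
#'   points with distinct Re.
#' @param order `"cubic"` (default) or `"linear"` spline.
#' @return An object of class `drag_curve`. Evaluate with
#'   [predict.drag_curve()]; outside the data range the curve is continued by
#'   linear extrapolation in fit (log-log) space and flagged.
#' @examples
#' Re <- c(10, 20, 40, 70, 100)
#' pts <- data.frame(Re = Re, C_D = morrison_cd(Re))
#' crv <- fit_drag_spline(pts)
#' predict(crv, 50)
#' @export
fit_drag_spline <- function(points, order = c("cubic", "linear")) {
  order <- match.arg(order)
  if (!is.data.frame(points) || !all(c("Re", "C_D") %in% names(points))) {
    stop("points must be a data.frame with columns Re and C_D", call. = FALSE)
  }
  if (nrow(points) < 3L) {
    stop("insufficient data: at least 3 (Re, C_D) points are needed to fit a drag curve",
         call. = FALSE)
  }
  if (any(!is.finite(points$Re)) || any(points$Re <= 0) ||
      any(!is.finite(points$C_D)) || any(points$C_D <= 0)) {
    stop("all Re and C_D values must be positive and finite", call. = FALSE)
  }
  if (anyDuplicated(signif(points$Re, 12))) {
    stop("invalid input: duplicate Re values among drag data points", call. = FALSE)
  }
  ord <- if (order == "cubic") 4L else 2L
  o <- order(points$Re)
  x <- log10(points$Re)[o]
  y <- log10(points$C_D)[o]
  x0 <- x[1]; x1 <- x[length(x)]

  # interior knot: least squares over a candidate grid, midpoint fallback
  cands <- x0 + (x1 - x0) * seq(0.3, 0.7, length.out = 5)
  best <- NULL
  for (xm in cands) {
    f <- tryCatch(fit_at_knot(x, y, x0, xm, x1, ord), error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$ssr < best$ssr)) best <- f
  }
  if (is.null(best)) {
    best <- fit_at_knot(x, y, x0, x0 + (x1 - x0) / 2, x1, ord)
  }
  # data rising by >20% between consecutive Re cannot be explained by
  # replicate-level noise: the constrained curve is then a compromise
  data_infeasible <- any(diff(y) > log10(1.2))
  if (best$violation > 1e-6 || data_infeasible) {
    warning("drag data incompatible with monotone-decreasing/concave-up constraints; ",
            "returning best feasible fit", call. = FALSE)
  }

  kf <- best$knots_full
  # boundary values and slopes in fit space, for linear extrapolation
  b_lo <- spline_eval(kf, ord, best$coef, x0, derivs = 0:1)
  b_hi <- spline_eval(kf, ord, best$coef, x1, derivs = 0:1)
  structure(list(order = order, ord = ord,
                 knots_full = kf, coef = best$coef,
                 data_range = 10^c(x0, x1), x_range = c(x0, x1),
                 boundary = list(lo = b_lo, hi = b_hi),
                 fit_space = "log10(C_D) vs log10(Re)",
                 rms = sqrt(best$ssr / length(x)),
                 points = data.frame(Re = 10^x, C_D = 10^y)),
            class = "drag_curve")
}

#' @export
print.drag_curve <- function(x, ...) {
  cat(sprintf("<drag_curve> %s spline on %s, %d points, Re in [%.4g, %.4g], fit RMS %.2e (log10)\n",
              x$order, x$fit_space, nrow(x$points),
              x$data_range[1], x$data_range[2], x$rms))
  invisible(x)
}

#' Evaluate a fitted drag curve
#'
#' Inside the data range the fitted spline is evaluated; outside, the curve is
#' continued linearly in fit (log-log) space from the nearest boundary, and
#' the returned vector carries a logical attribute `"extrapolated"` marking
#' those evaluations (see [drag_curve_extrapolated()]).
#'
#' @param object A `drag_curve` from [fit_drag_spline()].
#' @param Re Reynolds number(s), positive.
#' @param ... Unused.
#' @return Numeric `C_D` value(s) with attribute `"extrapolated"`.
#' @export
predict.drag_curve <- function(object, Re, ...) {
  if (any(!is.finite(Re)) || any(Re <= 0)) {
    stop("Re must be positive and finite", call. = FALSE)
  }
  xs <- log10(Re)
  ys <- numeric(length(xs))
  lo <- xs < object$x_range[1]
  hi <- xs > object$x_range[2]
  inside <- !(lo | hi)
  if (any(inside)) {
    ys[inside] <- spline_eval(object$knots_full, object$ord, object$coef,
                              xs[inside], derivs = 0)[, 1]
  }
  if (any(lo)) {
    b <- object$boundary$lo
    ys[lo] <- b[1] + b[2] * (xs[lo] - object$x_range[1])
  }
  if (any(hi)) {
    b <- object$boundary$hi
    ys[hi] <- b[1] + b[2] * (xs[hi] - object$x_range[2])
  }
  out <- 10^ys
  attr(out, "extrapolated") <- lo | hi
  out
}

#' Which evaluations of a drag curve would be extrapolations?
#'
#' @param curve A `drag_curve`.
#' @param Re Reynolds number(s).
#' @return Logical vector, `TRUE` where `Re` lies outside the fitted data range.
#' @export
drag_curve_extrapolated <- function(curve, Re) {
  stopifnot(inherits(curve, "drag_curve"))
  Re < curve$data_range[1] | Re > curve$data_range[2]
}

#' Serialize / restore a drag curve
#'
#' Writes the knots, coefficients, order and data range of a fitted curve as
#' JSON for audit trails, and restores an evaluable curve from that JSON.
#'
#' @param curve A `drag_curve`.
#' @param path Optional file path; if `NULL`, the JSON string is returned.
#' @return `drag_curve_to_json()`: the JSON string (invisibly, if written to a
#'   file); `drag_curve_from_json()`: a `drag_curve`.
#' @export
drag_curve_to_json <- function(curve, path = NULL) {
  stopifnot(inherits(curve, "drag_curve"))
  payload <- list(order = curve$order, ord = curve$ord,
                  knots_full = curve$knots_full, coef = curve$coef,
                  x_range = curve$x_range, fit_space = curve$fit_space,
                  rms = curve$rms, points = curve$points)
  js <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' @rdname drag_curve_to_json
#' @param json JSON string or path to a JSON file produced by
#'   [drag_curve_to_json()].
#' @export
drag_curve_from_json <- function(json) {
  p <- jsonlite::fromJSON(json)
  kf <- as.numeric(p$knots_full)
  coef <- as.numeric(p$coef)
  ord <- as.integer(p$ord)
  xr <- as.numeric(p$x_range)
  b_lo <- spline_eval(kf, ord, coef, xr[1], derivs = 0:1)
  b_hi <- spline_eval(kf, ord, coef, xr[2], derivs = 0:1)
  structure(list(order = p$order, ord = ord, knots_full = kf, coef = coef,
                 data_range = 10^xr, x_range = xr,
                 boundary = list(lo = b_lo, hi = b_hi),
                 fit_space = p$fit_space, rms = as.numeric(p$rms),
                 points = as.data.frame(p$points)),
            class = "drag_curve")
}

# ---- internal fitting machinery ----

# Evaluate the B-spline with full knot vector kf, order ord and coefficients
# coef at points xs; derivs is a vector of derivative orders, one column each.
spline_eval <- function(kf, ord, coef, xs, derivs = 0) {
  out <- vapply(derivs, function(d) {
    B <- splines::splineDesign(kf, xs, ord = ord, derivs = rep(d, length(xs)))
    as.numeric(B %*% coef)
  }, numeric(length(xs)))
  matrix(out, nrow = length(xs))
}

# Constrained least-squares fit for fixed knots. Monotone decrease (f' <= 0)
# and, for cubics, convexity (f'' >= 0) are imposed via an escalating
# quadratic penalty on a dense grid; returns coef, SSR and residual violation.
fit_at_knot <- function(x, y, x0, xm, x1, ord) {
  kf <- c(rep(x0, ord), xm, rep(x1, ord))
  p <- length(kf) - ord
  B <- splines::splineDesign(kf, x, ord = ord)
  m <- 201L
  xg <- seq(x0, x1, length.out = m)
  B1 <- splines::splineDesign(kf, xg, ord = ord, derivs = rep(1L, m))
  B2 <- if (ord >= 3L) splines::splineDesign(kf, xg, ord = ord, derivs = rep(2L, m)) else NULL
  n <- length(x)
  yscale <- max(stats::var(y), 1e-4)

  # tiny curvature penalty: regularizes the under-determined 3-point cubic case
  ws <- 1e-7 * yscale
  G <- if (!is.null(B2)) crossprod(B2) / m else crossprod(B1) / m

  start <- tryCatch(
    solve(crossprod(B) / n + ws * G + 1e-12 * diag(p), crossprod(B, y) / n),
    error = function(e) rep(mean(y), p))
  start <- as.numeric(start)

  violation <- function(cf) {
    v1 <- max(B1 %*% cf, 0)
    v2 <- if (!is.null(B2)) max(-(B2 %*% cf), 0) else 0
    max(v1, v2)
  }

  cf <- start
  if (violation(cf) > 1e-8) {
    for (wp in yscale * c(1e2, 1e4, 1e6, 1e8)) {
      objgrad <- make_shape_objective(B, y, B1, B2, ws, G, wp)
      fit <- stats::nlminb(cf, objgrad$fn, objgrad$gr,
                           control = list(iter.max = 500, eval.max = 1000))
      cf <- fit$par
      if (violation(cf) <= 1e-8) break
    }
  }
  res <- as.numeric(B %*% cf) - y
  list(coef = cf, knots_full = kf, ssr = sum(res^2), violation = violation(cf))
}

make_shape_objective <- function(B, y, B1, B2, ws, G, wp) {
  n <- nrow(B); m <- nrow(B1)
  fn <- function(cf) {
    r <- as.numeric(B %*% cf) - y
    s1 <- pmax(as.numeric(B1 %*% cf), 0)
    s2 <- if (!is.null(B2)) pmax(-as.numeric(B2 %*% cf), 0) else 0
    sum(r^2) / n + ws * as.numeric(crossprod(cf, G %*% cf)) +
      wp * (sum(s1^2) + sum(s2^2)) / m
  }
  gr <- function(cf) {
    r <- as.numeric(B %*% cf) - y
    g <- 2 * crossprod(B, r) / n + 2 * ws * (G %*% cf)
    s1 <- pmax(as.numeric(B1 %*% cf), 0)
    g <- g + 2 * wp * crossprod(B1, s1) / m
    if (!is.null(B2)) {
      s2 <- pmax(-as.numeric(B2 %*% cf), 0)
      g <- g - 2 * wp * crossprod(B2, s2) / m
    }
    as.numeric(g)
  }
  list(fn = fn, gr = gr)
}
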