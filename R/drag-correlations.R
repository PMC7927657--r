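#' Reference drag-coefficient curve
#'
#' A drag correlation packages an evaluator mapping Reynolds number to drag
#' coefficient together with its validity interval. Evaluation outside the
#' interval is an error for the sphere reference curve; ground-truth curves
#' used by the virtual tank are built with [perturbed_cd()].
#'
#' @param evaluator Function of `Re` returning `C_D`.
#' @param validity Length-2 numeric, the open Re interval on which the curve
#'   is defined.
#' @param name Curve name.
#' @return An object of class `drag_correlation`; call it like a function or
#'   use [eval_drag()].
#' @export
drag_correlation <- function(evaluator, validity = c(0, 1e6), name = "drag correlation") {
  stopifnot(is.function(evaluator), length(validity) == 2L, validity[1] < validity[2])
  structure(list(evaluator = evaluator, validity = as.numeric(validity),
                 name = as.character(name)),
            class = "drag_correlation")
}

#' @export
print.drag_correlation <- function(x, ...) {
  cat(sprintf("<drag_correlation> %s, valid for Re in (%g, %g)\n",
              x$name, x$validity[1], x$validity[2]))
  invisible(x)
}

#' Evaluate a drag correlation
#'
#' @param corr A [drag_correlation()].
#' @param Re Reynolds number(s).
#' @return `C_D` value(s).
#' @export
eval_drag <- function(corr, Re) {
  stopifnot(inherits(corr, "drag_correlation"))
  if (any(!is.finite(Re)) || any(Re <= corr$validity[1]) || any(Re >= corr$validity[2])) {
    stop(sprintf("Re outside validity interval (%g, %g) of '%s'",
                 corr$validity[1], corr$validity[2], corr$name), call. = FALSE)
  }
  corr$evaluator(Re)
}

#' Morrison sphere drag correlation
#'
#' The four-term empirical fit of the standard sphere drag curve, valid for
#' 0 < Re < 1e6, covering the Stokes limit (C_D -> 24/Re), the intermediate
#' regime, the pre-crisis plateau and the drag crisis:
#' \deqn{C_D = \frac{24}{Re}
#'   + \frac{2.6\,(Re/5)}{1 + (Re/5)^{1.52}}
#'   + \frac{0.411\,(Re/2.63\times 10^5)^{-7.94}}{1 + (Re/2.63\times 10^5)^{-8.00}}
#'   + \frac{0.25\,(Re/10^6)}{1 + Re/10^6}.}
#' For a sphere at Re = 1000 it gives about 0.48, matching the textbook value
#' of roughly 0.5. Used to seed the iterative loop with initial guesses before
#' any shape-specific data exist.
#'
#' @param Re Reynolds number(s), 0 < Re < 1e6.
#' @return Sphere drag coefficient(s).
#' @examples
#' morrison_cd(1000)
#' morrison_cd(0.001) * 0.001 / 24 # -> 1 in the Stokes limit
#' @export
morrison_cd <- function(Re) {
  if (any(!is.finite(Re)) || any(Re <= 0) || any(Re >= 1e6)) {
    stop("morrison_cd: Re must satisfy 0 < Re < 1e6", call. = FALSE)
  }
  24 / Re +
    2.6 * (Re / 5) / (1 + (Re / 5)^1.52) +
    0.411 * (Re / 2.63e5)^-7.94 / (1 + (Re / 2.63e5)^-8.00) +
    0.25 * (Re / 1e6) / (1 + Re / 1e6)
}

#' The Morrison curve as a drag_correlation object
#'
#' @return A [drag_correlation()] wrapping [morrison_cd()].
#' @export
morrison_correlation <- function() {
  drag_correlation(morrison_cd, validity = c(0, 1e6), name = "Morrison sphere")
}

#' Perturb a drag correlation
#'
#' Builds a new curve `C_D(Re) = factor * base(Re) * Re^exponent_shift`. Used
#' to manufacture ground-truth drag curves for non-spherical virtual particles
#' whose drag differs from a sphere's by a multiplicative offset and a mild
#' change of power-law slope. Construction fails if the perturbation breaks
#' positivity or strict monotone decrease on Re in [1, 100] (checked on a
#' logarithmic sample grid), since such a curve would no longer look like drag
#' on a compact particle at low to moderate Re.
#'
#' @param base A [drag_correlation()].
#' @param factor Positive multiplier.
#' @param exponent_shift Additive change to the local log-log slope.
#' @return A new [drag_correlation()].
#' @examples
#' rough_sphere <- perturbed_cd(morrison_correlation(), factor = 1.5)
#' @export
perturbed_cd <- function(base, factor = 1, exponent_shift = 0) {
  stopifnot(inherits(base, "drag_correlation"))
  check_positive_scalar(factor, "factor")
  stopifnot(is.numeric(exponent_shift), length(exponent_shift) == 1L, is.finite(exponent_shift))
  f <- function(Re) factor * base$evaluator(Re) * Re^exponent_shift
  grid <- 10^seq(0, 2, length.out = 101)
  vals <- f(grid)
  if (any(!is.finite(vals)) || any(vals <= 0) || any(diff(vals) >= 0)) {
    stop("perturbed_cd: perturbation breaks positivity or monotone decrease on Re in [1, 100]",
         call. = FALSE)
  }
  drag_correlation(f, validity = base$validity,
                   name = sprintf("%s x %g * Re^%g", base$name, factor, exponent_shift))
}
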