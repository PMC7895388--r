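#' Specify a switching nonlinearity
#'
#' The regulatory interactions of the model are sigmoidal Hill functions
#' \eqn{x^n/(\theta^n + x^n)}. In the sharp-switch limit \eqn{n \to \infty}
#' the sigmoid becomes the Heaviside step \eqn{H(x - \theta)}. A
#' `switch_spec` records which of the two regimes is meant and, for the
#' finite regime, the exponent.
#'
#' @param mode `"finite"` for a Hill function, `"heaviside"` for the step.
#' @param exponent Hill exponent, required (and `> 1`) when `mode` is
#'   `"finite"`; ignored otherwise.
#' @return An object of class `switch_spec`.
#' @examples
#' hill(2, 1, switch_spec("heaviside"))
#' hill(1, 1, switch_spec("finite", 10))
#' @export
switch_spec <- function(mode = c("finite", "heaviside"), exponent = NULL) {
  mode <- match.arg(mode)
  if (mode == "finite") {
    if (is.null(exponent) || !is.numeric(exponent) || length(exponent) != 1L ||
        !is.finite(exponent) || exponent <= 1) {
      stop("finite mode requires a single Hill exponent > 1", call. = FALSE)
    }
  } else {
    exponent <- Inf
  }
  structure(list(mode = mode, exponent = exponent), class = "switch_spec")
}

#' @export
print.switch_spec <- function(x, ...) {
  if (x$mode == "finite") {
    cat(sprintf("<switch_spec> Hill, exponent %g\n", x$exponent))
  } else {
    cat("<switch_spec> Heaviside (sharp-switch limit)\n")
  }
  invisible(x)
}

#' Hill / Heaviside switching function
#'
#' `hill(x, theta, spec)` is \eqn{x^n/(\theta^n + x^n)} in finite mode and
#' the unit step \eqn{H(x - \theta)} in Heaviside mode. At the threshold the
#' Heaviside branch returns 1/2, the limiting value of the finite branch;
#' every region definition downstream uses strict inequalities, so the value
#' on this measure-zero set never matters.
#'
#' The finite branch is computed as \eqn{r^n/(1 + r^n)} with
#' \eqn{r = x/\theta}, which avoids overflow of \eqn{x^n} for large
#' arguments or exponents.
#'
#' @param x Nonnegative numeric vector.
#' @param theta Positive threshold (scalar or vector recycled against `x`).
#' @param spec A [switch_spec()].
#' @return Values in `[0, 1]`, same length as `x`.
#' @export
hill <- function(x, theta, spec) {
  stopifnot(inherits(spec, "switch_spec"))
  if (any(!is.finite(x)) && !all(is.finite(x) | x == Inf)) {
    stop("x must be finite or +Inf", call. = FALSE)
  }
  if (any(x < 0)) stop("hill() requires x >= 0", call. = FALSE)
  if (any(theta <= 0)) stop("hill() requires theta > 0", call. = FALSE)
  if (spec$mode == "heaviside") {
    return(as.numeric(x > theta) + 0.5 * (x == theta))
  }
  r <- x / theta
  rn <- r ^ spec$exponent
  out <- rn / (1 + rn)
  out[is.infinite(rn)] <- 1
  out
}
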