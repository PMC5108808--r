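#' Coding transforms for sensory and effector mappings
#'
#' A transform is a deterministic real-to-real function bundled with its
#' derivative, used both as the viscerosensory coding function `g` (body
#' state to sensory input) and as the effector mapping `f` (action to rate
#' of change of the state). Built-in transforms carry analytic gradients;
#' arbitrary functions fall back to a central finite difference.
#'
#' @param slope,intercept Parameters of the affine map `a*x + b`.
#' @param scale,midpoint Parameters of the logistic map
#'   `scale / (1 + exp(-slope * (x - midpoint)))`.
#' @param cap Saturation bound of the odd, bounded map `cap * tanh(x / cap)`
#'   (slope 1 at the origin, |value| < cap everywhere). Useful as an
#'   effector with finite corrective capacity.
#' @param fun A function of one numeric argument.
#' @param name Label used when printing and serializing.
#'
#' @details
#' `saturating_transform()` models an effector that cannot exceed a maximal
#' corrective rate; with it, sustained disturbances faster than the cap
#' cannot be compensated and the controlled state diverges.
#'
#' Custom transforms built with [as_transform()] use a central finite
#' difference with step `h = 1e-6 * max(1, |x|)` for the gradient and are
#' not serializable to scenario JSON.
#'
#' @return An object of class `reflex_transform`: a list with elements
#'   `fun`, `grad`, `name`, and `params`.
#' @examples
#' g <- logistic_transform(scale = 2, slope = 1, midpoint = 0)
#' g$fun(0)      # 1
#' g$grad(0)     # 0.5
#' @name transforms
NULL

new_transform <- function(fun, grad, name, params = list()) {
  structure(list(fun = fun, grad = grad, name = name, params = params),
            class = "reflex_transform")
}

#' @rdname transforms
#' @export
identity_transform <- function() {
  new_transform(function(x) x, function(x) rep(1, length(x)), "identity")
}

#' @rdname transforms
#' @export
linear_transform <- function(slope = 1, intercept = 0) {
  stopifnot(is.finite(slope), is.finite(intercept))
  new_transform(function(x) slope * x + intercept,
                function(x) rep(slope, length(x)),
                "linear", list(slope = slope, intercept = intercept))
}

#' @rdname transforms
#' @export
logistic_transform <- function(scale = 1, slope = 1, midpoint = 0) {
  stopifnot(is.finite(scale), is.finite(slope), is.finite(midpoint))
  new_transform(
    function(x) scale / (1 + exp(-slope * (x - midpoint))),
    function(x) {
      p <- 1 / (1 + exp(-slope * (x - midpoint)))
      scale * slope * p * (1 - p)
    },
    "logistic", list(scale = scale, slope = slope, midpoint = midpoint))
}

#' @rdname transforms
#' @export
saturating_transform <- function(cap = 1) {
  stopifnot(is.finite(cap), cap > 0)
  new_transform(function(x) cap * tanh(x / cap),
                function(x) 1 / cosh(x / cap)^2,
                "saturating", list(cap = cap))
}

#' @rdname transforms
#' @export
as_transform <- function(fun, name = "custom") {
  if (inherits(fun, "reflex_transform")) return(fun)
  stopifnot(is.function(fun))
  new_transform(
    fun,
    function(x) {
      h <- 1e-6 * pmax(1, abs(x))
      (fun(x + h) - fun(x - h)) / (2 * h)
    },
    name)
}

#' @export
print.reflex_transform <- function(x, ...) {
  ps <- if (length(x$params))
    paste0("(", paste(names(x$params), unlist(x$params), sep = " = ",
                      collapse = ", "), ")") else ""
  cat("<transform: ", x$name, ps, ">\n", sep = "")
  invisible(x)
}

# gradient of a transform at x, erroring where the mapping from state to
# input is not locally invertible (a vanishing derivative makes dy/dx
# ambiguous and the action gradient undefined)
transform_grad <- function(transform, x, require_invertible = FALSE) {
  g <- transform$grad(x)
  if (any(!is.finite(g)))
    stop("transform '", transform$name, "' is not differentiable at x = ",
         paste(x[!is.finite(g)], collapse = ", "))
  if (require_invertible && any(abs(g) < 1e-12))
    stop("transform '", transform$name, "' has vanishing gradient at x = ",
         paste(x[abs(g) < 1e-12], collapse = ", "),
         "; the state-to-input mapping is not invertible there")
  g
}
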