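# LINEX loss in plain and invariant (relative-error) form.
#
# The loss is b*(exp(a*e) - a*e - 1) where e is the estimation error.  The
# shape a != 0 controls asymmetry: a > 0 penalizes overestimation roughly
# exponentially and underestimation roughly linearly; a < 0 reverses this.
# As |a| -> 0 the loss approaches (b*a^2/2) * e^2, i.e. squared error.

check_linex <- function(a, b) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a))
    stop("LINEX shape 'a' must be a single finite number", call. = FALSE)
  if (a == 0)
    stop("LINEX shape 'a' must be nonzero (use a small |a| for the squared-error limit)",
         call. = FALSE)
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0)
    stop("LINEX scale 'b' must be a single positive number", call. = FALSE)
  invisible(TRUE)
}

#' LINEX loss
#'
#' Asymmetric linear-exponential loss `b * (exp(a*d) - a*d - 1)` with
#' `d = estimate - truth`.  Nonnegative, zero only at `d = 0`, convex in `d`;
#' for `a > 0` overestimation is penalized more heavily than underestimation
#' of the same magnitude.
#'
#' @param estimate numeric vector of estimates.
#' @param truth numeric vector of true parameter values (recycled).
#' @param a LINEX shape (asymmetry), nonzero scalar.
#' @param b LINEX scale, positive scalar.  Rescales the loss; never moves a
#'   minimizer, so it defaults to 1.
#' @return Numeric vector of losses.
#' @seealso [invariant_linex_loss()] for the relative-error form.
#' @export
#' @examples
#' linex_loss(1, 0, a = 1)    # exp(1) - 2
#' linex_loss(-1, 0, a = 1)   # exp(-1), cheaper: underestimation
linex_loss <- function(estimate, truth, a, b = 1) {
  check_linex(a, b)
  d <- estimate - truth
  b * (expm1(a * d) - a * d)
}

#' Invariant (relative-error) LINEX loss
#'
#' LINEX loss applied to the relative error `d = estimate/truth - 1`, which
#' makes the risk of scale estimators free of the parameter's scale.
#'
#' @inheritParams linex_loss
#' @return Numeric vector of losses.
#' @export
invariant_linex_loss <- function(estimate, truth, a, b = 1) {
  check_linex(a, b)
  if (any(truth == 0)) stop("invariant LINEX loss requires truth != 0", call. = FALSE)
  d <- estimate / truth - 1
  b * (expm1(a * d) - a * d)
}
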