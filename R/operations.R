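#' Cross-ratio arithmetic on intuitionistic fuzzy values
#'
#' The four operations of the cross-ratio algebra. In odds space
#' (`x -> x/(1-x)`, see [to_odds()]) they take an elementary form, which is
#' how they are computed internally (via log-odds for stability near 0/1):
#'
#' * `ifv_oplus(a, b)` -- memberships combine by the or-like cross-ratio
#'   t-conorm `(x + y - 2xy)/(1 - xy)` (odds add); non-memberships by its
#'   dual (odds combine harmonically).
#' * `ifv_otimes(a, b)` -- both components combine by the and-like
#'   representable cross-ratio (ALRCR) uninorm `xy/(xy + (1-x)(1-y))`
#'   (odds multiply). The neutral element is (0.5, 0.5).
#' * `ifv_scale(lambda, a)` -- membership odds scale by `lambda`,
#'   non-membership odds by `1/lambda`; for integer `n`,
#'   `ifv_scale(n, a)` equals `a (+) ... (+) a` n times.
#' * `ifv_pow(a, lambda)` -- both odds are raised to `lambda`; for integer
#'   `n`, `ifv_pow(a, n)` equals `a (x) ... (x) a` n times. `lambda = 0` is
#'   additionally allowed and yields the neutral element (0.5, 0.5), so
#'   zero weights in aggregation degrade gracefully.
#'
#' All four are closed on valid values: outputs again satisfy the open
#' interval and sum constraints, and ordinary fuzzy inputs (components
#' summing to 1) give ordinary fuzzy outputs.
#'
#' @param a,b `ifv` vectors (recycled to a common length).
#' @param lambda positive scalar or vector (non-negative for `ifv_pow`).
#' @return an `ifv` vector.
#' @examples
#' ifv_oplus(ifv(0.5, 0.5), ifv(0.5, 0.5))   # (2/3, 1/3)
#' ifv_otimes(ifv(0.9, 0.1), ifv(0.1, 0.9))  # (0.5, 0.5)
#' ifv_pow(ifv(0.9, 0.1), 0.5)               # (0.75, 0.25)
#' @name ifv-arithmetic
NULL

#' @rdname ifv-arithmetic
#' @export
ifv_oplus <- function(a, b) {
  stopifnot(is_ifv(a), is_ifv(b))
  ou <- a$mu / (1 - a$mu) + b$mu / (1 - b$mu)
  ov <- 1 / (1 / (a$nu / (1 - a$nu)) + 1 / (b$nu / (1 - b$nu)))
  new_ifv(ou / (1 + ou), ov / (1 + ov))
}

#' @rdname ifv-arithmetic
#' @export
ifv_otimes <- function(a, b) {
  stopifnot(is_ifv(a), is_ifv(b))
  new_ifv(plogis(qlogis(a$mu) + qlogis(b$mu)),
          plogis(qlogis(a$nu) + qlogis(b$nu)))
}

#' @rdname ifv-arithmetic
#' @export
ifv_scale <- function(lambda, a) {
  stopifnot(is_ifv(a))
  if (!is.numeric(lambda) || any(!is.finite(lambda)) || any(lambda <= 0))
    domain_error("lambda must be a finite positive real")
  new_ifv(plogis(qlogis(a$mu) + log(lambda)),
          plogis(qlogis(a$nu) - log(lambda)))
}

#' @rdname ifv-arithmetic
#' @export
ifv_pow <- function(a, lambda) {
  stopifnot(is_ifv(a))
  if (!is.numeric(lambda) || any(!is.finite(lambda)) || any(lambda < 0))
    domain_error("lambda must be a finite non-negative real")
  new_ifv(plogis(lambda * qlogis(a$mu)),
          plogis(lambda * qlogis(a$nu)))
}
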