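#' Weight vectors for aggregation
#'
#' Validates a numeric weight vector: every weight in \[0, 1\] and the sum
#' equal to 1 within `tol` (strict mode) or renormalised to sum 1
#' (permissive mode). Zero weights are allowed; the corresponding input is
#' neutral under the cross-ratio geometric aggregator.
#'
#' @param w numeric vector of weights.
#' @param strict if `TRUE` (default) a sum away from 1 is an error;
#'   otherwise weights are renormalised.
#' @param tol tolerance on the sum in strict mode.
#' @return a numeric weight vector summing to 1.
#' @export
weight_vector <- function(w, strict = TRUE, tol = 1e-6) {
  if (!is.numeric(w) || length(w) == 0L || anyNA(w))
    contract_error("weights must be a non-empty numeric vector")
  if (any(w < 0 | w > 1))
    contract_error("every weight must lie in [0, 1]")
  s <- sum(w)
  if (abs(s - 1) > tol) {
    if (strict)
      contract_error(sprintf("weights must sum to 1 (got %.8g)", s))
    if (s <= 0) contract_error("weights must have a positive sum")
    w <- w / s
  }
  w
}

#' Intuitionistic cross-ratio weighted geometric aggregation
#'
#' `icrwg()` aggregates values by the weighted cross-ratio product
#' `(x) (a_i ^ w_i)`; in closed form each component is
#' `prod(x_i^w_i) / (prod(x_i^w_i) + prod((1-x_i)^w_i))`, i.e. the
#' componentwise weighted geometric mean of odds. Computation is a weighted
#' arithmetic mean of log-odds, which is the same thing without underflow.
#' `icrwgm()` is the equal-weights special case (the cross-ratio geometric
#' mean). The operator is idempotent, monotone and bounded: with all inputs
#' on the 0.1--0.9 scale the output stays on the scale.
#'
#' @param values an `ifv` vector (the values to aggregate).
#' @param w numeric weights, one per value (validated by [weight_vector()]).
#' @param strict_weights passed to [weight_vector()].
#' @return a length-1 `ifv`.
#' @examples
#' v <- ifv(c(0.9, 0.9, 0.9, 0.1), c(0.1, 0.1, 0.1, 0.9))
#' icrwgm(v)                         # (0.75, 0.25)
#' icrwg(v, rep(0.25, 4))            # identical
#' @export
icrwg <- function(values, w, strict_weights = TRUE) {
  stopifnot(is_ifv(values))
  if (length(values) == 0L)
    contract_error("cannot aggregate an empty sequence of values")
  w <- weight_vector(w, strict = strict_weights)
  if (length(w) != length(values))
    contract_error(sprintf("length mismatch: %d values but %d weights",
                           length(values), length(w)))
  new_ifv(plogis(sum(w * qlogis(values$mu))),
          plogis(sum(w * qlogis(values$nu))))
}

#' @rdname icrwg
#' @export
icrwgm <- function(values) {
  stopifnot(is_ifv(values))
  if (length(values) == 0L)
    contract_error("cannot aggregate an empty sequence of values")
  icrwg(values, rep(1 / length(values), length(values)))
}

#' Baseline geometric aggregators (for comparison only)
#'
#' Two published weighted geometric operators for intuitionistic fuzzy
#' values, retained solely to compare discrimination power against
#' [icrwg()]; the decision procedure never uses them. Both treat membership
#' and non-membership by different operational rules:
#'
#' * `baseline_ifwg()` -- the Xu--Yager form
#'   `(prod(mu_i^w_i), 1 - prod((1-nu_i)^w_i))`.
#' * `baseline_ifga_einstein()` -- the Einstein weighted geometric closed
#'   form `(2 prod(mu_i^w_i) / (prod((2-mu_i)^w_i) + prod(mu_i^w_i)),
#'   (prod((1+nu_i)^w_i) - prod((1-nu_i)^w_i)) /
#'   (prod((1+nu_i)^w_i) + prod((1-nu_i)^w_i)))`.
#'
#' @inheritParams icrwg
#' @return a length-1 `ifv`.
#' @examples
#' v <- ifv(c(0.9, 0.9, 0.9, 0.1), c(0.1, 0.1, 0.1, 0.9))
#' baseline_ifwg(v, rep(0.25, 4))            # (0.5196, 0.4804)
#' baseline_ifga_einstein(v, rep(0.25, 4))   # (0.5836, 0.4164)
#' @name baseline-aggregators
NULL

#' @rdname baseline-aggregators
#' @export
baseline_ifwg <- function(values, w, strict_weights = TRUE) {
  stopifnot(is_ifv(values))
  if (length(values) == 0L)
    contract_error("cannot aggregate an empty sequence of values")
  w <- weight_vector(w, strict = strict_weights)
  if (length(w) != length(values))
    contract_error(sprintf("length mismatch: %d values but %d weights",
                           length(values), length(w)))
  new_ifv(prod(values$mu^w), 1 - prod((1 - values$nu)^w))
}

#' @rdname baseline-aggregators
#' @export
baseline_ifga_einstein <- function(values, w, strict_weights = TRUE) {
  stopifnot(is_ifv(values))
  if (length(values) == 0L)
    contract_error("cannot aggregate an empty sequence of values")
  w <- weight_vector(w, strict = strict_weights)
  if (length(w) != length(values))
    contract_error(sprintf("length mismatch: %d values but %d weights",
                           length(values), length(w)))
  pm <- prod(values$mu^w)
  mu <- 2 * pm / (prod((2 - values$mu)^w) + pm)
  pp <- prod((1 + values$nu)^w); pq <- prod((1 - values$nu)^w)
  new_ifv(mu, (pp - pq) / (pp + pq))
}
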