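#' The cross-ratio bipolar 0.1--0.9 rating scale
#'
#' Pairwise ratings live on a bounded bipolar scale with neutral value 0.5,
#' related to Saaty's 1--9 ratio scale by the odds map `r -> r/(1+r)` and
#' its inverse `v -> v/(1-v)`. Saaty's 9 corresponds to 0.9 ("absolutely
#' preferred"), 1 to 0.5 ("equally preferred"), 1/9 to 0.1; reciprocal
#' Saaty ratings map to complementary scale values (`f(1/r) = 1 - f(r)`).
#'
#' @param r a Saaty rating in \[1/9, 9\].
#' @param v a cross-ratio scale value in \[0.1, 0.9\].
#' @return the converted rating(s).
#' @examples
#' saaty_to_cross_ratio(c(9, 1, 3))   # 0.9, 0.5, 0.75
#' cross_ratio_to_saaty(5/6)          # 5
#' @export
saaty_to_cross_ratio <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r)))
    domain_error("rating must be a finite real")
  if (any(r < 1 / 9 - 1e-12 | r > 9 + 1e-12))
    domain_error("Saaty rating out of range [1/9, 9]")
  r / (1 + r)
}

#' @rdname saaty_to_cross_ratio
#' @export
cross_ratio_to_saaty <- function(v) {
  if (!is.numeric(v) || any(!is.finite(v)))
    domain_error("rating must be a finite real")
  if (any(v < 0.1 - 1e-12 | v > 0.9 + 1e-12))
    domain_error("cross-ratio rating out of range [0.1, 0.9]")
  v / (1 - v)
}

#' Anchor points of the bipolar rating scale
#'
#' The nine verbal anchors linking Saaty's 1--9 scale to the cross-ratio
#' 0.1--0.9 scale; in-between values are admissible for intermediate
#' preference.
#'
#' @return a data.frame with columns `saaty`, `cross_ratio`, `label`.
#' @export
cross_ratio_scale <- function() {
  saaty <- c(9, 7, 5, 3, 1, 1/3, 1/5, 1/7, 1/9)
  data.frame(
    saaty = saaty,
    # the anchors as exact rationals, not via the floating conversion
    cross_ratio = c(0.9, 7/8, 5/6, 3/4, 0.5, 1/4, 1/6, 1/8, 0.1),
    label = c("Absolutely preferred", "Very strongly preferred",
              "Strongly preferred", "Moderately preferred",
              "Equally preferred", "Moderately less preferred",
              "Strongly less preferred", "Very strongly less preferred",
              "Extremely less preferred"),
    stringsAsFactors = FALSE)
}
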