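#' Score, hesitation margin and accuracy of intuitionistic fuzzy values
#'
#' Ranking of cross-ratio intuitionistic fuzzy values uses two functionals
#' of the odds ratio `rho = [mu/(1-mu)] / [nu/(1-nu)]` and the odds product
#' `H = [mu/(1-mu)] * [nu/(1-nu)]`:
#'
#' * the **score** maps a value to (0, 1); 0.5 exactly when `mu == nu`.
#'   Variant `"geometric"` (the default) is
#'   `sqrt(mu(1-nu)) / (sqrt(mu(1-nu)) + sqrt((1-mu)nu))`, i.e. the logistic
#'   of half the log odds ratio; variant `"eq4"` is
#'   `mu(1-nu) / (mu(1-nu) + (1-mu)nu)`, the logistic of the full log odds
#'   ratio. Both are strictly increasing transforms of `rho`, so they induce
#'   the same strict order; the geometric variant is the one consistent with
#'   the bounded 0.1--0.9 rating scale (it maps (0.9, 0.1) to 0.9, not to
#'   81/82) and is used throughout the decision procedure's reports.
#' * the **accuracy** `H = mu*nu / ((1-mu)(1-nu))` lies in (0, 1], equals 1
#'   exactly for ordinary fuzzy values (`mu + nu = 1`), and is the ranking
#'   tie-breaker. The **hesitation margin** is `pi = 1 - H`, equivalently
#'   `(1 - mu - nu) / ((1-mu)(1-nu))`.
#'
#' @param a,b `ifv` vectors.
#' @param variant `"geometric"` (default) or `"eq4"`.
#' @return numeric vector (scores in (0,1); accuracy in (0,1]; hesitation in
#'   \[0,1)).
#' @examples
#' ifv_score(ifv(0.9, 0.1))                    # 0.9
#' ifv_score(ifv(0.9, 0.1), variant = "eq4")   # 81/82
#' ifv_accuracy(ifv(0.1, 0.9))                 # 1: ordinary fuzzy value
#' @name ifv-ranking
NULL

#' @rdname ifv-ranking
#' @export
ifv_score <- function(a, variant = c("geometric", "eq4")) {
  stopifnot(is_ifv(a))
  variant <- match.arg(variant)
  d <- qlogis(a$mu) - qlogis(a$nu)   # log odds ratio
  if (variant == "geometric") plogis(d / 2) else plogis(d)
}

#' @rdname ifv-ranking
#' @export
ifv_accuracy <- function(a) {
  stopifnot(is_ifv(a))
  pmin(exp(qlogis(a$mu) + qlogis(a$nu)), 1)
}

#' @rdname ifv-ranking
#' @export
ifv_hesitation <- function(a) {
  1 - ifv_accuracy(a)
}

#' Two-stage comparison of intuitionistic fuzzy values
#'
#' Compares by score, breaking score ties by accuracy; values with equal
#' score and equal accuracy are equal (which, for this algebra, happens
#' exactly when both components agree). Comparison is carried out on the
#' exact log-odds quantities (log odds ratio, log odds product) at relative
#' tolerance 1e-10, so it is independent of the score variant.
#'
#' @param a,b `ifv` vectors (recycled).
#' @param tol tolerance on the log-odds scale.
#' @return integer vector: -1 (`a < b`), 0 (`a == b`), or 1 (`a > b`).
#' @examples
#' ifv_compare(ifv(0.6, 0.2), ifv(0.5, 0.3))   #  1
#' ifv_compare(ifv(0.6, 0.4), ifv(3/7, 1/4))   #  1: equal scores, higher accuracy
#' @export
ifv_compare <- function(a, b, tol = 1e-10) {
  stopifnot(is_ifv(a), is_ifv(b))
  sa <- qlogis(a$mu) - qlogis(a$nu); sb <- qlogis(b$mu) - qlogis(b$nu)
  ha <- qlogis(a$mu) + qlogis(a$nu); hb <- qlogis(b$mu) + qlogis(b$nu)
  out <- integer(max(length(sa), length(sb)))
  ds <- sa - sb; dh <- ha - hb
  scale_s <- pmax(1, abs(sa), abs(sb))
  scale_h <- pmax(1, abs(ha), abs(hb))
  out[ds > tol * scale_s] <- 1L
  out[ds < -tol * scale_s] <- -1L
  tie <- out == 0L
  out[tie & dh > tol * scale_h] <- 1L
  out[tie & dh < -tol * scale_h] <- -1L
  out
}

#' Rank a vector of intuitionistic fuzzy values
#'
#' Sorts in decreasing order under [ifv_compare()], grouping exact ties.
#' Ties are reported as groups and ordered by input position (stable).
#'
#' @param x an `ifv` vector.
#' @param labels optional character labels (defaults to `x1, x2, ...`).
#' @param tol comparison tolerance, see [ifv_compare()].
#' @return a list with `order` (integer permutation, best first),
#'   `tie_groups` (list of integer vectors into `x`, best group first) and
#'   `ranking_string` (e.g. `"x1 > x2 = x3"`).
#' @export
ifv_rank <- function(x, labels = NULL, tol = 1e-10) {
  stopifnot(is_ifv(x))
  n <- length(x)
  if (is.null(labels)) labels <- paste0("x", seq_len(n))
  stopifnot(length(labels) == n)
  s <- qlogis(x$mu) - qlogis(x$nu)
  h <- qlogis(x$mu) + qlogis(x$nu)
  ord <- order(-s, -h, seq_len(n))
  groups <- list()
  for (i in ord) {
    k <- length(groups)
    if (k > 0L && ifv_compare(x[groups[[k]][1]], x[i], tol = tol) == 0L) {
      groups[[k]] <- c(groups[[k]], i)
    } else {
      groups[[k + 1L]] <- i
    }
  }
  ranking_string <- paste(
    vapply(groups, function(g) paste(labels[g], collapse = " = "), character(1)),
    collapse = " > ")
  list(order = ord, tie_groups = groups, ranking_string = ranking_string)
}
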