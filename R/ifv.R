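#' Cross-ratio intuitionistic fuzzy values
#'
#' An `ifv` is a vector of (membership, non-membership) pairs with both
#' components strictly inside (0, 1) and membership + non-membership <= 1.
#' The residual `1 - membership - nonmembership` is the hesitancy and is
#' derived, never stored. Boundary components are rejected: the algebra's
#' odds transform `x/(1-x)` is undefined at 0 and 1.
#'
#' @param membership,nonmembership numeric vectors (recycled to a common
#'   length). Components must lie strictly in (0, 1); values closer than
#'   1e-12 to a boundary are rejected unless `clamp = TRUE`.
#' @param tol_sum tolerance on the constraint membership + nonmembership <= 1.
#' @param clamp if `TRUE`, components are clamped into `[1e-9, 1 - 1e-9]`
#'   before validation (robustness mode for file input).
#' @return an object of class `ifv`.
#' @examples
#' ifv(0.5, 0.5)                   # the indifference value
#' ifv(c(0.9, 0.6), c(0.1, 0.3))   # vectorised
#' @seealso [ifv_oplus()], [ifv_otimes()], [ifv_scale()], [ifv_pow()],
#'   [to_odds()], [ifv_score()]
#' @export
ifv <- function(membership, nonmembership, tol_sum = 1e-9, clamp = FALSE) {
  if (!is.numeric(membership) || !is.numeric(nonmembership))
    domain_error("membership and nonmembership must be numeric")
  n <- max(length(membership), length(nonmembership))
  if (n == 0L) return(new_ifv(numeric(0), numeric(0)))
  mu <- rep_len(as.numeric(membership), n)
  nu <- rep_len(as.numeric(nonmembership), n)
  if (anyNA(mu) || anyNA(nu) || any(!is.finite(mu)) || any(!is.finite(nu)))
    domain_error("components must be finite, non-missing reals")
  if (clamp) {
    mu <- pmin(pmax(mu, 1e-9), 1 - 1e-9)
    nu <- pmin(pmax(nu, 1e-9), 1 - 1e-9)
  }
  edge <- 1e-12
  bad <- mu <= edge | mu >= 1 - edge | nu <= edge | nu >= 1 - edge
  if (any(bad))
    domain_error(sprintf(
      "component out of the open interval (0, 1) at position %d: (%.6g, %.6g)",
      which(bad)[1], mu[which(bad)[1]], nu[which(bad)[1]]))
  over <- mu + nu > 1 + tol_sum
  if (any(over))
    constraint_error(sprintf(
      "membership + nonmembership > 1 at position %d: %.6g + %.6g = %.6g",
      which(over)[1], mu[which(over)[1]], nu[which(over)[1]],
      mu[which(over)[1]] + nu[which(over)[1]]))
  new_ifv(mu, nu)
}

# internal constructor: trusted inputs, nudges floating-point boundary hits
# back into the open interval (plogis can underflow to exactly 0 or 1)
new_ifv <- function(mu, nu) {
  eps <- 1e-15
  structure(list(mu = pmin(pmax(mu, eps), 1 - eps),
                 nu = pmin(pmax(nu, eps), 1 - eps)),
            class = "ifv")
}

#' @export
is_ifv <- function(x) inherits(x, "ifv")

#' Component accessors and hesitancy
#'
#' @param x an `ifv` vector.
#' @return numeric vector of memberships, non-memberships, or the derived
#'   hesitancy `1 - membership - nonmembership`.
#' @export
membership <- function(x) {
  stopifnot(is_ifv(x))
  x$mu
}

#' @rdname membership
#' @export
nonmembership <- function(x) {
  stopifnot(is_ifv(x))
  x$nu
}

#' @rdname membership
#' @export
hesitancy <- function(x) {
  stopifnot(is_ifv(x))
  pmax(1 - x$mu - x$nu, 0)
}

#' @export
length.ifv <- function(x) length(x$mu)

#' @export
`[.ifv` <- function(x, i) new_ifv(x$mu[i], x$nu[i])

#' @export
c.ifv <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, is_ifv, logical(1))))
  new_ifv(unlist(lapply(parts, `[[`, "mu")), unlist(lapply(parts, `[[`, "nu")))
}

#' @export
format.ifv <- function(x, digits = 4, ...) {
  sprintf("(%s, %s)", formatC(x$mu, digits = digits, format = "f"),
          formatC(x$nu, digits = digits, format = "f"))
}

#' @export
print.ifv <- function(x, digits = 4, ...) {
  cat("<ifv[", length(x), "]>\n", sep = "")
  if (length(x)) print(format(x, digits = digits), quote = FALSE)
  invisible(x)
}

#' @export
as.data.frame.ifv <- function(x, ...) {
  data.frame(membership = x$mu, nonmembership = x$nu)
}

#' Approximate equality of ifv vectors
#'
#' Componentwise comparison at an absolute tolerance (default 1e-9).
#'
#' @param a,b `ifv` vectors of equal length.
#' @param tol absolute tolerance per component.
#' @return logical vector.
#' @export
ifv_equal <- function(a, b, tol = 1e-9) {
  stopifnot(is_ifv(a), is_ifv(b), length(a) == length(b))
  abs(a$mu - b$mu) <= tol & abs(a$nu - b$nu) <= tol
}

#' Complement of an intuitionistic fuzzy value
#'
#' Swaps membership and non-membership; an involution. This is the operation
#' preference-relation reciprocity is built on: the judgment of `xj` against
#' `xi` is the complement of the judgment of `xi` against `xj`.
#'
#' @param a an `ifv` vector.
#' @return an `ifv` vector.
#' @export
ifv_complement <- function(a) {
  stopifnot(is_ifv(a))
  new_ifv(a$nu, a$mu)
}

#' Odds-space representation
#'
#' The cross-ratio algebra is the image of ordinary odds arithmetic under
#' `x = u/(1+u)`. `to_odds()` maps both components through `x/(1-x)`;
#' `from_odds()` inverts. The pair of odds always satisfies
#' `odds_membership * odds_nonmembership <= 1`, the odds form of the
#' membership + non-membership constraint.
#'
#' @param a an `ifv` vector.
#' @param o an `odds_pair` as returned by [to_odds()], or a list with
#'   numeric fields `odds_membership` and `odds_nonmembership`.
#' @param tol_sum tolerance on the product constraint.
#' @return `to_odds()`: an object of class `odds_pair`; `from_odds()`: an
#'   `ifv` vector.
#' @examples
#' to_odds(ifv(0.9, 0.1))   # odds (9, 1/9)
#' from_odds(odds_pair(3, 1/3))
#' @export
to_odds <- function(a) {
  stopifnot(is_ifv(a))
  odds_pair(a$mu / (1 - a$mu), a$nu / (1 - a$nu))
}

#' @rdname to_odds
#' @param odds_membership,odds_nonmembership positive odds vectors.
#' @export
odds_pair <- function(odds_membership, odds_nonmembership, tol_sum = 1e-9) {
  u <- as.numeric(odds_membership); v <- as.numeric(odds_nonmembership)
  if (any(!is.finite(u)) || any(!is.finite(v)) || any(u <= 0) || any(v <= 0))
    domain_error("odds must be finite and strictly positive")
  if (any(u * v > 1 + tol_sum))
    constraint_error("odds product exceeds 1: not a valid intuitionistic pair")
  structure(list(odds_membership = u, odds_nonmembership = v),
            class = "odds_pair")
}

#' @rdname to_odds
#' @export
from_odds <- function(o) {
  if (!inherits(o, "odds_pair"))
    o <- odds_pair(o$odds_membership, o$odds_nonmembership)
  u <- o$odds_membership; v <- o$odds_nonmembership
  new_ifv(u / (1 + u), v / (1 + v))
}

#' @export
print.odds_pair <- function(x, ...) {
  cat("<odds_pair[", length(x$odds_membership), "]>\n", sep = "")
  print(data.frame(odds_membership = x$odds_membership,
                   odds_nonmembership = x$odds_nonmembership))
  invisible(x)
}

#' Parse "membership,nonmembership" cells
#'
#' Cells may be written as `"0.5,0.5"`, `"(5/8, 1/5)"`, etc. Fractions are
#' parsed exactly (numerator divided by denominator in double precision)
#' rather than through a decimal expansion, so table entries like `5/8`
#' carry full precision.
#'
#' @param cells character vector of cells.
#' @param tol_sum,clamp passed to [ifv()].
#' @return an `ifv` vector.
#' @examples
#' parse_ifv(c("5/8,1/5", "(0.5, 0.5)"))
#' @export
parse_ifv <- function(cells, tol_sum = 1e-9, clamp = FALSE) {
  cells <- as.character(cells)
  stripped <- gsub("[()[:space:]]", "", cells)
  parts <- strsplit(stripped, ",", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad))
    domain_error(sprintf("cannot parse cell '%s': expected two comma-separated components",
                         cells[which(bad)[1]]))
  mu <- vapply(parts, function(p) parse_fraction(p[1]), numeric(1))
  nu <- vapply(parts, function(p) parse_fraction(p[2]), numeric(1))
  ifv(mu, nu, tol_sum = tol_sum, clamp = clamp)
}

#' @noRd
parse_fraction <- function(token) {
  token <- trimws(token)
  if (grepl("/", token, fixed = TRUE)) {
    nm <- strsplit(token, "/", fixed = TRUE)[[1]]
    if (length(nm) != 2L)
      domain_error(sprintf("cannot parse fraction '%s'", token))
    num <- suppressWarnings(as.numeric(nm[1]))
    den <- suppressWarnings(as.numeric(nm[2]))
    if (is.na(num) || is.na(den) || den == 0)
      domain_error(sprintf("cannot parse fraction '%s'", token))
    return(num / den)
  }
  val <- suppressWarnings(as.numeric(token))
  if (is.na(val)) domain_error(sprintf("cannot parse number '%s'", token))
  val
}

# canonical machine serialisation: enough digits for an exact round trip
fmt_g15 <- function(x) trimws(formatC(x, digits = 15, format = "g"))

format_ifv_cell <- function(a) {
  paste0(fmt_g15(a$mu), ",", fmt_g15(a$nu))
}
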