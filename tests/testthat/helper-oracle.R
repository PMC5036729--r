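# Independent oracle: the literal closed forms, evaluated in probability
# space exactly as printed, with no shared code with the package's
# log-odds implementation.

o_oplus <- function(m1, n1, m2, n2) {
  c((m1 + m2 - 2 * m1 * m2) / (1 - m1 * m2),
    n1 * n2 / (n1 + n2 - n1 * n2))
}

o_uninorm <- function(x, y) x * y / (x * y + (1 - x) * (1 - y))

o_otimes <- function(m1, n1, m2, n2) {
  c(o_uninorm(m1, m2), o_uninorm(n1, n2))
}

o_scale <- function(lam, m, n) {
  c(lam * m / (lam * m + 1 - m), n / (n + lam * (1 - n)))
}

o_pow <- function(m, n, lam) {
  c(m^lam / (m^lam + (1 - m)^lam), n^lam / (n^lam + (1 - n)^lam))
}

o_icrwg <- function(mu, nu, w) {
  g <- function(x) prod(x^w) / (prod(x^w) + prod((1 - x)^w))
  c(g(mu), g(nu))
}

o_score_eq4 <- function(m, n) m * (1 - n) / (m * (1 - n) + (1 - m) * n)

o_score_geom <- function(m, n) {
  a <- sqrt(m * (1 - n)); b <- sqrt((1 - m) * n)
  a / (a + b)
}

o_pi <- function(m, n) (1 - m - n) / ((1 - m) * (1 - n))

o_H <- function(m, n) m * n / ((1 - m) * (1 - n))

# random valid values, strictly interior (sum strictly below 1)
rand_ifv <- function(k) {
  mu <- runif(k, 0.02, 0.95)
  nu <- runif(k, 0.05, 0.95) * (1 - mu)
  ifv(mu, nu)
}

# random values on the bounded 0.1-0.9 rating scale
rand_ifv_scale <- function(k) {
  mu <- runif(k, 0.1, 0.9)
  nu <- runif(k, 0.1, pmin(0.9, 1 - mu))
  ifv(mu, nu)
}

# absolute-tolerance comparison (4-decimal published figures)
expect_near <- function(got, want, tol = 5e-5) {
  expect_lt(max(abs(got - want)), tol)
}

# valid ifv invariants, as an expectation
expect_valid_ifv <- function(x, tol_sum = 1e-9) {
  expect_true(all(membership(x) > 0 & membership(x) < 1))
  expect_true(all(nonmembership(x) > 0 & nonmembership(x) < 1))
  expect_true(all(membership(x) + nonmembership(x) <= 1 + tol_sum))
}
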