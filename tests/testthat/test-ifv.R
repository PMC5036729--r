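test_that("constructor validates the open interval and the sum constraint", {
  a <- ifv(0.5, 0.5)
  expect_s3_class(a, "ifv")
  expect_equal(membership(a), 0.5)
  expect_equal(hesitancy(a), 0)

  expect_error(ifv(0.0, 0.5), class = "icrdm_domain_error")
  expect_error(ifv(0.5, 1.0), class = "icrdm_domain_error")
  expect_error(ifv(1e-13, 0.5), class = "icrdm_domain_error")
  expect_error(ifv(0.9, 0.2), class = "icrdm_constraint_error")
  expect_error(ifv(NA_real_, 0.5), class = "icrdm_domain_error")

  # permissive mode clamps boundary-adjacent file input instead
  clamped <- ifv(1e-13, 0.5, clamp = TRUE)
  expect_equal(membership(clamped), 1e-9)
  expect_valid_ifv(clamped)
})

test_that("cells parse with exact fractions, parentheses, and spacing", {
  v <- parse_ifv(c("5/8,1/5", "(5/8, 1/5)", " 0.5 , 0.5 "))
  expect_equal(membership(v), c(5/8, 5/8, 0.5))
  expect_equal(nonmembership(v), c(1/5, 1/5, 0.5))
  expect_error(parse_ifv("0.5"), class = "icrdm_domain_error")
  expect_error(parse_ifv("a/b,0.5"), class = "icrdm_domain_error")
})

test_that("odds transform round-trips and matches the defining algebra", {
  o <- to_odds(ifv(0.9, 0.1))
  expect_equal(o$odds_membership, 9, tolerance = 1e-12)
  expect_equal(o$odds_nonmembership, 1 / 9, tolerance = 1e-12)
  expect_equal(to_odds(ifv(0.5, 0.5))$odds_membership, 1)

  b <- from_odds(odds_pair(3, 1 / 3))
  expect_equal(membership(b), 0.75, tolerance = 1e-12)
  expect_equal(nonmembership(b), 0.25, tolerance = 1e-12)

  expect_error(odds_pair(-1, 0.5), class = "icrdm_domain_error")
  expect_error(odds_pair(9, 9), class = "icrdm_constraint_error")

  set.seed(11)
  x <- rand_ifv(500)
  rt <- from_odds(to_odds(x))
  expect_equal(membership(rt), membership(x), tolerance = 1e-12)
  expect_equal(nonmembership(rt), nonmembership(x), tolerance = 1e-12)
})

test_that("complement swaps components and is an involution", {
  a <- parse_ifv("5/8,1/5")
  expect_equal(as.data.frame(ifv_complement(a)),
               data.frame(membership = 1/5, nonmembership = 5/8))
  expect_true(ifv_equal(ifv_complement(ifv(0.5, 0.5)), ifv(0.5, 0.5)))
  set.seed(12)
  x <- rand_ifv(200)
  expect_true(all(ifv_equal(ifv_complement(ifv_complement(x)), x, tol = 0)))
})

test_that("frozen examples: the four operations in odds space", {
  half <- ifv(0.5, 0.5)
  # odds add: 1 + 1 = 2 -> 2/3; harmonic: 1/(1+1) = 1/2 -> 1/3
  expect_true(ifv_equal(ifv_oplus(half, half), ifv(2/3, 1/3), tol = 1e-12))
  a <- ifv(0.6, 0.3); b <- ifv(0.7, 0.2)
  # odds 1.5 + 7/3 = 23/6 -> 23/29; harmonic of 3/7 and 1/4 is 3/19 -> 3/22
  expect_true(ifv_equal(ifv_oplus(a, b), ifv(23/29, 3/22), tol = 1e-12))
  # odds multiply: 1.5 * 7/3 = 3.5 -> 7/9; (3/7) * (1/4) -> 3/31
  expect_true(ifv_equal(ifv_otimes(a, b), ifv(7/9, 3/31), tol = 1e-12))
  expect_true(ifv_equal(ifv_otimes(ifv(0.9, 0.1), ifv(0.1, 0.9)), half,
                        tol = 1e-12))
  # 0.5 is the neutral element of the uninorm
  expect_true(all(ifv_equal(ifv_otimes(half, a), a, tol = 1e-12)))
  expect_true(ifv_equal(ifv_scale(2, half), ifv(2/3, 1/3), tol = 1e-12))
  # odds 9^0.5 = 3 -> 3/4
  expect_true(ifv_equal(ifv_pow(ifv(0.9, 0.1), 0.5), ifv(0.75, 0.25),
                        tol = 1e-12))
  # lambda = 1 is the identity; lambda = 0 yields the neutral element
  expect_true(all(ifv_equal(ifv_scale(1, a), a, tol = 1e-12)))
  expect_true(all(ifv_equal(ifv_pow(a, 1), a, tol = 1e-12)))
  expect_true(ifv_equal(ifv_pow(a, 0), half, tol = 1e-12))
  expect_error(ifv_scale(0, a), class = "icrdm_domain_error")
  expect_error(ifv_scale(-2, a), class = "icrdm_domain_error")
  expect_error(ifv_pow(a, -0.5), class = "icrdm_domain_error")
})

test_that("operations agree with the literal printed formulas on 1e4 random inputs", {
  set.seed(101)
  n <- 10000L
  a <- rand_ifv(n); b <- rand_ifv(n)
  lam <- runif(n, 0.05, 6)
  rel <- function(got, want) abs(got - want) / pmax(abs(want), 1e-12)

  ab <- ifv_oplus(a, b)
  want <- mapply(o_oplus, a$mu, a$nu, b$mu, b$nu)
  expect_lt(max(rel(ab$mu, want[1, ]), rel(ab$nu, want[2, ])), 1e-10)

  ab <- ifv_otimes(a, b)
  want <- mapply(o_otimes, a$mu, a$nu, b$mu, b$nu)
  expect_lt(max(rel(ab$mu, want[1, ]), rel(ab$nu, want[2, ])), 1e-10)

  sa <- ifv_scale(lam, a)
  want <- mapply(o_scale, lam, a$mu, a$nu)
  expect_lt(max(rel(sa$mu, want[1, ]), rel(sa$nu, want[2, ])), 1e-10)

  pa <- ifv_pow(a, lam)
  want <- mapply(o_pow, a$mu, a$nu, lam)
  expect_lt(max(rel(pa$mu, want[1, ]), rel(pa$nu, want[2, ])), 1e-10)
})

test_that("all operations are closed; ordinary fuzzy inputs stay ordinary fuzzy", {
  set.seed(102)
  n <- 2000L
  a <- rand_ifv(n); b <- rand_ifv(n)
  lam <- runif(n, 0.05, 6)
  for (x in list(ifv_oplus(a, b), ifv_otimes(a, b),
                 ifv_scale(lam, a), ifv_pow(a, lam)))
    expect_valid_ifv(x)

  mu <- runif(n, 0.02, 0.98)
  f <- ifv(mu, 1 - mu); g <- ifv(rev(mu), 1 - rev(mu))
  for (x in list(ifv_oplus(f, g), ifv_otimes(f, g),
                 ifv_scale(lam, f), ifv_pow(f, lam)))
    expect_equal(max(abs(membership(x) + nonmembership(x) - 1)), 0,
                 tolerance = 1e-12)
})

test_that("algebraic laws hold on random inputs", {
  set.seed(103)
  n <- 1500L
  a <- rand_ifv(n); b <- rand_ifv(n)
  l1 <- runif(n, 0.1, 4); l2 <- runif(n, 0.1, 4)
  ok <- function(x, y) expect_true(all(ifv_equal(x, y, tol = 1e-10)))

  ok(ifv_oplus(a, b), ifv_oplus(b, a))                      # commutativity
  ok(ifv_otimes(a, b), ifv_otimes(b, a))
  ok(ifv_scale(l1, ifv_oplus(a, b)),                        # distributivity
     ifv_oplus(ifv_scale(l1, a), ifv_scale(l1, b)))
  ok(ifv_pow(ifv_otimes(a, b), l1),
     ifv_otimes(ifv_pow(a, l1), ifv_pow(b, l1)))
  ok(ifv_oplus(ifv_scale(l1, a), ifv_scale(l2, a)),         # exponent laws
     ifv_scale(l1 + l2, a))
  ok(ifv_otimes(ifv_pow(a, l1), ifv_pow(a, l2)), ifv_pow(a, l1 + l2))
  ok(ifv_scale(2, a), ifv_oplus(a, a))                      # n-fold forms
  ok(ifv_pow(a, 2), ifv_otimes(a, a))
})

test_that("accuracy is conserved under scalar multiplication", {
  set.seed(104)
  a <- rand_ifv(1000)
  lam <- runif(1000, 0.05, 8)
  expect_equal(ifv_accuracy(ifv_scale(lam, a)), ifv_accuracy(a),
               tolerance = 1e-10)
})
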