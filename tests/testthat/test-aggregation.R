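example1 <- function() ifv(c(0.9, 0.9, 0.9, 0.1), c(0.1, 0.1, 0.1, 0.9))

test_that("weight vectors validate in strict mode and renormalise in permissive", {
  expect_equal(weight_vector(c(0.4, 0.35, 0.25)), c(0.4, 0.35, 0.25))
  expect_error(weight_vector(c(0.5, 0.4)), class = "icrdm_contract_error")
  expect_error(weight_vector(c(0.5, 0.6, -0.1)), class = "icrdm_contract_error")
  expect_error(weight_vector(numeric(0)), class = "icrdm_contract_error")
  expect_equal(weight_vector(c(1, 1), strict = FALSE), c(0.5, 0.5))
})

test_that("the cross-ratio geometric mean reproduces the worked example", {
  got <- icrwgm(example1())
  # closed form gives odds 3 and 1/3 exactly
  expect_equal(membership(got), 0.75, tolerance = 1e-12)
  expect_equal(nonmembership(got), 0.25, tolerance = 1e-12)
  expect_true(ifv_equal(icrwg(example1(), rep(0.25, 4)), got, tol = 1e-12))
  expect_true(ifv_equal(icrwgm(ifv(rep(0.5, 3), rep(0.5, 3))), ifv(0.5, 0.5),
                        tol = 1e-12))
})

test_that("published case-study aggregates reproduce to 4 decimals", {
  r1 <- parse_ifv(c("0.5,0.5", "5/8,1/5", "7/8,0.1", "3/4,1/8", "0.5,1/6"))
  b11 <- icrwgm(r1)
  expect_near(membership(b11), 0.6706)
  expect_near(nonmembership(b11), 0.1934)

  locals <- ifv(c(0.6706, 0.7445, 0.6508), c(0.1934, 0.1758, 0.2701))
  overall <- icrwg(locals, c(0.4, 0.35, 0.25))
  expect_near(membership(overall), 0.6930)
  expect_near(nonmembership(overall), 0.2042)
})

test_that("baseline aggregators match their printed comparison values", {
  w <- rep(0.25, 4)
  g <- baseline_ifwg(example1(), w)
  expect_near(membership(g), 0.5196)
  expect_near(nonmembership(g), 0.4804)
  e <- baseline_ifga_einstein(example1(), w)
  expect_near(membership(e), 0.5836)
  expect_near(nonmembership(e), 0.4164)

  # direct closed-form evaluations
  g2 <- baseline_ifwg(ifv(c(0.8, 0.2), c(0.1, 0.7)), c(0.5, 0.5))
  expect_equal(membership(g2), 0.4, tolerance = 1e-12)
  expect_equal(nonmembership(g2), 1 - sqrt(0.27), tolerance = 1e-12)

  one <- ifv(0.55, 0.3)
  expect_true(ifv_equal(baseline_ifwg(one, 1), one, tol = 1e-12))
  expect_true(ifv_equal(baseline_ifga_einstein(one, 1), one, tol = 1e-12))
  set.seed(31)
  a <- rand_ifv(1)
  rep4 <- c(a, a, a, a)
  expect_true(ifv_equal(baseline_ifga_einstein(rep4, w), a, tol = 1e-10))
})

test_that("icrwg agrees with the closed-form product oracle on 1e4 random cases", {
  set.seed(32)
  worst <- 0
  for (i in 1:2000) {
    m <- sample(2:6, 1)
    v <- rand_ifv(m)
    w <- runif(m); w <- w / sum(w)
    got <- icrwg(v, w)
    want <- o_icrwg(v$mu, v$nu, w)
    worst <- max(worst, abs(c(got$mu, got$nu) - want) / pmax(abs(want), 1e-12))
  }
  expect_lt(worst, 1e-10)
})

test_that("idempotency, boundedness, monotonicity, scale closure", {
  set.seed(33)
  for (i in 1:300) {
    m <- sample(2:5, 1)
    w <- runif(m); w <- w / sum(w)

    a <- rand_ifv(1)
    expect_true(ifv_equal(icrwg(ifv(rep(a$mu, m), rep(a$nu, m)), w), a,
                          tol = 1e-10))

    v <- rand_ifv(m)
    agg <- icrwg(v, w)
    vmax <- ifv(max(v$mu), min(v$nu)); vmin <- ifv(min(v$mu), max(v$nu))
    expect_gte(ifv_compare(vmax, agg), 0L)
    expect_gte(ifv_compare(agg, vmin), 0L)

    # replace one input by a componentwise-greater value
    k <- sample(m, 1)
    v2 <- v
    v2$mu[k] <- runif(1, v$mu[k], 1 - v$nu[k])
    v2$nu[k] <- runif(1, 0.001, v$nu[k])
    expect_gte(ifv_compare(icrwg(v2, w), agg), 0L)

    s <- rand_ifv_scale(m)
    aggs <- icrwg(s, w)
    expect_true(all(c(aggs$mu, aggs$nu) >= 0.1 - 1e-12 &
                    c(aggs$mu, aggs$nu) <= 0.9 + 1e-12))
  }
})

test_that("accuracy composes geometrically and zero weights are neutral", {
  set.seed(34)
  for (i in 1:200) {
    m <- sample(2:5, 1)
    v <- rand_ifv(m)
    w <- runif(m); w <- w / sum(w)
    expect_equal(ifv_accuracy(icrwg(v, w)),
                 prod(ifv_accuracy(v)^w), tolerance = 1e-10)
  }
  v <- rand_ifv(3)
  expect_true(ifv_equal(icrwg(v, c(1, 0, 0)), v[1], tol = 1e-10))
})

test_that("aggregation contract errors", {
  v <- rand_ifv(3)
  expect_error(icrwg(v, c(0.5, 0.5)), class = "icrdm_contract_error")
  expect_error(icrwg(ifv(numeric(0), numeric(0)), numeric(0)),
               class = "icrdm_contract_error")
  expect_error(baseline_ifwg(v, c(0.5, 0.5)), class = "icrdm_contract_error")
  expect_error(baseline_ifga_einstein(v, c(0.5, 0.5)),
               class = "icrdm_contract_error")
})
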