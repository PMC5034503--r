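test_that("binary search performs exactly ceil(log2((b-a)/eps)) halvings", {
  m <- make_analytic_model()
  for (eps in c(1e-3, 1e-6)) {
    s <- bisect_me(m, interval = c(0, 2), epsilon = eps)
    expect_identical(s$iterations, as.integer(ceiling(log2(2 / eps))))
    expect_gte(s$lp_evaluations, s$iterations)
  }
  # the 3-decimals case: ceil(log2(2000)) = 11
  expect_identical(bisect_me(m, decimals = 3)$iterations, 11L)
  # bracket width after k halvings is (b-a)/2^k exactly
  s <- bisect_me(m, epsilon = 1e-6)
  expect_equal(s$mu_hi - s$mu_lo, 2 / 2^s$iterations, tolerance = 1e-12)
})

test_that("bisection recovers the closed-form optimum and keeps its bracket", {
  set.seed(5)
  for (k in 1:3) {
    U <- runif(1, 2, 20); a_bio <- runif(1, 4, 15)
    mc <- runif(1, 0.1, 3); ke <- runif(1, 20, 500)
    m <- make_analytic_model(U, a_bio, mc, ke)
    mu_true <- closed_form_mu(U, a_bio, mc, ke)
    s <- suppressWarnings(bisect_me(m, epsilon = 1e-9))
    expect_lt(abs(s$mu_best - mu_true), 1e-9)
    # bracket invariant: every feasible point below every infeasible point
    expect_lt(max(s$history$mu[s$history$feasible]),
              min(s$history$mu[!s$history$feasible]))
    expect_true(s$mu_lo <= s$mu_best && s$mu_best <= s$mu_hi)
  }
})

test_that("golden-section search agrees with binary within 2*epsilon", {
  for (m in list(make_analytic_model(), make_coupled_complex_model())) {
    b <- bisect_me(m, epsilon = 1e-6, method = "binary")
    g <- bisect_me(m, epsilon = 1e-6, method = "golden")
    expect_lt(abs(b$mu_best - g$mu_best), 2e-6)
    expect_identical(g$method, "golden")
  }
})

test_that("bracket endpoints are validated, extended, and warm-starts agree", {
  m <- make_analytic_model()  # mu* ~ 0.99
  expect_error(bisect_me(m, interval = c(1.5, 2)), "infeasible at lower bracket")
  w <- testthat::capture_warnings(
    s <- bisect_me(m, interval = c(0, 0.3), epsilon = 1e-4))
  expect_true(any(grepl("extending", w)))
  expect_lt(abs(s$mu_best - closed_form_mu(10, 10, 1, 100)), 1e-4)

  # a model feasible everywhere in reach: extension gives up after 4 doublings
  free <- me_model("growth", character(0),
                   list(i = integer(0), j = integer(0), x = character(0)),
                   0, 100, growth_reaction = "growth")
  expect_error(suppressWarnings(bisect_me(free, interval = c(0, 2))),
               "4 extensions")

  # warm and cold verdicts match at the same mu
  f_cold <- feasible_at(m, 0.7)
  f_warm <- feasible_at(m, 0.7, warm = feasible_at(m, 0.3)$basis)
  expect_identical(f_warm$feasible, f_cold$feasible)
  f2_cold <- feasible_at(m, 1.3)
  f2_warm <- feasible_at(m, 1.3, warm = f_warm$basis)
  expect_identical(f2_warm$feasible, f2_cold$feasible)
})
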