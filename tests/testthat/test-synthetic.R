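test_that("the analytic generator validates parameters and has the closed form", {
  expect_error(make_analytic_model(U = -1), "strictly positive")
  expect_error(make_analytic_model(m = -0.1), "nonnegative")
  m <- make_analytic_model(U = 7, a_bio = 9, m = 2, k_eff = 50)
  expect_s3_class(m, "me_model")
  mu_true <- closed_form_mu(7, 9, 2, 50)
  expect_true(feasible_at(m, mu_true - 1e-9)$feasible)
  expect_false(feasible_at(m, mu_true + 1e-9)$feasible)
})

test_that("the coupled-complex model has a single sink per subunit", {
  m <- make_coupled_complex_model()
  for (pep in c("pepA", "pepB")) {
    i <- match(pep, m$metabolite_ids)
    consumers <- m$S$j[m$S$i == i & memax:::qnum(m$S$x) < 0]
    expect_identical(m$reaction_ids[consumers], "complex_formation")
  }
  # knocking out either subunit kills growth
  fit <- solve_me(m)
  k <- knockout_screen(m, c("subA", "subB"), mu_test = fit$mu_star / 2)
  expect_identical(k$verdict, c("essential", "essential"))
})

test_that("the multiscale generator is deterministic given its seed", {
  a <- make_multiscale_model(seed = 9)
  b <- make_multiscale_model(seed = 9)
  fa <- withr::local_tempfile(); fb <- withr::local_tempfile()
  write_me_model(a, fa); write_me_model(b, fb)
  expect_identical(readLines(fa), readLines(fb))
  expect_identical(a$meta$seed, 9)
  # a different seed gives a different model
  d <- make_multiscale_model(seed = 10)
  fd <- withr::local_tempfile(); write_me_model(d, fd)
  expect_false(identical(readLines(fa), readLines(fd)))
  # and the generator does not disturb the session RNG stream
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(make_multiscale_model(seed = 4)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("every generated model satisfies the bracket contract", {
  for (seed in 1:5) {
    m <- make_multiscale_model(seed = seed)
    expect_s3_class(m, "me_model")     # constructor re-validates all fields
    f0 <- feasible_at(m, 0)
    expect_true(f0$feasible)
    expect_false(feasible_at(m, 2, warm = f0$basis)$feasible)
    mu_t <- as.numeric(m$meta$mu_target)
    expect_true(mu_t > 0 && mu_t < 2)
  }
})

test_that("all four machinery families are instantiated", {
  m <- make_multiscale_model(seed = 1)
  fam <- vapply(m$dilution_rows, function(d) d$family, character(1))
  expect_setequal(unique(fam),
                  c("ribosome", "rnap", "trna", "enzyme", "generic"))
  expect_identical(sum(fam == "enzyme"), 6L)
  expect_identical(sum(fam == "trna"), 4L)
})
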