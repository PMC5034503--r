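test_that("linearization expands the bilinear rows correctly", {
  # row b = {x:1}, c = {x:1} expanded at mu_k = 1, v_k = {x:2}:
  # x - 1*x - 2*(mu - 1)  =>  mu column coefficient -2, rhs -2
  m <- me_model("x", "met", list(i = 1L, j = 1L, x = "1"), 0, 10,
                dilution_rows = list(dilution_row(b = c(x = 1), c = c(x = 1),
                                                  label = "d")))
  lp <- linearize_at(m, 1, c(x = 2), trust = c(0, 2))
  expect_identical(lp$col_names, c("x", "mu"))
  dil <- match("d", lp$row_names)
  t <- which(lp$A$i == dil)
  co <- setNames(memax:::qnum(lp$A$x[t]), lp$col_names[lp$A$j[t]])
  expect_equal(unname(co[["mu"]]), -2)
  expect_false("x" %in% names(co))   # 1 - 1*1 = 0 dropped
  expect_equal(memax:::qnum(lp$rhs[dil]), -2)

  # without dilution rows the subproblem is independent of the expansion
  # point and mu is bounded only by the trust region / growth link
  m2 <- me_model("g", character(0),
                 list(i = integer(0), j = integer(0), x = character(0)),
                 0, 0.7, growth_reaction = "g")
  lpa <- linearize_at(m2, 0.1, c(g = 0.1), trust = c(0, 2))
  lpb <- linearize_at(m2, 0.5, c(g = 0.5), trust = c(0, 2))
  expect_identical(lpa$A, lpb$A)
  expect_identical(lpa$rhs, lpb$rhs)
  s <- solve_lp(lpa)
  expect_equal(s$objective, 0.7)   # capped by the growth bound, not trust

  # exactness at the expansion point: the linearized rows reproduce the
  # original slack for a feasible iterate
  ma <- make_analytic_model()
  f <- feasible_at(ma, 0.5)
  vk <- f$solution$primal_chr
  lp3 <- linearize_at(ma, 0.5, vk, trust = c(0.25, 0.75))
  point <- c(vk, mu = memax:::qchr(0.5))
  act <- memax:::.q_row_sums(lp3$A$i, lp3$A$j, lp3$A$x, point[lp3$col_names],
                             lp3$m)
  lin_slack <- memax:::qnum(memax:::.q_op("-", act, lp3$rhs))
  orig <- mu_level_set_residual(ma, 0.5, vk)
  expect_equal(lin_slack[match("enzyme_capacity", lp3$row_names)],
               orig$residual, tolerance = 1e-30)
  expect_error(linearize_at(ma, 0.5, c(1, 2)), "length")
})

test_that("the SLP solver recovers closed-form optima to high precision", {
  fit <- solve_me(make_analytic_model())
  expect_true(fit$converged)
  expect_lt(abs(fit$mu_star - 10 / 10.1) / (10 / 10.1), 1e-14)

  # enzyme-free limit: mu* = U/a_bio exactly
  expect_lt(abs(solve_me(make_analytic_model(m = 0))$mu_star - 1), 1e-12)
  # very fast enzyme: mu* -> U/a_bio
  expect_lt(abs(solve_me(make_analytic_model(k_eff = 1e12))$mu_star - 1), 1e-10)

  # growth capped by a plain bound (no dilution rows): mu* = 0.7 exactly
  m2 <- me_model("g", character(0),
                 list(i = integer(0), j = integer(0), x = character(0)),
                 0, 0.7, growth_reaction = "g")
  f2 <- solve_me(m2)
  expect_equal(f2$mu_star, 0.7)

  # returned fluxes satisfy all constraints at mu*
  rr <- fit$residual_report
  expect_lte(rr[["max_stoichiometric"]], 1e-15)
  expect_lte(rr[["max_nonlinear"]], 1e-15)
})

test_that("the optimum is independent of the coarse-search accuracy", {
  m <- make_analytic_model()
  mus <- vapply(0:3, function(d) solve_me(m, decimals_coarse = d)$mu_star,
                numeric(1))
  expect_lt(max(mus) - min(mus), 1e-12)
})

test_that("starting safeguards: mu0 = 0 converges, mu0 > mu* restarts", {
  m <- make_analytic_model()
  mu_true <- closed_form_mu(10, 10, 1, 100)
  f0 <- solve_me(m, mu0 = 0)
  expect_true(f0$converged)
  expect_lt(abs(f0$mu_star - mu_true), 1e-12)

  fhi <- solve_me(m, mu0 = 1.9)            # above mu*: restart from mu0/2
  expect_true(fhi$converged)
  expect_lt(abs(fhi$mu_star - mu_true), 1e-12)

  # hopelessly high starts are reported, not silently absorbed
  expect_error(solve_me(m, mu0 = 1e6), "restarts")
})

test_that("SLP and bisection agree on multiscale models", {
  for (seed in c(1, 2, 7)) {
    m <- make_multiscale_model(seed = seed)
    fit <- solve_me(m)
    b <- bisect_me(m, epsilon = 1e-9)
    expect_true(fit$converged)
    expect_lt(abs(fit$mu_star - b$mu_best), 1e-9)
    expect_true(certify_optimum(m, fit$mu_star))
  }
})

test_that("the accepted-step sequence has a contracting tail", {
  for (m in list(make_analytic_model(), make_multiscale_model(seed = 1))) {
    fit <- solve_me(m)
    steps <- abs(fit$history$step[fit$history$accepted])
    steps <- steps[!is.na(steps)]
    tail_steps <- steps[steps < 1e-4]
    if (length(tail_steps) > 1)
      expect_true(all(diff(tail_steps) <= 1e-15))
  }
})

test_that("optimum certification straddles correctly", {
  m <- make_analytic_model()
  mu_true <- closed_form_mu(10, 10, 1, 100)
  expect_true(certify_optimum(m, mu_true))
  expect_false(certify_optimum(m, mu_true / 2))   # upper test feasible
  expect_false(certify_optimum(m, 2 * mu_true))   # lower test infeasible
})

test_that("fit methods expose fluxes, residuals and convergence history", {
  fit <- solve_me(make_analytic_model())
  v <- coef(fit)
  expect_named(v)
  expect_equal(unname(v[["growth"]]), fit$mu_star)
  r <- residuals(fit)
  expect_true(all(r$satisfied))
  expect_output(print(fit), "mu\\*")
  expect_output(summary(fit), "orders of magnitude")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
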