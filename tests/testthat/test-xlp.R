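test_that("simplex solves, certifies and classifies small problems", {
  lp <- me_lp(obj = 1, A = matrix(1, 1, 1), sense = "L", rhs = 3, lb = 0, ub = Inf)
  s <- expect_certified(solve_lp(lp))
  expect_equal(s$objective, 3)

  lp2 <- me_lp(obj = c(1, 1), A = matrix(c(1, 1), 1, 2), sense = "L", rhs = 1,
               lb = c(2, 2), ub = c(Inf, Inf))
  expect_identical(solve_lp(lp2)$status, "infeasible")
  expect_gt(solve_lp(lp2)$phase1_infeasibility, 0)

  lp3 <- me_lp(obj = 1, A = list(i = integer(0), j = integer(0), x = character(0)),
               sense = character(0), rhs = character(0), lb = 0, ub = Inf)
  expect_identical(solve_lp(lp3)$status, "unbounded")

  # iteration limit surfaces as a status, not a wrong answer
  lp4 <- fix_mu(make_multiscale_model(seed = 4), 0.5)
  s4 <- solve_lp(lp4, me_context(iteration_limit = 2))
  expect_identical(s4$status, "iteration_limit")
})

test_that("simplex agrees with the exact rational oracle on random LPs", {
  set.seed(101)
  for (k in 1:60) {
    lp <- random_small_lp()
    o <- vertex_oracle(lp)
    s <- solve_lp(lp)
    expect_identical(s$status, o$status)
    if (o$status == "optimal") {
      expect_lt(qrel(s$objective_chr, o$objective_chr), 1e-20)
      expect_certified(s)
    }
  }
})

test_that("warm starts reproduce cold solves after bound perturbations", {
  set.seed(33)
  m <- make_multiscale_model(seed = 3)
  lp <- fix_mu(m, 0.5)
  base <- solve_lp(lp)
  for (k in 1:10) {
    lp2 <- lp
    j <- sample(lp$n, 1)
    ubj <- memax:::qnum(lp$ub[j])
    if (is.finite(ubj) && ubj > 0) lp2$ub[j] <- memax:::qchr(ubj * runif(1, 0.5, 1))
    lbj <- memax:::qnum(lp$lb[j])
    w <- solve_lp(lp2, warm = base)
    c0 <- solve_lp(lp2)
    expect_identical(w$status, c0$status)
    if (w$status == "optimal") {
      expect_lt(qrel(w$objective_chr, c0$objective_chr) /
                  max(1, abs(c0$objective)), 1e-12)
      expect_lte(w$iterations, c0$iterations)
    }
  }
  # dimension-mismatched bases are repaired, not rejected
  tiny <- me_lp(obj = 1, A = matrix(1, 1, 1), sense = "L", rhs = 3, lb = 0, ub = Inf)
  s <- solve_lp(tiny, warm = base)
  expect_equal(s$objective, 3)
})

test_that("power-of-two scaling is exactly invertible and tames the range", {
  m <- make_multiscale_model(seed = 1)
  lp <- fix_mu(m, 0.5)
  sc <- scale_problem(lp)
  expect_true(all(memax:::.q_cmp(unscale_problem(sc)$A$x, lp$A$x) == 0L))
  expect_true(all(memax:::.q_cmp(unscale_problem(sc)$obj, lp$obj) == 0L))
  expect_true(all(sc$row_factors == 2^sc$row_exp))

  rng <- function(l) {
    v <- abs(memax:::qnum(l$A$x)); v <- v[v > 0]
    max(v) / min(v)
  }
  expect_lt(rng(sc$lp), rng(lp))

  # a 1x1 identity-ish matrix needs no scaling
  one <- me_lp(obj = 1, A = matrix(1, 1, 1), sense = "L", rhs = 1, lb = 0, ub = 1)
  sc1 <- scale_problem(one)
  expect_identical(sc1$row_exp, 0L)
  expect_identical(sc1$col_exp, 0L)

  # objective is unaffected by scaling choice
  s2 <- solve_lp(lp, scaling = "2")
  s0 <- solve_lp(lp, scaling = "off")
  expect_lt(qrel(s2$objective_chr, s0$objective_chr) /
              max(1, abs(s0$objective)), 1e-12)
})

test_that("double-precision mode works at its looser tolerances", {
  ctx <- me_context("double")
  expect_identical(ctx$feas_tol, 1e-9)
  lp <- fix_mu(make_analytic_model(), 0.5, ctx)
  s <- solve_lp(lp, ctx)
  expect_identical(s$status, "optimal")
  expect_lte(s$residual_report[["max_primal"]], ctx$feas_tol)
})

test_that("vertex oracle handles degeneracy, unboundedness and the size cap", {
  lp <- me_lp(obj = 1, A = matrix(1, 1, 1), sense = "L", rhs = 3, lb = 0, ub = Inf)
  expect_equal(vertex_oracle(lp)$objective, 3)

  # duplicate rows (degenerate) still give the simplex optimum
  dup <- me_lp(obj = c(2, 1), A = matrix(c(1, 1, 1, 1), 2, 2), sense = c("L", "L"),
               rhs = c(4, 4), lb = c(0, 0), ub = c(Inf, Inf))
  o <- vertex_oracle(dup)
  s <- solve_lp(dup)
  expect_identical(o$status, "optimal")
  expect_lt(qrel(s$objective_chr, o$objective_chr), 1e-20)

  unb <- me_lp(obj = 1, A = list(i = integer(0), j = integer(0), x = character(0)),
               sense = character(0), rhs = character(0), lb = 0, ub = Inf)
  expect_identical(vertex_oracle(unb)$status, "unbounded")

  wide <- me_lp(obj = rep(1, 9), A = matrix(0:0, 1, 9), sense = "L", rhs = 1,
                lb = rep(0, 9), ub = rep(1, 9))
  expect_error(vertex_oracle(wide), "8 variables")
})
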