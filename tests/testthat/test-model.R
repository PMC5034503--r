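test_that("model validation rejects malformed input", {
  S <- list(i = 1L, j = 1L, x = "1")
  expect_error(me_model(c("a", "a"), "m", S, 0, 1), "duplicate reaction")
  expect_error(me_model("a", "m", S, c(0, 0), c(1, 1)), "one entry per reaction")
  expect_error(me_model("a", "m", S, 1, 0), "v_lower exceeds")
  expect_error(me_model("a", "m", list(i = 2L, j = 1L, x = "1"), 0, 1),
               "out of range")
  expect_error(
    me_model("a", "m", S, -1, 1, growth_reaction = "a"),
    "nonnegative lower bound")
  dr <- dilution_row(b = c(ghost = 1), c = c(ghost = 2), label = "bad")
  expect_error(me_model("a", "m", S, 0, 1, dilution_rows = list(dr)),
               "unknown reaction 'ghost'")
  expect_error(
    me_model("a", "m", S, 0, 1,
             annotations = data.frame(reaction = "a", category = "nonsense")),
    "unknown annotation category")
  expect_error(dilution_row(b = c(x = 0), c = c(x = 0)), "both zero")
})

test_that("dilution-row coefficients follow the machinery formulas", {
  # one peptide of length 300, c_ribo = 3, kappa_tau = 4, r0 = 0.5:
  # expanding (mu + r0*kappa_tau) gives b = -l*r0/c_ribo = -50 on translation
  # and c = l/(c_ribo*kappa_tau) = 25
  rxn <- c("tr", "dil_rib")
  m <- me_model(rxn, "pep", list(i = c(1L, 1L), j = c(1L, 2L), x = c("1", "-1")),
                c(0, 0), c(Inf, Inf),
                annotations = data.frame(
                  reaction = rxn, category = c("translation", "dilution"),
                  length = c(300, NA), complex = c(NA, "ribosome")))
  rows <- build_dilution_rows(m, me_constants(c_ribo = 3, kappa_tau = 4, r0 = 0.5))
  expect_length(rows, 1)
  r <- rows[[1]]
  expect_identical(r$family, "ribosome")
  expect_equal(memax:::qnum(r$b[["dil_rib"]]), 1)
  expect_equal(memax:::qnum(r$b[["tr"]]), -50)
  expect_equal(memax:::qnum(r$c[["tr"]]), 25)

  # enzyme family: b = +1 on the dilution flux only, c = 1/k_eff on usage
  rxn2 <- c("use", "dil_e")
  m2 <- me_model(rxn2, "E", list(i = c(1L), j = c(2L), x = "-1"),
                 c(0, 0), c(Inf, Inf),
                 annotations = data.frame(
                   reaction = rxn2, category = c("metabolic", "dilution"),
                   complex = c(NA, "enzA")))
  rows2 <- build_dilution_rows(
    m2, me_constants(1, 1, 1, k_eff = data.frame(enzyme = "enzA",
                                                 usage = "use", k_eff = 100)))
  expect_length(rows2, 1)
  expect_identical(names(rows2[[1]]$b), "dil_e")
  expect_equal(memax:::qnum(rows2[[1]]$c[["use"]]), 0.01)

  # no machinery annotations: no rows
  m3 <- me_model("a", "m", list(i = 1L, j = 1L, x = "1"), 0, 1)
  expect_length(build_dilution_rows(m3, me_constants(1, 1, 1)), 0)

  # structured errors: translation present but no ribosome dilution reaction
  m_bad <- me_model(rxn, "pep",
                    list(i = c(1L, 1L), j = c(1L, 2L), x = c("1", "-1")),
                    c(0, 0), c(Inf, Inf),
                    annotations = data.frame(
                      reaction = rxn,
                      category = c("translation", "metabolic"),
                      length = c(300, NA)))
  expect_error(build_dilution_rows(m_bad, me_constants(3, 4, 0.5)),
               "ribosome dilution")
  expect_error(me_constants(c_ribo = -1, kappa_tau = 1, r0 = 1),
               "strictly positive")
  m4 <- m2
  expect_error(build_dilution_rows(
    m4, me_constants(1, 1, 1, k_eff = data.frame(enzyme = "enzA",
                                                 usage = "ghost", k_eff = 2))),
    "unknown usage reaction")
})

test_that("general form assembly stacks and round-trips dilution rows", {
  m0 <- me_model("a", "m", list(i = 1L, j = 1L, x = "1"), 0, 1)
  gf0 <- assemble_general_form(m0)
  expect_identical(gf0$n_rows, 0L)
  expect_length(gf0$Bmat$i, 0)

  rxn <- sprintf("r%d", 1:5)
  rows <- list(
    dilution_row(b = c(r1 = 1, r3 = -2), c = c(r2 = 0.5), label = "d1"),
    dilution_row(b = c(r5 = 1), c = c(r4 = 3), sense = "eq", label = "d2"))
  m <- me_model(rxn, "met", list(i = 1L, j = 1L, x = "1"),
                rep(0, 5), rep(10, 5), dilution_rows = rows)
  gf <- assemble_general_form(m)
  expect_identical(gf$n_rows, 2L)
  expect_identical(gf$n_reactions, 5L)
  expect_identical(gf$senses, c("ge", "eq"))
  # round-trip row extraction
  b1 <- setNames(memax:::qnum(gf$Bmat$x[gf$Bmat$i == 1]),
                 rxn[gf$Bmat$j[gf$Bmat$i == 1]])
  expect_equal(b1[c("r1", "r3")], c(r1 = 1, r3 = -2))
  c2 <- memax:::qnum(gf$Cmat$x[gf$Cmat$i == 2])
  expect_equal(c2, 3)

  # analytic fixture: single enzyme row with c-coefficient 1/k_eff
  gfa <- assemble_general_form(make_analytic_model(k_eff = 250))
  expect_identical(gfa$n_rows, 1L)
  expect_equal(memax:::qnum(gfa$Cmat$x), 1 / 250)
})

test_that("fixed-mu reduction substitutes mu into dilution rows only", {
  # a ge-row b = {x:+1}, c = {y:+2} at mu = 0.5 becomes x - y >= 0
  rxn <- c("x", "y")
  m <- me_model(rxn, "met", list(i = c(1L, 1L), j = c(1L, 2L), x = c("1", "-1")),
                c(0, 0), c(5, 5),
                dilution_rows = list(dilution_row(b = c(x = 1), c = c(y = 2),
                                                  label = "d")))
  lp <- fix_mu(m, 0.5)
  t <- which(lp$A$i == 2)
  co <- setNames(memax:::qnum(lp$A$x[t]), lp$col_names[lp$A$j[t]])
  expect_equal(co[["x"]], 1)
  expect_equal(co[["y"]], -1)
  expect_identical(lp$sense[2], "G")

  # without dilution rows the LP is exactly the flux-balance problem
  m2 <- me_model(rxn, "met", list(i = c(1L, 1L), j = c(1L, 2L), x = c("1", "-1")),
                 c(0, 0), c(5, 5))
  lp2 <- fix_mu(m2, 0.25)
  expect_identical(lp2$m, 1L)
  expect_identical(lp2$A$x, m2$S$x)

  expect_error(fix_mu(m, -1), "nonnegative")
  expect_error(fix_mu(m, Inf), "finite")

  # same sparsity pattern for different mu (coefficients differ only in
  # dilution rows)
  ma <- make_analytic_model()
  lpa <- fix_mu(ma, 0.3); lpb <- fix_mu(ma, 1.1)
  expect_identical(lpa$A$i, lpb$A$i)
  expect_identical(lpa$A$j, lpb$A$j)
  same <- memax:::.q_cmp(lpa$A$x, lpb$A$x) == 0L
  dil_row <- match("enzyme_capacity", lpa$row_names)
  expect_true(all(same[lpa$A$i != dil_row]))
  expect_false(all(same[lpa$A$i == dil_row]))
})

test_that("feasibility at the closed-form optimum flips within 1e-6", {
  m <- make_analytic_model()
  mu_star <- closed_form_mu(10, 10, 1, 100)
  expect_true(feasible_at(m, mu_star)$feasible)
  expect_false(feasible_at(m, mu_star + 1e-6)$feasible)
})

test_that("feasibility in mu is an interval (nonincreasing indicator)", {
  for (model in list(make_analytic_model(), make_coupled_complex_model())) {
    fit <- solve_me(model)
    mus <- seq(0, 2 * fit$mu_star, length.out = 50)
    warm <- NULL
    feas <- logical(50)
    for (k in seq_along(mus)) {
      f <- feasible_at(model, mus[k], warm = warm)
      feas[k] <- f$feasible
      warm <- f$basis
    }
    expect_true(all(diff(as.integer(feas)) <= 0))
    expect_true(feas[1])
    expect_false(feas[50])
  }
})

test_that("level-set residuals match an independent dense accumulation", {
  m <- make_multiscale_model(seed = 11)
  n <- length(m$reaction_ids)
  set.seed(7)
  v <- runif(n, 0, 2)
  res <- mu_level_set_residual(m, 0.8, v)
  expect_identical(nrow(res), length(m$dilution_rows))

  # dense recomputation through a different quad accumulation path
  vchr <- memax:::qchr(v)
  for (k in seq_along(m$dilution_rows)) {
    d <- m$dilution_rows[[k]]
    dense_b <- rep("0", n); dense_b[match(names(d$b), m$reaction_ids)] <- d$b
    dense_c <- rep("0", n); dense_c[match(names(d$c), m$reaction_ids)] <- d$c
    bd <- memax:::.q_dot(dense_b, vchr)
    cd <- memax:::.q_dot(dense_c, vchr)
    expected <- memax:::.q_axmy(bd, cd, memax:::qchr(0.8))
    expect_lt(qrel(res$residual_chr[k], expected), 1e-25)
  }

  # v = 0 gives all-zero residuals; an eq row with b^T v = 3, c^T v = 2 is
  # exactly satisfied at mu = 1.5
  expect_true(all(mu_level_set_residual(m, 1.3, rep(0, n))$residual == 0))
  m2 <- me_model(c("p", "q"), "met",
                 list(i = c(1L, 1L), j = c(1L, 2L), x = c("1", "-1")),
                 c(0, 0), c(10, 10),
                 dilution_rows = list(dilution_row(b = c(p = 1), c = c(q = 1),
                                                   sense = "eq", label = "d")))
  r2 <- mu_level_set_residual(m2, 1.5, c(p = 3, q = 2))
  expect_equal(r2$residual, 0)
  expect_true(r2$satisfied)
  expect_error(mu_level_set_residual(m2, 1, c(1, 2, 3)), "length")
})
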