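test_that("FVA recovers plain bounds for a reaction outside every row", {
  rxn <- c("free_rxn", "growth")
  m <- me_model(rxn, character(0),
                list(i = integer(0), j = integer(0), x = character(0)),
                v_lower = c(-5, 0), v_upper = c(5, 1),
                growth_reaction = "growth")
  f <- vary_me(m, mu_fraction = 0.5, mu_star = 1)
  row <- as.data.frame(f)[f$reaction == "free_rxn", ]
  expect_equal(row$vmin, -5)
  expect_equal(row$vmax, 5)
  expect_identical(attr(f, "lp_count"), 4L)
})

test_that("coupled subunits get identical ranges and 2 LPs per reaction", {
  m <- make_coupled_complex_model()
  fit <- solve_me(m)
  for (frac in c(0.5, 1)) {
    f <- vary_me(m, mu_fraction = frac, fit = fit)
    expect_identical(attr(f, "lp_count"), 2L * nrow(f))
    a <- as.data.frame(f)
    expect_lt(abs(a$vmin[a$reaction == "tr_subA"] -
                    a$vmin[a$reaction == "tr_subB"]), 1e-12)
    expect_lt(abs(a$vmax[a$reaction == "tr_subA"] -
                    a$vmax[a$reaction == "tr_subB"]), 1e-12)
    expect_true(all(a$vmin <= a$vmax + 1e-15))
  }
})

test_that("warm and cold FVA agree to 1e-12 with fewer warm iterations", {
  m <- make_multiscale_model(seed = 2)
  fit <- solve_me(m)
  fw <- vary_me(m, mu_fraction = 0.5, fit = fit, warm = TRUE)
  fc <- vary_me(m, mu_fraction = 0.5, fit = fit, warm = FALSE)
  expect_lt(max(abs(fw$vmin - fc$vmin)), 1e-12)
  expect_lt(max(abs(fw$vmax - fc$vmax)), 1e-12)
  expect_lt(attr(fw, "iterations_total"), attr(fc, "iterations_total"))
  expect_true(all(fw$vmin <= fw$vmax + 1e-15))
})

test_that("variability collapses at mu* and nests at lower growth", {
  m <- make_multiscale_model(seed = 1)
  fit <- solve_me(m)
  f1 <- vary_me(m, mu_fraction = 1, fit = fit)
  tr <- grepl("^tr\\d+$", f1$reaction)
  expect_true(any(tr))
  expect_true(all(f1$vmax[tr] - f1$vmin[tr] <= 1e-10))
  f05 <- vary_me(m, mu_fraction = 0.5, fit = fit)
  expect_true(all(f05$vmin[tr] <= f1$vmin[tr] + 1e-12))
  expect_true(all(f05$vmax[tr] >= f1$vmax[tr] - 1e-12))
  expect_error(vary_me(m, mu_fraction = 1.5), "mu_fraction")
})

test_that("knockout essentiality is one LP per gene with correct calls", {
  m <- make_analytic_model()
  fit <- solve_me(m)
  # the enzyme-synthesis gene is essential: the dilution row then forces
  # zero uptake, and the substrate balance forces mu = 0
  k <- knockout_screen(m, "enz", mu_test = fit$mu_star / 2)
  expect_identical(k$verdict, "essential")
  expect_identical(attr(k, "lp_count"), 1L)

  # redundant parallel pathways are individually dispensable
  tp <- make_two_pathway_model()
  k2 <- knockout_screen(tp, c("g1", "g2"), mu_test = 0.3)
  expect_identical(k2$verdict, c("nonessential", "nonessential"))
  expect_identical(attr(k2, "lp_count"), 2L)

  # empty gene list
  k3 <- knockout_screen(m, character(0), mu_test = 0.1)
  expect_identical(nrow(k3), 0L)
  expect_identical(attr(k3, "lp_count"), 0L)

  # unknown genes are reported per-gene while the screen continues
  expect_message(k4 <- knockout_screen(m, c("ghost", "enz"),
                                       mu_test = fit$mu_star / 2),
                 "ghost")
  expect_identical(k4$verdict, c("unknown_gene", "essential"))

  # warm and cold screens agree
  k5 <- knockout_screen(tp, c("g0", "g1", "g2"), mu_test = 0.3, warm = FALSE)
  k6 <- knockout_screen(tp, c("g0", "g1", "g2"), mu_test = 0.3, warm = TRUE)
  expect_identical(k5$verdict, k6$verdict)
})

test_that("flux-magnitude accounting floors, bins and spans correctly", {
  ctx20 <- me_context(feas_tol = 1e-20)
  s <- flux_magnitude_summary(c(a = 1e-14, b = 1e-6, c = 1e-4),
                              c(a = "x", b = "x", c = "x"), ctx20)
  expect_identical(s$table$min_exp, -14L)
  expect_identical(s$table$max_exp, -4L)
  expect_equal(s$table$median, 1e-6)

  # everything below the floor: empty summary, not an error
  s2 <- flux_magnitude_summary(c(a = 1e-30), c(a = "x"), me_context())
  expect_identical(s2$table$n, 0L)
  expect_true(is.na(s2$span_orders))

  # the span of {9.35e-14, 45.4} is 14.7 orders of magnitude
  s3 <- flux_magnitude_summary(c(tx = 9.35e-14, ex = 45.4),
                               c(tx = "transcription", ex = "exchange"),
                               ctx20)
  expect_equal(round(s3$span_orders, 1), 14.7)
  expect_identical(s3$table$min_exp[s3$table$category == "transcription"], -14L)

  # categories with no surviving flux are reported empty
  s4 <- flux_magnitude_summary(c(a = 1, b = 1e-30),
                               c(a = "big", b = "small"), me_context())
  expect_identical(s4$table$n[s4$table$category == "small"], 0L)
})

test_that("the optimal multiscale flux vector is itself multiscale", {
  m <- make_multiscale_model(seed = 1, magnitude_span_orders = 12)
  fit <- solve_me(m)
  cats <- setNames(m$annotations$category, m$annotations$reaction)
  s <- flux_magnitude_summary(coef(fit), cats)
  expect_gte(s$span_orders, 10)   # at least span - 2 orders
})
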