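test_that("sector mass fractions follow rate-times-weight accounting", {
  sec1 <- data.frame(reaction = "tr1", sector = "core", mw = 30000)
  f1 <- proteome_sector_fractions(c(tr1 = 1e-5), sec1)
  expect_equal(unname(f1[["core"]]), 1)

  # rates {2e-5, 1e-5} with MWs {30000, 60000}: equal 0.6 mass units each
  sec2 <- data.frame(reaction = c("trA", "trB"), sector = c("s1", "s2"),
                     mw = c(30000, 60000))
  f2 <- proteome_sector_fractions(c(trA = 2e-5, trB = 1e-5), sec2)
  expect_equal(unname(f2[c("s1", "s2")]), c(0.5, 0.5))
  expect_equal(sum(f2), 1)

  # all-zero rates come back flagged, not NaN
  f3 <- proteome_sector_fractions(c(trA = 0, trB = 0), sec2)
  expect_true(attr(f3, "zero_mass"))
  expect_equal(sum(f3), 0)

  expect_error(proteome_sector_fractions(c(trA = 1), sec2), "trB")
  dup <- rbind(sec1, sec1)
  expect_error(proteome_sector_fractions(c(tr1 = 1), dup), "more than one")
})

test_that("the expression grid scan runs the full three-step protocol", {
  tp <- make_two_pathway_model()
  fr <- seq(0.05, 0.95, length.out = 3)
  sc <- expression_grid_scan(tp, knockout_genes = "g0",
                             pathway_1 = "cf1", pathway_2 = "cf2",
                             fractions = fr,
                             product_exchange = tp$meta$product_exchange,
                             substrate_uptake = tp$meta$substrate_uptake,
                             sectors = tp$meta$sectors)
  expect_identical(nrow(sc), 9L)             # levels1 x levels2
  expect_true(all(c("f1", "f2", "feasible", "mu", "product_flux",
                    "yield", "pathway1_ratio") %in% names(sc)))
  ok <- sc$feasible
  expect_true(any(ok))
  expect_true(all(sc$yield[ok] >= 0, na.rm = TRUE))
  # sector fractions sum to 1 wherever total mass is positive
  secsum <- rowSums(as.data.frame(sc)[ok, c("core", "pathway_1", "pathway_2")])
  expect_true(all(abs(secsum - 1) < 1e-12 | secsum == 0))

  # growth is nonincreasing along f1 at fixed f2 (raised lower bounds only
  # shrink the feasible set)
  for (f2v in unique(sc$f2)) {
    sl <- sc[sc$f2 == f2v, ]
    sl <- sl[order(sl$f1), ]
    mus <- ifelse(sl$feasible, sl$mu, -Inf)
    expect_true(all(diff(mus) <= 1e-9))
  }

  # knockout consistency: the deleted strain grows no faster than wild type
  expect_lte(attr(sc, "mu_ko"), solve_me(tp)$mu_star + 1e-12)
})

test_that("zero expression forcing reproduces the knockout optimum", {
  tp <- make_two_pathway_model()
  sc0 <- expression_grid_scan(tp, knockout_genes = "g0",
                              pathway_1 = "cf1", pathway_2 = "cf2",
                              fractions = 0,
                              product_exchange = tp$meta$product_exchange,
                              substrate_uptake = tp$meta$substrate_uptake)
  expect_identical(nrow(sc0), 1L)
  expect_lt(abs(sc0$mu[1] - attr(sc0, "mu_ko")), 1e-10)
})
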