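test_that("JSON serialization round-trips every bundled fixture losslessly", {
  fixtures <- list(make_analytic_model(),
                   make_coupled_complex_model(),
                   make_two_pathway_model(),
                   make_multiscale_model(seed = 5))
  for (m in fixtures) {
    tf <- withr::local_tempfile(fileext = ".json")
    write_me_model(m, tf)
    m2 <- read_me_model(tf)
    expect_identical(m2$reaction_ids, m$reaction_ids)
    expect_identical(m2$metabolite_ids, m$metabolite_ids)
    expect_identical(m2$S, m$S)
    expect_identical(m2$v_lower, m$v_lower)
    expect_identical(m2$v_upper, m$v_upper)
    expect_identical(m2$growth_reaction, m$growth_reaction)
    expect_identical(lapply(m2$dilution_rows, unclass),
                     lapply(m$dilution_rows, unclass))
    expect_identical(m2$annotations, m$annotations)
  }
})

test_that("schema violations are reported with the offending key", {
  m <- make_analytic_model()
  tf <- withr::local_tempfile(fileext = ".json")
  write_me_model(m, tf)
  obj <- jsonlite::read_json(tf, simplifyVector = FALSE)

  broken <- obj
  broken$reactions[[1]]$lb <- NULL
  tf2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(broken, tf2, auto_unbox = TRUE, digits = NA, null = "null")
  expect_error(read_me_model(tf2), "'lb'")

  broken2 <- obj
  broken2$version <- 99
  jsonlite::write_json(broken2, tf2, auto_unbox = TRUE, digits = NA, null = "null")
  expect_error(read_me_model(tf2), "version")

  broken3 <- obj
  broken3$format <- "something-else"
  jsonlite::write_json(broken3, tf2, auto_unbox = TRUE, digits = NA, null = "null")
  expect_error(read_me_model(tf2), "format")

  expect_error(read_me_model(withr::local_tempfile()), "not found")
})

test_that("tiny decimal coefficients survive the round trip verbatim", {
  rxn <- c("a", "b")
  m <- me_model(rxn, "met",
                list(i = c(1L, 1L), j = c(1L, 2L), x = c("1e-15", "-9.35e-14")),
                c(0, 0), c("1e-20", "Inf"),
                dilution_rows = list(
                  dilution_row(b = c(a = "1"), c = c(b = "1.0000000000000001e-8"),
                               label = "d")))
  tf <- withr::local_tempfile(fileext = ".json")
  write_me_model(m, tf)
  m2 <- read_me_model(tf)
  expect_identical(m2$S$x, c("1e-15", "-9.35e-14"))
  expect_identical(m2$v_upper[1], "1e-20")
  expect_identical(unname(m2$dilution_rows[[1]]$c), "1.0000000000000001e-8")
  # and the value is preserved beyond double precision
  expect_identical(memax:::.q_cmp(m2$dilution_rows[[1]]$c, "1e-8"), 1L)
})
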