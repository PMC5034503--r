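# Shared fixtures and independent oracles for the test suite.

# closed-form optimum of the single-enzyme analytic model, derived by
# eliminating the minimal enzyme expenditure from the substrate balance:
#   uptake = a_bio*mu + m*v_syn,  v_syn >= mu*uptake/k_eff,  uptake <= U
closed_form_mu <- function(U, a_bio, m, k_eff) U / (a_bio + m * U / k_eff)

# random small LP with integer data (rational-oracle compatible)
random_small_lp <- function(max_n = 6, max_m = 4) {
  n <- sample(seq_len(max_n), 1)
  m <- sample(0:max_m, 1)
  A <- matrix(sample(-5:5, m * n, replace = TRUE), m, n)
  sense <- sample(c("L", "G", "E"), m, replace = TRUE, prob = c(.45, .35, .2))
  rhs <- sample(-6:6, m, replace = TRUE)
  lb <- sample(c(0, 0, -3, -Inf), n, replace = TRUE)
  ub <- ifelse(is.finite(lb), lb, 0) + sample(c(2, 5, 10, Inf), n, replace = TRUE)
  obj <- sample(-4:4, n, replace = TRUE)
  me_lp(obj, list(i = row(A)[A != 0], j = col(A)[A != 0], x = A[A != 0]),
        sense, rhs, lb, ub, maximize = sample(c(TRUE, FALSE), 1))
}

# every certified-optimal solution must satisfy its tolerances
expect_certified <- function(sol, ctx = me_context()) {
  expect_identical(sol$status, "optimal")
  r <- sol$residual_report
  expect_lte(r[["max_primal"]], ctx$feas_tol)
  expect_lte(r[["max_bound"]], ctx$feas_tol)
  expect_lte(r[["max_dual"]], ctx$opt_tol)
  expect_lte(r[["max_complementarity"]], ctx$opt_tol)
  invisible(sol)
}

# quad-exact relative difference between two decimal strings, as a double
qrel <- function(a, b) max(memax:::.q_rel_diff(memax:::qchr(a), memax:::qchr(b)))

# minimal MPS reader: enough to recover dimensions and coefficients of the
# files write_mps() emits (an independent check that the export is readable)
parse_mps <- function(path) {
  lines <- readLines(path)
  section <- ""
  rows <- character(0)
  cols <- character(0)
  coef <- list()
  objsense <- NA_character_
  for (ln in lines) {
    if (!startsWith(ln, " ") && nzchar(trimws(ln))) {
      section <- trimws(strsplit(ln, "[[:space:]]+")[[1]][1])
      next
    }
    f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (section == "OBJSENSE" && length(f) == 1) objsense <- f[1]
    if (section == "ROWS" && length(f) == 2 && f[2] != "OBJ")
      rows <- c(rows, f[2])
    if (section == "COLUMNS" && length(f) == 3) {
      cols <- union(cols, f[1])
      coef[[paste(f[1], f[2])]] <- f[3]
    }
  }
  list(n = length(cols), m = length(rows), rows = rows, cols = cols,
       coef = coef, objsense = objsense,
       sections = intersect(c("NAME", "ROWS", "COLUMNS", "RHS", "BOUNDS",
                              "ENDATA"),
                            trimws(sub("[[:space:]].*$", "", lines))))
}
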