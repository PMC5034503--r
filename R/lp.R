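#' Construct a linear program
#'
#' The container used by the extended-precision simplex.  Coefficients may be
#' given as numerics or as decimal strings; strings are kept verbatim so that
#' values such as `"9.35e-14"` enter the solver at full precision.  Rows are
#' stored as a triplet list.
#'
#' @param obj objective coefficients (length `n`).
#' @param A row matrix as a list with integer vectors `i` (row), `j`
#'   (column) and coefficient vector `x`, or a base dense matrix.
#' @param sense row senses: `"E"` (=), `"G"` (>=) or `"L"` (<=).
#' @param rhs right-hand sides (finite).
#' @param lb,ub variable bounds; `-Inf`/`Inf` (or `"-Inf"`/`"Inf"`) allowed.
#' @param maximize logical; maximize the objective?
#' @param col_names,row_names identifiers (defaulted when missing).
#' @return an object of class `me_lp`.
#' @examples
#' lp <- me_lp(obj = 1, A = matrix(1, 1, 1), sense = "L", rhs = 3,
#'             lb = 0, ub = Inf)
#' solve_lp(lp)$objective
#' @export
me_lp <- function(obj, A, sense, rhs, lb, ub, maximize = TRUE,
                  col_names = NULL, row_names = NULL) {
  if (is.matrix(A)) {
    nz <- which(A != 0, arr.ind = TRUE)
    A <- list(i = as.integer(nz[, 1]), j = as.integer(nz[, 2]),
              x = qchr(A[nz]))
    if (length(A$i) == 0) A$x <- character(0)
  }
  n <- length(obj)
  m <- length(rhs)
  A$i <- as.integer(A$i); A$j <- as.integer(A$j); A$x <- qchr(A$x)
  stopifnot(length(A$i) == length(A$j), length(A$i) == length(A$x))
  if (length(A$i) && (min(A$i) < 1 || max(A$i) > m || min(A$j) < 1 || max(A$j) > n))
    stop("triplet indices out of range", call. = FALSE)
  sense <- toupper(substr(as.character(sense), 1, 1))
  sense[sense == "="] <- "E"; sense[sense == ">"] <- "G"; sense[sense == "<"] <- "L"
  if (!all(sense %in% c("E", "G", "L")))
    stop("row senses must be E, G or L", call. = FALSE)
  if (length(sense) == 1) sense <- rep(sense, m)
  stopifnot(length(sense) == m, length(lb) == n, length(ub) == n)
  rhs <- qchr(rhs)
  if (any(!is.finite(qnum(rhs)))) stop("right-hand sides must be finite", call. = FALSE)
  lb <- qchr(lb); ub <- qchr(ub)
  if (any(qnum(lb) > qnum(ub)))
    stop("lower bound exceeds upper bound", call. = FALSE)
  if (is.null(col_names)) col_names <- sprintf("x%d", seq_len(n))
  if (is.null(row_names)) row_names <- sprintf("r%d", seq_len(m))
  stopifnot(length(col_names) == n, length(row_names) == m)
  structure(list(n = n, m = m, obj = qchr(obj), maximize = isTRUE(maximize),
                 A = A, sense = sense, rhs = rhs, lb = lb, ub = ub,
                 col_names = as.character(col_names),
                 row_names = as.character(row_names)),
            class = "me_lp")
}

#' @export
print.me_lp <- function(x, ...) {
  cat(sprintf("Linear program: %d rows, %d columns, %d nonzeros (%s)\n",
              x$m, x$n, length(x$A$i),
              if (x$maximize) "maximize" else "minimize"))
  invisible(x)
}

basis_names <- function(lp) {
  c(lp$col_names,
    if (lp$m > 0) paste0("slack:", lp$row_names) else character(0))
}

# Map a basis (named status vector, possibly from a different LP) onto the
# variables of `lp`.  Unknown variables start nonbasic; the C++ side repairs
# any remaining rank deficiency with slacks in row order.
map_basis <- function(warm, lp) {
  if (is.null(warm)) return(integer(0))
  if (inherits(warm, "me_lp_solution")) warm <- warm$basis
  nm <- basis_names(lp)
  out <- rep(1L, length(nm))
  hit <- match(nm, names(warm))
  out[!is.na(hit)] <- as.integer(warm[hit[!is.na(hit)]])
  out
}

#' Solve a linear program with the extended-precision simplex
#'
#' A two-phase bounded-variable revised simplex run in the precision of the
#' arithmetic context.  Phase 1 drives the summed bound violations of the
#' basic variables to zero (no artificial columns); pricing is Dantzig with a
#' switch to Bland's rule after a run of degenerate pivots, and ratio-test
#' ties are broken by the lowest variable index so that solves are
#' deterministic.  With `scaling = "2"` the problem is first solved under
#' iterative geometric-mean row/column scaling with power-of-two factors and
#' the resulting basis is then polished on the unscaled data, so the
#' certified residuals always refer to the original problem.
#'
#' @param lp an [me_lp()] problem.
#' @param ctx an [me_context()].
#' @param warm optional warm-start basis: an `me_basis` status vector or a
#'   previous `me_lp_solution`.  Dimension mismatches are repaired, not
#'   rejected.
#' @param scaling `"2"` (alternating geometric-mean scaling, the default) or
#'   `"off"`.
#' @return an `me_lp_solution`: status (`optimal`, `infeasible`, `unbounded`,
#'   `iteration_limit`), primal/dual values, reduced costs, the final basis,
#'   the simplex iteration count, the phase-1 infeasibility, and a
#'   `residual_report` with the maximal primal row residual, bound
#'   violation, dual infeasibility and complementarity violation recomputed
#'   from scratch at the returned point.
#' @export
solve_lp <- function(lp, ctx = me_context(), warm = NULL,
                     scaling = c("2", "off")) {
  stopifnot(inherits(lp, "me_lp"))
  ctx <- as_me_context(ctx)
  scaling <- match.arg(scaling)
  res <- .solve_lp_core(lp$m, lp$n, lp$A$i, lp$A$j, lp$A$x, lp$sense,
                        lp$rhs, lp$obj, lp$maximize, lp$lb, lp$ub,
                        ctx$precision == "quad",
                        ctx$feas_tol, ctx$opt_tol, ctx$iteration_limit,
                        if (scaling == "2") 2L else 0L,
                        map_basis(warm, lp))
  if (res$status == "numerical")
    stop("numerical breakdown in simplex (singular basis after repair)",
         call. = FALSE)
  nm <- basis_names(lp)
  if (length(res$vstatus) == 0) {
    # contradictory bounds short-circuit: synthesize an empty report
    res$vstatus <- rep(1L, length(nm))
    res$x <- rep(0, lp$n); res$x_chr <- rep("0", lp$n)
    res$slack <- rep(0, lp$m); res$dual <- rep(0, lp$m)
    res$reduced_cost <- rep(0, lp$n + lp$m)
    res$residuals <- c(max_primal = 0, max_bound = 0, max_dual = 0,
                       max_complementarity = 0)
    res$iterations <- 0
  }
  basis <- structure(as.integer(res$vstatus), names = nm, class = "me_basis")
  primal <- setNames(as.numeric(res$x), lp$col_names)
  primal_chr <- setNames(as.character(res$x_chr), lp$col_names)
  out <- structure(list(
    status = res$status,
    objective = as.numeric(res$objective),
    objective_chr = as.character(res$objective_chr),
    primal = primal, primal_chr = primal_chr,
    slack = setNames(as.numeric(res$slack), lp$row_names),
    dual = setNames(as.numeric(res$dual), lp$row_names),
    reduced_cost = setNames(as.numeric(res$reduced_cost), nm),
    basis = basis,
    iterations = as.numeric(res$iterations),
    phase1_infeasibility = as.numeric(res$phase1_infeasibility),
    residual_report = res$residuals,
    precision = ctx$precision), class = "me_lp_solution")
  if (out$status == "optimal") {
    r <- out$residual_report
    if (r[["max_primal"]] > ctx$feas_tol * 4 || r[["max_bound"]] > ctx$feas_tol * 4)
      warning(sprintf("optimal solution exceeds feasibility tolerance (%.3g)",
                      max(r[["max_primal"]], r[["max_bound"]])))
  }
  out
}

#' @export
print.me_lp_solution <- function(x, ...) {
  cat(sprintf("LP solution: %s", x$status))
  if (x$status == "optimal")
    cat(sprintf(", objective %.12g (%s precision, %g iterations)",
                x$objective, x$precision, x$iterations))
  cat("\n")
  if (x$status == "optimal") {
    r <- x$residual_report
    cat(sprintf("  residuals: primal %.2e, bound %.2e, dual %.2e, compl %.2e\n",
                r[["max_primal"]], r[["max_bound"]], r[["max_dual"]],
                r[["max_complementarity"]]))
  }
  invisible(x)
}

#' Exact rational vertex-enumeration oracle for small LPs
#'
#' Enumerates every candidate vertex (each choice of `n` active constraints
#' among rows and bounds) in exact rational arithmetic and returns the
#' optimal objective.  Infinite bounds are boxed at `2^40` and the
#' enumeration is repeated at `2^44`; if the optimum moves the problem is
#' declared unbounded.  This is the independent certificate used to validate
#' [solve_lp()]; it refuses problems with more than 8 variables or rows.
#'
#' @param lp an [me_lp()] with rational (decimal) data.
#' @return list with `status` (`optimal`, `infeasible`, `unbounded`), the
#'   `objective` (double), `objective_chr` (36-digit decimal) and
#'   `objective_fraction` (exact `p/q`).
#' @export
vertex_oracle <- function(lp) {
  stopifnot(inherits(lp, "me_lp"))
  if (lp$n > 8 || lp$m > 8)
    stop("vertex_oracle is limited to at most 8 variables and 8 rows",
         call. = FALSE)
  .vertex_oracle_core(lp$m, lp$n, lp$A$i, lp$A$j, lp$A$x, lp$sense,
                      lp$rhs, lp$obj, lp$maximize, lp$lb, lp$ub)
}

#' Geometric-mean scaling with power-of-two factors
#'
#' Alternating row/column geometric-mean scaling (up to 10 passes or until
#' the factor change drops below 10%), followed by a final column pass that
#' brings the largest entry of each column near 1.  All factors are rounded
#' to powers of two, so scaling is exactly invertible in binary floating
#' point: [unscale_problem()] reproduces the input coefficients bit for bit.
#'
#' @param lp an [me_lp()].
#' @param mode `"2"` for the alternating scheme, `"off"` for identity
#'   factors.
#' @return a list of class `me_scaled_lp` with the scaled `lp`, integer
#'   exponent vectors `row_exp`/`col_exp` and the factors `2^row_exp`,
#'   `2^col_exp`.
#' @export
scale_problem <- function(lp, mode = c("2", "off")) {
  stopifnot(inherits(lp, "me_lp"))
  mode <- match.arg(mode)
  if (mode == "off" || lp$m == 0 || lp$n == 0) {
    f <- list(row_exp = rep(0L, lp$m), col_exp = rep(0L, lp$n))
  } else {
    f <- .scale_factors(lp$m, lp$n, lp$A$i, lp$A$j, lp$A$x)
  }
  out <- lp
  if (length(lp$A$i))
    out$A$x <- .q_scalbn(lp$A$x, f$row_exp[lp$A$i] + f$col_exp[lp$A$j])
  out$rhs <- .q_scalbn(lp$rhs, f$row_exp)
  scale_bound <- function(b, k) {
    fin <- is.finite(qnum(b))
    b[fin] <- .q_scalbn(b[fin], k[fin])
    b
  }
  out$lb <- scale_bound(lp$lb, -f$col_exp)
  out$ub <- scale_bound(lp$ub, -f$col_exp)
  out$obj <- .q_scalbn(lp$obj, f$col_exp)
  structure(list(lp = out, row_exp = f$row_exp, col_exp = f$col_exp,
                 row_factors = 2^f$row_exp, col_factors = 2^f$col_exp),
            class = "me_scaled_lp")
}

#' @rdname scale_problem
#' @param scaled an `me_scaled_lp` returned by [scale_problem()].
#' @export
unscale_problem <- function(scaled) {
  stopifnot(inherits(scaled, "me_scaled_lp"))
  lp <- scaled$lp
  out <- lp
  if (length(lp$A$i))
    out$A$x <- .q_scalbn(lp$A$x, -(scaled$row_exp[lp$A$i] + scaled$col_exp[lp$A$j]))
  out$rhs <- .q_scalbn(lp$rhs, -scaled$row_exp)
  scale_bound <- function(b, k) {
    fin <- is.finite(qnum(b))
    b[fin] <- .q_scalbn(b[fin], k[fin])
    b
  }
  out$lb <- scale_bound(lp$lb, scaled$col_exp)
  out$ub <- scale_bound(lp$ub, scaled$col_exp)
  out$obj <- .q_scalbn(lp$obj, -scaled$col_exp)
  out
}
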