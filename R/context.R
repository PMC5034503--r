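#' Arithmetic context: precision and tolerance contract
#'
#' Every numerical routine in memax runs under an arithmetic context that
#' fixes the working precision and the feasibility/optimality tolerances.
#' The extended mode performs all simplex arithmetic in IEEE binary128
#' (roughly 34 significant decimal digits) with tolerances of `1e-15`; the
#' double mode uses native floating point with tolerances of `1e-9`.
#'
#' @param precision `"quad"` (binary128, the default) or `"double"`.
#' @param feas_tol feasibility tolerance; defaults to `1e-15` in quad mode
#'   and `1e-9` in double mode.
#' @param opt_tol optimality tolerance; same defaults.
#' @param iteration_limit simplex pivot limit per solve.
#' @return an object of class `me_context`.
#' @examples
#' me_context()
#' me_context("double")
#' @export
me_context <- function(precision = c("quad", "double"),
                       feas_tol = NULL, opt_tol = NULL,
                       iteration_limit = 50000L) {
  precision <- match.arg(precision)
  quad <- precision == "quad"
  if (is.null(feas_tol)) feas_tol <- if (quad) 1e-15 else 1e-9
  if (is.null(opt_tol)) opt_tol <- if (quad) 1e-15 else 1e-9
  stopifnot(feas_tol > 0, opt_tol > 0, iteration_limit >= 1)
  digits <- if (quad) 34L else 15L
  structure(list(precision = precision, precision_digits = digits,
                 feas_tol = feas_tol, opt_tol = opt_tol,
                 iteration_limit = as.integer(iteration_limit)),
            class = "me_context")
}

as_me_context <- function(ctx) {
  if (inherits(ctx, "me_context")) return(ctx)
  stop("`ctx` must be an me_context object", call. = FALSE)
}

#' @export
print.me_context <- function(x, ...) {
  cat(sprintf("Arithmetic context: %s precision (%d digits)\n",
              x$precision, x$precision_digits))
  cat(sprintf("  feasibility tol %g, optimality tol %g, iteration limit %d\n",
              x$feas_tol, x$opt_tol, x$iteration_limit))
  invisible(x)
}
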