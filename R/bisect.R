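#' Test feasibility of a model at a fixed growth rate
#'
#' Solves the fixed-\eqn{\mu} LP as a feasibility problem.  The model is
#' feasible at `mu` when the phase-1 infeasibility is within the context's
#' feasibility tolerance; the final simplex basis is returned for chaining
#' into the next solve.
#'
#' @param model an [me_model()].
#' @param mu growth rate (1/h).
#' @param ctx an [me_context()].
#' @param warm optional warm-start basis or previous solution.
#' @return list with `feasible`, `infeasibility` (phase-1 objective),
#'   `basis`, and the full `solution`.
#' @export
feasible_at <- function(model, mu, ctx = me_context(), warm = NULL) {
  stopifnot(qnum(qchr(mu))[1] >= 0)
  lp <- fix_mu(model, mu, ctx)
  sol <- solve_lp(lp, ctx, warm = warm)
  if (sol$status %in% c("iteration_limit"))
    stop("iteration limit reached while testing feasibility at mu = ",
         qchr(mu), call. = FALSE)
  feas <- sol$status == "optimal"
  list(feasible = feas,
       infeasibility = if (feas) 0 else sol$phase1_infeasibility,
       basis = sol$basis, solution = sol)
}

#' Maximize the growth rate by bisection or golden-section search
#'
#' Feasibility search on \eqn{\mu} over fixed-\eqn{\mu} LP subproblems.
#' The feasible growth rates form an interval (the dilution rows are
#' quasilinear), so binary search brackets \eqn{\mu^*}: starting from
#' `[a, b]` it performs exactly `ceiling(log2((b - a)/epsilon))` halvings,
#' one LP each.  The golden-section variant maximizes the surrogate
#' \eqn{f(\mu) = \mu - K\cdot\mathrm{infeasibility}(\mu)} (K = 1e6), which
#' is unimodal with maximizer \eqn{\mu^*} for bounded models, shrinking the
#' bracket by \eqn{(\sqrt 5 - 1)/2} per new LP.  Every LP after the first is
#' warm-started from the previous basis.
#'
#' @param model an [me_model()].
#' @param interval initial bracket `c(a, b)`; the default `[0, 2]` covers
#'   realistic specific growth rates.  `a` must be feasible (checked); if
#'   `b` is feasible the bracket is extended by doubling, at most 4 times,
#'   with a warning.
#' @param epsilon bracket-width target (1/h).  Alternatively give
#'   `decimals`: `epsilon = 10^-decimals`.
#' @param method `"binary"` or `"golden"`.
#' @param decimals convenience accuracy spec, overrides `epsilon`.
#' @param ctx an [me_context()].
#' @return an object of class `me_search`: final bracket `mu_lo`/`mu_hi`
#'   (the largest proven-feasible and smallest proven-infeasible points),
#'   `mu_best`, the basis and flux solution at `mu_best`, LP/iteration
#'   counters and the evaluation history.
#' @examples
#' \donttest{
#' m <- make_analytic_model()
#' bisect_me(m, decimals = 6)$mu_best
#' }
#' @export
bisect_me <- function(model, interval = c(0, 2), epsilon = 1e-6,
                      method = c("binary", "golden"), decimals = NULL,
                      ctx = me_context()) {
  method <- match.arg(method)
  ctx <- as_me_context(ctx)
  if (!is.null(decimals)) epsilon <- 10^(-decimals)
  a <- interval[1]; b <- interval[2]
  stopifnot(a < b, epsilon > 0)
  history <- data.frame(mu = numeric(0), feasible = logical(0),
                        infeasibility = numeric(0))
  lp_evals <- 0L
  best <- list(mu = NA_real_, basis = NULL, solution = NULL)
  probe <- function(mu, warm) {
    f <- feasible_at(model, mu, ctx, warm = warm)
    lp_evals <<- lp_evals + 1L
    history[nrow(history) + 1L, ] <<- list(mu, f$feasible, f$infeasibility)
    if (f$feasible && (is.na(best$mu) || mu > best$mu))
      best <<- list(mu = mu, basis = f$basis, solution = f$solution)
    f
  }
  fa <- probe(a, NULL)
  if (!fa$feasible)
    stop("model infeasible at lower bracket mu = ", a, call. = FALSE)
  warm <- fa$basis
  fb <- probe(b, warm)
  ext <- 0L
  while (fb$feasible && ext < 4L) {
    ext <- ext + 1L
    bnew <- a + 2 * (b - a)
    warning(sprintf("upper bracket mu = %g is feasible; extending to %g",
                    b, bnew))
    b <- bnew
    fb <- probe(b, fb$basis)
    warm <- fb$basis
  }
  if (fb$feasible)
    stop("upper bracket still feasible after 4 extensions; ",
         "no finite optimum within reach", call. = FALSE)
  warm <- fb$basis

  iterations <- 0L
  if (method == "binary") {
    niter <- ceiling(log2((b - a) / epsilon))
    for (k in seq_len(niter)) {
      mid <- (a + b) / 2
      f <- probe(mid, warm)
      warm <- f$basis
      if (f$feasible) a <- mid else b <- mid
      iterations <- iterations + 1L
    }
  } else {
    phi <- (sqrt(5) - 1) / 2
    K <- 1e6
    fval <- function(rec) rec$mu_val - K * rec$inf
    ev <- function(mu) {
      f <- probe(mu, warm)
      warm <<- f$basis
      list(mu_val = mu, inf = f$infeasibility)
    }
    x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
    r1 <- ev(x1); r2 <- ev(x2)
    while (b - a > epsilon) {
      if (fval(r1) < fval(r2)) {
        a <- x1; x1 <- x2; r1 <- r2
        x2 <- a + phi * (b - a); r2 <- ev(x2)
      } else {
        b <- x2; x2 <- x1; r2 <- r1
        x1 <- b - phi * (b - a); r1 <- ev(x1)
      }
      iterations <- iterations + 1L
    }
  }
  mu_best <- if (is.na(best$mu)) 0 else best$mu
  # report the bracket around the optimum: largest feasible, smallest infeasible
  mu_lo <- max(history$mu[history$feasible], 0)
  inf_mu <- history$mu[!history$feasible]
  mu_hi <- if (length(inf_mu)) min(inf_mu) else b
  structure(list(mu_lo = mu_lo, mu_hi = mu_hi, mu_best = mu_best,
                 basis = best$basis, solution = best$solution,
                 lp_evaluations = lp_evals, iterations = iterations,
                 method = method, epsilon = epsilon, history = history),
            class = "me_search")
}

#' @export
print.me_search <- function(x, ...) {
  cat(sprintf("Growth-rate search (%s): mu_best = %.15g 1/h\n",
              x$method, x$mu_best))
  cat(sprintf("  bracket [%.15g, %.15g], width %.3g\n",
              x$mu_lo, x$mu_hi, x$mu_hi - x$mu_lo))
  cat(sprintf("  %d iterations, %d LP evaluations\n",
              x$iterations, x$lp_evaluations))
  invisible(x)
}
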