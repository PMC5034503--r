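#' Linearize the bilinear growth problem at an iterate
#'
#' First-order expansion of every dilution row
#' \eqn{g_i(\mu, v) = b_i^T v - \mu\, c_i^T v} about \eqn{(\mu_k, v_k)}:
#' \deqn{b_i^T v - \mu_k c_i^T v - (c_i^T v_k)(\mu - \mu_k) \{\ge,=\} 0.}
#' Because each \eqn{g_i} is bilinear, the expansion is exact at the
#' expansion point and its error at \eqn{(\mu, v)} is
#' \eqn{-(\mu-\mu_k)\,c_i^T(v - v_k)}.  The growth rate becomes an explicit
#' bounded column with objective weight 1; when the model has a growth
#' reaction the coupling row \eqn{v_{growth} - \mu = 0} ties the two.
#'
#' @param model an [me_model()].
#' @param mu_k expansion growth rate.
#' @param v_k expansion flux vector (length = reactions; numeric or decimal
#'   strings, optionally named).
#' @param trust bounds `c(lo, hi)` for the \eqn{\mu} column (the trust
#'   region).
#' @return an [me_lp()] over `(v, mu)` with the growth-rate column labelled
#'   `"mu"`.
#' @export
linearize_at <- function(model, mu_k, v_k, trust = c(0, 2)) {
  stopifnot(inherits(model, "me_model"), qnum(qchr(mu_k))[1] >= 0)
  n <- length(model$reaction_ids)
  if (length(v_k) != n)
    stop("v_k has length ", length(v_k), ", expected ", n, call. = FALSE)
  if (!is.null(names(v_k))) v_k <- v_k[model$reaction_ids]
  vchr <- qchr(v_k)
  mu_chr <- qchr(mu_k)[1]
  nmet <- length(model$metabolite_ids)
  ai <- model$S$i; aj <- model$S$j; ax <- model$S$x
  sense <- rep("E", nmet); rhs <- rep("0", nmet)
  row_names <- model$metabolite_ids
  mu_col <- n + 1L
  r <- nmet
  for (d in model$dilution_rows) {
    r <- r + 1L
    u <- union(names(d$b), names(d$c))
    bv <- setNames(rep("0", length(u)), u); bv[names(d$b)] <- d$b
    cv <- setNames(rep("0", length(u)), u); cv[names(d$c)] <- d$c
    coef <- .q_axmy(bv, cv, mu_chr)              # b - mu_k c on v
    keep <- .q_cmp(coef, "0") != 0L
    ai <- c(ai, rep(r, sum(keep)))
    aj <- c(aj, match(u[keep], model$reaction_ids))
    ax <- c(ax, coef[keep])
    cdot <- .q_dot(cv, vchr[match(u, model$reaction_ids)])  # c^T v_k
    if (.q_cmp(cdot, "0") != 0L) {
      ai <- c(ai, r); aj <- c(aj, mu_col); ax <- c(ax, q_neg(cdot))
      rhs_k <- q_neg(q_mul(cdot, mu_chr))        # -(c^T v_k) mu_k
    } else {
      rhs_k <- "0"
    }
    sense <- c(sense, if (d$sense == "eq") "E" else "G")
    rhs <- c(rhs, rhs_k)
    row_names <- c(row_names, d$label)
  }
  if (!is.null(model$growth_reaction)) {
    g <- match(model$growth_reaction, model$reaction_ids)
    r <- r + 1L
    ai <- c(ai, r, r); aj <- c(aj, g, mu_col); ax <- c(ax, "1", "-1")
    sense <- c(sense, "E"); rhs <- c(rhs, "0")
    row_names <- c(row_names, "growth_fix")
  }
  obj <- c(rep("0", n), "1")
  me_lp(obj = obj, A = list(i = ai, j = aj, x = ax), sense = sense, rhs = rhs,
        lb = c(model$v_lower, qchr(max(trust[1], 0))),
        ub = c(model$v_upper, qchr(trust[2])), maximize = TRUE,
        col_names = c(model$reaction_ids, "mu"), row_names = row_names)
}

# max violation of the true bilinear rows at (mu, v): eq rows |g|, ge rows
# the negative part of g
nonlinear_violation <- function(model, mu, v) {
  if (length(model$dilution_rows) == 0) return(0)
  res <- mu_level_set_residual(model, mu, v)
  viol <- ifelse(res$sense == "ge", pmax(0, -res$residual), abs(res$residual))
  max(viol)
}

#' Maximize growth rate: the combined coarse-search + SLP procedure
#'
#' The central solver.  A coarse search (default: golden section to one
#' decimal) finds a proven-feasible growth-rate estimate \eqn{\mu^0 < \mu^*}
#' together with a simplex basis; a warm-started sequential linearization of
#' the bilinear dilution constraints then drives \eqn{\mu} to full working
#' precision (about 15 digits in extended mode).  Each major iteration
#' solves [linearize_at()] inside a trust region on \eqn{\mu}; a step is
#' accepted when the true bilinear rows hold at the new point (directly, or
#' after a warm-started feasibility restoration at the candidate
#' \eqn{\mu}), and the trust region halves when the candidate overshoots
#' \eqn{\mu^*}.  Because the feasible growth rates form an interval, the
#' accepted iterates increase monotonically and the returned \eqn{\mu^*} is
#' the global optimum.
#'
#' Starting safeguards: a user-supplied `mu0` that is infeasible
#' (\eqn{\mu^0 > \mu^*}) triggers an automatic restart from `mu0/2`, at most
#' 5 times; \eqn{\mu^0 = 0} converges but spends extra iterations climbing.
#'
#' @param model an [me_model()].
#' @param decimals_coarse accuracy (decimal digits) requested from the
#'   coarse search; 1 is the speed sweet spot.
#' @param method_coarse `"golden"` (default) or `"binary"`.
#' @param mu_tol convergence tolerance on \eqn{|\mu^{k+1} - \mu^k|}.
#' @param trust_region_init initial half-width of the \eqn{\mu} trust
#'   region; default `0.5 * max(mu0, 0.1)`.
#' @param max_major major-iteration cap.
#' @param mu0 optional explicit starting estimate (bypasses the coarse
#'   search; used by the safeguard paths).
#' @param ctx an [me_context()].
#' @return an object of class `me_nlp` with `mu_star` (and the 36-digit
#'   `mu_star_chr`), the flux vector `v_star`, iteration/LP counters, the
#'   per-iteration history, a `residual_report` (LP residuals plus the
#'   maximal bilinear-row violation at the solution) and a `converged`
#'   flag.  Methods: `print`, `summary`, `coef` (fluxes), `residuals`,
#'   `plot` (convergence history).
#' @examples
#' \donttest{
#' fit <- solve_me(make_analytic_model())
#' coef(fit)[["growth"]]
#' }
#' @export
solve_me <- function(model, decimals_coarse = 1, method_coarse = c("golden", "binary"),
                     mu_tol = 1e-15, trust_region_init = NULL, max_major = 50L,
                     mu0 = NULL, ctx = me_context()) {
  stopifnot(inherits(model, "me_model"))
  method_coarse <- match.arg(method_coarse)
  ctx <- as_me_context(ctx)
  lp_evals <- 0L
  coarse <- NULL

  # Feasibility restoration at a candidate mu.  The parsimonious objective
  # (minimize total flux over bounded-below reactions) lands on a tight
  # vertex where the dilution rows bind, so the next linearization carries
  # the optimal active set and the candidate mu is Newton-quality.
  restore_at <- function(mu_chr, warm) {
    lp <- fix_mu(model, mu_chr, ctx)
    lp$obj <- ifelse(is.finite(qnum(lp$lb)), "1", "0")
    lp$maximize <- FALSE
    solve_lp(lp, ctx, warm = warm)
  }

  if (is.null(mu0)) {
    coarse <- bisect_me(model, decimals = decimals_coarse,
                        method = method_coarse, ctx = ctx)
    lp_evals <- lp_evals + coarse$lp_evaluations
    mu_k <- coarse$mu_best
    basis <- coarse$basis
    v_k <- coarse$solution$primal_chr
  } else {
    mu_k <- mu0
    restarts <- 0L
    repeat {
      f <- restore_at(qchr(mu_k), NULL)
      lp_evals <- lp_evals + 1L
      if (f$status == "optimal") break
      restarts <- restarts + 1L
      if (restarts > 5L)
        stop("starting estimate remained infeasible after 5 restarts ",
             "(mu0 likely far above the optimum)", call. = FALSE)
      mu_k <- mu_k / 2
    }
    basis <- f$basis
    v_k <- f$primal_chr
  }

  delta <- if (is.null(trust_region_init)) 0.5 * max(mu_k, 0.1) else trust_region_init
  history <- data.frame(major = 0L, mu = mu_k, step = NA_real_,
                        trust = delta, accepted = TRUE)
  converged <- FALSE
  full_steps <- 0L
  major <- 0L
  last_sol <- NULL
  mu_chr <- qchr(mu_k)

  while (major < max_major) {
    major <- major + 1L
    lp <- linearize_at(model, mu_k, v_k, trust = c(max(0, mu_k - delta), mu_k + delta))
    sol <- solve_lp(lp, ctx, warm = basis)
    lp_evals <- lp_evals + 1L
    if (sol$status != "optimal") {
      # the expansion point itself is feasible for the subproblem, so this
      # signals numerical stress: shrink the trust region and retry
      delta <- delta / 2
      history[nrow(history) + 1L, ] <- list(major, mu_k, NA_real_, delta, FALSE)
      if (delta < mu_tol) break
      next
    }
    mu_c <- unname(sol$primal[["mu"]])
    mu_c_chr <- unname(sol$primal_chr[["mu"]])
    v_c <- sol$primal_chr[model$reaction_ids]
    hit_bound <- mu_c >= mu_k + delta * (1 - 1e-9)

    viol <- nonlinear_violation(model, mu_c_chr, v_c)
    accepted <- FALSE
    if (viol <= ctx$feas_tol) {
      accepted <- TRUE
      v_new <- v_c
      basis_new <- sol$basis
      last_sol <- sol
    } else {
      rest <- restore_at(mu_c_chr, sol$basis)
      lp_evals <- lp_evals + 1L
      if (rest$status == "optimal") {
        accepted <- TRUE
        v_new <- rest$primal_chr
        basis_new <- rest$basis
        last_sol <- rest
      } else {
        # the candidate may overshoot mu* by less than the convergence
        # tolerance (the linearized bound is one-sided); back off by mu_tol
        # before giving up on the step
        mu_b <- mu_c - mu_tol * max(1, abs(mu_c))
        if (mu_b > mu_k) {
          rb <- restore_at(qchr(mu_b), sol$basis)
          lp_evals <- lp_evals + 1L
          if (rb$status == "optimal") {
            accepted <- TRUE
            mu_c <- mu_b
            mu_c_chr <- qchr(mu_b)
            v_new <- rb$primal_chr
            basis_new <- rb$basis
            last_sol <- rb
          }
        }
      }
    }
    if (!accepted) {
      delta <- delta / 2
      history[nrow(history) + 1L, ] <- list(major, mu_k, NA_real_, delta, FALSE)
      if (delta < .Machine$double.xmin * 8) break
      next
    }
    step <- mu_c - mu_k
    mu_k <- mu_c
    mu_chr <- mu_c_chr
    v_k <- v_new
    basis <- basis_new
    history[nrow(history) + 1L, ] <- list(major, mu_k, step, delta, TRUE)
    if (hit_bound) {
      full_steps <- full_steps + 1L
      if (full_steps >= 2L) { delta <- 2 * delta; full_steps <- 0L }
    } else {
      full_steps <- 0L
    }
    if (abs(step) <= mu_tol && !hit_bound) { converged <- TRUE; break }
  }

  # residual certificates at the returned point
  sres <- if (length(model$S$i))
    max(abs(qnum(.q_row_sums(model$S$i, model$S$j, model$S$x, v_k,
                             length(model$metabolite_ids))))) else 0
  nviol <- nonlinear_violation(model, mu_chr, v_k)
  rr <- if (!is.null(last_sol)) last_sol$residual_report else
    c(max_primal = NA_real_, max_bound = NA_real_, max_dual = NA_real_,
      max_complementarity = NA_real_)
  rr <- c(rr, max_stoichiometric = sres, max_nonlinear = nviol)

  structure(list(mu_star = unname(qnum(mu_chr)), mu_star_chr = unname(mu_chr),
                 v_star = setNames(qnum(v_k), model$reaction_ids),
                 v_star_chr = setNames(v_k, model$reaction_ids),
                 basis = basis,
                 major_iterations = major, lp_evaluations = lp_evals,
                 coarse = if (is.null(coarse)) NULL else
                   list(mu0 = coarse$mu_best, method = coarse$method,
                        lp_evaluations = coarse$lp_evaluations),
                 residual_report = rr, converged = converged,
                 history = history, model = model, ctx = ctx),
            class = "me_nlp")
}

#' Certify a growth-rate optimum by straddling feasibility tests
#'
#' The constraints are feasible for every \eqn{\mu \le \mu^*} and infeasible
#' beyond it, so a candidate optimum is certified by one feasible LP just
#' below and one infeasible LP just above.
#'
#' @param model an [me_model()].
#' @param mu_star candidate optimum.
#' @param delta straddle width (default `1e-9`).
#' @param ctx an [me_context()].
#' @return `TRUE` iff the model is feasible at `mu_star - delta` and
#'   infeasible at `mu_star + delta`.
#' @export
certify_optimum <- function(model, mu_star, delta = 1e-9, ctx = me_context()) {
  stopifnot(mu_star >= 0)
  lo <- feasible_at(model, max(mu_star - delta, 0), ctx)
  if (!lo$feasible) return(FALSE)
  hi <- feasible_at(model, mu_star + delta, ctx, warm = lo$basis)
  !hi$feasible
}

#' @export
print.me_nlp <- function(x, ...) {
  cat(sprintf("ME growth optimum: mu* = %.15g 1/h%s\n", x$mu_star,
              if (x$converged) "" else "  [NOT converged]"))
  cat(sprintf("  %d major iterations, %d LP evaluations\n",
              x$major_iterations, x$lp_evaluations))
  rr <- x$residual_report
  cat(sprintf("  residuals: stoichiometric %.2e, dilution %.2e, dual %.2e\n",
              rr[["max_stoichiometric"]], rr[["max_nonlinear"]],
              rr[["max_dual"]]))
  invisible(x)
}

#' @export
summary.me_nlp <- function(object, ...) {
  print(object)
  if (!is.null(object$coarse))
    cat(sprintf("  coarse start: mu0 = %.4g (%s search, %d LPs)\n",
                object$coarse$mu0, object$coarse$method,
                object$coarse$lp_evaluations))
  v <- abs(object$v_star)
  v <- v[v > object$ctx$feas_tol]
  if (length(v))
    cat(sprintf("  nonzero fluxes: %d, spanning %.1f orders of magnitude\n",
                length(v), log10(max(v) / min(v))))
  acc <- object$history[object$history$accepted & !is.na(object$history$step), ]
  if (nrow(acc))
    cat(sprintf("  final step |mu_k+1 - mu_k| = %.3g\n",
                abs(acc$step[nrow(acc)])))
  invisible(object)
}

#' @export
coef.me_nlp <- function(object, ...) object$v_star

#' @export
residuals.me_nlp <- function(object, ...) {
  mu_level_set_residual(object$model, object$mu_star_chr, object$v_star_chr,
                        object$ctx)
}

#' @export
plot.me_nlp <- function(x, ...) {
  h <- x$history[x$history$accepted, ]
  plot(h$major, h$mu, type = "b", xlab = "major iteration",
       ylab = expression(mu[k] ~ (1/h)),
       main = "SLP convergence of the growth rate", ...)
  abline(h = x$mu_star, lty = 3)
  invisible(x)
}
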