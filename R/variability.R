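#' Flux variability analysis at a fixed growth-rate fraction
#'
#' Fixes the growth rate to `mu_fraction * mu_star` (the growth flux is
#' pinned as an equality) and solves two LPs per reaction — minimize then
#' maximize its flux — in model column order.  With `warm = TRUE` every LP
#' is warm-started from the previous LP's basis (the first from the
#' supplied fit), which typically cuts simplex iterations dramatically
#' while returning identical ranges; `warm = FALSE` solves each LP from
#' scratch.
#'
#' @param model an [me_model()].
#' @param mu_fraction fraction of the optimal growth rate in `(0, 1]`.
#' @param reactions subset of reaction ids (default: all).
#' @param ctx an [me_context()].
#' @param warm chain bases between LPs?
#' @param fit optional [solve_me()] result; when missing, `solve_me()` is
#'   run first.  Alternatively pass `mu_star` directly.
#' @param mu_star optional known optimal growth rate.
#' @return an object of class `me_fva`: a data frame with `reaction`,
#'   `vmin`, `vmax` (mmol/gDW/h, plus 36-digit string columns) and status
#'   flags, with attributes `mu_used`, `lp_count`, `warm_start_hits` and
#'   total simplex iterations.
#' @export
vary_me <- function(model, mu_fraction = 1, reactions = NULL,
                    ctx = me_context(), warm = TRUE, fit = NULL,
                    mu_star = NULL) {
  stopifnot(inherits(model, "me_model"),
            mu_fraction > 0, mu_fraction <= 1)
  ctx <- as_me_context(ctx)
  if (is.null(mu_star)) {
    if (is.null(fit)) fit <- solve_me(model, ctx = ctx)
    stopifnot(inherits(fit, "me_nlp"))
    mu_star <- fit$mu_star
  }
  mu_t <- mu_fraction * mu_star
  lp <- fix_mu(model, mu_t, ctx)
  base <- solve_lp(lp, ctx, warm = if (!is.null(fit)) fit$basis else NULL)
  if (base$status != "optimal")
    stop("model infeasible at mu = ", signif(mu_t, 10),
         "; try a smaller mu_fraction", call. = FALSE)
  if (is.null(reactions)) reactions <- model$reaction_ids
  bad <- setdiff(reactions, model$reaction_ids)
  if (length(bad)) stop("unknown reaction '", bad[1], "'", call. = FALSE)
  # keep model column order
  reactions <- model$reaction_ids[model$reaction_ids %in% reactions]
  nR <- length(reactions)
  vmin <- vmax <- numeric(nR)
  vmin_chr <- vmax_chr <- character(nR)
  smin <- smax <- character(nR)
  basis <- base$basis
  iters <- 0
  hits <- 0L
  one <- function(rxn, maximize, basis) {
    lp2 <- lp
    lp2$obj <- rep("0", lp$n)
    lp2$obj[match(rxn, lp$col_names)] <- "1"
    lp2$maximize <- maximize
    solve_lp(lp2, ctx, warm = basis)
  }
  for (k in seq_len(nR)) {
    lo <- one(reactions[k], FALSE, if (warm) basis else NULL)
    iters <- iters + lo$iterations
    if (warm && lo$status == "optimal") { basis <- lo$basis; hits <- hits + 1L }
    hi <- one(reactions[k], TRUE, if (warm) basis else NULL)
    iters <- iters + hi$iterations
    if (warm && hi$status == "optimal") { basis <- hi$basis; hits <- hits + 1L }
    smin[k] <- lo$status; smax[k] <- hi$status
    vmin[k] <- if (lo$status == "unbounded") -Inf else lo$objective
    vmax[k] <- if (hi$status == "unbounded") Inf else hi$objective
    vmin_chr[k] <- lo$objective_chr; vmax_chr[k] <- hi$objective_chr
  }
  out <- data.frame(reaction = reactions, vmin = vmin, vmax = vmax,
                    vmin_chr = vmin_chr, vmax_chr = vmax_chr,
                    status_min = smin, status_max = smax,
                    stringsAsFactors = FALSE)
  structure(out, mu_used = mu_t, mu_fraction = mu_fraction,
            lp_count = 2L * nR, warm_start_hits = hits,
            warm = warm, iterations_total = iters,
            class = c("me_fva", "data.frame"))
}

#' @export
print.me_fva <- function(x, ...) {
  cat(sprintf("Flux variability at mu = %.10g 1/h (%s starts): %d reactions, %d LPs, %g simplex iterations\n",
              attr(x, "mu_used"), if (attr(x, "warm")) "warm" else "cold",
              nrow(x), attr(x, "lp_count"), attr(x, "iterations_total")))
  print.data.frame(head(as.data.frame(x)[c("reaction", "vmin", "vmax")], 10))
  if (nrow(x) > 10) cat("  ...\n")
  invisible(x)
}

#' Gene-knockout essentiality screen at a fixed growth rate
#'
#' For each gene, the bounds of its translation reactions are set to zero
#' and a single feasibility LP is solved at the fixed test growth rate
#' `mu_test`; the gene is essential iff that LP is infeasible.  Bounds are
#' restored after each gene and consecutive LPs are warm-started.  One LP
#' per gene, plus one baseline LP checking that the unperturbed model grows
#' at `mu_test` at all.
#'
#' @param model an [me_model()] whose annotations carry gene tags on
#'   translation reactions.
#' @param genes character vector of gene ids.
#' @param mu_test growth rate at which essentiality is called (a common
#'   choice is half the wild-type optimum).
#' @param ctx an [me_context()].
#' @param warm chain bases between LPs?
#' @return an object of class `me_essentiality`: data frame of per-gene
#'   verdicts (`essential`, `nonessential`, `unknown_gene`, or
#'   `no_growth_baseline`), with `mu_threshold` and `lp_count` attributes.
#' @export
knockout_screen <- function(model, genes, mu_test, ctx = me_context(),
                            warm = TRUE) {
  stopifnot(inherits(model, "me_model"), mu_test >= 0)
  ctx <- as_me_context(ctx)
  genes <- as.character(genes)
  lp <- fix_mu(model, mu_test, ctx)
  base <- solve_lp(lp, ctx)
  baseline_ok <- base$status == "optimal"
  ann <- model$annotations
  verdict <- character(length(genes))
  lp_count <- 0L
  basis <- base$basis
  for (k in seq_along(genes)) {
    rxns <- ann$reaction[ann$category == "translation" &
                           !is.na(ann$gene) & ann$gene == genes[k]]
    if (length(rxns) == 0) {
      verdict[k] <- "unknown_gene"
      next
    }
    if (!baseline_ok) {
      verdict[k] <- "no_growth_baseline"
      next
    }
    lp2 <- lp
    idx <- match(rxns, lp$col_names)
    lp2$lb[idx] <- "0"
    lp2$ub[idx] <- "0"
    sol <- solve_lp(lp2, ctx, warm = if (warm) basis else NULL)
    lp_count <- lp_count + 1L
    verdict[k] <- if (sol$status == "optimal") "nonessential" else "essential"
    if (warm) basis <- sol$basis
  }
  bad <- genes[verdict == "unknown_gene"]
  if (length(bad))
    message("knockout_screen: no translation reaction for gene(s) ",
            paste(bad, collapse = ", "))
  structure(data.frame(gene = genes, verdict = verdict,
                       stringsAsFactors = FALSE),
            mu_threshold = mu_test, lp_count = lp_count,
            baseline_feasible = baseline_ok,
            class = c("me_essentiality", "data.frame"))
}

#' @export
print.me_essentiality <- function(x, ...) {
  tab <- table(x$verdict)
  cat(sprintf("Knockout screen at mu = %.6g 1/h: %d genes, %d LPs\n",
              attr(x, "mu_threshold"), nrow(x), attr(x, "lp_count")))
  cat(" ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Orders of magnitude spanned by a flux vector
#'
#' Per-category accounting of flux magnitudes: fluxes with
#' `|v| <= feas_tol` are floor-filtered out (they are numerically zero at
#' the solver's tolerance), the remaining magnitudes are summarized as
#' integer base-10 exponents (`floor(log10 |v|)`), median and mean, and the
#' global span is `log10(max/min)` over all surviving fluxes.
#'
#' @param v named flux vector (mmol/gDW/h).
#' @param categories named character vector or data frame
#'   (`reaction`, `category`) mapping reactions to biological process
#'   categories.
#' @param ctx an [me_context()]; its `feas_tol` is the filter floor.
#' @return an object of class `me_magnitude`: per-category table plus the
#'   global `span_orders`.
#' @examples
#' flux <- c(a = 9.35e-14, b = 45.4)
#' flux_magnitude_summary(flux, c(a = "transcription", b = "exchange"))
#' @export
flux_magnitude_summary <- function(v, categories, ctx = me_context()) {
  ctx <- as_me_context(ctx)
  if (is.data.frame(categories))
    categories <- setNames(categories$category, categories$reaction)
  if (is.null(names(v))) stop("flux vector must be named", call. = FALSE)
  cat_of <- categories[names(v)]
  keep <- abs(v) > ctx$feas_tol
  av <- abs(v[keep])
  cats <- unique(unname(categories))
  rowify <- function(cc) {
    x <- av[!is.na(cat_of[keep]) & cat_of[keep] == cc]
    if (length(x) == 0)
      return(data.frame(category = cc, n = 0L, min_exp = NA_integer_,
                        max_exp = NA_integer_, median = NA_real_,
                        mean = NA_real_))
    data.frame(category = cc, n = length(x),
               min_exp = as.integer(floor(log10(min(x)))),
               max_exp = as.integer(floor(log10(max(x)))),
               median = median(x), mean = mean(x))
  }
  tab <- do.call(rbind, lapply(cats, rowify))
  span <- if (length(av)) log10(max(av) / min(av)) else NA_real_
  structure(list(table = tab, span_orders = span, floor = ctx$feas_tol,
                 n_filtered = sum(!keep)),
            class = "me_magnitude")
}

#' @export
print.me_magnitude <- function(x, ...) {
  cat(sprintf("Flux magnitudes (floor %g): global span %.1f orders\n",
              x$floor, x$span_orders))
  print(x$table, row.names = FALSE)
  invisible(x)
}
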