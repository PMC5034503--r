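#' Proteome sector mass fractions
#'
#' Sector mass is the sum of translation rate (mmol/gDW/h) times protein
#' molecular weight (g/mol) over the proteins of the sector; fractions are
#' normalized to sum to one.  A zero total mass returns a flagged zero
#' vector rather than NaNs.
#'
#' @param v named flux vector containing every mapped translation reaction.
#' @param sectors data frame with columns `reaction` (translation reaction
#'   id), `sector` and `mw` (g/mol); every translation reaction must be
#'   mapped exactly once.
#' @return named numeric vector of sector mass fractions with attributes
#'   `total_mass` and `zero_mass`.
#' @export
proteome_sector_fractions <- function(v, sectors) {
  sectors <- as.data.frame(sectors, stringsAsFactors = FALSE)
  stopifnot(all(c("reaction", "sector", "mw") %in% names(sectors)))
  if (anyDuplicated(sectors$reaction))
    stop("translation reaction '",
         sectors$reaction[duplicated(sectors$reaction)][1],
         "' mapped to more than one sector", call. = FALSE)
  miss <- setdiff(sectors$reaction, names(v))
  if (length(miss))
    stop("flux vector lacks translation reaction '", miss[1], "'",
         call. = FALSE)
  mass <- tapply(v[sectors$reaction] * sectors$mw, sectors$sector, sum)
  total <- sum(mass)
  if (total <= 0) {
    out <- setNames(rep(0, length(mass)), names(mass))
    return(structure(out, total_mass = 0, zero_mass = TRUE))
  }
  structure(setNames(as.numeric(mass) / total, names(mass)),
            total_mass = total, zero_mass = FALSE)
}

# translation reactions producing the peptides consumed by a
# complex-formation reaction
pathway_translation_reactions <- function(model, cf) {
  j <- match(cf, model$reaction_ids)
  if (is.na(j)) stop("unknown complex-formation reaction '", cf, "'",
                     call. = FALSE)
  consumed <- model$S$i[model$S$j == j & qnum(model$S$x) < 0]
  ann <- model$annotations
  tr <- character(0)
  for (met in consumed) {
    producers <- model$S$j[model$S$i == met & qnum(model$S$x) > 0]
    ids <- model$reaction_ids[producers]
    tr <- c(tr, ids[ids %in% ann$reaction[ann$category == "translation"]])
  }
  unique(tr)
}

# zero the translation bounds of the given genes (the knockout operation)
apply_knockout <- function(model, genes) {
  ann <- model$annotations
  for (g in genes) {
    rxns <- ann$reaction[ann$category == "translation" &
                           !is.na(ann$gene) & ann$gene == g]
    if (length(rxns) == 0)
      stop("no translation reaction annotated for gene '", g, "'",
           call. = FALSE)
    idx <- match(rxns, model$reaction_ids)
    model$v_lower[idx] <- "0"
    model$v_upper[idx] <- "0"
  }
  model
}

#' Growth-coupled overproduction scan over a two-pathway expression grid
#'
#' The three-step case-study protocol for growth-coupled production
#' designs: (1) maximize growth with the knockout applied; (2) run flux
#' variability restricted to the two production-pathway complex-formation
#' reactions at a small fraction (default 0.05) of that maximum to obtain
#' each pathway's maximum expression flux; (3) sweep a grid of lower bounds
#' set to linearly spaced fractions of those maxima (default 11 levels from
#' 0.05 to 0.95, i.e. 121 combinations), re-maximizing growth at each grid
#' point and recording product flux, molar product yield (product exchange
#' flux over absolute substrate uptake), the pathway-1 share of pathway
#' translation flux, and proteome sector mass fractions.
#'
#' @param model wild-type [me_model()].
#' @param knockout_genes genes deleted throughout the scan.
#' @param pathway_1,pathway_2 complex-formation reaction ids of the two
#'   production pathways.
#' @param fractions expression levels as fractions of the maximum
#'   expression flux.
#' @param baseline_fraction growth-rate fraction at which the maximum
#'   expression fluxes are measured.
#' @param product_exchange,substrate_uptake exchange reaction ids used for
#'   the yield.
#' @param sectors optional sector map for [proteome_sector_fractions()].
#' @param ctx an [me_context()].
#' @return an object of class `me_scan`: the grid data frame (one row per
#'   `(f1, f2)` combination, infeasible points flagged) with attributes
#'   `mu_ko`, `vmax_1`, `vmax_2` and `n_infeasible`.
#' @export
expression_grid_scan <- function(model, knockout_genes, pathway_1, pathway_2,
                                 fractions = seq(0.05, 0.95, length.out = 11),
                                 baseline_fraction = 0.05,
                                 product_exchange = NULL,
                                 substrate_uptake = NULL,
                                 sectors = NULL, ctx = me_context()) {
  stopifnot(inherits(model, "me_model"),
            all(fractions >= 0), all(fractions <= 1))
  ctx <- as_me_context(ctx)
  ko <- apply_knockout(model, knockout_genes)
  fit_ko <- solve_me(ko, ctx = ctx)
  mu_ko <- fit_ko$mu_star

  fva <- vary_me(ko, mu_fraction = baseline_fraction,
                 reactions = c(pathway_1, pathway_2), ctx = ctx,
                 fit = fit_ko)
  vmax <- setNames(fva$vmax, fva$reaction)[c(pathway_1, pathway_2)]

  tr1 <- pathway_translation_reactions(model, pathway_1)
  tr2 <- pathway_translation_reactions(model, pathway_2)

  grid <- expand.grid(f1 = fractions, f2 = fractions,
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  mu <- prod_flux <- yield <- ratio1 <- rep(NA_real_, n)
  feasible <- rep(FALSE, n)
  sector_tab <- NULL
  for (k in seq_len(n)) {
    mk <- ko
    i1 <- match(pathway_1, mk$reaction_ids)
    i2 <- match(pathway_2, mk$reaction_ids)
    mk$v_lower[i1] <- qchr(grid$f1[k] * vmax[[pathway_1]])
    mk$v_lower[i2] <- qchr(grid$f2[k] * vmax[[pathway_2]])
    fit <- tryCatch(solve_me(mk, ctx = ctx), error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    feasible[k] <- TRUE
    mu[k] <- fit$mu_star
    vstar <- fit$v_star
    if (!is.null(product_exchange)) prod_flux[k] <- vstar[[product_exchange]]
    if (!is.null(product_exchange) && !is.null(substrate_uptake)) {
      up <- abs(vstar[[substrate_uptake]])
      yield[k] <- if (up > 0) prod_flux[k] / up else NA_real_
    }
    p1 <- sum(vstar[tr1]); p2 <- sum(vstar[tr2])
    ratio1[k] <- if (p1 + p2 > 0) p1 / (p1 + p2) else NA_real_
    if (!is.null(sectors)) {
      fr <- proteome_sector_fractions(vstar, sectors)
      if (is.null(sector_tab))
        sector_tab <- matrix(NA_real_, n, length(fr),
                             dimnames = list(NULL, names(fr)))
      sector_tab[k, names(fr)] <- fr
    }
  }
  out <- cbind(grid,
               data.frame(feasible = feasible, mu = mu,
                          product_flux = prod_flux, yield = yield,
                          pathway1_ratio = ratio1))
  if (!is.null(sector_tab))
    out <- cbind(out, as.data.frame(sector_tab))
  structure(out, mu_ko = mu_ko, vmax_1 = vmax[[pathway_1]],
            vmax_2 = vmax[[pathway_2]], n_infeasible = sum(!feasible),
            pathways = c(pathway_1, pathway_2),
            class = c("me_scan", "data.frame"))
}

#' @export
print.me_scan <- function(x, ...) {
  cat(sprintf("Expression grid scan: %d points (%d infeasible), knockout mu = %.6g 1/h\n",
              nrow(x), attr(x, "n_infeasible"), attr(x, "mu_ko")))
  ok <- x$feasible
  if (any(ok))
    cat(sprintf("  growth %.4g..%.4g, product flux %.4g..%.4g\n",
                min(x$mu[ok]), max(x$mu[ok]),
                min(x$product_flux[ok]), max(x$product_flux[ok])))
  invisible(x)
}
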