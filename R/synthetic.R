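# Desk-scale synthetic ME-like fixtures.  The analytic model has a closed
# form; the coupled-complex and two-pathway models are deterministic; the
# multiscale generator is seeded and emits the seed in the model metadata.

#' Analytically solvable single-enzyme model
#'
#' Four reactions: a bounded substrate uptake (`uptake <= U`) catalyzed by
#' one enzyme, a growth reaction consuming `a_bio` substrate per unit
#' growth rate, and enzyme synthesis/dilution costing `m` substrate per
#' enzyme.  The single enzyme dilution row
#' \eqn{v_{dil} - \mu\, v_{up}/k_{eff} \ge 0} makes the optimum
#' \deqn{\mu^* = U / (a_{bio} + m\,U/k_{eff}),}
#' obtained by eliminating the minimal enzyme expenditure from the
#' substrate balance.  The closed form makes the model the reference
#' oracle for the search and NLP solvers.
#'
#' @param U uptake bound (mmol/gDW/h).
#' @param a_bio substrate per unit growth rate.
#' @param m substrate per unit enzyme synthesis.
#' @param k_eff effective catalytic rate (1/h).
#' @return an [me_model()].
#' @examples
#' m <- make_analytic_model()
#' # closed form: 10 / (10 + 1 * 10 / 100)
#' @export
make_analytic_model <- function(U = 10, a_bio = 10, m = 1, k_eff = 100) {
  for (p in c(U = U, a_bio = a_bio, k_eff = k_eff))
    if (!is.finite(p) || p <= 0)
      stop("U, a_bio and k_eff must be strictly positive", call. = FALSE)
  if (!is.finite(m) || m < 0)
    stop("m must be finite and nonnegative", call. = FALSE)
  rxn <- c("uptake", "growth", "enzyme_synthesis", "enzyme_dilution")
  met <- c("substrate", "enzyme")
  S <- list(i = c(1L, 1L, 1L, 2L, 2L),
            j = c(1L, 2L, 3L, 3L, 4L),
            x = c("1", q_neg(qchr(a_bio)), q_neg(qchr(m)), "1", "-1"))
  dil <- dilution_row(b = c(enzyme_dilution = "1"),
                      c = setNames(q_div("1", qchr(k_eff)), "uptake"),
                      sense = "ge", family = "enzyme",
                      label = "enzyme_capacity")
  ann <- data.frame(
    reaction = rxn,
    category = c("exchange", "metabolic", "translation", "dilution"),
    gene = c(NA, NA, "enz", NA),
    length = c(NA, NA, 300, NA),
    mw = c(NA, NA, 33000, NA),
    complex = c(NA, NA, NA, "enz"),
    trna = NA, stringsAsFactors = FALSE)
  me_model(rxn, met, S,
           v_lower = c(0, 0, 0, 0),
           v_upper = c(qchr(U), "10", "Inf", "Inf"),
           growth_reaction = "growth", dilution_rows = list(dil),
           annotations = ann,
           meta = list(kind = "analytic",
                       U = qchr(U), a_bio = qchr(a_bio), m = qchr(m),
                       k_eff = qchr(k_eff)))
}

#' Two-subunit complex model (coupled translation fluxes)
#'
#' Two translation reactions whose products have a single sink: a 1:1
#' complex-formation reaction whose product drives a catalyzed uptake via
#' an enzyme dilution row.  The mass balances force both translation fluxes
#' to equal the complex-formation flux, so flux variability analysis must
#' return identical ranges for the two subunits at any growth rate — the
#' desk-scale analog of a two-subunit isomerase complex.
#'
#' @return an [me_model()] (deterministic, no randomness).
#' @export
make_coupled_complex_model <- function() {
  rxn <- c("uptake", "growth", "tr_subA", "tr_subB", "complex_formation",
           "complex_dilution")
  met <- c("substrate", "pepA", "pepB", "cplx")
  # substrate: +uptake - 6*growth - 2*trA - 3*trB
  S <- list(i = c(1L, 1L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L),
            j = c(1L, 2L, 3L, 4L, 3L, 5L, 4L, 5L, 5L, 6L),
            x = c("1", "-6", "-2", "-3", "1", "-1", "1", "-1", "1", "-1"))
  dil <- dilution_row(b = c(complex_dilution = "1"),
                      c = c(uptake = "0.01"),
                      sense = "ge", family = "enzyme",
                      label = "complex_capacity")
  ann <- data.frame(
    reaction = rxn,
    category = c("exchange", "metabolic", "translation", "translation",
                 "complex_formation", "dilution"),
    gene = c(NA, NA, "subA", "subB", NA, NA),
    length = c(NA, NA, 300, 310, NA, NA),
    mw = c(NA, NA, 33000, 34100, NA, NA),
    complex = c(NA, NA, NA, NA, "cplxAB", "cplxAB"),
    trna = NA, stringsAsFactors = FALSE)
  me_model(rxn, met, S,
           v_lower = rep(0, 6),
           v_upper = c("10", "10", "Inf", "Inf", "Inf", "Inf"),
           growth_reaction = "growth", dilution_rows = list(dil),
           annotations = ann, meta = list(kind = "coupled_complex"))
}

#' Two-pathway overproduction model
#'
#' A deterministic fixture for the knockout + expression-grid pipeline: a
#' bounded glucose uptake feeds either an efficient respiration reaction
#' (enzyme E0, gene `g0`) yielding two biomass precursors per substrate, or
#' two parallel fermentation pathways (E1/`g1`, E2/`g2`) that each yield
#' one precursor plus one unit of secreted product.  Deleting `g0` forces
#' growth-coupled product secretion; `g1` and `g2` are mutually redundant.
#' Each enzyme is expressed through its own translation, complex-formation
#' and dilution reactions with an enzyme-family dilution row.
#'
#' @return an [me_model()] with meta fields naming the product exchange
#'   (`ex_prod`), substrate uptake (`glc_uptake`), the two pathway
#'   complex-formation reactions, and a default proteome sector map.
#' @export
make_two_pathway_model <- function() {
  rxn <- c("glc_uptake", "resp", "pf1", "pf2", "ex_prod", "growth",
           "tr_p0", "tr_p1", "tr_p2", "cf0", "cf1", "cf2", "d0", "d1", "d2")
  met <- c("m1", "m2", "prod", "pep0", "pep1", "pep2", "E0", "E1", "E2")
  tri <- function(i, j, x) data.frame(i = i, j = j, x = x)
  ix <- function(id) match(id, rxn)
  mx <- function(id) match(id, met)
  rows <- rbind(
    tri(mx("m1"), ix("glc_uptake"), "1"),
    tri(mx("m1"), ix("resp"), "-1"),
    tri(mx("m1"), ix("pf1"), "-1"),
    tri(mx("m1"), ix("pf2"), "-1"),
    tri(mx("m2"), ix("resp"), "2"),
    tri(mx("m2"), ix("pf1"), "1"),
    tri(mx("m2"), ix("pf2"), "1"),
    tri(mx("m2"), ix("growth"), "-12"),
    tri(mx("m2"), ix("tr_p0"), "-2"),
    tri(mx("m2"), ix("tr_p1"), "-2"),
    tri(mx("m2"), ix("tr_p2"), "-2"),
    tri(mx("prod"), ix("pf1"), "1"),
    tri(mx("prod"), ix("pf2"), "1"),
    tri(mx("prod"), ix("ex_prod"), "-1"),
    tri(mx("pep0"), ix("tr_p0"), "1"),
    tri(mx("pep0"), ix("cf0"), "-1"),
    tri(mx("pep1"), ix("tr_p1"), "1"),
    tri(mx("pep1"), ix("cf1"), "-1"),
    tri(mx("pep2"), ix("tr_p2"), "1"),
    tri(mx("pep2"), ix("cf2"), "-1"),
    tri(mx("E0"), ix("cf0"), "1"),
    tri(mx("E0"), ix("d0"), "-1"),
    tri(mx("E1"), ix("cf1"), "1"),
    tri(mx("E1"), ix("d1"), "-1"),
    tri(mx("E2"), ix("cf2"), "1"),
    tri(mx("E2"), ix("d2"), "-1"))
  dil <- list(
    dilution_row(b = c(d0 = "1"), c = c(resp = qchr(1 / 100)),
                 sense = "ge", family = "enzyme", label = "enzyme_E0"),
    dilution_row(b = c(d1 = "1"), c = c(pf1 = qchr(1 / 50)),
                 sense = "ge", family = "enzyme", label = "enzyme_E1"),
    dilution_row(b = c(d2 = "1"), c = c(pf2 = qchr(1 / 25)),
                 sense = "ge", family = "enzyme", label = "enzyme_E2"))
  ann <- data.frame(
    reaction = rxn,
    category = c("exchange", "metabolic", "metabolic", "metabolic",
                 "exchange", "metabolic", "translation", "translation",
                 "translation", "complex_formation", "complex_formation",
                 "complex_formation", "dilution", "dilution", "dilution"),
    gene = c(NA, NA, NA, NA, NA, NA, "g0", "g1", "g2", NA, NA, NA, NA, NA, NA),
    length = c(NA, NA, NA, NA, NA, NA, 400, 350, 360, NA, NA, NA, NA, NA, NA),
    mw = c(NA, NA, NA, NA, NA, NA, 44000, 38500, 39600, NA, NA, NA, NA, NA, NA),
    complex = c(NA, NA, NA, NA, NA, NA, NA, NA, NA,
                "E0", "E1", "E2", "E0", "E1", "E2"),
    trna = NA, stringsAsFactors = FALSE)
  sectors <- data.frame(reaction = c("tr_p0", "tr_p1", "tr_p2"),
                        sector = c("core", "pathway_1", "pathway_2"),
                        mw = c(44000, 38500, 39600),
                        stringsAsFactors = FALSE)
  me_model(rxn, met, list(i = rows$i, j = rows$j, x = rows$x),
           v_lower = rep(0, length(rxn)),
           v_upper = c("10", rep("1000000", 4), "10", rep("1000000", 9)),
           growth_reaction = "growth", dilution_rows = dil,
           annotations = ann,
           meta = list(kind = "two_pathway",
                       product_exchange = "ex_prod",
                       substrate_uptake = "glc_uptake",
                       pathway_1 = "cf1", pathway_2 = "cf2",
                       sectors = sectors))
}

#' Random multiscale ME-like model
#'
#' Generates a model instantiating all four expression-machinery dilution
#' families around a linear metabolic chain: a bounded uptake feeds
#' `n_enzymes` conversion reactions (each catalyzed by its own enzyme,
#' expressed from `n_peptides` peptides through complex formation), with
#' ribosome and RNA-polymerase capacity rows over the translation and
#' transcription reactions, per-tRNA charging rows, and generic
#' mRNA-availability rows coupling transcription to translation.  Effective
#' catalytic rates are log-uniform with pinned extremes over
#' `magnitude_span_orders` orders of magnitude, which makes both the
#' constraint coefficients and the optimal fluxes multiscale.
#'
#' Feasibility is guaranteed by construction: a target growth rate is drawn
#' in (0.3, 1.5), the minimum-uptake flux template at that rate is computed
#' in extended precision, and the uptake bound is set to exactly that
#' requirement, so the optimal growth rate equals the target and the
#' default search bracket `[0, 2]` always applies.
#'
#' @param n_peptides,n_tus,n_trnas,n_enzymes family sizes (all >= 1).
#' @param magnitude_span_orders decadic span of `k_eff` (<= 15).
#' @param seed integer seed; stored in the model metadata so any instance
#'   can be regenerated.
#' @return an [me_model()].
#' @export
make_multiscale_model <- function(n_peptides = 12, n_tus = 6, n_trnas = 4,
                                  n_enzymes = 6, magnitude_span_orders = 12,
                                  seed = 1L) {
  stopifnot(n_peptides >= 1, n_tus >= 1, n_trnas >= 1, n_enzymes >= 1,
            magnitude_span_orders <= 15, magnitude_span_orders >= 0)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)

  l_p <- round(runif(n_peptides, 50, 1500))
  l_tu <- round(runif(n_tus, 0.8, 1.2) * 3 * mean(l_p))
  span <- magnitude_span_orders
  # log-uniform over the requested span with pinned extremes; the base of
  # 10^2 keeps the proteome burden of the least efficient enzyme below the
  # substrate budget at every growth rate in the bracket
  expo <- 2 + (if (n_enzymes == 1) span else
    c(0, span, if (n_enzymes > 2) runif(n_enzymes - 2, 0, span)))
  k_eff <- 10^expo
  c_ribo <- runif(1, 8, 16)
  kappa_tau <- runif(1, 2, 6)
  r0 <- runif(1, 0.1, 0.5)
  c_trna <- setNames(runif(n_trnas, 1e3, 1e5), sprintf("trna%d", seq_len(n_trnas)))
  c_mrna <- setNames(runif(n_tus, 1, 10), sprintf("tu%d", seq_len(n_tus)))
  a_bio <- runif(1, 5, 15)
  mu_target <- runif(1, 0.3, 1.5)
  w_aa <- 0.001; w_nt <- 0.0005; w_mach <- 0.1; w_ch <- 1e-4; w_trna <- 0.1
  beta <- 0.01

  E <- sprintf("E%d", seq_len(n_enzymes))
  pep2enz <- rep(seq_len(n_enzymes), length.out = n_peptides)
  pep2tu <- rep(seq_len(n_tus), length.out = n_peptides)

  rxn <- c("uptake", "growth", sprintf("conv%d", seq_len(n_enzymes)),
           sprintf("tr%d", seq_len(n_peptides)),
           sprintf("cf%d", seq_len(n_enzymes)),
           sprintf("dil%d", seq_len(n_enzymes)),
           sprintf("tx%d", seq_len(n_tus)),
           "rib_syn", "rib_dil", "rnap_syn", "rnap_dil",
           sprintf("ch%d", seq_len(n_trnas)),
           sprintf("trna_syn%d", seq_len(n_trnas)),
           sprintf("trna_dil%d", seq_len(n_trnas)))
  met <- c(sprintf("m%d", 0:n_enzymes),
           sprintf("pep%d", seq_len(n_peptides)), E,
           "ribo", "rnap",
           sprintf("aa%d", seq_len(n_trnas)),
           sprintf("trna%d", seq_len(n_trnas)))
  ix <- function(id) match(id, rxn)
  mx <- function(id) match(id, met)
  ti <- tj <- integer(0); txx <- character(0)
  add <- function(i, j, x) {
    ti <<- c(ti, i); tj <<- c(tj, j); txx <<- c(txx, qchr(x))
  }
  mend <- mx(sprintf("m%d", n_enzymes))
  add(mx("m0"), ix("uptake"), 1)
  for (e in seq_len(n_enzymes)) {
    add(mx(sprintf("m%d", e - 1)), ix(sprintf("conv%d", e)), -1)
    add(mx(sprintf("m%d", e)), ix(sprintf("conv%d", e)), 1)
  }
  add(mend, ix("growth"), -a_bio)
  for (i in seq_len(n_peptides)) {
    tr <- ix(sprintf("tr%d", i))
    add(mend, tr, -l_p[i] * w_aa)
    add(mx(sprintf("pep%d", i)), tr, 1)
    add(mx(sprintf("pep%d", i)), ix(sprintf("cf%d", pep2enz[i])), -1)
    for (j in seq_len(n_trnas))
      add(mx(sprintf("aa%d", j)), tr, -l_p[i] * 0.01 / n_trnas)
  }
  for (e in seq_len(n_enzymes)) {
    add(mx(E[e]), ix(sprintf("cf%d", e)), 1)
    add(mx(E[e]), ix(sprintf("dil%d", e)), -1)
  }
  for (j in seq_len(n_tus))
    add(mend, ix(sprintf("tx%d", j)), -l_tu[j] * w_nt)
  add(mend, ix("rib_syn"), -w_mach)
  add(mx("ribo"), ix("rib_syn"), 1)
  add(mx("ribo"), ix("rib_dil"), -1)
  add(mend, ix("rnap_syn"), -w_mach)
  add(mx("rnap"), ix("rnap_syn"), 1)
  add(mx("rnap"), ix("rnap_dil"), -1)
  for (j in seq_len(n_trnas)) {
    add(mend, ix(sprintf("ch%d", j)), -w_ch)
    add(mx(sprintf("aa%d", j)), ix(sprintf("ch%d", j)), 1)
    add(mend, ix(sprintf("trna_syn%d", j)), -w_trna)
    add(mx(sprintf("trna%d", j)), ix(sprintf("trna_syn%d", j)), 1)
    add(mx(sprintf("trna%d", j)), ix(sprintf("trna_dil%d", j)), -1)
  }

  cat_of <- c("exchange", "metabolic", rep("metabolic", n_enzymes),
              rep("translation", n_peptides),
              rep("complex_formation", n_enzymes),
              rep("dilution", n_enzymes),
              rep("transcription", n_tus),
              "complex_formation", "dilution", "complex_formation", "dilution",
              rep("charging", n_trnas),
              rep("metabolic", n_trnas), rep("dilution", n_trnas))
  ann <- data.frame(reaction = rxn, category = cat_of,
                    gene = NA_character_, length = NA_real_, mw = NA_real_,
                    complex = NA_character_, trna = NA_character_,
                    stringsAsFactors = FALSE)
  tr_idx <- match(sprintf("tr%d", seq_len(n_peptides)), rxn)
  ann$gene[tr_idx] <- sprintf("g%d", seq_len(n_peptides))
  ann$length[tr_idx] <- l_p
  ann$mw[tr_idx] <- l_p * 110
  tx_idx <- match(sprintf("tx%d", seq_len(n_tus)), rxn)
  ann$length[tx_idx] <- l_tu
  ann$complex[match(sprintf("cf%d", seq_len(n_enzymes)), rxn)] <- E
  ann$complex[match(sprintf("dil%d", seq_len(n_enzymes)), rxn)] <- E
  ann$complex[ix("rib_syn")] <- "ribosome"
  ann$complex[ix("rib_dil")] <- "ribosome"
  ann$complex[ix("rnap_syn")] <- "rnap"
  ann$complex[ix("rnap_dil")] <- "rnap"
  ann$trna[match(sprintf("ch%d", seq_len(n_trnas)), rxn)] <-
    sprintf("trna%d", seq_len(n_trnas))
  ann$trna[match(sprintf("trna_dil%d", seq_len(n_trnas)), rxn)] <-
    sprintf("trna%d", seq_len(n_trnas))

  constants <- me_constants(
    c_ribo = c_ribo, kappa_tau = kappa_tau, r0 = r0,
    k_eff = data.frame(enzyme = E,
                       usage = sprintf("conv%d", seq_len(n_enzymes)),
                       k_eff = qchr(k_eff), stringsAsFactors = FALSE),
    c_trna = c_trna, c_mrna = c_mrna)

  model <- me_model(rxn, met, list(i = ti, j = tj, x = txx),
                    v_lower = rep(0, length(rxn)),
                    v_upper = c("Inf", "10", rep("1000000", length(rxn) - 2)),
                    growth_reaction = "growth",
                    annotations = ann,
                    meta = list())
  rows <- build_dilution_rows(model, constants)
  # mRNA availability: transcription of each unit must keep pace with
  # growth-diluted translation of its peptides (generic family)
  for (j in seq_len(n_tus)) {
    members <- sprintf("tr%d", which(pep2tu == j))
    if (length(members) == 0) next
    rows <- c(rows, list(dilution_row(
      b = setNames("1", sprintf("tx%d", j)),
      c = setNames(rep(qchr(beta), length(members)), members),
      sense = "ge", family = "generic",
      label = sprintf("mrna_coupling_tu%d", j))))
  }
  model$dilution_rows <- rows

  # uptake requirement at the target growth rate fixes the bound exactly
  lp <- fix_mu(model, mu_target)
  lp$obj <- rep("0", lp$n)
  lp$obj[match("uptake", lp$col_names)] <- "1"
  lp$maximize <- FALSE
  sol <- solve_lp(lp, me_context())
  if (sol$status != "optimal")
    stop("internal error: multiscale template infeasible (seed ", seed, ")",
         call. = FALSE)
  model$v_upper[match("uptake", model$reaction_ids)] <- sol$objective_chr
  model$meta <- list(kind = "multiscale", seed = seed,
                     mu_target = qchr(mu_target),
                     magnitude_span_orders = magnitude_span_orders,
                     n_peptides = n_peptides, n_tus = n_tus,
                     n_trnas = n_trnas, n_enzymes = n_enzymes,
                     constants = list(c_ribo = qchr(c_ribo),
                                      kappa_tau = qchr(kappa_tau),
                                      r0 = qchr(r0),
                                      k_eff = qchr(k_eff),
                                      c_trna = as.list(qchr(c_trna)),
                                      c_mrna = as.list(qchr(c_mrna))))
  model
}
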