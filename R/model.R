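me_categories <- c("metabolic", "transcription", "translation",
                   "complex_formation", "enzyme_usage", "charging",
                   "dilution", "exchange")

#' Construct a metabolism-and-expression model
#'
#' The central model container: a stoichiometric core `S v = 0` with flux
#' bounds, plus bilinear dilution rows of the form
#' \eqn{b^T v - \mu\, c^T v \{=,\ge\} 0} that couple macromolecule synthesis
#' to dilution by growth.  An optional growth reaction carries the growth
#' rate \eqn{\mu} (1/h) as its flux.  All coefficients are stored as exact
#' decimal strings; fluxes are in mmol/gDW/h.
#'
#' @param reaction_ids,metabolite_ids unique identifiers.
#' @param S stoichiometric matrix: dense base matrix
#'   (metabolites x reactions) or triplet list `list(i, j, x)`.
#' @param v_lower,v_upper per-reaction flux bounds.
#' @param growth_reaction id of the reaction whose flux equals the growth
#'   rate, or `NULL` when the growth rate only enters through dilution rows.
#' @param dilution_rows list of [dilution_row()] objects.
#' @param annotations data frame with columns `reaction`, `category` (one of
#'   metabolic, transcription, translation, complex_formation, enzyme_usage,
#'   charging, dilution, exchange) and optional `gene`, `length` (peptide
#'   length in amino acids for translation reactions, transcription-unit
#'   length in nucleotides for transcription reactions), `mw` (protein
#'   molecular weight, g/mol), `complex` (enzyme/complex tag for usage,
#'   complex-formation and dilution reactions) and `trna` (tRNA tag for
#'   charging and tRNA-dilution reactions).
#' @param meta free-form metadata list (kept in the JSON serialization).
#' @return an object of class `me_model`.
#' @seealso [make_analytic_model()], [make_multiscale_model()], [fix_mu()]
#' @export
me_model <- function(reaction_ids, metabolite_ids, S, v_lower, v_upper,
                     growth_reaction = NULL, dilution_rows = list(),
                     annotations = NULL, meta = list()) {
  reaction_ids <- as.character(reaction_ids)
  metabolite_ids <- as.character(metabolite_ids)
  if (anyDuplicated(reaction_ids))
    stop("duplicate reaction id: ",
         reaction_ids[duplicated(reaction_ids)][1], call. = FALSE)
  if (anyDuplicated(metabolite_ids))
    stop("duplicate metabolite id: ",
         metabolite_ids[duplicated(metabolite_ids)][1], call. = FALSE)
  n <- length(reaction_ids)
  if (is.matrix(S)) {
    nz <- which(S != 0, arr.ind = TRUE)
    S <- list(i = as.integer(nz[, 1]), j = as.integer(nz[, 2]), x = qchr(S[nz]))
  }
  S$i <- as.integer(S$i); S$j <- as.integer(S$j); S$x <- qchr(S$x)
  if (length(S$i) && (max(S$i) > length(metabolite_ids) || max(S$j) > n ||
                      min(S$i) < 1 || min(S$j) < 1))
    stop("stoichiometric triplet index out of range", call. = FALSE)
  if (length(v_lower) != n || length(v_upper) != n)
    stop("bounds must have one entry per reaction (got ",
         length(v_lower), "/", length(v_upper), ", need ", n, ")", call. = FALSE)
  v_lower <- qchr(v_lower); v_upper <- qchr(v_upper)
  if (any(qnum(v_lower) > qnum(v_upper)))
    stop("v_lower exceeds v_upper for reaction ",
         reaction_ids[which(qnum(v_lower) > qnum(v_upper))[1]], call. = FALSE)
  if (!is.null(growth_reaction)) {
    if (!growth_reaction %in% reaction_ids)
      stop("growth reaction '", growth_reaction, "' not in model", call. = FALSE)
    g <- match(growth_reaction, reaction_ids)
    if (qnum(v_lower[g]) < 0)
      stop("growth reaction must have a nonnegative lower bound", call. = FALSE)
  }
  for (k in seq_along(dilution_rows)) {
    dr <- dilution_rows[[k]]
    if (!inherits(dr, "me_dilution_row"))
      stop("dilution_rows[[", k, "]] is not a dilution_row", call. = FALSE)
    bad <- setdiff(c(names(dr$b), names(dr$c)), reaction_ids)
    if (length(bad))
      stop("dilution row '", dr$label, "' references unknown reaction '",
           bad[1], "'", call. = FALSE)
  }
  if (is.null(annotations))
    annotations <- data.frame(reaction = reaction_ids,
                              category = "metabolic",
                              stringsAsFactors = FALSE)
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  for (col in c("gene", "length", "mw", "complex", "trna"))
    if (is.null(annotations[[col]])) annotations[[col]] <- NA
  for (col in c("gene", "complex", "trna"))
    annotations[[col]] <- as.character(annotations[[col]])
  for (col in c("length", "mw"))
    annotations[[col]] <- as.numeric(annotations[[col]])
  annotations$reaction <- as.character(annotations$reaction)
  annotations$category <- as.character(annotations$category)
  bad <- setdiff(annotations$reaction, reaction_ids)
  if (length(bad))
    stop("annotation references unknown reaction '", bad[1], "'", call. = FALSE)
  bad <- setdiff(annotations$category, me_categories)
  if (length(bad))
    stop("unknown annotation category '", bad[1], "'", call. = FALSE)
  labs <- vapply(dilution_rows, function(d) d$label, character(1))
  if (anyDuplicated(labs))
    stop("duplicate dilution row label '", labs[duplicated(labs)][1], "'",
         call. = FALSE)
  structure(list(reaction_ids = reaction_ids,
                 metabolite_ids = metabolite_ids, S = S,
                 v_lower = v_lower, v_upper = v_upper,
                 growth_reaction = growth_reaction,
                 dilution_rows = dilution_rows,
                 annotations = annotations, meta = meta),
            class = "me_model")
}

#' @export
print.me_model <- function(x, ...) {
  cat(sprintf("ME model: %d reactions, %d metabolites, %d dilution rows\n",
              length(x$reaction_ids), length(x$metabolite_ids),
              length(x$dilution_rows)))
  if (!is.null(x$growth_reaction))
    cat(sprintf("  growth reaction: %s\n", x$growth_reaction))
  fam <- table(vapply(x$dilution_rows, function(d) d$family, character(1)))
  if (length(fam))
    cat("  dilution families:",
        paste(sprintf("%s (%d)", names(fam), fam), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.me_model <- function(object, ...) {
  cat2 <- table(object$annotations$category)
  print(object)
  cat("  reaction categories:\n")
  for (nm in names(cat2)) cat(sprintf("    %-18s %d\n", nm, cat2[[nm]]))
  mags <- abs(qnum(object$S$x))
  mags <- mags[mags > 0]
  for (d in object$dilution_rows) {
    v <- abs(qnum(c(d$b, d$c)))
    mags <- c(mags, v[v > 0])
  }
  if (length(mags))
    cat(sprintf("  coefficient magnitudes span %.1f orders (%.3g .. %.3g)\n",
                log10(max(mags) / min(mags)), min(mags), max(mags)))
  invisible(object)
}

#' Construct a bilinear dilution row
#'
#' One coupling constraint \eqn{b^T v - \mu\, c^T v \{=,\ge\} 0}.  `b` holds
#' the dimensionless part, `c` the coefficients multiplying the growth rate
#' (units of h, so that \eqn{\mu c^T v} has flux units).
#'
#' @param b,c named coefficient vectors over reaction ids (numeric or
#'   decimal strings).  Not both may be empty/zero.
#' @param sense `"ge"` (the model statement) or `"eq"`.
#' @param family one of `"ribosome"`, `"rnap"`, `"trna"`, `"enzyme"`,
#'   `"generic"`.
#' @param label row identifier.
#' @export
dilution_row <- function(b, c, sense = c("ge", "eq"),
                         family = c("generic", "ribosome", "rnap", "trna",
                                    "enzyme"),
                         label = "dilution") {
  sense <- match.arg(sense)
  family <- match.arg(family)
  b <- if (length(b)) setNames(qchr(b), names(b)) else setNames(character(0), character(0))
  c <- if (length(c)) setNames(qchr(c), names(c)) else setNames(character(0), character(0))
  if ((length(b) == 0 || all(q_is_zero(b))) &&
      (length(c) == 0 || all(q_is_zero(c))))
    stop("dilution row '", label, "': b and c are both zero", call. = FALSE)
  if (is.null(names(b)) && length(b) || is.null(names(c)) && length(c))
    stop("b and c must be named by reaction id", call. = FALSE)
  structure(list(b = b, c = c, sense = sense, family = family,
                 label = as.character(label)),
            class = "me_dilution_row")
}

#' Expression-machinery constants
#'
#' The rate and capacity constants of the four dilution-constraint families:
#' the ribosome catalytic constant `c_ribo` (aa per ribosome per time), the
#' coupling constants `kappa_tau` and `r0`, effective catalytic rates
#' `k_eff` (1/h) linking enzyme dilution to the metabolic flux each enzyme
#' carries, and per-tRNA charging capacities `c_trna`.  `c_mrna` is carried
#' for completeness but no displayed constraint family consumes it.
#'
#' @param c_ribo,kappa_tau,r0 strictly positive scalars.
#' @param k_eff data frame with columns `enzyme`, `usage`, `k_eff`: one row
#'   per (enzyme, usage-reaction) pair.
#' @param c_trna named vector (names = tRNA tags), strictly positive.
#' @param c_mrna optional named vector, strictly positive.
#' @export
me_constants <- function(c_ribo, kappa_tau, r0,
                         k_eff = NULL, c_trna = NULL, c_mrna = NULL) {
  for (v in list(c_ribo = c_ribo, kappa_tau = kappa_tau, r0 = r0)) {
    if (!is.finite(qnum(qchr(v))) || qnum(qchr(v)) <= 0)
      stop("expression constants must be strictly positive", call. = FALSE)
  }
  if (!is.null(k_eff)) {
    k_eff <- as.data.frame(k_eff, stringsAsFactors = FALSE)
    stopifnot(all(c("enzyme", "usage", "k_eff") %in% names(k_eff)))
    if (any(qnum(qchr(k_eff$k_eff)) <= 0))
      stop("k_eff values must be strictly positive", call. = FALSE)
  }
  for (v in list(c_trna, c_mrna))
    if (!is.null(v) && any(qnum(qchr(v)) <= 0))
      stop("tRNA/mRNA constants must be strictly positive", call. = FALSE)
  structure(list(c_ribo = qchr(c_ribo), kappa_tau = qchr(kappa_tau),
                 r0 = qchr(r0), k_eff = k_eff,
                 c_trna = if (is.null(c_trna)) NULL else setNames(qchr(c_trna), names(c_trna)),
                 c_mrna = if (is.null(c_mrna)) NULL else setNames(qchr(c_mrna), names(c_mrna))),
            class = "me_constants")
}

# find reactions of a category, optionally filtered by a tag column
ann_filter <- function(model, category, col = NULL, value = NULL) {
  a <- model$annotations
  keep <- a$category == category
  if (!is.null(col)) keep <- keep & !is.na(a[[col]]) & a[[col]] == value
  a[keep, , drop = FALSE]
}

#' Build the four dilution-constraint families from annotations
#'
#' Expands the machinery constraints into explicit rows.  With the coupling
#' factor \eqn{(\mu + r_0 \kappa_\tau)} multiplied out, the families are:
#' \describe{
#'   \item{ribosome}{\eqn{v_{dil,ribo} \ge \sum_i \frac{l_{p,i}}{c_{ribo}\kappa_\tau}(\mu + r_0\kappa_\tau)\, v_{tr,i}}:
#'     b gets \eqn{-l_{p,i} r_0 / c_{ribo}} on each translation reaction and
#'     +1 on the ribosome dilution reaction; c gets
#'     \eqn{l_{p,i}/(c_{ribo}\kappa_\tau)}.}
#'   \item{rnap}{same with \eqn{l_{TU,i}/3} in place of \eqn{l_{p,i}} over
#'     transcription reactions (3 nucleotides per codon).}
#'   \item{trna}{per tRNA j: b gets \eqn{-r_0/c_{tRNA,j}} on the charging
#'     reaction and +1 on that tRNA's dilution reaction; c gets
#'     \eqn{1/(\kappa_\tau c_{tRNA,j})}.}
#'   \item{enzyme}{per enzyme j: b is +1 on the enzyme dilution reaction
#'     only; c gets \eqn{1/k^{eff}_{ij}} on each usage reaction.}
#' }
#' Coefficient arithmetic is performed in extended precision.
#'
#' @param model an [me_model()] whose annotations tag the translation,
#'   transcription, charging, usage and dilution reactions.
#' @param constants an [me_constants()] object.
#' @param sense sense given to the created rows (default `"ge"`).
#' @return list of [dilution_row()] objects (possibly empty).
#' @export
build_dilution_rows <- function(model, constants, sense = "ge") {
  stopifnot(inherits(model, "me_model"), inherits(constants, "me_constants"))
  rows <- list()
  need <- function(df, what) {
    if (nrow(df) != 1)
      stop("expected exactly one ", what, " reaction, found ", nrow(df),
           call. = FALSE)
    df$reaction
  }
  kt <- constants$kappa_tau; r0 <- constants$r0; cr <- constants$c_ribo

  tr <- ann_filter(model, "translation")
  if (nrow(tr)) {
    if (any(is.na(tr$length)))
      stop("translation reaction '", tr$reaction[is.na(tr$length)][1],
           "' lacks a peptide length", call. = FALSE)
    dil <- need(ann_filter(model, "dilution", "complex", "ribosome"),
                "ribosome dilution")
    lp <- qchr(tr$length)
    b <- c(setNames("1", dil), setNames(q_neg(q_div(q_mul(lp, r0), cr)), tr$reaction))
    cc <- setNames(q_div(lp, q_mul(cr, kt)), tr$reaction)
    rows <- c(rows, list(dilution_row(b, cc, sense, "ribosome", "ribosome_capacity")))
  }

  tx <- ann_filter(model, "transcription")
  if (nrow(tx)) {
    if (any(is.na(tx$length)))
      stop("transcription reaction '", tx$reaction[is.na(tx$length)][1],
           "' lacks a transcription-unit length", call. = FALSE)
    dil <- need(ann_filter(model, "dilution", "complex", "rnap"),
                "RNA-polymerase dilution")
    l3 <- q_div(qchr(tx$length), "3")
    b <- c(setNames("1", dil), setNames(q_neg(q_div(q_mul(l3, r0), cr)), tx$reaction))
    cc <- setNames(q_div(l3, q_mul(cr, kt)), tx$reaction)
    rows <- c(rows, list(dilution_row(b, cc, sense, "rnap", "rnap_capacity")))
  }

  if (!is.null(constants$c_trna)) {
    for (j in names(constants$c_trna)) {
      ch <- ann_filter(model, "charging", "trna", j)
      if (nrow(ch) == 0) next
      dil <- need(ann_filter(model, "dilution", "trna", j),
                  paste0("tRNA '", j, "' dilution"))
      ct <- constants$c_trna[[j]]
      b <- c(setNames("1", dil),
             setNames(rep(q_neg(q_div(r0, ct)), nrow(ch)), ch$reaction))
      cc <- setNames(rep(q_div("1", q_mul(kt, ct)), nrow(ch)), ch$reaction)
      rows <- c(rows, list(dilution_row(b, cc, sense, "trna",
                                        paste0("trna_", j, "_charging"))))
    }
  }

  if (!is.null(constants$k_eff) && nrow(constants$k_eff)) {
    for (enz in unique(constants$k_eff$enzyme)) {
      tab <- constants$k_eff[constants$k_eff$enzyme == enz, , drop = FALSE]
      dil <- need(ann_filter(model, "dilution", "complex", enz),
                  paste0("enzyme '", enz, "' dilution"))
      bad <- setdiff(tab$usage, model$reaction_ids)
      if (length(bad))
        stop("enzyme row '", enz, "' references unknown usage reaction '",
             bad[1], "'", call. = FALSE)
      b <- setNames("1", dil)
      cc <- setNames(q_div("1", qchr(tab$k_eff)), tab$usage)
      rows <- c(rows, list(dilution_row(b, cc, sense, "enzyme",
                                        paste0("enzyme_", enz, "_dilution"))))
    }
  }
  rows
}

#' Assemble the generalized bilinear form
#'
#' Stacks the dilution rows into sparse matrices `Bmat` and `Cmat` (rows =
#' dilution constraints, columns = reactions, identical shape) so that row
#' \eqn{i} reads \eqn{b_i^T v - \mu\, c_i^T v \{=,\ge\} 0}, alongside the
#' stoichiometric matrix and bounds.
#'
#' @param model an [me_model()].
#' @return an object of class `me_general_form` with triplet matrices `S`,
#'   `Bmat`, `Cmat`, the per-row `senses`, labels, and bounds.
#' @export
assemble_general_form <- function(model) {
  stopifnot(inherits(model, "me_model"))
  nd <- length(model$dilution_rows)
  bi <- bj <- ci <- cj <- integer(0)
  bx <- cx <- character(0)
  for (k in seq_len(nd)) {
    d <- model$dilution_rows[[k]]
    jb <- match(names(d$b), model$reaction_ids)
    jc <- match(names(d$c), model$reaction_ids)
    bi <- c(bi, rep(k, length(jb))); bj <- c(bj, jb); bx <- c(bx, unname(d$b))
    ci <- c(ci, rep(k, length(jc))); cj <- c(cj, jc); cx <- c(cx, unname(d$c))
  }
  structure(list(
    n_rows = nd, n_reactions = length(model$reaction_ids),
    S = model$S,
    Bmat = list(i = bi, j = bj, x = bx),
    Cmat = list(i = ci, j = cj, x = cx),
    senses = vapply(model$dilution_rows, function(d) d$sense, character(1)),
    labels = vapply(model$dilution_rows, function(d) d$label, character(1)),
    v_lower = model$v_lower, v_upper = model$v_upper,
    reaction_ids = model$reaction_ids), class = "me_general_form")
}

#' Reduce the model to a linear program at fixed growth rate
#'
#' At fixed \eqn{\mu} every dilution row becomes the linear row
#' \eqn{(b_i - \mu c_i)^T v \{=,\ge\} 0}; the substitution is carried out in
#' extended precision.  When a growth reaction exists, its flux is pinned to
#' \eqn{\mu} through an explicit equality row (so that a \eqn{\mu} beyond
#' the declared growth bound is correctly infeasible) and the objective
#' maximizes the growth flux; otherwise the objective is zero (pure
#' feasibility).
#'
#' @param model an [me_model()].
#' @param mu growth rate (1/h), finite and nonnegative; numeric or decimal
#'   string.
#' @param ctx arithmetic context (kept for interface symmetry; the
#'   substitution itself is always performed in extended precision).
#' @return an [me_lp()].
#' @export
fix_mu <- function(model, mu, ctx = me_context()) {
  stopifnot(inherits(model, "me_model"))
  mu_chr <- qchr(mu)[1]
  mu_num <- qnum(mu_chr)
  if (!is.finite(mu_num) || mu_num < 0)
    stop("mu must be finite and nonnegative (got ", mu_chr, ")", call. = FALSE)
  n <- length(model$reaction_ids)
  nmet <- length(model$metabolite_ids)
  ai <- model$S$i; aj <- model$S$j; ax <- model$S$x
  sense <- rep("E", nmet)
  rhs <- rep("0", nmet)
  row_names <- model$metabolite_ids
  r <- nmet
  for (d in model$dilution_rows) {
    r <- r + 1L
    u <- union(names(d$b), names(d$c))
    bv <- setNames(rep("0", length(u)), u); bv[names(d$b)] <- d$b
    cv <- setNames(rep("0", length(u)), u); cv[names(d$c)] <- d$c
    coef <- .q_axmy(bv, cv, mu_chr)
    keep <- .q_cmp(coef, "0") != 0L
    ai <- c(ai, rep(r, sum(keep)))
    aj <- c(aj, match(u[keep], model$reaction_ids))
    ax <- c(ax, coef[keep])
    sense <- c(sense, if (d$sense == "eq") "E" else "G")
    rhs <- c(rhs, "0")
    row_names <- c(row_names, d$label)
  }
  obj <- rep("0", n)
  if (!is.null(model$growth_reaction)) {
    g <- match(model$growth_reaction, model$reaction_ids)
    obj[g] <- "1"
    r <- r + 1L
    ai <- c(ai, r); aj <- c(aj, g); ax <- c(ax, "1")
    sense <- c(sense, "E"); rhs <- c(rhs, mu_chr)
    row_names <- c(row_names, "growth_fix")
  }
  me_lp(obj = obj, A = list(i = ai, j = aj, x = ax), sense = sense, rhs = rhs,
        lb = model$v_lower, ub = model$v_upper, maximize = TRUE,
        col_names = model$reaction_ids, row_names = row_names)
}

#' Dilution-row residuals at a candidate point
#'
#' Evaluates \eqn{b_i^T v - \mu\, c_i^T v} for every dilution row in
#' extended precision.  For `ge` rows a nonnegative residual means the row
#' is satisfied; for `eq` rows the residual itself should vanish.
#'
#' @param model an [me_model()].
#' @param mu growth rate.
#' @param v flux vector (length = number of reactions), numeric or decimal
#'   strings; may be named by reaction id.
#' @param ctx arithmetic context providing the satisfaction tolerance.
#' @return data frame with label, family, sense, the residual (double and
#'   36-digit string) and a satisfaction flag.
#' @export
mu_level_set_residual <- function(model, mu, v, ctx = me_context()) {
  stopifnot(inherits(model, "me_model"))
  ctx <- as_me_context(ctx)
  n <- length(model$reaction_ids)
  if (length(v) != n)
    stop("flux vector has length ", length(v), ", expected ", n, call. = FALSE)
  if (!is.null(names(v))) v <- v[model$reaction_ids]
  vchr <- qchr(v)
  mu_chr <- qchr(mu)[1]
  gf <- assemble_general_form(model)
  nd <- gf$n_rows
  if (nd == 0)
    return(data.frame(label = character(0), family = character(0),
                      sense = character(0), residual = numeric(0),
                      residual_chr = character(0), satisfied = logical(0)))
  bsum <- .q_row_sums(gf$Bmat$i, gf$Bmat$j, gf$Bmat$x, vchr, nd)
  csum <- .q_row_sums(gf$Cmat$i, gf$Cmat$j, gf$Cmat$x, vchr, nd)
  res <- .q_axmy(bsum, csum, mu_chr)
  fam <- vapply(model$dilution_rows, function(d) d$family, character(1))
  sat <- ifelse(gf$senses == "ge",
                qnum(res) >= -ctx$feas_tol,
                abs(qnum(res)) <= ctx$feas_tol)
  data.frame(label = gf$labels, family = fam, sense = gf$senses,
             residual = qnum(res), residual_chr = res, satisfied = sat,
             stringsAsFactors = FALSE)
}
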