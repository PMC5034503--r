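#' Write a linear program in MPS format
#'
#' Writes the standard ROWS/COLUMNS/RHS/BOUNDS sections with free-form
#' numeric fields carrying the full stored decimal precision, plus an
#' OBJSENSE section recording the optimization direction.  The export is
#' meant for cross-validation of fixed-growth-rate subproblems with external
#' solvers.  Duplicate row/column names are renamed deterministically (a
#' `#k` suffix) with a message.
#'
#' @param lp an [me_lp()].
#' @param path output file path.
#' @param name problem name stamped in the NAME record.
#' @return `path`, invisibly.
#' @export
write_mps <- function(lp, path, name = "MEMAX") {
  stopifnot(inherits(lp, "me_lp"))
  cn <- lp$col_names
  rn <- lp$row_names
  fix <- function(x, what) {
    bad <- duplicated(x)
    if (any(bad)) {
      message(sprintf("write_mps: renamed %d duplicate %s name(s)",
                      sum(bad), what))
      x <- make.unique(x, sep = "#")
    }
    gsub("[[:space:]]", "_", x)
  }
  cn <- fix(cn, "column")
  rn <- fix(rn, "row")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("NAME          %s", name)
  w("OBJSENSE")
  w("    %s", if (lp$maximize) "MAX" else "MIN")
  w("ROWS")
  w(" N  OBJ")
  for (i in seq_len(lp$m)) w(" %s  %s", lp$sense[i], rn[i])
  w("COLUMNS")
  obj_nz <- which(!vapply(lp$obj, q_is_zero, logical(1)))
  by_col <- split(seq_along(lp$A$i), lp$A$j)
  for (j in seq_len(lp$n)) {
    if (j %in% obj_nz) w("    %-10s OBJ       %s", cn[j], lp$obj[j])
    for (t in by_col[[as.character(j)]]) {
      w("    %-10s %-9s %s", cn[j], rn[lp$A$i[t]], lp$A$x[t])
    }
  }
  w("RHS")
  for (i in seq_len(lp$m)) {
    if (!q_is_zero(lp$rhs[i])) w("    RHS        %-9s %s", rn[i], lp$rhs[i])
  }
  w("BOUNDS")
  lbn <- qnum(lp$lb); ubn <- qnum(lp$ub)
  for (j in seq_len(lp$n)) {
    if (lbn[j] == ubn[j]) {
      w(" FX BND        %-9s %s", cn[j], lp$lb[j])
      next
    }
    if (is.infinite(lbn[j]) && is.infinite(ubn[j])) {
      w(" FR BND        %s", cn[j])
      next
    }
    if (is.infinite(lbn[j])) w(" MI BND        %s", cn[j])
    else if (lbn[j] != 0) w(" LO BND        %-9s %s", cn[j], lp$lb[j])
    if (is.infinite(ubn[j])) {
      if (!is.infinite(lbn[j])) w(" PL BND        %s", cn[j])
    } else {
      w(" UP BND        %-9s %s", cn[j], lp$ub[j])
    }
  }
  w("ENDATA")
  invisible(path)
}
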