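# Internal helpers around the binary128 string arithmetic in src/.
# Coefficients live as decimal strings ("q-strings") end to end; doubles are
# convenience mirrors only.

#' Convert numbers to exact decimal strings
#'
#' Numeric input is rendered with 17 significant digits (lossless for
#' doubles); character input is passed through untouched so that strings such
#' as `"1e-15"` keep their full meaning in the extended-precision core.
#' @param x numeric or character vector
#' @return character vector
#' @keywords internal
#' @noRd
qchr <- function(x) {
  if (is.character(x)) return(x)
  vapply(as.numeric(x), function(v) {
    if (is.na(v)) stop("NA is not a valid coefficient", call. = FALSE)
    sprintf("%.17g", v)
  }, character(1))
}

# double mirror of q-strings
qnum <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  .q_double(x)
}

q_add <- function(a, b) .q_op("+", qchr(a), qchr(b))
q_sub <- function(a, b) .q_op("-", qchr(a), qchr(b))
q_mul <- function(a, b) .q_op("*", qchr(a), qchr(b))
q_div <- function(a, b) .q_op("/", qchr(a), qchr(b))
q_neg <- function(a) .q_op("-", "0", qchr(a))

# is the q-string exactly zero?
q_is_zero <- function(a) .q_cmp(qchr(a), "0") == 0L
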