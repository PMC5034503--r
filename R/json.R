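ME_MODEL_FORMAT <- "memax-model"
ME_MODEL_VERSION <- 1L

#' Read and write ME models as JSON
#'
#' Versioned, lossless serialization of an [me_model()].  Every coefficient
#' is written as a decimal string, never as a JSON number, so round-trips
#' preserve extended-precision values exactly (a double round-trip would
#' truncate them to 53 bits).  The schema has fixed field names:
#' `format`, `version`, `metabolites`, `reactions` (with `id`, `lb`, `ub`
#' and annotation fields), `growth_reaction`, `S` as a triplet list, and
#' `dilution_rows` with `b`/`c` coefficient maps, `sense` and `family`.
#'
#' @param model an [me_model()].
#' @param path file path.
#' @return `read_me_model()` returns the validated model;
#'   `write_me_model()` returns `path` invisibly.
#' @export
write_me_model <- function(model, path) {
  stopifnot(inherits(model, "me_model"))
  a <- model$annotations
  a <- a[match(model$reaction_ids, a$reaction), , drop = FALSE]
  reactions <- lapply(seq_along(model$reaction_ids), function(j) {
    r <- list(id = model$reaction_ids[j],
              lb = model$v_lower[j], ub = model$v_upper[j],
              category = a$category[j])
    for (col in c("gene", "complex", "trna"))
      if (!is.na(a[[col]][j])) r[[col]] <- a[[col]][j]
    for (col in c("length", "mw"))
      if (!is.na(a[[col]][j])) r[[col]] <- as.numeric(a[[col]][j])
    r
  })
  dil <- lapply(model$dilution_rows, function(d)
    list(label = d$label, family = d$family, sense = d$sense,
         b = as.list(d$b), c = as.list(d$c)))
  obj <- list(format = ME_MODEL_FORMAT, version = ME_MODEL_VERSION,
              metabolites = model$metabolite_ids,
              growth_reaction = model$growth_reaction,
              reactions = reactions,
              S = list(i = model$S$i, j = model$S$j, x = model$S$x),
              dilution_rows = dil,
              meta = model$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_me_model
#' @export
read_me_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, ME_MODEL_FORMAT))
    stop("not a ", ME_MODEL_FORMAT, " file (key 'format')", call. = FALSE)
  if (!identical(as.integer(obj$version), ME_MODEL_VERSION))
    stop("unsupported model schema version (key 'version'): ",
         obj$version, call. = FALSE)
  for (key in c("metabolites", "reactions", "S"))
    if (is.null(obj[[key]])) stop("missing key '", key, "'", call. = FALSE)
  rx <- obj$reactions
  get_chr <- function(r, key) {
    if (is.null(r[[key]])) stop("reaction '", r$id %||% "?",
                                "' missing key '", key, "'", call. = FALSE)
    as.character(r[[key]])
  }
  ids <- vapply(rx, get_chr, character(1), key = "id")
  lb <- vapply(rx, get_chr, character(1), key = "lb")
  ub <- vapply(rx, get_chr, character(1), key = "ub")
  pick <- function(key, as = as.character) {
    num <- identical(as, as.numeric)
    vapply(rx, function(r) {
      if (is.null(r[[key]])) (if (num) NA_real_ else NA_character_)
      else as(r[[key]])
    }, if (num) numeric(1) else character(1))
  }
  ann <- data.frame(reaction = ids,
                    category = vapply(rx, get_chr, character(1), key = "category"),
                    gene = pick("gene"), length = pick("length", as.numeric),
                    mw = pick("mw", as.numeric), complex = pick("complex"),
                    trna = pick("trna"), stringsAsFactors = FALSE)
  S <- list(i = vapply(obj$S$i, as.integer, integer(1)),
            j = vapply(obj$S$j, as.integer, integer(1)),
            x = vapply(obj$S$x, as.character, character(1)))
  dil <- lapply(obj$dilution_rows, function(d) {
    for (key in c("label", "sense", "family"))
      if (is.null(d[[key]])) stop("dilution row missing key '", key, "'",
                                  call. = FALSE)
    dilution_row(b = unlist(d$b), c = unlist(d$c), sense = d$sense,
                 family = d$family, label = d$label)
  })
  me_model(reaction_ids = ids,
           metabolite_ids = vapply(obj$metabolites, as.character, character(1)),
           S = S, v_lower = lb, v_upper = ub,
           growth_reaction = obj$growth_reaction,
           dilution_rows = dil, annotations = ann,
           meta = if (is.null(obj$meta)) list() else obj$meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
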