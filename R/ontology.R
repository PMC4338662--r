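#' Ontology terms
#'
#' Terms are opaque identifiers drawn from controlled vocabularies:
#' anatomy terms (FMA-style ids) for gross anatomical structures,
#' cell-type terms (CT-style ids) for cells, and subcellular terms.
#' The package treats term ids as opaque strings; no reasoning or
#' subsumption is performed, and matching is exact-string.
#'
#' @param id Non-empty identifier string, e.g. `"FMA:kidney"`.
#' @param label Human-readable label; defaults to the id.
#' @param vocabulary One of `"anatomy"`, `"cell_type"`, `"subcellular"`.
#' @return An `ontology_term` object (named list).
#' @export
#' @examples
#' ontology_term("FMA:kidney", "kidney", "anatomy")
ontology_term <- function(id, label = id,
                          vocabulary = c("anatomy", "cell_type", "subcellular")) {
  vocabulary <- match.arg(vocabulary)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("ontology term id must be a non-empty string", call. = FALSE)
  structure(list(id = id, label = label, vocabulary = vocabulary),
            class = "ontology_term")
}

#' @export
print.ontology_term <- function(x, ...) {
  cat(sprintf("<%s> %s [%s]\n", x$id, x$label, x$vocabulary))
  invisible(x)
}

#' @export
format.ontology_term <- function(x, ...) x$id

## Coerce a term given as string or ontology_term to its id string.
term_id <- function(x) {
  if (inherits(x, "ontology_term")) x$id
  else if (is.character(x) && length(x) == 1L && nzchar(x)) x
  else stop("expected an ontology term or a non-empty id string", call. = FALSE)
}

#' Term store
#'
#' A small in-memory vocabulary: a named list of [ontology_term()]s with
#' unique ids. Used for the fixture vocabularies that stand in for
#' full-scale anatomy/cell-type ontologies.
#'
#' @param terms List of `ontology_term` objects.
#' @return A `term_store` object.
#' @export
term_store <- function(terms = list()) {
  ids <- vapply(terms, function(t) t$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate term ids in store: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  names(terms) <- ids
  structure(list(terms = terms), class = "term_store")
}

#' @export
print.term_store <- function(x, ...) {
  cat(sprintf("term store: %d terms\n", length(x$terms)))
  invisible(x)
}
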