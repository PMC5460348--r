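#' Construct a prefix context
#'
#' @param ... prefix = base pairs, or a single named character vector/list.
#' @return a [PrefixContext-class] object.
#' @examples
#' ctx <- prefixContext(EX = "http://example.org/EX_")
#' expandCurie("EX:0000003", ctx)
#' @export
prefixContext <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) &&
      (is.list(args[[1]]) || length(args[[1]]) > 1L ||
       !is.null(names(args[[1]])))) {
    m <- unlist(args[[1]])
  } else {
    m <- unlist(args)
  }
  if (is.null(m)) m <- character(0)
  new("PrefixContext", mapping = setNames(as.character(m), names(m)))
}

#' Default prefix context with the standard OBO/OWL namespaces
#'
#' Covers rdfs, owl, xsd, oboInOwl, IAO and dcterms; fixture and user
#' contexts are merged on top of it.
#'
#' @return a [PrefixContext-class].
#' @export
defaultContext <- function() {
  prefixContext(c(
    rdfs = "http://www.w3.org/2000/01/rdf-schema#",
    owl = "http://www.w3.org/2002/07/owl#",
    xsd = "http://www.w3.org/2001/XMLSchema#",
    oboInOwl = "http://www.geneontology.org/formats/oboInOwl#",
    IAO = "http://purl.obolibrary.org/obo/IAO_",
    dcterms = "http://purl.org/dc/terms/"
  ))
}

#' Merge prefix contexts
#'
#' Later contexts win on prefix clashes.
#'
#' @param ... [PrefixContext-class] objects.
#' @return a merged [PrefixContext-class].
#' @export
mergeContexts <- function(...) {
  maps <- lapply(list(...), function(x) x@mapping)
  out <- character(0)
  for (m in maps) out[names(m)] <- m
  prefixContext(out)
}

#' Read a prefix context from a JSON file
#'
#' The file is a JSON object of prefix -> IRI base pairs (JSON-LD-context
#' like); keys starting with `@` are ignored.
#'
#' @param path path to a JSON file.
#' @return a [PrefixContext-class].
#' @export
readContext <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.list(obj) && "@context" %in% names(obj)) obj <- obj[["@context"]]
  obj <- unlist(obj)
  obj <- obj[!startsWith(names(obj), "@")]
  prefixContext(obj)
}

.isCurie <- function(x) {
  grepl("^[A-Za-z_][A-Za-z0-9_.-]*:[^/<>\"'[:space:]][^<>\"'[:space:]]*$", x)
}

.curiePrefix <- function(curie) sub(":.*$", "", curie)
.curieLocal <- function(curie) sub("^[^:]*:", "", curie)

#' Expand a CURIE to a full IRI
#'
#' `expandCurie` and [compactIri()] are exact inverses over a given context:
#' compacting the expansion returns the input CURIE.
#'
#' @param curie a compact identifier of the form `prefix:local`.
#' @param context a [PrefixContext-class].
#' @return the full IRI string.
#' @export
expandCurie <- function(curie, context) {
  stopifnot(length(curie) == 1L)
  if (!grepl(":", curie, fixed = TRUE))
    .dosdpError("dosdp_unresolved_prefix",
                paste0("not a CURIE (no prefix): '", curie, "'"))
  p <- .curiePrefix(curie)
  if (!(p %in% names(context@mapping)))
    .dosdpError("dosdp_unresolved_prefix",
                paste0("unresolved CURIE prefix: '", p, "'"))
  paste0(context@mapping[[p]], .curieLocal(curie))
}

#' Compact a full IRI to a CURIE
#'
#' Uses the longest matching base in the context. Errors when no base
#' matches.
#'
#' @param iri a full IRI string.
#' @param context a [PrefixContext-class].
#' @return the CURIE string.
#' @export
compactIri <- function(iri, context) {
  stopifnot(length(iri) == 1L)
  m <- context@mapping
  hit <- vapply(m, function(b) startsWith(iri, b), logical(1))
  if (!any(hit))
    .dosdpError("dosdp_unresolved_prefix",
                paste0("no prefix base matches IRI: <", iri, ">"))
  bases <- m[hit]
  best <- which.max(nchar(bases))
  paste0(names(bases)[best], ":",
         substring(iri, nchar(bases[best]) + 1L))
}
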