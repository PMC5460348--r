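## Reading, parsing and serialising pattern documents. Documents are the
## JSON-compatible subset of YAML: anchors, aliases, merge keys and custom
## tags are rejected up front so that any JSON-schema-capable consumer can
## read the same files.

.TOP_LEVEL_KEYS <- c(
  "pattern_name", "pattern_iri", "base_iri", "extends", "description",
  "readable_identifier",
  "classes", "relations", "annotationProperties", "dataProperties",
  "vars", "data_list_vars",
  "annotations", "logical_axioms",
  "equivalentTo", "subClassOf", "disjointWith", "GCI",
  "name", "def", "comment", "xrefs", "exact_synonyms"
)

.OBO_ANNOTATION_SLOTS <- c("name", "def", "comment")
.OBO_LIST_SLOTS <- c("xrefs", "exact_synonyms")
.CONVENIENCE_SLOTS <- c("equivalentTo", "subClassOf", "disjointWith", "GCI")

## crude but effective JSON-subset guard: scan text with quoted spans
## blanked out for YAML anchors, aliases, merge keys and tags
.checkJsonSubset <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  for (ln in seq_along(lines)) {
    l <- lines[ln]
    ## blank quoted spans and trailing comments
    l <- gsub("'[^']*'", "''", l)
    l <- gsub('"[^"]*"', '""', l)
    l <- sub("\\s#.*$", "", l)
    if (grepl("(^|[\\s,\\[{])&[A-Za-z0-9_-]+", l, perl = TRUE))
      .dosdpError("dosdp_json_subset_error",
                  paste0("json-subset violation: YAML anchor on line ", ln))
    if (grepl("(^|[\\s,\\[{:])\\*[A-Za-z0-9_-]+", l, perl = TRUE))
      .dosdpError("dosdp_json_subset_error",
                  paste0("json-subset violation: YAML alias on line ", ln))
    if (grepl("<<\\s*:", l))
      .dosdpError("dosdp_json_subset_error",
                  paste0("json-subset violation: merge key on line ", ln))
    if (grepl("![A-Za-z!]", l))
      .dosdpError("dosdp_json_subset_error",
                  paste0("json-subset violation: YAML tag on line ", ln))
  }
  invisible(TRUE)
}

.asNamedChr <- function(x, what) {
  if (is.null(x) || length(x) == 0L) return(.emptyNamed())
  if (!is.list(x) && is.null(names(x)))
    .dosdpError("dosdp_parse_error",
                paste0(what, " must be a mapping of key: value pairs"))
  v <- vapply(x, function(e) {
    if (is.null(e) || length(e) != 1L)
      .dosdpError("dosdp_parse_error",
                  paste0(what, " values must be single strings"))
    as.character(e)
  }, character(1))
  setNames(v, names(x))
}

.asChr <- function(x) {
  if (is.null(x)) return(NULL)
  if (length(x) == 0L) return(character(0))
  as.character(unlist(x, use.names = FALSE))
}

.parseAxiomSpecMap <- function(m, where, forceOwl = FALSE) {
  if (!is.list(m))
    .dosdpError("dosdp_parse_error",
                paste0(where, ": axiom specification must be a mapping"))
  hasText <- "text" %in% names(m)
  hasValue <- "value" %in% names(m)
  hasAxiomType <- "axiom_type" %in% names(m)
  specKind <- if (hasAxiomType || forceOwl) "printf_owl"
              else if (hasValue && !hasText) "list_annotation"
              else "printf_annotation"
  at <- if (hasAxiomType) as.character(m[["axiom_type"]]) else NULL
  nested <- lapply(m[["annotations"]],
                   .parseAxiomSpecMap, where = paste0(where, ".annotations"))
  new("AxiomSpec",
      specKind = specKind,
      axiomType = if (specKind == "printf_owl") at else "annotation",
      annotationProperty = if ("annotationProperty" %in% names(m))
        as.character(m[["annotationProperty"]]) else NULL,
      slotName = NULL,
      text = if (hasText) as.character(m[["text"]]) else NULL,
      vars = if ("vars" %in% names(m)) .asChr(m[["vars"]]) else NULL,
      value = if (hasValue) as.character(m[["value"]]) else NULL,
      annotations = nested)
}

.parseOboSlot <- function(m, slot) {
  if (slot %in% .OBO_LIST_SLOTS) {
    val <- if (is.list(m) && "value" %in% names(m))
      as.character(m[["value"]])
    else if (is.character(m) && length(m) == 1L) as.character(m)
    else NULL
    return(new("AxiomSpec", specKind = "list_annotation_obo",
               axiomType = "annotation", slotName = slot, value = val))
  }
  if (!is.list(m))
    .dosdpError("dosdp_parse_error",
                paste0(slot, ": expected a mapping with text and vars"))
  nested <- lapply(m[["annotations"]],
                   .parseAxiomSpecMap, where = paste0(slot, ".annotations"))
  if ("xrefs" %in% names(m)) {
    nested <- c(nested, list(
      new("AxiomSpec", specKind = "list_annotation_obo",
          axiomType = "annotation", slotName = "xrefs",
          value = as.character(m[["xrefs"]]))))
  }
  new("AxiomSpec", specKind = "printf_annotation_obo",
      axiomType = "annotation", slotName = slot,
      text = if ("text" %in% names(m)) as.character(m[["text"]]) else NULL,
      vars = if ("vars" %in% names(m)) .asChr(m[["vars"]]) else NULL,
      annotations = nested)
}

.parseConvenienceSlot <- function(m, slot) {
  if (!is.list(m))
    .dosdpError("dosdp_parse_error",
                paste0(slot, ": expected a mapping with text and vars"))
  nested <- lapply(m[["annotations"]],
                   .parseAxiomSpecMap, where = paste0(slot, ".annotations"))
  new("AxiomSpec", specKind = "printf_owl_convenience",
      axiomType = slot, slotName = slot,
      text = if ("text" %in% names(m)) as.character(m[["text"]]) else NULL,
      vars = if ("vars" %in% names(m)) .asChr(m[["vars"]]) else NULL,
      annotations = nested)
}

#' Parse a pattern document from YAML text
#'
#' Enforces the JSON-compatible subset of YAML (no anchors, aliases, merge
#' keys or tags), then builds a [PatternDocument-class]. Documents using the
#' OBO extension (`extends: obo`) are flagged but not normalised; see
#' [normalizeObo()]. Unknown top-level keys are kept verbatim (and reported
#' by [validatePattern()]).
#'
#' @param text YAML text of one pattern document.
#' @param context optional [PrefixContext-class] (kept for interface
#'   symmetry; CURIE resolution happens in validation).
#' @return a [PatternDocument-class].
#' @export
parsePattern <- function(text, context = NULL) {
  .checkJsonSubset(text)
  obj <- tryCatch(yaml::yaml.load(text),
                  error = function(e)
                    .dosdpError("dosdp_parse_error",
                                paste0("YAML syntax error: ",
                                       conditionMessage(e))))
  if (!is.list(obj))
    .dosdpError("dosdp_parse_error", "pattern document must be a mapping")
  if (!("pattern_name" %in% names(obj)))
    .dosdpError("dosdp_missing_field",
                "missing mandatory field: pattern_name")

  extension <- if ("extends" %in% names(obj))
    tolower(as.character(obj[["extends"]])) else "core"
  if (!(extension %in% c("core", "obo")))
    .dosdpError("dosdp_parse_error",
                paste0("unknown extension: ", extension))

  annSpecs <- lapply(seq_along(obj[["annotations"]]), function(i)
    .parseAxiomSpecMap(obj[["annotations"]][[i]],
                       where = paste0("annotations[", i, "]")))
  logSpecs <- lapply(seq_along(obj[["logical_axioms"]]), function(i)
    .parseAxiomSpecMap(obj[["logical_axioms"]][[i]],
                       where = paste0("logical_axioms[", i, "]"),
                       forceOwl = TRUE))
  for (slot in .OBO_ANNOTATION_SLOTS)
    if (slot %in% names(obj))
      annSpecs <- c(annSpecs, list(.parseOboSlot(obj[[slot]], slot)))
  for (slot in .OBO_LIST_SLOTS)
    if (slot %in% names(obj))
      annSpecs <- c(annSpecs, list(.parseOboSlot(obj[[slot]], slot)))
  for (slot in .CONVENIENCE_SLOTS)
    if (slot %in% names(obj))
      logSpecs <- c(logSpecs,
                    list(.parseConvenienceSlot(obj[[slot]], slot)))

  extras <- obj[setdiff(names(obj), .TOP_LEVEL_KEYS)]

  new("PatternDocument",
      patternName = as.character(obj[["pattern_name"]]),
      patternIRI = if ("pattern_iri" %in% names(obj))
        as.character(obj[["pattern_iri"]]) else NULL,
      extension = extension,
      description = if ("description" %in% names(obj))
        as.character(obj[["description"]]) else NULL,
      classes = .asNamedChr(obj[["classes"]], "classes"),
      relations = .asNamedChr(obj[["relations"]], "relations"),
      annotationProperties = .asNamedChr(obj[["annotationProperties"]],
                                         "annotationProperties"),
      dataProperties = .asNamedChr(obj[["dataProperties"]],
                                   "dataProperties"),
      readableIdentifier = if ("readable_identifier" %in% names(obj))
        as.character(obj[["readable_identifier"]]) else NULL,
      baseIRI = if ("base_iri" %in% names(obj))
        as.character(obj[["base_iri"]]) else NULL,
      vars = .asNamedChr(obj[["vars"]], "vars"),
      dataListVars = .asNamedChr(obj[["data_list_vars"]], "data_list_vars"),
      annotationAxioms = annSpecs,
      logicalAxioms = logSpecs,
      extras = if (length(extras)) extras else list())
}

#' Read a pattern document from a YAML file
#'
#' @param path path to a `.yaml` pattern file.
#' @param context optional [PrefixContext-class].
#' @return a [PatternDocument-class].
#' @export
readPattern <- function(path, context = NULL) {
  parsePattern(paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
                     collapse = "\n"),
               context = context)
}

## serialisation -------------------------------------------------------------

.specToMap <- function(spec) {
  m <- list()
  if (spec@specKind == "printf_owl" && !is.null(spec@axiomType))
    m$axiom_type <- spec@axiomType
  if (!is.null(spec@annotationProperty))
    m$annotationProperty <- spec@annotationProperty
  if (!is.null(spec@text)) m$text <- spec@text
  if (!is.null(spec@vars)) m$vars <- as.list(spec@vars)
  if (!is.null(spec@value)) m$value <- spec@value
  if (length(spec@annotations))
    m$annotations <- lapply(spec@annotations, .specToMap)
  m
}

.oboSlotToMap <- function(spec) {
  if (spec@specKind == "list_annotation_obo")
    return(list(value = spec@value))
  m <- list()
  if (!is.null(spec@text)) m$text <- spec@text
  if (!is.null(spec@vars)) m$vars <- as.list(spec@vars)
  nested <- spec@annotations
  xref <- vapply(nested, function(a)
    identical(a@slotName, "xrefs"), logical(1))
  if (any(xref)) m$xrefs <- nested[xref][[1]]@value
  rest <- nested[!xref]
  if (length(rest)) m$annotations <- lapply(rest, .specToMap)
  m
}

#' Serialise a pattern document to YAML text
#'
#' Inverse of [parsePattern()]: `parsePattern(serializePattern(doc))`
#' reproduces `doc` field for field (OBO slots are written back to their
#' named fields, core specs to `annotations` / `logical_axioms`).
#'
#' @param doc a [PatternDocument-class].
#' @return YAML text.
#' @export
serializePattern <- function(doc) {
  out <- list(pattern_name = doc@patternName)
  if (!is.null(doc@patternIRI)) out$pattern_iri <- doc@patternIRI
  if (!is.null(doc@baseIRI)) out$base_iri <- doc@baseIRI
  if (doc@extension != "core") out$extends <- doc@extension
  if (!is.null(doc@description)) out$description <- doc@description
  if (!is.null(doc@readableIdentifier))
    out$readable_identifier <- doc@readableIdentifier
  dict <- function(x) if (length(x)) as.list(x) else NULL
  if (!is.null(d <- dict(doc@classes))) out$classes <- d
  if (!is.null(d <- dict(doc@relations))) out$relations <- d
  if (!is.null(d <- dict(doc@annotationProperties)))
    out$annotationProperties <- d
  if (!is.null(d <- dict(doc@dataProperties))) out$dataProperties <- d
  if (!is.null(d <- dict(doc@vars))) out$vars <- d
  if (!is.null(d <- dict(doc@dataListVars))) out$data_list_vars <- d

  coreAnn <- list(); coreLog <- list()
  for (spec in doc@annotationAxioms) {
    if (spec@specKind %in% c("printf_annotation_obo", "list_annotation_obo")
        && !is.null(spec@slotName)) {
      out[[spec@slotName]] <- .oboSlotToMap(spec)
    } else {
      coreAnn[[length(coreAnn) + 1L]] <- .specToMap(spec)
    }
  }
  for (spec in doc@logicalAxioms) {
    if (spec@specKind == "printf_owl_convenience" && !is.null(spec@slotName)) {
      m <- .specToMap(spec)
      out[[spec@slotName]] <- m
    } else {
      coreLog[[length(coreLog) + 1L]] <- .specToMap(spec)
    }
  }
  if (length(coreAnn)) out$annotations <- coreAnn
  if (length(coreLog)) out$logical_axioms <- coreLog
  for (k in names(doc@extras)) out[[k]] <- doc@extras[[k]]
  yaml::as.yaml(out)
}

#' Write a pattern document to a file named after the pattern
#'
#' @param doc a [PatternDocument-class].
#' @param dir output directory.
#' @return the path written, invisibly.
#' @export
writePattern <- function(doc, dir = ".") {
  path <- file.path(dir, paste0(doc@patternName, ".yaml"))
  writeLines(serializePattern(doc), path, useBytes = TRUE)
  invisible(path)
}

## accessors -----------------------------------------------------------------

#' Pattern document accessors
#'
#' @param doc a [PatternDocument-class].
#' @return `patternName`: the short identifier; `patternIri`: the pattern's
#'   IRI (stored, or derived from the base IRI and name); `patternVars`:
#'   named character of class-variable ranges; `patternDictionary`: the
#'   merged label -> CURIE map across the four dictionaries.
#' @param context a [PrefixContext-class] (unused placeholder for
#'   derivation; the IRI is a plain concatenation).
#' @export
patternName <- function(doc) doc@patternName

#' @rdname patternName
#' @export
patternIri <- function(doc, context = NULL) {
  if (!is.null(doc@patternIRI)) return(doc@patternIRI)
  base <- if (!is.null(doc@baseIRI)) doc@baseIRI
          else "http://purl.obolibrary.org/obo/"
  paste0(base, doc@patternName)
}

#' @rdname patternName
#' @export
patternVars <- function(doc) doc@vars

#' @rdname patternName
#' @export
patternDictionary <- function(doc) {
  c(doc@classes, doc@relations, doc@annotationProperties, doc@dataProperties)
}
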