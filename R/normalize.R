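## OBO-extension normalisation: rewrite the named convenience slots
## (name/def/comment/xrefs/exact_synonyms) into explicit core annotation
## specs against fixed OBO-convention annotation properties, default the
## readable-identifier property to rdfs:label and the identifier base to
## the OBO PURL convention.

.OBO_SLOT_PROPERTIES <- list(
  name = c(label = "label", curie = "rdfs:label"),
  def = c(label = "definition", curie = "IAO:0000115"),
  comment = c(label = "comment", curie = "rdfs:comment"),
  xrefs = c(label = "database_cross_reference", curie = "oboInOwl:hasDbXref"),
  exact_synonyms = c(label = "has_exact_synonym",
                     curie = "oboInOwl:hasExactSynonym")
)

.OBO_BASE_IRI <- "http://purl.obolibrary.org/obo/"

.normalizeSpec <- function(spec, props) {
  anns <- lapply(spec@annotations, .normalizeSpec, props = props)
  if (spec@specKind %in% c("printf_annotation_obo", "list_annotation_obo")) {
    slot <- spec@slotName
    if (is.null(slot) || !(slot %in% names(.OBO_SLOT_PROPERTIES)))
      .dosdpError("dosdp_conflict_error",
                  paste0("OBO spec with unknown slot: ",
                         if (is.null(slot)) "<none>" else slot))
    prop <- .OBO_SLOT_PROPERTIES[[slot]]
    kind <- if (spec@specKind == "printf_annotation_obo")
      "printf_annotation" else "list_annotation"
    initialize(spec, specKind = kind,
               annotationProperty = unname(prop[["label"]]),
               slotName = NULL, annotations = anns)
  } else {
    initialize(spec, annotations = anns)
  }
}

.oboSlotsUsed <- function(specs) {
  out <- character(0)
  for (spec in specs) {
    if (spec@specKind %in% c("printf_annotation_obo", "list_annotation_obo")
        && !is.null(spec@slotName))
      out <- c(out, spec@slotName)
    out <- c(out, .oboSlotsUsed(spec@annotations))
  }
  out
}

#' Normalise an OBO-extension document into core form
#'
#' Rewrites the OBO convenience slots (`name`, `def`, `comment`, `xrefs`,
#' `exact_synonyms`) as explicit `printf_annotation` / `list_annotation`
#' specs against the OBO-convention annotation properties (rdfs:label,
#' the IAO textual definition, rdfs:comment, oboInOwl database cross
#' reference and exact synonym), adds those properties to the
#' annotation-property dictionary, defaults `readable_identifier` to the
#' label property, and defaults the identifier base to the OBO PURL
#' convention. Core documents are returned unchanged; the operation is
#' idempotent.
#'
#' @param doc a [PatternDocument-class].
#' @return an equivalent core-form [PatternDocument-class].
#' @export
normalizeObo <- function(doc) {
  if (doc@extension == "core") return(doc)

  slots <- unique(.oboSlotsUsed(c(doc@annotationAxioms, doc@logicalAxioms)))
  props <- doc@annotationProperties
  for (slot in slots) {
    prop <- .OBO_SLOT_PROPERTIES[[slot]]
    lab <- unname(prop[["label"]]); cur <- unname(prop[["curie"]])
    if (lab %in% names(props) && props[[lab]] != cur)
      .dosdpError("dosdp_conflict_error",
                  paste0("conflict: annotation property '", lab,
                         "' already maps to ", props[[lab]],
                         ", OBO slot '", slot, "' requires ", cur))
    ## an explicit core spec already targets the same property: the obo
    ## slot and the explicit spec would generate conflicting axioms
    explicit <- vapply(doc@annotationAxioms, function(s)
      s@specKind %in% c("printf_annotation", "list_annotation") &&
        !is.null(s@annotationProperty) &&
        identical(unname(props[s@annotationProperty]), cur),
      logical(1))
    if (any(explicit))
      .dosdpError("dosdp_conflict_error",
                  paste0("conflict: OBO slot '", slot, "' and an explicit ",
                         "annotation spec both target property ", cur))
    props[lab] <- cur
  }
  ## the readable-identifier default also needs the label property
  if (is.null(doc@readableIdentifier) &&
      !("label" %in% names(props)))
    props["label"] <- "rdfs:label"

  initialize(doc,
             extension = "core",
             annotationProperties = props,
             readableIdentifier = if (is.null(doc@readableIdentifier))
               "label" else doc@readableIdentifier,
             baseIRI = if (is.null(doc@baseIRI)) .OBO_BASE_IRI
                       else doc@baseIRI,
             annotationAxioms = lapply(doc@annotationAxioms,
                                       .normalizeSpec, props = props),
             logicalAxioms = lapply(doc@logicalAxioms,
                                    .normalizeSpec, props = props))
}

## convenience logical slots are part of the core schema; expand them to
## plain printf_owl specs for generation/matching
.coreLogicalSpecs <- function(doc) {
  lapply(doc@logicalAxioms, function(spec) {
    if (spec@specKind == "printf_owl_convenience")
      initialize(spec, specKind = "printf_owl", slotName = NULL)
    else spec
  })
}

## the annotation property (CURIE) used as readable identifier
.labelProperty <- function(doc) {
  ri <- doc@readableIdentifier
  if (!is.null(ri) && ri %in% names(doc@annotationProperties))
    return(unname(doc@annotationProperties[[ri]]))
  "rdfs:label"
}
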