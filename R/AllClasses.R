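#' @import methods
#' @importFrom utils read.delim head tail
#' @importFrom stats setNames
NULL

setClassUnion("characterOrNULL", c("character", "NULL"))

## internal error/condition helper -----------------------------------------

.dosdpError <- function(class, msg, call. = FALSE, data = NULL) {
  cond <- structure(
    class = c(class, "dosdp_error", "error", "condition"),
    list(message = msg, call = NULL, data = data)
  )
  stop(cond)
}

.emptyNamed <- function() setNames(character(0), character(0))

## PrefixContext ------------------------------------------------------------

#' Prefix context: CURIE prefix to IRI base mapping
#'
#' Maps CURIE prefixes (e.g. `"EX"`, `"rdfs"`) to absolute IRI bases,
#' JSON-LD-context style. Every base must be a syntactically valid absolute
#' IRI ending in `/`, `#` or `_` so that expansion is plain concatenation
#' and compaction is an exact inverse.
#'
#' @slot mapping named character vector, prefix -> IRI base.
#' @seealso [prefixContext()], [expandCurie()], [compactIri()]
#' @exportClass PrefixContext
setClass("PrefixContext", representation(mapping = "character"))

setValidity("PrefixContext", function(object) {
  m <- object@mapping
  if (length(m) == 0L) return(TRUE)
  if (is.null(names(m)) || anyNA(names(m)) || any(names(m) == ""))
    return("all bases must be named by a prefix")
  if (anyDuplicated(names(m)))
    return("prefixes must be unique")
  badIri <- !grepl("^[A-Za-z][A-Za-z0-9+.-]*:\\S+$", m)
  if (any(badIri))
    return(paste0("not an absolute IRI base: ", m[badIri][1L]))
  badEnd <- !grepl("[/#_]$", m)
  if (any(badEnd))
    return(paste0("IRI base must end in '/', '#' or '_': ", m[badEnd][1L]))
  TRUE
})

## Class expressions ---------------------------------------------------------

#' Class expression AST
#'
#' Virtual parent of the Manchester-syntax class-expression node types:
#' [NamedClass-class], [AndExpression-class], [OrExpression-class],
#' [NotExpression-class] and [SomeValuesFrom-class]. And/Or operands are
#' kept in a canonical sort order (by serialised key) so structurally equal
#' expressions compare equal.
#'
#' @exportClass ClassExpression
setClass("ClassExpression", representation("VIRTUAL"))

#' @rdname ClassExpression-class
#' @slot label readable label of the entity.
#' @slot curie compact identifier (prefix:local) of the entity.
#' @exportClass NamedClass
setClass("NamedClass", contains = "ClassExpression",
         representation(label = "character", curie = "character"))

#' @rdname ClassExpression-class
#' @slot operands list of >= 2 child expressions, canonically ordered.
#' @exportClass AndExpression
setClass("AndExpression", contains = "ClassExpression",
         representation(operands = "list"))

#' @rdname ClassExpression-class
#' @exportClass OrExpression
setClass("OrExpression", contains = "ClassExpression",
         representation(operands = "list"))

#' @rdname ClassExpression-class
#' @slot operand single child expression.
#' @exportClass NotExpression
setClass("NotExpression", contains = "ClassExpression",
         representation(operand = "ClassExpression"))

#' @rdname ClassExpression-class
#' @slot relationLabel readable label of the object property.
#' @slot relationCurie compact identifier of the object property.
#' @slot filler the filler class expression.
#' @exportClass SomeValuesFrom
setClass("SomeValuesFrom", contains = "ClassExpression",
         representation(relationLabel = "character",
                        relationCurie = "character",
                        filler = "ClassExpression"))

## AxiomSpec -----------------------------------------------------------------

#' Axiom specification within a pattern document
#'
#' One templated axiom of a pattern: a printf-templated logical axiom
#' (`printf_owl`, or the convenience kind `printf_owl_convenience` for the
#' equivalentTo/subClassOf/disjointWith/GCI slots), a printf-templated
#' annotation (`printf_annotation`, or `printf_annotation_obo` for the OBO
#' name/def/comment slots), or a list annotation expanded from a data list
#' variable (`list_annotation` / `list_annotation_obo`). Subfields that were
#' absent in the source document are `NULL`.
#'
#' @slot specKind one of printf_owl, printf_annotation, list_annotation,
#'   printf_owl_convenience, printf_annotation_obo, list_annotation_obo.
#' @slot axiomType equivalentTo, subClassOf, disjointWith, GCI or annotation.
#' @slot annotationProperty dictionary label of the annotation property
#'   (annotation kinds; `NULL` for un-normalised OBO kinds).
#' @slot slotName originating convenience/OBO slot name, or `NULL`.
#' @slot text printf template text (printf kinds).
#' @slot vars ordered variable names filling the template conversions.
#' @slot value data list variable name (list kinds).
#' @slot annotations nested axiom-annotation specs (annotation kinds only).
#' @exportClass AxiomSpec
setClass("AxiomSpec",
         representation(specKind = "character",
                        axiomType = "characterOrNULL",
                        annotationProperty = "characterOrNULL",
                        slotName = "characterOrNULL",
                        text = "characterOrNULL",
                        vars = "characterOrNULL",
                        value = "characterOrNULL",
                        annotations = "list"),
         prototype(axiomType = NULL, annotationProperty = NULL,
                   slotName = NULL, text = NULL, vars = NULL, value = NULL,
                   annotations = list()))

.SPEC_KINDS <- c("printf_owl", "printf_annotation", "list_annotation",
                 "printf_owl_convenience", "printf_annotation_obo",
                 "list_annotation_obo")

setValidity("AxiomSpec", function(object) {
  if (length(object@specKind) != 1L || !(object@specKind %in% .SPEC_KINDS))
    return("specKind must be one of the six schema field types")
  if (!all(vapply(object@annotations, is, logical(1), "AxiomSpec")))
    return("nested annotations must be AxiomSpec objects")
  TRUE
})

## PatternDocument -----------------------------------------------------------

#' A design pattern document
#'
#' In-memory form of one DOS-DP YAML file: metadata, the four entity
#' dictionaries (readable label -> CURIE), variable declarations, and the
#' annotation/logical axiom specifications. OBO-extension documents carry
#' their convenience slots as [AxiomSpec-class] objects with OBO spec kinds
#' until [normalizeObo()] rewrites them into core form.
#'
#' @slot patternName file-name-safe short identifier of the pattern.
#' @slot patternIRI absolute IRI identifying the pattern (`NULL` when the
#'   document relies on derivation from the name and a base IRI).
#' @slot extension "core" or "obo".
#' @slot description free-text description (`NULL` if absent).
#' @slot classes,relations,annotationProperties,dataProperties named
#'   character vectors: readable label -> CURIE.
#' @slot readableIdentifier dictionary label of the annotation property used
#'   as the source of readable identifiers (`NULL` before OBO defaulting).
#' @slot baseIRI IRI base for minted term identifiers (`NULL` before
#'   defaulting).
#' @slot vars named character: class variable name -> Manchester range text.
#' @slot dataListVars named character: list variable name -> XSD datatype.
#' @slot annotationAxioms,logicalAxioms lists of [AxiomSpec-class].
#' @slot extras unknown top-level keys kept verbatim for round-tripping.
#' @exportClass PatternDocument
setClass("PatternDocument",
         representation(patternName = "character",
                        patternIRI = "characterOrNULL",
                        extension = "character",
                        description = "characterOrNULL",
                        classes = "character",
                        relations = "character",
                        annotationProperties = "character",
                        dataProperties = "character",
                        readableIdentifier = "characterOrNULL",
                        baseIRI = "characterOrNULL",
                        vars = "character",
                        dataListVars = "character",
                        annotationAxioms = "list",
                        logicalAxioms = "list",
                        extras = "list"),
         prototype(patternIRI = NULL, extension = "core", description = NULL,
                   classes = setNames(character(0), character(0)),
                   relations = setNames(character(0), character(0)),
                   annotationProperties = setNames(character(0), character(0)),
                   dataProperties = setNames(character(0), character(0)),
                   readableIdentifier = NULL, baseIRI = NULL,
                   vars = setNames(character(0), character(0)),
                   dataListVars = setNames(character(0), character(0)),
                   annotationAxioms = list(), logicalAxioms = list(),
                   extras = list()))

setValidity("PatternDocument", function(object) {
  if (length(object@patternName) != 1L || is.na(object@patternName))
    return("patternName must be a single string")
  if (!(object@extension %in% c("core", "obo")))
    return("extension must be 'core' or 'obo'")
  ok <- function(x) length(x) == 0L || !is.null(names(x))
  if (!all(vapply(list(object@classes, object@relations,
                       object@annotationProperties, object@dataProperties,
                       object@vars, object@dataListVars), ok, logical(1))))
    return("dictionaries and variable maps must be named")
  specsOk <- function(l) all(vapply(l, is, logical(1), "AxiomSpec"))
  if (!specsOk(object@annotationAxioms) || !specsOk(object@logicalAxioms))
    return("axiom lists must contain AxiomSpec objects")
  TRUE
})

## Binding -------------------------------------------------------------------

#' Variable fillers for one pattern instantiation
#'
#' @slot classFillers named list, class variable name -> entity reference
#'   (a list with elements `label` and `curie`, see [entityRef()]).
#' @slot listFillers named list, data list variable name -> character vector
#'   of literal values.
#' @exportClass Binding
setClass("Binding",
         representation(classFillers = "list", listFillers = "list"),
         prototype(classFillers = list(), listFillers = list()))

setValidity("Binding", function(object) {
  cf <- object@classFillers
  if (length(cf) && (is.null(names(cf)) || any(names(cf) == "")))
    return("classFillers must be named by variable")
  okRef <- function(x) is.list(x) && all(c("label", "curie") %in% names(x))
  if (!all(vapply(cf, okRef, logical(1))))
    return("each class filler must be an entityRef (label + curie)")
  lf <- object@listFillers
  if (length(lf) && (is.null(names(lf)) || any(names(lf) == "")))
    return("listFillers must be named by variable")
  if (!all(vapply(lf, is.character, logical(1))))
    return("list fillers must be character vectors")
  TRUE
})

## Generated classes and ontology fragments ----------------------------------

#' A generated (or parsed) OWL class
#'
#' Annotation entries are lists with elements `property` (CURIE), `value`
#' (literal string), optional `datatype` (XSD CURIE, NULL for plain strings)
#' and `annotations` (nested axiom-annotation entries of the same shape).
#' Logical axiom entries are lists with elements `type` (equivalentTo /
#' subClassOf / disjointWith / GCI), `expr` and, for GCI only, `expr2`.
#'
#' @slot iri class identifier (CURIE form).
#' @slot annotations list of annotation axiom entries.
#' @slot logicalAxioms list of logical axiom entries.
#' @exportClass GeneratedClass
setClass("GeneratedClass",
         representation(iri = "character", annotations = "list",
                        logicalAxioms = "list"),
         prototype(annotations = list(), logicalAxioms = list()))

#' A small ontology: classes, asserted hierarchy, label index
#'
#' Representation of both generated outputs and input ontologies: a set of
#' [GeneratedClass-class] objects keyed by identifier, asserted named-class
#' subclass axioms, declared object properties, and a label index mapping
#' readable labels to identifiers.
#'
#' @slot classes named list of [GeneratedClass-class], keyed and sorted by
#'   identifier; no duplicates.
#' @slot subClassAxioms list of named character pairs `c(sub=, super=)`.
#' @slot objectProperties named character: property CURIE -> readable label.
#' @slot labelIndex named character: class label -> CURIE.
#' @exportClass OntologyFragment
setClass("OntologyFragment",
         representation(classes = "list", subClassAxioms = "list",
                        objectProperties = "character",
                        labelIndex = "character"),
         prototype(classes = list(), subClassAxioms = list(),
                   objectProperties = setNames(character(0), character(0)),
                   labelIndex = setNames(character(0), character(0))))

setValidity("OntologyFragment", function(object) {
  iris <- names(object@classes)
  if (length(object@classes)) {
    if (is.null(iris) || anyDuplicated(iris))
      return("classes must be uniquely keyed by identifier")
    slotIris <- vapply(object@classes, function(x) x@iri, character(1))
    if (!identical(unname(iris), unname(slotIris)))
      return("class list names must equal class identifiers")
    if (is.unsorted(iris)) return("classes must be sorted by identifier")
  }
  li <- object@labelIndex
  if (length(li)) {
    bad <- !(li %in% c(iris, character(0)))
    if (any(bad))
      return(paste0("labelIndex points at unknown class: ", li[bad][1L]))
  }
  TRUE
})

## TBox ----------------------------------------------------------------------

#' Terminology box for the structural reasoner
#'
#' @slot subClassOf named list: sub-class CURIE -> character vector of
#'   asserted named superclasses.
#' @slot definitions named list: class CURIE -> defining
#'   [ClassExpression-class] (from its single equivalence axiom).
#' @slot subPropertyOf named list: sub-property CURIE -> character vector of
#'   asserted super-properties.
#' @slot classes all named class CURIEs.
#' @exportClass TBox
setClass("TBox",
         representation(subClassOf = "list", definitions = "list",
                        subPropertyOf = "list", classes = "character"),
         prototype(subClassOf = list(), definitions = list(),
                   subPropertyOf = list(), classes = character(0)))

## Match results -------------------------------------------------------------

setClassUnion("BindingOrNULL", c("Binding", "NULL"))

#' Result of matching one class against a pattern
#'
#' @slot classIri the class that was tested.
#' @slot binding recovered [Binding-class], present iff `logicalMatch`.
#' @slot logicalMatch did an equivalence axiom unify with the pattern's
#'   logical template?
#' @slot annotationMatches named logical: per printf-annotation spec, does
#'   the re-rendered template equal the class's annotation value?
#' @slot conformant conjunction of the required matches.
#' @slot reasons human-readable reasons for non-conformance.
#' @exportClass MatchResult
setClass("MatchResult",
         representation(classIri = "character", binding = "BindingOrNULL",
                        logicalMatch = "logical",
                        annotationMatches = "logical",
                        conformant = "logical", reasons = "character"),
         prototype(binding = NULL, logicalMatch = FALSE,
                   annotationMatches = setNames(logical(0), character(0)),
                   conformant = FALSE, reasons = character(0)))

setValidity("MatchResult", function(object) {
  if (object@conformant && !object@logicalMatch)
    return("conformant implies logicalMatch")
  if (object@logicalMatch != !is.null(object@binding))
    return("binding must be present exactly when logicalMatch is TRUE")
  TRUE
})

#' Conformance report over a set of tagged classes
#'
#' @slot update identifiers of classes that conform (safe to regenerate).
#' @slot manual identifiers needing manual inspection, with `reasons`.
#' @slot reasons named list: identifier -> character vector of reasons.
#' @slot results named list of [MatchResult-class].
#' @exportClass ConformanceReport
setClass("ConformanceReport",
         representation(update = "character", manual = "character",
                        reasons = "list", results = "list"),
         prototype(update = character(0), manual = character(0),
                   reasons = list(), results = list()))

## show methods --------------------------------------------------------------

setMethod("show", "PrefixContext", function(object) {
  cat("PrefixContext with", length(object@mapping), "prefixes\n")
  if (length(object@mapping))
    cat(paste0("  ", names(object@mapping), " -> ", object@mapping,
               collapse = "\n"), "\n")
})

setMethod("show", "ClassExpression", function(object) {
  cat(class(object), ": ", toManchester(object), "\n", sep = "")
})

setMethod("show", "PatternDocument", function(object) {
  cat("PatternDocument '", object@patternName, "' (", object@extension,
      ")\n", sep = "")
  cat("  variables: ",
      paste(c(names(object@vars), names(object@dataListVars)),
            collapse = ", "), "\n", sep = "")
  cat("  axiom specs: ", length(object@annotationAxioms), " annotation, ",
      length(object@logicalAxioms), " logical\n", sep = "")
})

setMethod("show", "Binding", function(object) {
  cat("Binding\n")
  for (v in names(object@classFillers))
    cat("  ", v, " = ", object@classFillers[[v]]$label, " (",
        object@classFillers[[v]]$curie, ")\n", sep = "")
  for (v in names(object@listFillers))
    cat("  ", v, " = [",
        paste(object@listFillers[[v]], collapse = ", "), "]\n", sep = "")
})

setMethod("show", "GeneratedClass", function(object) {
  cat("GeneratedClass <", object@iri, "> with ",
      length(object@annotations), " annotation and ",
      length(object@logicalAxioms), " logical axiom(s)\n", sep = "")
})

setMethod("show", "OntologyFragment", function(object) {
  cat("OntologyFragment: ", length(object@classes), " classes, ",
      length(object@subClassAxioms), " asserted subclass axioms, ",
      length(object@objectProperties), " object properties\n", sep = "")
})

setMethod("show", "MatchResult", function(object) {
  cat("MatchResult <", object@classIri, ">: logicalMatch=",
      object@logicalMatch, ", conformant=", object@conformant, "\n", sep = "")
})

setMethod("show", "ConformanceReport", function(object) {
  cat("ConformanceReport: ", length(object@update), " update, ",
      length(object@manual), " manual\n", sep = "")
})

setMethod("show", "TBox", function(object) {
  cat("TBox: ", length(object@classes), " classes, ",
      length(object@definitions), " definitions\n", sep = "")
})
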