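## Pattern instantiation: render a pattern's axiom specifications against a
## binding to produce one OWL class, or a whole ontology fragment from a
## TSV filler table.

#' Construct an entity reference
#'
#' @param label readable label.
#' @param curie compact identifier.
#' @return a list with elements `label` and `curie`.
#' @export
entityRef <- function(label, curie) {
  list(label = as.character(label), curie = as.character(curie))
}

#' Construct a binding of pattern variables to fillers
#'
#' @param classFillers named list: class variable -> [entityRef()].
#' @param listFillers named list: data list variable -> character vector.
#' @return a [Binding-class].
#' @export
binding <- function(classFillers = list(), listFillers = list()) {
  new("Binding", classFillers = classFillers, listFillers = listFillers)
}

#' Canonical serialisation of a binding (used for ordering and dedup)
#'
#' @param b a [Binding-class].
#' @return a character scalar.
#' @export
bindingKey <- function(b) {
  cf <- b@classFillers
  if (length(cf)) cf <- cf[order(names(cf))]
  lf <- b@listFillers
  if (length(lf)) lf <- lf[order(names(lf))]
  paste(c(vapply(seq_along(cf), function(i)
            paste0(names(cf)[i], "=", cf[[i]]$curie), character(1)),
          vapply(seq_along(lf), function(i)
            paste0(names(lf)[i], "=[", paste(lf[[i]], collapse = "|"), "]"),
            character(1))),
        collapse = ";")
}

.checkBindingArity <- function(doc, b, strict) {
  need <- names(doc@vars)
  have <- names(b@classFillers)
  missing <- setdiff(need, have)
  if (length(missing))
    .dosdpError("dosdp_unbound_var",
                paste0("unbound class variable(s): ",
                       paste(missing, collapse = ", ")))
  extra <- setdiff(have, need)
  if (length(extra))
    .dosdpError("dosdp_arity_error",
                paste0("binding fills undeclared variable(s): ",
                       paste(extra, collapse = ", ")))
  if (strict) {
    lmiss <- setdiff(names(doc@dataListVars), names(b@listFillers))
    if (length(lmiss))
      .dosdpError("dosdp_unbound_var",
                  paste0("strict mode: unbound list variable(s): ",
                         paste(lmiss, collapse = ", ")))
    lex <- setdiff(names(b@listFillers), names(doc@dataListVars))
    if (length(lex))
      .dosdpError("dosdp_arity_error",
                  paste0("binding fills undeclared list variable(s): ",
                         paste(lex, collapse = ", ")))
  }
  invisible(TRUE)
}

.listFiller <- function(b, var) {
  v <- b@listFillers[[var]]
  if (is.null(v)) character(0) else v
}

.instantiateAnnotationSpec <- function(spec, doc, b) {
  prop <- unname(doc@annotationProperties[[spec@annotationProperty]])
  if (is.null(prop))
    .dosdpError("dosdp_undeclared_entity",
                paste0("annotation property '", spec@annotationProperty,
                       "' is not in the dictionary"))
  if (spec@specKind == "printf_annotation") {
    val <- renderTemplate(spec@text, spec@vars %||% character(0), b,
                          mode = "label")$text
    nested <- list()
    for (sub in spec@annotations)
      nested <- c(nested, .instantiateAnnotationSpec(sub, doc, b))
    list(list(property = prop, value = val, datatype = NULL,
              annotations = nested))
  } else if (spec@specKind == "list_annotation") {
    dt <- unname(doc@dataListVars[[spec@value]])
    if (identical(dt, "xsd:string")) dt <- NULL
    lapply(.listFiller(b, spec@value), function(v)
      list(property = prop, value = v, datatype = dt, annotations = list()))
  } else {
    .dosdpError("dosdp_conflict_error",
                paste0("cannot instantiate un-normalised spec kind: ",
                       spec@specKind))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.instantiateLogicalSpec <- function(spec, doc, b) {
  vars <- spec@vars %||% character(0)
  rendered <- renderTemplate(spec@text, vars, b, mode = "logical")$text
  classes <- doc@classes
  for (ref in b@classFillers)
    classes[ref$label] <- ref$curie
  parseOne <- function(txt)
    parseClassExpression(txt, classes = classes, relations = doc@relations)
  if (identical(spec@axiomType, "GCI")) {
    parts <- strsplit(rendered, " SubClassOf: ", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      .dosdpError("dosdp_parse_error",
                  paste0("GCI template must contain exactly one ",
                         "' SubClassOf: ' separator: ", spec@text))
    list(type = "GCI", expr = parseOne(parts[1]), expr2 = parseOne(parts[2]))
  } else {
    list(type = spec@axiomType, expr = parseOne(rendered), expr2 = NULL)
  }
}

#' Instantiate a pattern with a binding to produce one OWL class
#'
#' Renders every axiom the pattern specifies: printf annotation specs in
#' label mode, printf logical specs in logical mode (then parsed back to
#' class expressions), list specs expanded to one axiom (or axiom
#' annotation) per list element, and convenience slots treated as their
#' core equivalents. Instantiation is a pure function of
#' `(doc, binding, iri)`.
#'
#' In strict mode with an ontology supplied, each class filler is verified
#' to lie within its variable's declared range using the structural
#' reasoner ([subsumes()]); a violation raises an error naming the
#' variable, the filler and the range.
#'
#' @param doc a [PatternDocument-class].
#' @param binding a [Binding-class].
#' @param iri identifier (CURIE) for the new class.
#' @param ontology optional [OntologyFragment-class] providing the class
#'   hierarchy for range checking.
#' @param strict logical; enforce exact variable coverage and range checks.
#' @return a [GeneratedClass-class].
#' @examples
#' pat <- makeTransmembranePattern()
#' b <- binding(
#'   classFillers = list(cargo = entityRef("leucine", "EX:0000004"),
#'                       membrane = entityRef("plasma membrane", "EX:0000009")),
#'   listFillers = list(def_dbxref = c("PMID:1", "GOC:dos")))
#' instantiate(pat, b, "EX:1000001")
#' @export
instantiate <- function(doc, binding, iri, ontology = NULL, strict = FALSE) {
  doc <- normalizeObo(doc)
  .checkBindingArity(doc, binding, strict)
  if (strict && !is.null(ontology)) {
    tb <- asTBox(ontology)
    for (v in names(doc@vars)) {
      ref <- binding@classFillers[[v]]
      rangeExpr <- parseClassExpression(doc@vars[[v]],
                                        classes = doc@classes,
                                        relations = doc@relations)
      fillerExpr <- namedClass(ref$label, ref$curie)
      if (!subsumes(tb, rangeExpr, fillerExpr))
        .dosdpError("dosdp_range_violation",
                    paste0("range violation: filler '", ref$label,
                           "' (", ref$curie, ") for variable '", v,
                           "' is not within its range: ", doc@vars[[v]]))
    }
  }
  anns <- list()
  for (spec in doc@annotationAxioms)
    anns <- c(anns, .instantiateAnnotationSpec(spec, doc, binding))
  logs <- lapply(.coreLogicalSpecs(doc), .instantiateLogicalSpec,
                 doc = doc, b = binding)
  new("GeneratedClass", iri = iri, annotations = anns, logicalAxioms = logs)
}

## minting -------------------------------------------------------------------

#' Identifier minting policy
#'
#' Minted identifiers follow the OBO numbering convention: a CURIE prefix
#' plus a zero-padded numeric local part.
#'
#' @param prefix CURIE prefix for minted identifiers.
#' @param start first counter value.
#' @param width zero-padding width (7 by OBO convention).
#' @return a minting policy list.
#' @export
mintingPolicy <- function(prefix = "EX", start = 1L, width = 7L) {
  stopifnot(is.character(prefix), length(prefix) == 1L)
  list(prefix = prefix, start = as.integer(start), width = as.integer(width))
}

.mint <- function(policy, counter) {
  sprintf("%s:%0*d", policy$prefix, policy$width, counter)
}

## filler tables -------------------------------------------------------------

#' Read a TSV filler table
#'
#' One row per term to generate, one column per pattern variable; list
#' values are pipe-separated within a cell; an optional `iri` column
#' overrides identifier minting.
#'
#' @param path path to a UTF-8 TSV file.
#' @return a data.frame of character columns.
#' @export
readFillerTable <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, colClasses = "character",
             check.names = FALSE, quote = "", fileEncoding = "UTF-8")
}

.resolveCell <- function(cell, doc, ontology) {
  cell <- trimws(cell)
  if (cell %in% names(doc@classes))
    return(entityRef(cell, doc@classes[[cell]]))
  if (!is.null(ontology) && cell %in% names(ontology@labelIndex))
    return(entityRef(cell, ontology@labelIndex[[cell]]))
  if (.isCurie(cell)) {
    lab <- cell
    if (!is.null(ontology)) {
      hit <- names(ontology@labelIndex)[ontology@labelIndex == cell]
      if (length(hit)) lab <- hit[1]
    }
    return(entityRef(lab, cell))
  }
  NULL
}

#' Generate a batch of classes from a filler table
#'
#' One [GeneratedClass-class] per table row. Minted identifiers are
#' deterministic given the policy and row order; rows carrying an explicit
#' `iri` keep it regardless of order. Duplicate bindings collapse to one
#' class with a warning; identifier collisions are an error.
#'
#' @param doc a [PatternDocument-class].
#' @param table a data.frame (see [readFillerTable()]) whose columns cover
#'   the pattern variables, plus an optional `iri` column.
#' @param minting a [mintingPolicy()].
#' @param ontology optional [OntologyFragment-class] used to resolve labels
#'   and (in strict mode) to range-check fillers.
#' @param strict logical, see [instantiate()].
#' @return an [OntologyFragment-class] of the generated classes.
#' @export
generateBatch <- function(doc, table, minting = mintingPolicy(),
                          ontology = NULL, strict = FALSE) {
  doc <- normalizeObo(doc)
  need <- names(doc@vars)
  if (!all(need %in% colnames(table)))
    .dosdpError("dosdp_arity_error",
                paste0("table is missing variable column(s): ",
                       paste(setdiff(need, colnames(table)),
                             collapse = ", ")))
  listCols <- intersect(names(doc@dataListVars), colnames(table))
  counter <- minting$start
  seen <- character(0)
  used <- character(0)
  classes <- list()
  for (i in seq_len(nrow(table))) {
    cf <- list()
    for (v in need) {
      ref <- .resolveCell(table[i, v], doc, ontology)
      if (is.null(ref))
        .dosdpError("dosdp_parse_error",
                    paste0("malformed row ", i, ": cannot resolve filler '",
                           table[i, v], "' for variable '", v, "'"))
      cf[[v]] <- ref
    }
    lf <- list()
    for (v in listCols) {
      cell <- trimws(table[i, v])
      lf[[v]] <- if (nzchar(cell))
        strsplit(cell, "|", fixed = TRUE)[[1]] else character(0)
    }
    b <- binding(classFillers = cf, listFillers = lf)
    key <- bindingKey(b)
    if (key %in% seen) {
      warning("duplicate binding in row ", i, "; collapsed to one class",
              call. = FALSE)
      next
    }
    seen <- c(seen, key)
    iri <- if ("iri" %in% colnames(table) && nzchar(trimws(table[i, "iri"])))
      trimws(table[i, "iri"])
    else {
      m <- .mint(minting, counter)
      counter <- counter + 1L
      m
    }
    if (iri %in% used)
      .dosdpError("dosdp_conflict_error",
                  paste0("identifier collision in row ", i, ": ", iri))
    used <- c(used, iri)
    classes[[iri]] <- instantiate(doc, b, iri, ontology = ontology,
                                  strict = strict)
  }
  ontologyFragment(classes = classes,
                   labelProperty = .labelProperty(doc))
}

## fragments -----------------------------------------------------------------

#' Construct an ontology fragment
#'
#' Classes are sorted by identifier; the label index is derived from the
#' classes' label annotations unless supplied.
#'
#' @param classes named list of [GeneratedClass-class] (names = identifiers).
#' @param subClassAxioms list of `c(sub=, super=)` pairs.
#' @param objectProperties named character: property CURIE -> label.
#' @param labelIndex named character, label -> CURIE; derived when `NULL`.
#' @param labelProperty annotation property CURIE treated as the label.
#' @return an [OntologyFragment-class].
#' @export
ontologyFragment <- function(classes = list(), subClassAxioms = list(),
                             objectProperties = NULL, labelIndex = NULL,
                             labelProperty = "rdfs:label") {
  if (length(classes)) classes <- classes[order(names(classes))]
  if (is.null(objectProperties)) objectProperties <- .emptyNamed()
  if (is.null(labelIndex)) {
    labelIndex <- .emptyNamed()
    for (cl in classes) {
      for (a in cl@annotations) {
        if (identical(a$property, labelProperty)) {
          labelIndex[a$value] <- cl@iri
          break
        }
      }
    }
  }
  if (length(subClassAxioms)) {
    keys <- vapply(subClassAxioms, function(p)
      paste(p[["sub"]], p[["super"]]), character(1))
    subClassAxioms <- subClassAxioms[order(keys)][!duplicated(sort(keys))]
  }
  if (length(labelIndex)) labelIndex <- labelIndex[order(names(labelIndex))]
  if (length(objectProperties))
    objectProperties <- objectProperties[order(names(objectProperties))]
  new("OntologyFragment", classes = classes,
      subClassAxioms = subClassAxioms,
      objectProperties = objectProperties, labelIndex = labelIndex)
}

#' Merge ontology fragments
#'
#' Classes sharing an identifier must be identical; later fragments
#' contribute additional classes, axioms and index entries.
#'
#' @param ... [OntologyFragment-class] objects.
#' @return the merged [OntologyFragment-class].
#' @export
mergeFragments <- function(...) {
  frs <- list(...)
  classes <- list()
  axioms <- list()
  props <- .emptyNamed()
  labels <- .emptyNamed()
  for (fr in frs) {
    for (iri in names(fr@classes)) {
      if (!is.null(classes[[iri]]) &&
          !identical(classes[[iri]], fr@classes[[iri]]))
        .dosdpError("dosdp_conflict_error",
                    paste0("conflicting definitions for class ", iri,
                           " while merging fragments"))
      classes[[iri]] <- fr@classes[[iri]]
    }
    axioms <- c(axioms, fr@subClassAxioms)
    props[names(fr@objectProperties)] <- fr@objectProperties
    labels[names(fr@labelIndex)] <- fr@labelIndex
  }
  ontologyFragment(classes = classes, subClassAxioms = axioms,
                   objectProperties = props, labelIndex = labels)
}

#' Fragment accessors
#'
#' @param frag an [OntologyFragment-class].
#' @return `fragmentClasses`: the named list of classes; `labelIndex`: the
#'   label -> identifier map; `classLabel`: the label of one class (`NA`
#'   when unlabelled).
#' @export
fragmentClasses <- function(frag) frag@classes

#' @rdname fragmentClasses
#' @export
labelIndex <- function(frag) frag@labelIndex

#' @rdname fragmentClasses
#' @param iri a class identifier.
#' @export
classLabel <- function(frag, iri) {
  hit <- names(frag@labelIndex)[frag@labelIndex == iri]
  if (length(hit)) hit[1] else NA_character_
}
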