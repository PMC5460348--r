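## The inverse of generation: unify a class's equivalence axiom against a
## pattern's logical template (template conversions become match variables
## binding named-class leaves), modulo the canonical ordering of and/or
## operands, then reverse-check the printf annotation specs. Matching is
## purely structural; reasoning is used only for optional range checks.

## Unify a template AST (with variable leaves) against a target
## expression. Returns a list of bindings: named lists var -> entityRef
## (or var -> list(label=, curie=NA, expr=) for complex fillers).
.unifyExpr <- function(p, t, b, complexFillers = FALSE) {
  if (.isVarLeaf(p)) {
    v <- .varLeafName(p)
    if (is(t, "NamedClass")) {
      ref <- entityRef(t@label, t@curie)
    } else if (complexFillers) {
      ref <- list(label = toManchester(t), curie = NA_character_, expr = t)
    } else {
      return(list())
    }
    if (!is.null(b[[v]])) {
      same <- if (is.na(ref$curie) || is.na(b[[v]]$curie))
        identical(ref$label, b[[v]]$label)
      else identical(ref$curie, b[[v]]$curie)
      if (!same) return(list())
      return(list(b))
    }
    b[[v]] <- ref
    return(list(b))
  }
  if (is(p, "NamedClass")) {
    if (is(t, "NamedClass") && identical(p@curie, t@curie))
      return(list(b))
    return(list())
  }
  if (is(p, "SomeValuesFrom")) {
    if (!is(t, "SomeValuesFrom")) return(list())
    if (!identical(p@relationCurie, t@relationCurie)) return(list())
    return(.unifyExpr(p@filler, t@filler, b, complexFillers))
  }
  if (is(p, "NotExpression")) {
    if (!is(t, "NotExpression")) return(list())
    return(.unifyExpr(p@operand, t@operand, b, complexFillers))
  }
  if (is(p, "AndExpression") || is(p, "OrExpression")) {
    same <- (is(p, "AndExpression") && is(t, "AndExpression")) ||
      (is(p, "OrExpression") && is(t, "OrExpression"))
    if (!same) return(list())
    if (length(p@operands) != length(t@operands)) return(list())
    return(.unifyLists(p@operands, t@operands, b, complexFillers))
  }
  list()
}

## backtracking bijection between pattern operands and target operands
.unifyLists <- function(ps, ts, b, complexFillers) {
  if (length(ps) == 0L)
    return(if (length(ts) == 0L) list(b) else list())
  p1 <- ps[[1]]
  out <- list()
  for (i in seq_along(ts)) {
    bs <- .unifyExpr(p1, ts[[i]], b, complexFillers)
    for (b2 in bs)
      out <- c(out, .unifyLists(ps[-1], ts[-i], b2, complexFillers))
  }
  out
}

.bindingSortKey <- function(cf) {
  cf <- cf[order(names(cf))]
  paste(vapply(seq_along(cf), function(i)
    paste0(names(cf)[i], "=", cf[[i]]$label), character(1)),
    collapse = ";")
}

## annotation values of a class for one property
.annotationValues <- function(cl, prop) {
  vals <- character(0)
  for (a in cl@annotations)
    if (identical(a$property, prop)) vals <- c(vals, a$value)
  vals
}

#' Match one class against a pattern
#'
#' Tries to unify each of the class's equivalence axioms against the
#' pattern's equivalence template; template conversions act as match
#' variables binding named-class leaves (sub-expressions with
#' `complexFillers = TRUE`), modulo the canonical ordering of and/or
#' operands. On logical success the printf annotation specs are
#' re-rendered under the recovered binding and compared against the
#' class's annotation values; list-annotation fillers (e.g. definition
#' cross-references) are read back from the corresponding axiom
#' annotations. Candidates must bind each variable identically across
#' axioms; among several candidates the lexicographically first fully
#' conformant one wins.
#'
#' @param doc a [PatternDocument-class].
#' @param classIri identifier of a class present in `ontology`.
#' @param ontology an [OntologyFragment-class].
#' @param strict logical; also require fillers to lie within variable
#'   ranges (checked with the structural reasoner).
#' @param complexFillers allow variables to bind complex sub-expressions.
#' @return a [MatchResult-class]; non-matches are results, not errors.
#' @export
matchClass <- function(doc, classIri, ontology, strict = FALSE,
                       complexFillers = FALSE) {
  cl <- ontology@classes[[classIri]]
  if (is.null(cl))
    .dosdpError("dosdp_conflict_error",
                paste0("class not found in ontology: ", classIri))
  doc <- normalizeObo(doc)
  logical_specs <- Filter(function(s) identical(s@axiomType, "equivalentTo"),
                          .coreLogicalSpecs(doc))
  noMatch <- new("MatchResult", classIri = classIri, binding = NULL,
                 logicalMatch = FALSE,
                 annotationMatches = setNames(logical(0), character(0)),
                 conformant = FALSE,
                 reasons = "no equivalence axiom matched")
  if (length(logical_specs) == 0L) return(noMatch)
  spec <- logical_specs[[1]]
  if (is.null(spec@text) || is.null(spec@vars)) return(noMatch)
  tmpl <- .templateExpression(doc, spec)

  eqAxioms <- Filter(function(a) a$type == "equivalentTo", cl@logicalAxioms)
  if (length(eqAxioms) == 0L) return(noMatch)

  candidates <- list()
  for (ax in eqAxioms) {
    for (b in .unifyExpr(tmpl, ax$expr, list(), complexFillers))
      candidates[[length(candidates) + 1L]] <- b
  }
  ## every declared class variable must be bound
  candidates <- Filter(function(b)
    all(names(doc@vars) %in% names(b)), candidates)
  if (length(candidates) == 0L) return(noMatch)
  keys <- vapply(candidates, .bindingSortKey, character(1))
  candidates <- candidates[order(keys)][!duplicated(sort(keys))]

  annSpecs <- Filter(function(s) s@specKind == "printf_annotation",
                     doc@annotationAxioms)
  specName <- function(s, i) {
    if (!is.null(s@slotName)) s@slotName
    else if (!is.null(s@annotationProperty)) s@annotationProperty
    else paste0("annotation_", i)
  }
  evalCandidate <- function(cf) {
    amatch <- logical(0)
    reasons <- character(0)
    lf <- list()
    b <- binding(classFillers = cf[order(names(cf))])
    for (i in seq_along(annSpecs)) {
      s <- annSpecs[[i]]
      nm <- specName(s, i)
      prop <- unname(doc@annotationProperties[[s@annotationProperty]])
      expected <- tryCatch(
        renderTemplate(s@text, s@vars %||% character(0), b,
                       mode = "label")$text,
        error = function(e) NA_character_)
      vals <- .annotationValues(cl, prop)
      ok <- !is.na(expected) && expected %in% vals
      amatch[nm] <- ok
      if (!ok)
        reasons <- c(reasons,
                     paste0("annotation '", nm, "' does not match"))
      ## recover list fillers from the matched annotation's axiom
      ## annotations
      for (sub in s@annotations) {
        if (sub@specKind != "list_annotation" || is.null(sub@value)) next
        subProp <- unname(doc@annotationProperties[[sub@annotationProperty]])
        got <- character(0)
        if (ok) {
          for (a in cl@annotations) {
            if (identical(a$property, prop) &&
                identical(a$value, expected)) {
              for (aa in a$annotations)
                if (identical(aa$property, subProp))
                  got <- c(got, aa$value)
              break
            }
          }
        }
        lf[[sub@value]] <- got
      }
    }
    ## top-level list specs carry data, not identity: recover only
    for (s in doc@annotationAxioms) {
      if (s@specKind != "list_annotation" || is.null(s@value)) next
      prop <- unname(doc@annotationProperties[[s@annotationProperty]])
      lf[[s@value]] <- .annotationValues(cl, prop)
    }
    for (v in names(doc@dataListVars))
      if (is.null(lf[[v]])) lf[[v]] <- character(0)
    if (length(lf)) lf <- lf[order(names(lf))]
    list(binding = binding(classFillers = b@classFillers,
                           listFillers = lf),
         amatch = amatch, reasons = reasons)
  }

  evals <- lapply(candidates, evalCandidate)
  fullOk <- vapply(evals, function(e) all(e$amatch), logical(1))
  pick <- if (any(fullOk)) which(fullOk)[1] else 1L
  ev <- evals[[pick]]
  reasons <- ev$reasons
  rangeOk <- TRUE
  if (strict) {
    tb <- asTBox(ontology)
    for (v in names(doc@vars)) {
      ref <- ev$binding@classFillers[[v]]
      rangeExpr <- parseClassExpression(doc@vars[[v]],
                                        classes = doc@classes,
                                        relations = doc@relations)
      fillerExpr <- if (!is.na(ref$curie)) namedClass(ref$label, ref$curie)
                    else ref$expr
      if (!subsumes(tb, rangeExpr, fillerExpr)) {
        rangeOk <- FALSE
        reasons <- c(reasons,
                     paste0("filler '", ref$label, "' for variable '", v,
                            "' is outside its range"))
      }
    }
  }
  if (length(candidates) > 1L)
    reasons <- c(reasons, paste0(length(candidates),
                                 " candidate bindings; reporting the ",
                                 "first in canonical order"))
  new("MatchResult", classIri = classIri, binding = ev$binding,
      logicalMatch = TRUE, annotationMatches = ev$amatch,
      conformant = all(ev$amatch) && rangeOk,
      reasons = reasons)
}

#' Find all classes of an ontology matching a pattern
#'
#' One result per class whose equivalence axiom unifies with the
#' pattern's logical template, ordered by class identifier; classes
#' without an equivalence axiom are skipped silently. Results are
#' independent of ontology iteration order.
#'
#' @inheritParams matchClass
#' @return list of [MatchResult-class] with `logicalMatch = TRUE`.
#' @export
findMatches <- function(doc, ontology, strict = FALSE,
                        complexFillers = FALSE) {
  out <- list()
  for (iri in sort(names(ontology@classes))) {
    res <- matchClass(doc, iri, ontology, strict = strict,
                      complexFillers = complexFillers)
    if (res@logicalMatch) out[[length(out) + 1L]] <- res
  }
  out
}

#' Check pattern conformance of tagged classes
#'
#' Partitions the tagged classes into those that conform to the pattern
#' (safe to update automatically when the pattern changes) and those
#' needing manual inspection, with per-class reasons.
#'
#' @param doc a [PatternDocument-class].
#' @param tagged character vector of class identifiers; all must exist.
#' @param ontology an [OntologyFragment-class].
#' @param strict logical, see [matchClass()].
#' @return a [ConformanceReport-class].
#' @export
checkConformance <- function(doc, tagged, ontology, strict = FALSE) {
  unknown <- setdiff(tagged, names(ontology@classes))
  if (length(unknown))
    .dosdpError("dosdp_conflict_error",
                paste0("tagged identifiers not present in the ontology: ",
                       paste(unknown, collapse = ", ")))
  results <- list()
  update <- character(0)
  manual <- character(0)
  reasons <- list()
  for (iri in tagged) {
    res <- matchClass(doc, iri, ontology, strict = strict)
    results[[iri]] <- res
    if (res@conformant) {
      update <- c(update, iri)
    } else {
      manual <- c(manual, iri)
      reasons[[iri]] <- res@reasons
    }
  }
  new("ConformanceReport", update = update, manual = manual,
      reasons = reasons, results = results)
}

## JSON serialisation --------------------------------------------------------

.bindingToList <- function(b) {
  if (is.null(b)) return(NULL)
  list(classFillers = lapply(b@classFillers, function(r)
         list(label = r$label, curie = r$curie)),
       listFillers = b@listFillers)
}

#' Serialise match results to JSON
#'
#' @param results a [MatchResult-class] or list of them.
#' @return a JSON string.
#' @export
matchesToJSON <- function(results) {
  if (is(results, "MatchResult")) results <- list(results)
  jsonlite::toJSON(lapply(results, function(r)
    list(class_iri = r@classIri,
         logical_match = r@logicalMatch,
         conformant = r@conformant,
         annotation_matches = as.list(r@annotationMatches),
         binding = .bindingToList(r@binding),
         reasons = r@reasons)),
    auto_unbox = TRUE, pretty = TRUE, null = "null")
}

#' Serialise a conformance report to JSON
#'
#' @param report a [ConformanceReport-class].
#' @return a JSON string.
#' @export
conformanceToJSON <- function(report) {
  jsonlite::toJSON(list(update = report@update, manual = report@manual,
                        reasons = report@reasons),
                   auto_unbox = TRUE, pretty = TRUE)
}
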