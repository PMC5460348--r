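## A small structural subsumption engine over the supported axiom subset.
## Sound but deliberately incomplete with respect to full OWL semantics:
## reflexive-transitive closure over asserted named subclass axioms,
## definition unfolding (equivalence axioms as necessary-and-sufficient
## conditions), conjunction introduction/elimination, disjunct
## introduction, and existential monotonicity over sub-properties. No
## property chains, no transitivity of object properties, no disjointness.

#' Construct a terminology box
#'
#' @param subClassOf named list: sub CURIE -> character of named supers.
#' @param definitions named list: CURIE -> defining
#'   [ClassExpression-class].
#' @param subPropertyOf named list: sub property -> character of supers.
#' @param classes all named class CURIEs (defaults to those mentioned).
#' @return a [TBox-class].
#' @export
tbox <- function(subClassOf = list(), definitions = list(),
                 subPropertyOf = list(), classes = NULL) {
  if (is.null(classes))
    classes <- unique(c(names(subClassOf), unlist(subClassOf),
                        names(definitions)))
  new("TBox", subClassOf = subClassOf, definitions = definitions,
      subPropertyOf = subPropertyOf, classes = sort(unique(classes)))
}

#' Build a TBox from ontology fragments
#'
#' Asserted named subclass axioms populate the hierarchy; each class's
#' single equivalence axiom (if any) becomes its definition. Additional
#' fragments or TBoxes may be merged in.
#'
#' @param frag an [OntologyFragment-class].
#' @param background optional [TBox-class] (or fragment) merged in.
#' @return a [TBox-class].
#' @export
asTBox <- function(frag, background = NULL) {
  sub <- list()
  defs <- list()
  for (p in frag@subClassAxioms)
    sub[[p[["sub"]]]] <- c(sub[[p[["sub"]]]], p[["super"]])
  for (cl in frag@classes) {
    eq <- Filter(function(a) a$type == "equivalentTo", cl@logicalAxioms)
    if (length(eq) > 1L)
      .dosdpError("dosdp_conflict_error",
                  paste0("class ", cl@iri,
                         " has more than one equivalence axiom"))
    if (length(eq) == 1L) defs[[cl@iri]] <- eq[[1]]$expr
    subs <- Filter(function(a) a$type == "subClassOf" &&
                     is(a$expr, "NamedClass"), cl@logicalAxioms)
    for (s in subs) sub[[cl@iri]] <- c(sub[[cl@iri]], s$expr@curie)
  }
  tb <- tbox(subClassOf = sub, definitions = defs,
             classes = c(names(frag@classes), unlist(sub)))
  if (!is.null(background)) {
    if (is(background, "OntologyFragment")) background <- asTBox(background)
    tb <- mergeTBoxes(tb, background)
  }
  tb
}

#' Merge TBoxes
#'
#' @param ... [TBox-class] objects.
#' @return the merged [TBox-class].
#' @export
mergeTBoxes <- function(...) {
  tbs <- list(...)
  sub <- list(); defs <- list(); rel <- list(); cls <- character(0)
  for (tb in tbs) {
    for (k in names(tb@subClassOf))
      sub[[k]] <- unique(c(sub[[k]], tb@subClassOf[[k]]))
    for (k in names(tb@definitions)) {
      if (!is.null(defs[[k]]) &&
          !identical(exprKey(defs[[k]]), exprKey(tb@definitions[[k]])))
        .dosdpError("dosdp_conflict_error",
                    paste0("conflicting definitions for ", k,
                           " while merging TBoxes"))
      defs[[k]] <- tb@definitions[[k]]
    }
    for (k in names(tb@subPropertyOf))
      rel[[k]] <- unique(c(rel[[k]], tb@subPropertyOf[[k]]))
    cls <- c(cls, tb@classes)
  }
  tbox(subClassOf = sub, definitions = defs, subPropertyOf = rel,
       classes = cls)
}

## reflexive-transitive closure over asserted named subclass edges
.namedAncestors <- function(tb, curie, env = NULL) {
  if (!is.null(env) && !is.null(env$anc[[curie]])) return(env$anc[[curie]])
  seen <- character(0)
  queue <- curie
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    if (x %in% seen) next
    seen <- c(seen, x)
    queue <- c(queue, tb@subClassOf[[x]])
  }
  if (!is.null(env)) env$anc[[curie]] <- seen
  seen
}

.relAncestors <- function(tb, rel) {
  seen <- character(0)
  queue <- rel
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    if (x %in% seen) next
    seen <- c(seen, x)
    queue <- c(queue, tb@subPropertyOf[[x]])
  }
  seen
}

#' Structural subsumption test
#'
#' Decides whether `sub` is subsumed by `super` (`sub` ⊑ `super`) using:
#' reflexive-transitive closure over asserted named subclass axioms,
#' unfolding of definitions (in both directions), conjunction
#' introduction/elimination, disjunct introduction (every disjunct of a
#' subsumee must be subsumed; any disjunct of a subsumer suffices), and
#' existential monotonicity ("p some F" is subsumed by "q some G" when
#' p is a sub-property of q and F is subsumed by G). Sound but
#' deliberately incomplete with respect to
#' full OWL semantics. Complement expressions are not supported here.
#'
#' @param tb a [TBox-class].
#' @param super,sub [ClassExpression-class] objects over the supported
#'   grammar (named, and, or, some).
#' @return logical scalar.
#' @export
subsumes <- function(tb, super, sub) {
  env <- new.env(parent = emptyenv())
  env$cache <- new.env(parent = emptyenv())
  env$anc <- new.env(parent = emptyenv())
  env$stack <- character(0)
  .subs(tb, super, sub, env)
}

.subs <- function(tb, sup, sub, env) {
  if (is(sup, "NotExpression") || is(sub, "NotExpression"))
    .dosdpError("dosdp_unsupported_construct",
                "complement expressions are not supported by the reasoner")
  key <- paste0(exprKey(sup), "⇐", exprKey(sub))
  cached <- env$cache[[key]]
  if (!is.null(cached)) return(cached)
  if (key %in% env$stack) return(FALSE)  # cyclic unfolding: assume false
  env$stack <- c(env$stack, key)
  on.exit(env$stack <- setdiff(env$stack, key))

  res <- FALSE
  if (identical(exprKey(sup), exprKey(sub))) {
    res <- TRUE
  } else if (is(sub, "OrExpression")) {
    res <- all(vapply(sub@operands, function(d)
      .subs(tb, sup, d, env), logical(1)))
  } else if (is(sup, "AndExpression")) {
    res <- all(vapply(sup@operands, function(cj)
      .subs(tb, cj, sub, env), logical(1)))
  } else if (is(sup, "OrExpression")) {
    res <- any(vapply(sup@operands, function(d)
      .subs(tb, d, sub, env), logical(1)))
  } else {
    ## sup is Named or Some; sub is Named, And or Some
    if (is(sub, "NamedClass")) {
      anc <- .namedAncestors(tb, sub@curie, env)
      if (is(sup, "NamedClass") && sup@curie %in% anc) {
        res <- TRUE
      } else {
        for (a in anc) {
          d <- tb@definitions[[a]]
          if (!is.null(d) && .subs(tb, sup, d, env)) { res <- TRUE; break }
        }
      }
    } else if (is(sub, "AndExpression")) {
      res <- any(vapply(sub@operands, function(cj)
        .subs(tb, sup, cj, env), logical(1)))
    } else if (is(sub, "SomeValuesFrom") && is(sup, "SomeValuesFrom")) {
      res <- (sup@relationCurie %in% .relAncestors(tb, sub@relationCurie)) &&
        .subs(tb, sup@filler, sub@filler, env)
    }
    if (!res && is(sup, "NamedClass")) {
      e <- tb@definitions[[sup@curie]]
      if (!is.null(e)) res <- .subs(tb, e, sub, env)
    }
  }
  env$cache[[key]] <- res
  res
}

## transitive reduction of a strict partial order given as a logical
## adjacency matrix (deterministic: inputs are sorted)
.transitiveReduce <- function(pairs, nodes) {
  if (nrow(pairs) == 0L) return(pairs)
  keep <- logical(nrow(pairs))
  rel <- paste(pairs$sub, pairs$super)
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$sub[i]; b <- pairs$super[i]
    mids <- pairs$super[pairs$sub == a]
    mids <- setdiff(mids, b)
    keep[i] <- !any(paste(mids, b) %in% rel)
  }
  out <- pairs[keep, , drop = FALSE]
  out[order(out$sub, out$super), , drop = FALSE]
}

#' Classify an ontology fragment
#'
#' Computes every derivable strict subsumption between named classes of
#' the fragment and the background, then transitively reduces it to the
#' direct (non-redundant) subclass pairs. Mutually equivalent classes are
#' excluded from the edge set.
#'
#' @param frag an [OntologyFragment-class] whose classes carry at most one
#'   definition each.
#' @param background a [TBox-class] (or [OntologyFragment-class]) of
#'   background axioms.
#' @return a data.frame with columns `sub`, `super`: the direct inferred
#'   subclass pairs, sorted.
#' @export
classify <- function(frag, background = NULL) {
  tb <- asTBox(frag, background = background)
  nodes <- sort(unique(c(names(frag@classes), tb@classes)))
  env <- new.env(parent = emptyenv())
  env$cache <- new.env(parent = emptyenv())
  env$anc <- new.env(parent = emptyenv())
  env$stack <- character(0)
  n <- length(nodes)
  le <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  exprs <- lapply(nodes, function(x) namedClass(x, x))
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j)
        le[i, j] <- .subs(tb, exprs[[j]], exprs[[i]], env)
  strict <- le & !t(le)
  idx <- which(strict, arr.ind = TRUE)
  pairs <- data.frame(sub = nodes[idx[, 1]], super = nodes[idx[, 2]],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$sub, pairs$super), , drop = FALSE]
  rownames(pairs) <- NULL
  out <- .transitiveReduce(pairs, nodes)
  rownames(out) <- NULL
  out
}

#' Derive the subsumption hierarchy among patterns
#'
#' Builds one prototype class expression per pattern by substituting each
#' class variable with its declared range expression (the pattern's
#' "default fillers"), then orders the prototypes by structural
#' subsumption: an edge runs from pattern A to pattern B when A's
#' prototype is strictly subsumed by B's. The edge set is transitively
#' reduced. Patterns without an instantiable equivalence template are
#' excluded with a warning.
#'
#' @param patterns list of [PatternDocument-class].
#' @param background a [TBox-class] (or [OntologyFragment-class]) giving
#'   the hierarchy the ranges refer to.
#' @return a list with `nodes` (pattern names) and `edges` (data.frame
#'   `from`, `to`).
#' @export
patternHierarchy <- function(patterns, background) {
  if (is(background, "OntologyFragment")) background <- asTBox(background)
  protos <- list()
  for (doc in patterns) {
    p <- tryCatch(.prototypeExpression(doc), error = function(e) NULL)
    if (is.null(p)) {
      warning("pattern '", doc@patternName,
              "' has no instantiable logical axiom; excluded",
              call. = FALSE)
      next
    }
    protos[[doc@patternName]] <- p
  }
  nodes <- names(protos)
  edges <- data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE)
  env <- new.env(parent = emptyenv())
  env$cache <- new.env(parent = emptyenv())
  env$anc <- new.env(parent = emptyenv())
  env$stack <- character(0)
  for (a in nodes) for (b in nodes) {
    if (a == b) next
    ab <- .subs(background, protos[[b]], protos[[a]], env)
    ba <- .subs(background, protos[[a]], protos[[b]], env)
    if (ab && !ba)
      edges <- rbind(edges, data.frame(from = a, to = b,
                                       stringsAsFactors = FALSE))
  }
  if (nrow(edges)) {
    red <- .transitiveReduce(
      data.frame(sub = edges$from, super = edges$to,
                 stringsAsFactors = FALSE), nodes)
    edges <- data.frame(from = red$sub, to = red$super,
                        stringsAsFactors = FALSE)
    rownames(edges) <- NULL
  }
  list(nodes = nodes, edges = edges)
}

## prototype: equivalence template with each class variable replaced by
## its declared range expression, verbatim
.prototypeExpression <- function(doc) {
  doc <- normalizeObo(doc)
  specs <- Filter(function(s) identical(s@axiomType, "equivalentTo"),
                  .coreLogicalSpecs(doc))
  if (length(specs) == 0L)
    .dosdpError("dosdp_missing_field",
                paste0("pattern '", doc@patternName,
                       "' has no equivalence axiom"))
  spec <- specs[[1]]
  if (is.null(spec@text) || is.null(spec@vars))
    .dosdpError("dosdp_missing_field", "equivalence template is incomplete")
  tmpl <- .templateExpression(doc, spec)
  ranges <- lapply(doc@vars, function(r)
    parseClassExpression(r, classes = doc@classes,
                         relations = doc@relations))
  .substituteVars(tmpl, ranges)
}

.VAR_PREFIX <- "_dosdpvar_:"

## parse a logical template into an AST whose variable conversions become
## placeholder named-class leaves (curie prefix marks them as variables)
.templateExpression <- function(doc, spec) {
  pf <- .parsePrintf(spec@text)
  if (length(spec@vars) != pf$nconv)
    .dosdpError("dosdp_arity_error",
                paste0("ARITY_MISMATCH in logical template: ", spec@text))
  ph <- paste0("__var ", spec@vars, "__")
  text <- pf$segments[1L]
  for (k in seq_len(pf$nconv))
    text <- paste0(text, "'", ph[k], "'", pf$segments[k + 1L])
  classes <- c(doc@classes,
               setNames(paste0(.VAR_PREFIX, spec@vars), ph))
  parseClassExpression(text, classes = classes, relations = doc@relations)
}

.isVarLeaf <- function(e)
  is(e, "NamedClass") && startsWith(e@curie, .VAR_PREFIX)

.varLeafName <- function(e) substring(e@curie, nchar(.VAR_PREFIX) + 1L)

.substituteVars <- function(expr, replacements) {
  if (is(expr, "NamedClass")) {
    if (.isVarLeaf(expr)) {
      r <- replacements[[.varLeafName(expr)]]
      if (is.null(r))
        .dosdpError("dosdp_unbound_var",
                    paste0("no replacement for variable '",
                           .varLeafName(expr), "'"))
      return(r)
    }
    return(expr)
  }
  if (is(expr, "AndExpression"))
    return(intersectionOf(lapply(expr@operands, .substituteVars,
                                 replacements = replacements)))
  if (is(expr, "OrExpression"))
    return(unionOf(lapply(expr@operands, .substituteVars,
                          replacements = replacements)))
  if (is(expr, "NotExpression"))
    return(complementOf(.substituteVars(expr@operand, replacements)))
  if (is(expr, "SomeValuesFrom"))
    return(someValuesFrom(expr@relationLabel,
                          .substituteVars(expr@filler, replacements),
                          expr@relationCurie))
  stop("unknown expression node: ", class(expr))
}

#' Serialise a pattern hierarchy
#'
#' @param hierarchy result of [patternHierarchy()].
#' @return `hierarchyToDot`: a DOT-format digraph; `hierarchyToJSON`: a
#'   JSON edge list.
#' @export
hierarchyToDot <- function(hierarchy) {
  lines <- c("digraph pattern_hierarchy {")
  for (nd in hierarchy$nodes)
    lines <- c(lines, paste0("  \"", nd, "\";"))
  if (nrow(hierarchy$edges))
    for (i in seq_len(nrow(hierarchy$edges)))
      lines <- c(lines, paste0("  \"", hierarchy$edges$from[i],
                               "\" -> \"", hierarchy$edges$to[i], "\";"))
  paste(c(lines, "}"), collapse = "\n")
}

#' @rdname hierarchyToDot
#' @export
hierarchyToJSON <- function(hierarchy) {
  jsonlite::toJSON(list(nodes = hierarchy$nodes,
                        edges = hierarchy$edges),
                   dataframe = "rows", auto_unbox = TRUE, pretty = TRUE)
}
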