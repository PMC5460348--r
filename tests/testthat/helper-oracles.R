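# Independent oracles used by the property tests. These deliberately do
# not share code paths with the package implementation.

# reachability closure over an edge list (sub -> supers), Warshall style
oracleClosure <- function(edges, nodes) {
  n <- length(nodes)
  m <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  diag(m) <- TRUE
  for (s in names(edges))
    for (p in edges[[s]])
      if (s %in% nodes && p %in% nodes) m[s, p] <- TRUE
  for (k in seq_len(n))
    m <- m | (m[, k] %o% m[k, ])
  m
}

# closed-form subsumption oracle for randomTBox() terminologies:
# definitions are genus-differentia conjunctions over primitives only,
# defined classes have no asserted superclasses, so subsumption reduces
# to coverage of normal forms under the primitive/property closures.
oracleLeMatrix <- function(rt) {
  prim <- rt$prim
  defs <- rt$defs
  pc <- oracleClosure(rt$subClassOf, prim)
  rels <- unique(c(names(rt$subPropertyOf), unlist(rt$subPropertyOf),
                   unlist(lapply(defs, function(d)
                     vapply(d$diff, function(x) x[["rel"]], character(1))))))
  rc <- oracleClosure(rt$subPropertyOf, rels)
  nodes <- sort(c(prim, names(defs)))
  le <- matrix(FALSE, length(nodes), length(nodes),
               dimnames = list(nodes, nodes))
  isDef <- nodes %in% names(defs)
  names(isDef) <- nodes
  for (a in nodes) for (b in nodes) {
    le[a, b] <- if (!isDef[a] && !isDef[b]) {
      pc[a, b]
    } else if (isDef[a] && !isDef[b]) {
      any(vapply(defs[[a]]$genus, function(g) pc[g, b], logical(1)))
    } else if (!isDef[a] && isDef[b]) {
      FALSE  # primitives cannot satisfy a differentium
    } else {
      A <- defs[[a]]; B <- defs[[b]]
      genusOk <- all(vapply(B$genus, function(g)
        any(vapply(A$genus, function(g2) pc[g2, g], logical(1))),
        logical(1)))
      diffOk <- all(vapply(B$diff, function(d)
        any(vapply(A$diff, function(d2)
          rc[d2[["rel"]], d[["rel"]]] &&
            pc[d2[["filler"]], d[["filler"]]], logical(1))),
        logical(1)))
      genusOk && diffOk
    }
  }
  le
}

# strict pairs + transitive reduction, written independently of the
# package's reducer
oracleDirectPairs <- function(le) {
  nodes <- rownames(le)
  strict <- le & !t(le)
  diag(strict) <- FALSE
  out <- list()
  for (a in nodes) for (b in nodes) {
    if (!strict[a, b]) next
    direct <- TRUE
    for (c in nodes) {
      if (c == a || c == b) next
      if (strict[a, c] && strict[c, b]) { direct <- FALSE; break }
    }
    if (direct) out[[length(out) + 1L]] <- c(a, b)
  }
  if (length(out) == 0L)
    return(data.frame(sub = character(0), super = character(0),
                      stringsAsFactors = FALSE))
  df <- data.frame(sub = vapply(out, `[`, character(1), 1),
                   super = vapply(out, `[`, character(1), 2),
                   stringsAsFactors = FALSE)
  df <- df[order(df$sub, df$super), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# resolve a validation-report path against the serialised document
resolveReportPath <- function(doc, path) {
  obj <- yaml::yaml.load(serializePattern(doc))
  segs <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- obj
  for (seg in segs) {
    idx <- NULL
    if (grepl("\\[[0-9]+\\]$", seg)) {
      idx <- as.integer(sub(".*\\[([0-9]+)\\]$", "\\1", seg))
      seg <- sub("\\[[0-9]+\\]$", "", seg)
    }
    if (!is.list(node) || !(seg %in% names(node))) return(FALSE)
    node <- node[[seg]]
    if (!is.null(idx)) {
      if (!is.list(node) || idx > length(node)) return(FALSE)
      node <- node[[idx]]
    }
  }
  TRUE
}

# every single-field deletion of a Table-1 mandatory subfield, applied to
# each axiom spec of a document (including nested ones)
mandatoryFieldsFor <- function(kind) {
  switch(kind,
         printf_owl = c("axiomType", "text", "vars"),
         printf_annotation = c("annotationProperty", "text", "vars"),
         list_annotation = c("annotationProperty", "value"),
         printf_owl_convenience = c("text", "vars"),
         printf_annotation_obo = c("text", "vars"),
         list_annotation_obo = c("value"))
}

specMutants <- function(spec) {
  out <- list()
  for (f in mandatoryFieldsFor(spec@specKind)) {
    s2 <- spec
    slot(s2, f) <- NULL
    out[[length(out) + 1L]] <- s2
  }
  for (j in seq_along(spec@annotations)) {
    for (m in specMutants(spec@annotations[[j]])) {
      s2 <- spec
      s2@annotations[[j]] <- m
      out[[length(out) + 1L]] <- s2
    }
  }
  out
}

docMutants <- function(doc) {
  out <- list()
  for (i in seq_along(doc@annotationAxioms)) {
    for (m in specMutants(doc@annotationAxioms[[i]])) {
      d2 <- doc
      d2@annotationAxioms[[i]] <- m
      out[[length(out) + 1L]] <- d2
    }
  }
  for (i in seq_along(doc@logicalAxioms)) {
    for (m in specMutants(doc@logicalAxioms[[i]])) {
      d2 <- doc
      d2@logicalAxioms[[i]] <- m
      out[[length(out) + 1L]] <- d2
    }
  }
  out
}

# structural fingerprint of a fragment: identifiers, annotations and
# expression shapes (CURIE-based), ignoring presentation labels that a
# standalone file cannot carry
fragStructuralKey <- function(frag) {
  annKey <- function(a)
    paste0(a$property, "=", a$value, "^",
           if (is.null(a$datatype)) "" else a$datatype, "[",
           paste(vapply(a$annotations, annKey, character(1)),
                 collapse = ","), "]")
  axKey <- function(x)
    paste0(x$type, ":", exprKey(x$expr),
           if (!is.null(x$expr2)) paste0("<", exprKey(x$expr2)) else "")
  clsKey <- function(cl)
    paste0(cl@iri, "{",
           paste(vapply(cl@annotations, annKey, character(1)),
                 collapse = ";"), "}{",
           paste(vapply(cl@logicalAxioms, axKey, character(1)),
                 collapse = ";"), "}")
  paste(c(vapply(frag@classes, clsKey, character(1)),
          vapply(frag@subClassAxioms, function(p)
            paste(p[["sub"]], "<", p[["super"]]), character(1)),
          names(frag@objectProperties)),
        collapse = "\n")
}

# fixture dictionaries in parse-ready form
fixtureClassDict <- function() labelIndex(makeFixtureOntology())
fixtureRelationDict <- function() {
  op <- makeFixtureOntology()@objectProperties
  setNames(names(op), unname(op))
}

# one generated class merged into the fixture ontology
fragmentWith <- function(..., ontology = makeFixtureOntology()) {
  cls <- list(...)
  names(cls) <- vapply(cls, function(x) x@iri, character(1))
  mergeFragments(ontology, ontologyFragment(classes = cls))
}
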