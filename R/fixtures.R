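## Self-contained test corpus: a miniature chemistry/process ontology in
## the style of the ChEBI-backed transport branch of the GO, the
## transmembrane-transport example pattern, and seeded random patterns,
## expressions and terminologies for property testing. Fixture entities
## live in a reserved example namespace (EX) rather than real CHEBI/GO/RO
## identifiers, to avoid false provenance.

## run code under a seed without clobbering the caller's RNG state
.withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.FIXTURE_CLASSES <- c(
  "transport" = "EX:0000001",
  "chemical entity" = "EX:0000002",
  "amino acid" = "EX:0000003",
  "leucine" = "EX:0000004",
  "glycine" = "EX:0000005",
  "serine" = "EX:0000006",
  "transcript" = "EX:0000007",
  "membrane" = "EX:0000008",
  "plasma membrane" = "EX:0000009"
)

.FIXTURE_RELATIONS <- c(
  "transports" = "EX:2000001",
  "crosses" = "EX:2000002"
)

.FIXTURE_SUBCLASS <- list(
  c(sub = "EX:0000003", super = "EX:0000002"),  # amino acid < chemical entity
  c(sub = "EX:0000004", super = "EX:0000003"),  # leucine < amino acid
  c(sub = "EX:0000005", super = "EX:0000003"),  # glycine < amino acid
  c(sub = "EX:0000006", super = "EX:0000003"),  # serine < amino acid
  c(sub = "EX:0000009", super = "EX:0000008")   # plasma membrane < membrane
)

#' Prefix context for the fixture namespace
#'
#' The example namespace `EX` on top of the standard OBO/OWL prefixes.
#'
#' @return a [PrefixContext-class].
#' @export
fixtureContext <- function() {
  mergeContexts(defaultContext(),
                prefixContext(EX = "http://example.org/EX_"))
}

#' The miniature fixture ontology
#'
#' Nine labelled classes — a chemical-entity branch (`chemical entity` >
#' `amino acid` > leucine/glycine/serine), `transcript`, a membrane branch
#' (`membrane` > `plasma membrane`) and the process genus `transport` —
#' plus the object properties `transports` and `crosses`. Deterministic by
#' construction.
#'
#' @return an [OntologyFragment-class].
#' @export
makeFixtureOntology <- function() {
  classes <- list()
  for (lab in names(.FIXTURE_CLASSES)) {
    iri <- unname(.FIXTURE_CLASSES[[lab]])
    classes[[iri]] <- new("GeneratedClass", iri = iri,
                          annotations = list(list(property = "rdfs:label",
                                                  value = lab,
                                                  datatype = NULL,
                                                  annotations = list())),
                          logicalAxioms = list())
  }
  ontologyFragment(classes = classes,
                   subClassAxioms = .FIXTURE_SUBCLASS,
                   objectProperties = setNames(names(.FIXTURE_RELATIONS),
                                               .FIXTURE_RELATIONS))
}

#' The transmembrane-transport example pattern
#'
#' An OBO-extension pattern with class variables `cargo` (range
#' `'chemical entity' or 'transcript'`) and `membrane` (range
#' `'membrane'`), a data list variable `def_dbxref` of XSD strings, a name
#' template `"%s transport across the %s"`, a definition template whose
#' cross-references come from `def_dbxref`, and an equivalence template
#' `'transport' and ('transports' some %s) and ('crosses' some %s)`.
#'
#' @return a [PatternDocument-class] (un-normalised OBO form).
#' @export
makeTransmembranePattern <- function() {
  readPattern(system.file("extdata", "transmembrane_transport.yaml",
                          package = "dosdp", mustWork = TRUE))
}

#' A cargo-restricted variant of the transmembrane pattern
#'
#' Identical to [makeTransmembranePattern()] but with the `cargo` range
#' restricted to `'amino acid'`; its prototype is therefore subsumed by
#' the general pattern's, giving the pattern hierarchy a single edge.
#'
#' @return a [PatternDocument-class].
#' @export
makeAminoAcidTransportPattern <- function() {
  doc <- makeTransmembranePattern()
  doc@patternName <- "amino_acid_transmembrane_transport"
  doc@patternIRI <-
    "http://example.org/patterns/amino_acid_transmembrane_transport.yaml"
  doc@vars[["cargo"]] <- "'amino acid'"
  doc
}

#' The worked-example binding (leucine across the plasma membrane)
#'
#' @param def_dbxref cross-reference literals for the definition axiom.
#' @return a [Binding-class].
#' @export
leucineBinding <- function(def_dbxref = c("PMID:1", "GOC:dos")) {
  binding(
    classFillers = list(
      cargo = entityRef("leucine", "EX:0000004"),
      membrane = entityRef("plasma membrane", "EX:0000009")),
    listFillers = list(def_dbxref = def_dbxref))
}

## descendants-or-self in the fixture hierarchy, by label
.fixtureDescendants <- function(label) {
  switch(label,
    "chemical entity" = c("chemical entity", "amino acid", "leucine",
                          "glycine", "serine"),
    "amino acid" = c("amino acid", "leucine", "glycine", "serine"),
    "membrane" = c("membrane", "plasma membrane"),
    "transcript" = "transcript",
    label)
}

#' Random class expressions over the fixture vocabulary
#'
#' Used for parser/printer round-trip property tests: depth at most 4,
#' at most 8 named leaves, drawing operators from and/or/not/some.
#' Reproducible from the seed.
#'
#' @param seed integer seed.
#' @param n number of expressions.
#' @return list of [ClassExpression-class].
#' @export
randomExpressions <- function(seed, n) {
  gen <- function(depth) {
    kind <- if (depth <= 0L) "named"
            else sample(c("named", "some", "and", "or", "not"), 1,
                        prob = c(0.40, 0.25, 0.15, 0.15, 0.05))
    switch(kind,
      named = {
        lab <- sample(names(.FIXTURE_CLASSES), 1)
        namedClass(lab, unname(.FIXTURE_CLASSES[[lab]]))
      },
      some = {
        rel <- sample(names(.FIXTURE_RELATIONS), 1)
        someValuesFrom(rel, gen(depth - 1L),
                       unname(.FIXTURE_RELATIONS[[rel]]))
      },
      and = intersectionOf(lapply(seq_len(2L), function(i) gen(depth - 1L))),
      or = unionOf(lapply(seq_len(2L), function(i) gen(depth - 1L))),
      not = complementOf(gen(depth - 1L)))
  }
  .withSeed(seed, lapply(seq_len(n), function(i) gen(sample(1:3, 1))))
}

## random-pattern corpus -----------------------------------------------------

.RANGE_POOL <- c("'chemical entity'", "'amino acid'", "'membrane'",
                 "'chemical entity' or 'transcript'")

.rangeFillerLabels <- function(rangeText) {
  labs <- regmatches(rangeText, gregexpr("'[^']+'", rangeText))[[1]]
  labs <- gsub("'", "", labs)
  unique(unlist(lapply(labs, .fixtureDescendants)))
}

.randomPatternDoc <- function(i, nv) {
  connectors <- c("involving %s", "affecting %s", "mediated via %s")
  ranges <- character(0)
  if (nv >= 1L) ranges["v1"] <- sample(.RANGE_POOL, 1)
  if (nv >= 2L) ranges["v2"] <- sample(.RANGE_POOL, 1)
  if (nv >= 3L) ranges["v3"] <- "'membrane'"
  nameText <- paste0("transport process ", i, " ",
                     paste(connectors[seq_len(nv)], collapse = " "))
  defText <- paste0("A transport process (kind ", i, ") ",
                    paste(connectors[seq_len(nv)], collapse = " "), ".")
  eqParts <- c("'transport'",
               if (nv >= 1L) "('transports' some %s)",
               if (nv >= 2L) "('crosses' some %s)",
               if (nv >= 3L) "%s")
  eqText <- paste(eqParts, collapse = " and ")
  vars <- paste0("v", seq_len(nv))
  annProps <- c("label" = "rdfs:label", "definition" = "IAO:0000115",
                "database_cross_reference" = "oboInOwl:hasDbXref")
  labelSpec <- new("AxiomSpec", specKind = "printf_annotation",
                   axiomType = "annotation",
                   annotationProperty = "label",
                   text = nameText, vars = vars)
  xrefSpec <- new("AxiomSpec", specKind = "list_annotation",
                  axiomType = "annotation",
                  annotationProperty = "database_cross_reference",
                  value = "def_dbxref")
  defSpec <- new("AxiomSpec", specKind = "printf_annotation",
                 axiomType = "annotation",
                 annotationProperty = "definition",
                 text = defText, vars = vars,
                 annotations = list(xrefSpec))
  eqSpec <- new("AxiomSpec", specKind = "printf_owl",
                axiomType = "equivalentTo", text = eqText, vars = vars)
  new("PatternDocument",
      patternName = sprintf("random_pattern_%03d", i),
      patternIRI = sprintf("http://example.org/patterns/random_pattern_%03d.yaml", i),
      extension = "core",
      description = paste0("Randomised test pattern ", i, "."),
      classes = .FIXTURE_CLASSES,
      relations = .FIXTURE_RELATIONS,
      annotationProperties = annProps,
      readableIdentifier = "label",
      vars = ranges,
      dataListVars = c(def_dbxref = "xsd:string"),
      annotationAxioms = list(labelSpec, defSpec),
      logicalAxioms = list(eqSpec))
}

.randomBindingFor <- function(doc) {
  cf <- list()
  for (v in names(doc@vars)) {
    lab <- sample(.rangeFillerLabels(doc@vars[[v]]), 1)
    cf[[v]] <- entityRef(lab, unname(.FIXTURE_CLASSES[[lab]]))
  }
  nx <- sample(0:3, 1)
  xr <- if (nx > 0L)
    sample(c("PMID:1234", "PMID:42", "GOC:ab", "ISBN:0123456789"), nx)
  else character(0)
  binding(classFillers = cf, listFillers = list(def_dbxref = xr))
}

#' Seeded corpus of random patterns with bindings
#'
#' Generates `n` valid core-form patterns over the fixture vocabulary
#' (one to three class variables, ranges drawn from the fixture
#' hierarchy, label/definition/equivalence templates and a `def_dbxref`
#' list variable) with three bindings each. The expected label recorded
#' for each binding is computed independently of the template engine,
#' with base `sprintf`. Byte-identical regeneration from the same seed.
#'
#' @param seed integer seed.
#' @param n number of patterns (>= 1).
#' @return a list with elements `ontology`, `patterns`, `bindings`
#'   (each a list of `pattern` index, `binding`, `expectedLabel`) and
#'   `seed`.
#' @export
randomPatterns <- function(seed, n) {
  stopifnot(n >= 1L)
  .withSeed(seed, {
    patterns <- lapply(seq_len(n), function(i)
      .randomPatternDoc(i, sample(1:3, 1)))
    bindings <- list()
    for (i in seq_len(n)) {
      for (k in 1:3) {
        b <- .randomBindingFor(patterns[[i]])
        labelSpec <- patterns[[i]]@annotationAxioms[[1]]
        labs <- vapply(labelSpec@vars, function(v)
          b@classFillers[[v]]$label, character(1))
        expected <- do.call(sprintf, c(list(labelSpec@text), as.list(labs)))
        bindings[[length(bindings) + 1L]] <-
          list(pattern = i, binding = b, expectedLabel = expected)
      }
    }
    list(ontology = makeFixtureOntology(), patterns = patterns,
         bindings = bindings, seed = seed)
  })
}

## random terminologies ------------------------------------------------------

#' A random terminology for reasoner testing
#'
#' Builds a random primitive class hierarchy (a DAG of up to 24 classes),
#' up to 3 object properties (occasionally with sub-property axioms), and
#' 3-6 defined classes whose definitions are genus-differentia
#' conjunctions over primitive classes. Definitions reference primitive
#' classes only and are pairwise distinct, so a closed-form normal-form
#' comparison can serve as an independent oracle for classification.
#'
#' @param seed integer seed.
#' @return a list: `background` ([TBox-class] of primitives and
#'   properties), `frag` ([OntologyFragment-class] holding the defined
#'   classes), `prim` (primitive CURIEs), `subClassOf`, `subPropertyOf`,
#'   and `defs` (normal forms: per defined class, `genus` labels and
#'   `diff` relation/filler pairs).
#' @export
randomTBox <- function(seed) {
  .withSeed(seed, {
    nprim <- sample(10:22, 1)
    prim <- sprintf("T:%07d", seq_len(nprim))
    sub <- list()
    for (i in seq(2L, nprim)) {
      np <- sample(0:2, 1, prob = c(0.2, 0.6, 0.2))
      if (np > 0L) {
        parents <- sample(prim[seq_len(i - 1L)], min(np, i - 1L))
        sub[[prim[i]]] <- parents
      }
    }
    nrel <- sample(1:3, 1)
    rels <- sprintf("R:%07d", seq_len(nrel))
    relSub <- list()
    if (nrel >= 2L && runif(1) < 0.5) relSub[[rels[2]]] <- rels[1]
    if (nrel >= 3L && runif(1) < 0.5) relSub[[rels[3]]] <- rels[1]
    ndef <- sample(3:6, 1)
    defs <- list()
    classes <- list()
    seen <- character(0)
    made <- 0L
    while (made < ndef) {
      genus <- sample(prim, sample(1:2, 1))
      k <- sample(1:2, 1)
      diff <- lapply(seq_len(k), function(j)
        c(rel = sample(rels, 1), filler = sample(prim, 1)))
      ops <- c(lapply(genus, function(g) namedClass(g, g)),
               lapply(diff, function(d)
                 someValuesFrom(d[["rel"]],
                                namedClass(d[["filler"]], d[["filler"]]),
                                d[["rel"]])))
      expr <- intersectionOf(ops)
      key <- exprKey(expr)
      if (key %in% seen) next
      seen <- c(seen, key)
      made <- made + 1L
      iri <- sprintf("D:%07d", made)
      defs[[iri]] <- list(genus = genus, diff = diff)
      classes[[iri]] <- new("GeneratedClass", iri = iri,
                            annotations = list(),
                            logicalAxioms = list(
                              list(type = "equivalentTo", expr = expr,
                                   expr2 = NULL)))
    }
    background <- tbox(subClassOf = sub, subPropertyOf = relSub,
                       classes = prim)
    frag <- ontologyFragment(classes = classes)
    list(background = background, frag = frag, prim = prim,
         subClassOf = sub, subPropertyOf = relSub, defs = defs)
  })
}

#' Write the fixture corpus to a directory
#'
#' Emits the example pattern and its cargo-restricted variant (YAML), the
#' fixture ontology (OWL functional-style syntax), the filler table
#' (TSV), and the prefix context (JSON).
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed recorded for corpus regeneration.
#' @return invisibly, the paths written.
#' @export
writeFixtures <- function(dir, seed = 42L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  paths <- c(paths, writePattern(makeTransmembranePattern(), dir))
  paths <- c(paths, writePattern(makeAminoAcidTransportPattern(), dir))
  ofn <- file.path(dir, "fixture_ontology.ofn")
  writeFragment(makeFixtureOntology(), fixtureContext(), file = ofn)
  paths <- c(paths, ofn)
  tsv <- file.path(dir, "transmembrane_fillers.tsv")
  file.copy(system.file("extdata", "transmembrane_fillers.tsv",
                        package = "dosdp", mustWork = TRUE), tsv,
            overwrite = TRUE)
  paths <- c(paths, tsv)
  ctx <- file.path(dir, "prefix_context.json")
  jsonlite::write_json(as.list(fixtureContext()@mapping), ctx,
                       auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, ctx)
  invisible(paths)
}
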