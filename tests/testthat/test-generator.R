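# Instantiation, batch generation, and OWL functional-syntax round trips.

test_that("the worked example instantiates label, xrefs and equivalence", {
  pat <- makeTransmembranePattern()
  gc <- instantiate(pat, leucineBinding(), "EX:1000001")
  labels <- Filter(function(a) a$property == "rdfs:label", gc@annotations)
  expect_length(labels, 1)
  expect_identical(labels[[1]]$value,
                   "leucine transport across the plasma membrane")
  defs <- Filter(function(a) a$property == "IAO:0000115", gc@annotations)
  expect_length(defs, 1)
  xrefs <- defs[[1]]$annotations
  expect_length(xrefs, 2)
  expect_setequal(vapply(xrefs, function(x) x$value, character(1)),
                  c("PMID:1", "GOC:dos"))
  expect_true(all(vapply(xrefs, function(x)
    x$property == "oboInOwl:hasDbXref", logical(1))))
  eq <- Filter(function(a) a$type == "equivalentTo", gc@logicalAxioms)
  expect_length(eq, 1)
  expect_identical(
    toManchester(eq[[1]]$expr),
    "transport and (transports some leucine) and (crosses some 'plasma membrane')")
})

test_that("an empty cross-reference list yields zero axiom annotations", {
  pat <- makeTransmembranePattern()
  gc <- instantiate(pat, leucineBinding(def_dbxref = character(0)),
                    "EX:1000001")
  defs <- Filter(function(a) a$property == "IAO:0000115", gc@annotations)
  expect_length(defs[[1]]$annotations, 0)
})

test_that("strict instantiation rejects fillers outside the variable range", {
  pat <- makeTransmembranePattern()
  ont <- makeFixtureOntology()
  bad <- binding(
    classFillers = list(cargo = entityRef("plasma membrane", "EX:0000009"),
                        membrane = entityRef("plasma membrane", "EX:0000009")),
    listFillers = list(def_dbxref = character(0)))
  # oracle: brute-force closure over the fixture hierarchy shows
  # plasma membrane reaches only membrane, never chemical entity/transcript
  edges <- list()
  for (p in makeFixtureOntology()@subClassAxioms)
    edges[[p[["sub"]]]] <- c(edges[[p[["sub"]]]], p[["super"]])
  closure <- oracleClosure(edges, unname(fixtureClassDict()))
  expect_false(closure["EX:0000009", "EX:0000002"] ||
                 closure["EX:0000009", "EX:0000007"])
  err <- tryCatch(
    instantiate(pat, bad, "EX:1000001", ontology = ont, strict = TRUE),
    error = function(e) e)
  expect_s3_class(err, "dosdp_range_violation")
  expect_match(conditionMessage(err), "cargo")
  expect_match(conditionMessage(err), "plasma membrane")
  expect_match(conditionMessage(err), "chemical entity")
  # the lenient default accepts the same binding
  expect_s4_class(instantiate(pat, bad, "EX:1000001", ontology = ont),
                  "GeneratedClass")
})

test_that("instantiation is pure: repeated calls are identical", {
  pat <- makeTransmembranePattern()
  expect_identical(instantiate(pat, leucineBinding(), "EX:1000001"),
                   instantiate(pat, leucineBinding(), "EX:1000001"))
})

test_that("annotation axiom count follows the printf + list-length law", {
  # a pattern with a top-level list spec in addition to two printf specs
  doc <- randomPatterns(21, 1)$patterns[[1]]
  topList <- new("AxiomSpec", specKind = "list_annotation",
                 axiomType = "annotation",
                 annotationProperty = "database_cross_reference",
                 value = "def_dbxref")
  doc@annotationAxioms <- c(doc@annotationAxioms, list(topList))
  corpus <- randomPatterns(22, 4)
  for (bb in corpus$bindings) {
    b <- bb$binding
    cf <- b@classFillers[intersect(names(doc@vars), names(b@classFillers))]
    if (length(cf) != length(doc@vars)) next
    b2 <- binding(classFillers = cf, listFillers = b@listFillers)
    gc <- instantiate(doc, b2, "EX:1000001")
    nPrintf <- 2L
    nList <- length(b2@listFillers$def_dbxref)
    expect_length(gc@annotations, nPrintf + nList)
  }
})

test_that("batch generation mints one class per row, deterministically", {
  pat <- makeTransmembranePattern()
  ont <- makeFixtureOntology()
  tab <- readFillerTable(system.file("extdata", "transmembrane_fillers.tsv",
                                     package = "dosdp"))
  frag <- generateBatch(pat, tab, mintingPolicy("EX", start = 1000001L),
                        ontology = ont)
  expect_length(fragmentClasses(frag), 3)
  expect_identical(names(fragmentClasses(frag)),
                   c("EX:1000001", "EX:1000002", "EX:1000003"))
  labs <- sort(names(labelIndex(frag)))
  expect_identical(labs, sort(paste0(
    c("glycine", "leucine", "serine"),
    " transport across the plasma membrane")))
})

test_that("explicit iri columns pin identifiers across row shuffles", {
  pat <- makeTransmembranePattern()
  tab <- readFillerTable(system.file("extdata", "transmembrane_fillers.tsv",
                                     package = "dosdp"))
  tab$iri <- c("EX:1000010", "EX:1000011", "EX:1000012")
  f1 <- generateBatch(pat, tab, ontology = makeFixtureOntology())
  f2 <- generateBatch(pat, tab[c(3, 1, 2), ],
                      ontology = makeFixtureOntology())
  expect_identical(f1, f2)
})

test_that("duplicate rows collapse with a warning; collisions error", {
  pat <- makeTransmembranePattern()
  ont <- makeFixtureOntology()
  tab <- readFillerTable(system.file("extdata", "transmembrane_fillers.tsv",
                                     package = "dosdp"))
  dup <- rbind(tab, tab[1, ])
  expect_warning(
    frag <- generateBatch(pat, dup, ontology = ont),
    "duplicate")
  expect_length(fragmentClasses(frag), 3)
  tab$iri <- c("EX:1000010", "EX:1000010", "EX:1000012")
  expect_error(generateBatch(pat, tab, ontology = ont),
               class = "dosdp_conflict_error")
  bad <- tab[, c("membrane", "def_dbxref")]
  expect_error(generateBatch(pat, bad, ontology = ont),
               class = "dosdp_arity_error")
})

test_that("an empty fragment writes to a bare prefixed document", {
  txt <- writeFragment(ontologyFragment(), fixtureContext())
  lines <- strsplit(txt, "\n")[[1]]
  expect_true(all(grepl("^Prefix\\(|^Ontology\\($|^\\)$", lines)))
  back <- readFragment(txt)
  expect_length(fragmentClasses(back), 0)
})

test_that("the leucine fragment re-parses with the expected axiom kinds", {
  pat <- makeTransmembranePattern()
  gc <- instantiate(pat, leucineBinding(), "EX:1000001")
  frag <- ontologyFragment(classes = list("EX:1000001" = gc))
  back <- readFragment(writeFragment(frag, fixtureContext()))
  cl <- fragmentClasses(back)[["EX:1000001"]]
  # oracle: count axiom kinds after the round trip
  expect_length(Filter(function(a) a$type == "equivalentTo",
                       cl@logicalAxioms), 1)
  expect_length(Filter(function(a) a$property == "rdfs:label",
                       cl@annotations), 1)
  defs <- Filter(function(a) a$property == "IAO:0000115", cl@annotations)
  expect_length(defs[[1]]$annotations, 2)
})

test_that("write/read round trip is the identity on batch outputs", {
  corpus <- randomPatterns(50, 5)
  ont <- corpus$ontology
  count <- 0L
  for (i in seq_along(corpus$patterns)) {
    doc <- corpus$patterns[[i]]
    cls <- list()
    for (bb in Filter(function(x) x$pattern == i, corpus$bindings)) {
      count <- count + 1L
      iri <- sprintf("EX:%07d", 5000000L + count)
      cls[[iri]] <- instantiate(doc, bb$binding, iri)
    }
    frag <- ontologyFragment(classes = cls)
    # a standalone file cannot carry labels of external entities, so the
    # round trip preserves structure (CURIE-based), and full identity
    # once the labelled background travels along
    back <- readFragment(writeFragment(frag, fixtureContext()))
    expect_identical(fragStructuralKey(back), fragStructuralKey(frag))
    withBg <- mergeFragments(makeFixtureOntology(), frag)
    expect_identical(readFragment(writeFragment(withBg, fixtureContext())),
                     withBg)
  }
  full <- mergeFragments(ont, makeFixtureOntology())
  expect_identical(readFragment(writeFragment(full, fixtureContext())),
                   full)
})

test_that("a hand-written toy hierarchy file parses to the stated counts", {
  txt <- paste(
    "Prefix(T:=<http://example.org/T_>)",
    "Prefix(rdfs:=<http://www.w3.org/2000/01/rdf-schema#>)",
    "Ontology(",
    "Declaration(Class(T:1))",
    "Declaration(Class(T:2))",
    "Declaration(Class(T:3))",
    "Declaration(Class(T:4))",
    "Declaration(Class(T:5))",
    "AnnotationAssertion(rdfs:label T:1 \"root\")",
    "SubClassOf(T:2 T:1)",
    "SubClassOf(T:3 T:1)",
    "SubClassOf(T:4 T:2)",
    "SubClassOf(T:5 T:4)",
    ")", sep = "\n")
  frag <- readFragment(txt)
  expect_length(fragmentClasses(frag), 5)   # manual count in fixture text
  expect_length(frag@subClassAxioms, 4)
  expect_identical(classLabel(frag, "T:1"), "root")
})

test_that("unsupported axioms are skipped leniently and rejected strictly", {
  txt <- paste(
    "Prefix(T:=<http://example.org/T_>)",
    "Ontology(",
    "Declaration(Class(T:1))",
    "SubObjectPropertyOf(ObjectPropertyChain(T:8 T:9) T:8)",
    ")", sep = "\n")
  expect_warning(frag <- readFragment(txt), "unsupported axiom")
  expect_length(fragmentClasses(frag), 1)
  expect_error(readFragment(txt, strict = TRUE),
               class = "dosdp_unsupported_axiom")
})
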