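# Pattern document model: parsing, JSON-subset enforcement, CURIE
# expansion, OBO normalisation, serialisation round trips, validation.

test_that("a minimal document parses to an empty pattern", {
  doc <- parsePattern("pattern_name: minimal\n")
  expect_s4_class(doc, "PatternDocument")
  expect_identical(patternName(doc), "minimal")
  expect_length(patternVars(doc), 0)
  expect_length(doc@annotationAxioms, 0)
  expect_length(doc@logicalAxioms, 0)
  expect_identical(doc@extension, "core")
})

test_that("the transmembrane fixture parses with the documented variables", {
  doc <- makeTransmembranePattern()
  expect_identical(doc@extension, "obo")
  expect_named(patternVars(doc), c("cargo", "membrane"))
  rng <- parseClassExpression(patternVars(doc)[["cargo"]],
                              classes = doc@classes,
                              relations = doc@relations)
  expect_s4_class(rng, "OrExpression")
  leaves <- sort(vapply(rng@operands, function(x) x@label, character(1)))
  expect_identical(leaves, c("chemical entity", "transcript"))
  expect_identical(doc@dataListVars[["def_dbxref"]], "xsd:string")
})

test_that("missing pattern_name raises a named missing-field error", {
  expect_error(parsePattern("description: no name here\n"),
               class = "dosdp_missing_field")
  expect_error(parsePattern("description: no name here\n"),
               "pattern_name")
})

test_that("YAML constructs outside the JSON subset are rejected", {
  expect_error(
    parsePattern("pattern_name: x\nclasses: &a {foo: 'EX:1'}\nextra: *a\n"),
    class = "dosdp_json_subset_error")
  expect_error(
    parsePattern("pattern_name: x\na: &anchor 1\n"),
    class = "dosdp_json_subset_error")
  expect_error(
    parsePattern("pattern_name: x\nd:\n  <<: {a: 1}\n"),
    class = "dosdp_json_subset_error")
  expect_error(
    parsePattern("pattern_name: x\nn: !!str 5\n"),
    class = "dosdp_json_subset_error")
})

test_that("CURIE expansion concatenates and inverts exactly", {
  ctx <- prefixContext(EX = "http://example.org/EX_")
  expect_identical(expandCurie("EX:0000003", ctx),
                   "http://example.org/EX_0000003")
  expect_error(expandCurie("NOPREFIX:1", ctx),
               class = "dosdp_unresolved_prefix")
  ## round trip over every dictionary value of the fixture pattern
  doc <- makeTransmembranePattern()
  full <- fixtureContext()
  for (curie in unname(patternDictionary(doc))) {
    expect_identical(compactIri(expandCurie(curie, full), full), curie)
  }
})

test_that("prefix contexts enforce IRI-base invariants", {
  expect_error(prefixContext(EX = "not an iri"), "absolute IRI")
  expect_error(prefixContext(EX = "http://example.org/EX"),
               "must end in")
  expect_error(validObject(new("PrefixContext",
                               mapping = c(A = "http://x.org/",
                                           A = "http://y.org/"))),
               "unique")
})

test_that("OBO normalisation rewrites slots to core annotation specs", {
  doc <- makeTransmembranePattern()
  core <- normalizeObo(doc)
  expect_identical(core@extension, "core")
  kinds <- vapply(core@annotationAxioms, function(s) s@specKind,
                  character(1))
  expect_identical(sort(kinds),
                   c("printf_annotation", "printf_annotation"))
  props <- vapply(core@annotationAxioms, function(s) s@annotationProperty,
                  character(1))
  expect_setequal(props, c("label", "definition"))
  ## the name slot keeps its template on the label property
  lab <- core@annotationAxioms[[
    which(props == "label")]]
  expect_identical(lab@text, "%s transport across the %s")
  expect_identical(unname(core@annotationProperties[["label"]]),
                   "rdfs:label")
  ## def xrefs became a nested list_annotation on the cross-ref property
  def <- core@annotationAxioms[[which(props == "definition")]]
  expect_length(def@annotations, 1)
  nested <- def@annotations[[1]]
  expect_identical(nested@specKind, "list_annotation")
  expect_identical(nested@annotationProperty, "database_cross_reference")
  expect_identical(nested@value, "def_dbxref")
  expect_identical(
    unname(core@annotationProperties[["database_cross_reference"]]),
    "oboInOwl:hasDbXref")
  ## defaults
  expect_identical(core@readableIdentifier, "label")
  expect_identical(core@baseIRI, "http://purl.obolibrary.org/obo/")
})

test_that("OBO normalisation is idempotent and fixes core documents", {
  doc <- makeTransmembranePattern()
  once <- normalizeObo(doc)
  expect_identical(normalizeObo(once), once)
  corpus <- randomPatterns(11, 2)
  for (p in corpus$patterns)
    expect_identical(normalizeObo(p), p)
})

test_that("an OBO slot conflicting with an explicit spec is an error", {
  doc <- makeTransmembranePattern()
  ## an explicit core annotation spec targeting rdfs:label alongside the
  ## name slot
  doc@annotationProperties <- c(doc@annotationProperties,
                                label = "rdfs:label")
  explicit <- new("AxiomSpec", specKind = "printf_annotation",
                  axiomType = "annotation", annotationProperty = "label",
                  text = "another %s label", vars = "cargo")
  doc@annotationAxioms <- c(doc@annotationAxioms, list(explicit))
  expect_error(normalizeObo(doc), class = "dosdp_conflict_error")
  ## and a dictionary collision on the mapped label
  doc2 <- makeTransmembranePattern()
  doc2@annotationProperties <- c(doc2@annotationProperties,
                                 label = "EX:9999999")
  expect_error(normalizeObo(doc2), class = "dosdp_conflict_error")
})

test_that("parse and serialize are inverse on fixtures and random patterns", {
  doc <- makeTransmembranePattern()
  expect_equal(parsePattern(serializePattern(doc)), doc)
  core <- normalizeObo(doc)
  expect_equal(parsePattern(serializePattern(core)), core)
  corpus <- randomPatterns(5, 5)
  for (p in corpus$patterns)
    expect_equal(parsePattern(serializePattern(p)), p)
  ## unknown keys round-trip through the extras slot
  withExtra <- parsePattern(paste0(serializePattern(doc),
                                   "custom_key: kept\n"))
  expect_identical(withExtra@extras$custom_key, "kept")
  expect_equal(parsePattern(serializePattern(withExtra)), withExtra)
})

test_that("validation reports arity and undeclared-entity violations", {
  doc <- normalizeObo(makeTransmembranePattern())
  ## two conversions, one listed var
  broken <- doc
  broken@annotationAxioms[[1]]@vars <- "cargo"
  rep <- validatePattern(broken)
  expect_true("ARITY_MISMATCH" %in% rep$code)
  ## quoted label absent from all dictionaries
  broken2 <- doc
  broken2@logicalAxioms[[1]]@text <-
    "'transport' and ('transports' some %s) and ('teleports' some %s)"
  rep2 <- validatePattern(broken2)
  expect_true("UNDECLARED_ENTITY" %in% rep2$code)
  ## the fixture itself is clean
  expect_identical(nrow(validatePattern(doc, fixtureContext())), 0L)
  expect_true(isValidPattern(doc, fixtureContext()))
})

test_that("validation flags unknown keys, bad datatypes, bad prefixes", {
  doc <- makeTransmembranePattern()
  doc@extras <- list(mystery = 1)
  rep <- validatePattern(doc)
  expect_identical(rep$severity[rep$code == "UNKNOWN_KEY"], "WARNING")
  expect_true(isValidPattern(doc))  # warnings do not invalidate
  repS <- validatePattern(doc, strict = TRUE)
  expect_identical(repS$severity[repS$code == "UNKNOWN_KEY"], "ERROR")
  doc2 <- makeTransmembranePattern()
  doc2@dataListVars[["def_dbxref"]] <- "xsd:nonsense"
  expect_true("UNKNOWN_DATATYPE" %in% validatePattern(doc2)$code)
  doc3 <- makeTransmembranePattern()
  doc3@classes[["transport"]] <- "UNBOUND:1"
  rep3 <- validatePattern(doc3, fixtureContext())
  expect_true("UNRESOLVED_PREFIX" %in% rep3$code)
})

test_that("every mandatory-subfield deletion is caught by validation", {
  docs <- list(normalizeObo(makeTransmembranePattern()),
               randomPatterns(3, 1)$patterns[[1]])
  total <- 0L
  killed <- 0L
  for (doc in docs) {
    for (mut in docMutants(doc)) {
      total <- total + 1L
      rep <- validatePattern(mut)
      if (any(rep$severity == "ERROR")) killed <- killed + 1L
    }
  }
  expect_gt(total, 10L)
  expect_identical(killed, total)
})

test_that("violation paths resolve to existing document nodes", {
  doc <- makeTransmembranePattern()
  broken <- doc
  broken@annotationAxioms[[1]]@vars <- "cargo"
  broken@dataListVars[["def_dbxref"]] <- "xsd:nonsense"
  rep <- validatePattern(broken, fixtureContext())
  expect_gt(nrow(rep), 0)
  for (p in rep$path)
    expect_true(resolveReportPath(broken, p), info = p)
  for (mut in docMutants(normalizeObo(doc))[1:6]) {
    rep <- validatePattern(mut)
    for (p in rep$path)
      expect_true(resolveReportPath(mut, p), info = p)
  }
})
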