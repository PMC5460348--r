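# Matching classes back to patterns: filler recovery, conformance
# checking, determinism.

test_that("a generated class matches back with its binding recovered", {
  pat <- makeTransmembranePattern()
  b <- leucineBinding()
  gc <- instantiate(pat, b, "EX:1000001")
  ont <- fragmentWith(gc)
  res <- matchClass(pat, "EX:1000001", ont)
  expect_true(res@logicalMatch)
  expect_true(res@conformant)
  # oracle: the generating binding
  expect_identical(bindingKey(res@binding), bindingKey(b))
  expect_identical(res@binding@listFillers$def_dbxref,
                   c("PMID:1", "GOC:dos"))
})

test_that("a class without an equivalence axiom does not match", {
  pat <- makeTransmembranePattern()
  ont <- makeFixtureOntology()
  res <- matchClass(pat, "EX:0000004", ont)  # 'leucine' itself
  expect_false(res@logicalMatch)
  expect_null(res@binding)
  expect_false(res@conformant)
})

test_that("a wrong label gives logical match but annotation mismatch", {
  pat <- makeTransmembranePattern()
  gc <- instantiate(pat, leucineBinding(), "EX:1000001")
  for (i in seq_along(gc@annotations))
    if (gc@annotations[[i]]$property == "rdfs:label")
      gc@annotations[[i]]$value <- "leucine import"
  ont <- fragmentWith(gc)
  res <- matchClass(pat, "EX:1000001", ont)
  expect_true(res@logicalMatch)
  expect_false(res@annotationMatches[["label"]])
  expect_false(res@conformant)
  # oracle: reverse matching the label spec against the mutated value
  # returns nothing
  expect_length(
    reverseTemplate("%s transport across the %s", c("cargo", "membrane"),
                    "leucine import", labelIndex(makeFixtureOntology())),
    0)
})

test_that("findMatches returns exactly the pattern's own classes, sorted", {
  pat <- makeTransmembranePattern()
  ont <- makeFixtureOntology()
  tab <- readFillerTable(system.file("extdata", "transmembrane_fillers.tsv",
                                     package = "dosdp"))
  gen <- generateBatch(pat, tab, mintingPolicy("EX", start = 1000001L),
                       ontology = ont)
  merged <- mergeFragments(ont, gen)
  res <- findMatches(pat, merged)
  expect_length(res, 3)
  expect_true(all(vapply(res, function(r) r@conformant, logical(1))))
  iris <- vapply(res, function(r) r@classIri, character(1))
  expect_identical(iris, sort(iris))
  expect_length(findMatches(pat, ontologyFragment()), 0)
})

test_that("each pattern matches only its own generated classes", {
  corpus <- randomPatterns(77, 8)
  # find two structurally different patterns (different variable count)
  nv <- vapply(corpus$patterns, function(p) length(p@vars), integer(1))
  i <- which(nv == min(nv))[1]
  j <- which(nv == max(nv))[1]
  expect_true(nv[i] != nv[j])  # corpus draws 1-3 variables over 8 patterns
  bi <- Filter(function(x) x$pattern == i, corpus$bindings)[[1]]$binding
  bj <- Filter(function(x) x$pattern == j, corpus$bindings)[[1]]$binding
  ci <- instantiate(corpus$patterns[[i]], bi, "EX:7000001")
  cj <- instantiate(corpus$patterns[[j]], bj, "EX:7000002")
  ont <- fragmentWith(ci, cj, ontology = corpus$ontology)
  ri <- findMatches(corpus$patterns[[i]], ont)
  rj <- findMatches(corpus$patterns[[j]], ont)
  expect_identical(vapply(ri, function(r) r@classIri, character(1)),
                   "EX:7000001")
  expect_identical(vapply(rj, function(r) r@classIri, character(1)),
                   "EX:7000002")
})

test_that("round-trip inversion holds across the random corpus", {
  corpus <- randomPatterns(42, 10)
  count <- 0L
  for (bb in corpus$bindings) {
    doc <- corpus$patterns[[bb$pattern]]
    gc <- instantiate(doc, bb$binding, "EX:9000001")
    ont <- fragmentWith(gc, ontology = corpus$ontology)
    res <- matchClass(doc, "EX:9000001", ont)
    expect_true(res@conformant)
    expect_identical(bindingKey(res@binding), bindingKey(bb$binding))
    # soundness: re-instantiating the recovered binding reproduces the
    # class's axioms (same identifier, canonical expressions)
    again <- instantiate(doc, res@binding, "EX:9000001")
    expect_identical(again, gc)
    count <- count + 1L
  }
  expect_identical(count, 30L)
})

test_that("results are independent of ontology construction order", {
  pat <- makeTransmembranePattern()
  ont <- makeFixtureOntology()
  b2 <- binding(
    classFillers = list(cargo = entityRef("glycine", "EX:0000005"),
                        membrane = entityRef("membrane", "EX:0000008")),
    listFillers = list(def_dbxref = "PMID:9"))
  g1 <- instantiate(pat, leucineBinding(), "EX:1000001")
  g2 <- instantiate(pat, b2, "EX:1000002")
  o1 <- fragmentWith(g1, g2)
  o2 <- fragmentWith(g2, g1)
  expect_identical(o1, o2)
  expect_identical(matchesToJSON(findMatches(pat, o1)),
                   matchesToJSON(findMatches(pat, o2)))
})

test_that("conformance partitions tagged classes with reasons", {
  pat <- makeTransmembranePattern()
  ont <- makeFixtureOntology()
  tab <- readFillerTable(system.file("extdata", "transmembrane_fillers.tsv",
                                     package = "dosdp"))
  gen <- generateBatch(pat, tab, mintingPolicy("EX", start = 1000001L),
                       ontology = ont)
  merged <- mergeFragments(ont, gen)
  rep <- checkConformance(pat, names(fragmentClasses(gen)), merged)
  expect_length(rep@update, 3)
  expect_length(rep@manual, 0)
  # tagging 'leucine' itself lands it in manual with a reason
  rep2 <- checkConformance(pat, c("EX:1000001", "EX:0000004"), merged)
  expect_identical(rep2@update, "EX:1000001")
  expect_identical(rep2@manual, "EX:0000004")
  expect_match(rep2@reasons[["EX:0000004"]], "no equivalence axiom matched")
  expect_error(checkConformance(pat, "EX:9999999", merged),
               class = "dosdp_conflict_error")
})

test_that("a filler mutated outside its range fails strict conformance", {
  pat <- makeTransmembranePattern()
  gc <- instantiate(pat, leucineBinding(), "EX:1000001")
  # swap the cargo filler to 'plasma membrane' inside the equivalence axiom
  mutated <- instantiate(pat, binding(
    classFillers = list(cargo = entityRef("plasma membrane", "EX:0000009"),
                        membrane = entityRef("plasma membrane", "EX:0000009")),
    listFillers = list(def_dbxref = c("PMID:1", "GOC:dos"))), "EX:1000002")
  ont <- fragmentWith(gc, mutated)
  rep <- checkConformance(pat, c("EX:1000001", "EX:1000002"), ont,
                          strict = TRUE)
  expect_identical(rep@update, "EX:1000001")
  expect_identical(rep@manual, "EX:1000002")
  expect_match(paste(rep@reasons[["EX:1000002"]], collapse = "; "),
               "outside its range")
  # lenient conformance accepts both
  repL <- checkConformance(pat, c("EX:1000001", "EX:1000002"), ont)
  expect_length(repL@manual, 0)
})
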