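# Manchester expression parsing/printing and the printf template engine.

cls <- fixtureClassDict()
rel <- fixtureRelationDict()

test_that("disjunction of quoted labels parses to an Or of Named nodes", {
  e <- parseClassExpression("'chemical entity' or 'transcript'",
                            classes = cls, relations = rel)
  expect_s4_class(e, "OrExpression")
  expect_true(all(vapply(e@operands, is, logical(1), "NamedClass")))
  expect_setequal(vapply(e@operands, function(x) x@curie, character(1)),
                  c("EX:0000002", "EX:0000007"))
})

test_that("a single quoted leaf parses to a Named node", {
  e <- parseClassExpression("'leucine'", classes = cls, relations = rel)
  expect_s4_class(e, "NamedClass")
  expect_identical(e@label, "leucine")
  expect_identical(e@curie, "EX:0000004")
})

test_that("genus-differentia conjunction parses to the expected shape", {
  # independently hand-traced AST: And(Named transport,
  #   Some(transports, Named leucine), Some(crosses, Named plasma membrane))
  e <- parseClassExpression(
    "'transport' and ('transports' some 'leucine') and ('crosses' some 'plasma membrane')",
    classes = cls, relations = rel)
  expect_s4_class(e, "AndExpression")
  expect_length(e@operands, 3)
  kinds <- sort(vapply(e@operands, function(x) class(x), character(1)))
  expect_identical(kinds, c("NamedClass", "SomeValuesFrom", "SomeValuesFrom"))
  somes <- Filter(function(x) is(x, "SomeValuesFrom"), e@operands)
  rels <- sort(vapply(somes, function(x) x@relationCurie, character(1)))
  expect_identical(rels, c("EX:2000001", "EX:2000002"))
  expected <- intersectionOf(
    namedClass("transport", "EX:0000001"),
    someValuesFrom("transports", namedClass("leucine", "EX:0000004"),
                   "EX:2000001"),
    someValuesFrom("crosses", namedClass("plasma membrane", "EX:0000009"),
                   "EX:2000002"))
  expect_true(exprEqual(e, expected))
})

test_that("unsupported Manchester keywords are rejected", {
  for (bad in c("'transports' only 'leucine'",
                "'transports' min 2 'leucine'",
                "'transports' value 'leucine'"))
    expect_error(parseClassExpression(bad, classes = cls, relations = rel),
                 class = "dosdp_unsupported_construct")
})

test_that("parse errors carry character offsets; unknown labels are typed", {
  err <- tryCatch(parseClassExpression("('leucine' or 'serine'",
                                       classes = cls, relations = rel),
                  error = function(e) e)
  expect_s3_class(err, "dosdp_parse_error")
  expect_match(conditionMessage(err), "offset [0-9]+")
  expect_error(parseClassExpression("'leucine", classes = cls,
                                    relations = rel),
               class = "dosdp_parse_error")
  expect_error(parseClassExpression("'dark matter'", classes = cls,
                                    relations = rel),
               class = "dosdp_undeclared_entity")
})

test_that("printing quotes multi-word labels and is parse-stable", {
  expect_identical(toManchester(namedClass("leucine", "EX:0000004")),
                   "leucine")
  expect_identical(toManchester(namedClass("plasma membrane", "EX:0000009")),
                   "'plasma membrane'")
  # canonical operand order is construction-order independent
  a <- namedClass("leucine", "EX:0000004")
  b <- namedClass("serine", "EX:0000006")
  expect_identical(toManchester(intersectionOf(a, b)),
                   toManchester(intersectionOf(b, a)))
  expect_true(exprEqual(intersectionOf(a, b), intersectionOf(b, a)))
})

test_that("parse/print round trip holds on 1000 random expressions", {
  exprs <- randomExpressions(101, 1000)
  for (e in exprs) {
    back <- parseClassExpression(toManchester(e), classes = cls,
                                 relations = rel)
    expect_true(exprEqual(e, back))
  }
})

test_that("templates render labels, escapes and logical quoting", {
  b <- leucineBinding()
  expect_identical(
    renderTemplate("%s transport across the %s", c("cargo", "membrane"),
                   b)$text,
    "leucine transport across the plasma membrane")
  expect_identical(renderTemplate("100%% done", character(0), b)$text,
                   "100% done")
  logical <- renderTemplate(
    "'transport' and ('transports' some %s) and ('crosses' some %s)",
    c("cargo", "membrane"), b, mode = "logical")$text
  expect_match(logical, "some 'plasma membrane'", fixed = TRUE)
  expect_match(logical, "some leucine", fixed = TRUE)
  ## re-rendering the provenance reproduces the text
  r <- renderTemplate("%s transport across the %s", c("cargo", "membrane"), b)
  expect_identical(renderTemplate(r$template, r$vars, r$binding)$text, r$text)
})

test_that("template rendering errors are informative", {
  b <- leucineBinding()
  expect_error(renderTemplate("%s and %s and %s", c("cargo", "membrane"), b),
               class = "dosdp_arity_error")
  err <- tryCatch(renderTemplate("%s by %s", c("cargo", "nothere"), b),
                  error = function(e) e)
  expect_s3_class(err, "dosdp_unbound_var")
  expect_match(conditionMessage(err), "nothere")
  expect_error(renderTemplate("%d done", character(0), b),
               class = "dosdp_parse_error")
})

test_that("reverse matching recovers the unique fixture binding", {
  idx <- labelIndex(makeFixtureOntology())
  got <- reverseTemplate("%s transport across the %s", c("cargo", "membrane"),
                         "leucine transport across the plasma membrane", idx)
  # brute-force oracle over all label pairs in the index
  oracle <- list()
  for (l1 in names(idx)) for (l2 in names(idx)) {
    if (sprintf("%s transport across the %s", l1, l2) ==
        "leucine transport across the plasma membrane")
      oracle[[length(oracle) + 1L]] <- c(l1, l2)
  }
  expect_length(oracle, 1)
  expect_length(got, 1)
  expect_identical(got[[1]]@classFillers$cargo$label, oracle[[1]][1])
  expect_identical(got[[1]]@classFillers$membrane$label, oracle[[1]][2])
  expect_identical(got[[1]]@classFillers$cargo$curie, "EX:0000004")
})

test_that("reverse matching returns empty on non-matching text", {
  idx <- labelIndex(makeFixtureOntology())
  expect_length(
    reverseTemplate("%s transport across the %s", c("cargo", "membrane"),
                    "flying over the membrane", idx), 0)
})

test_that("ambiguous segmentations are all returned, deterministically", {
  idx <- c("a" = "X:1", "a b" = "X:2", "b c" = "X:3", "c" = "X:4")
  # exhaustive segmentation oracle
  text <- "a b c"
  oracle <- list()
  for (cut in 1:(nchar(text) - 1)) {
    x <- substr(text, 1, cut); y <- substr(text, cut + 2, nchar(text))
    if (substr(text, cut + 1, cut + 1) == " " &&
        x %in% names(idx) && y %in% names(idx))
      oracle[[length(oracle) + 1L]] <- c(x, y)
  }
  expect_length(oracle, 2)
  got <- reverseTemplate("%s %s", c("x", "y"), text, idx)
  expect_length(got, 2)
  # deterministic: repeated calls identical
  expect_identical(lapply(got, bindingKey),
                   lapply(reverseTemplate("%s %s", c("x", "y"), text, idx),
                          bindingKey))
})

test_that("reverse is sound and inverts render on fixture templates", {
  idx <- labelIndex(makeFixtureOntology())
  tmpl <- "%s transport across the %s"
  vars <- c("cargo", "membrane")
  for (cargoLab in c("leucine", "glycine", "amino acid")) {
    b <- binding(classFillers = list(
      cargo = entityRef(cargoLab, idx[[cargoLab]]),
      membrane = entityRef("plasma membrane", idx[["plasma membrane"]])))
    rendered <- renderTemplate(tmpl, vars, b)$text
    cands <- reverseTemplate(tmpl, vars, rendered, idx)
    keys <- vapply(cands, bindingKey, character(1))
    expect_true(bindingKey(b) %in% keys)
    for (cand in cands)
      expect_identical(renderTemplate(tmpl, vars, cand)$text, rendered)
  }
})
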