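## Pattern validation: schema-level checks (mandatory subfields per spec
## kind, template arity, variable and entity declaration, dictionary label
## uniqueness, CURIE resolution, datatypes) reported as a structured table
## rather than thrown. ERROR severity decides validity; WARNINGs are style.

.XSD_DATATYPES <- c("xsd:string", "xsd:integer", "xsd:int", "xsd:long",
                    "xsd:float", "xsd:double", "xsd:decimal", "xsd:boolean",
                    "xsd:dateTime", "xsd:date", "xsd:anyURI")

.MANDATORY_SUBFIELDS <- list(
  printf_owl = c("axiom_type", "text", "vars"),
  printf_annotation = c("annotationProperty", "text", "vars"),
  list_annotation = c("annotationProperty", "value"),
  printf_owl_convenience = c("text", "vars"),
  printf_annotation_obo = c("text", "vars"),
  list_annotation_obo = c("value")
)

.specField <- function(spec, field) {
  switch(field,
         axiom_type = spec@axiomType,
         text = spec@text,
         vars = spec@vars,
         value = spec@value,
         annotationProperty = spec@annotationProperty)
}

#' Validate a pattern document
#'
#' Checks the document against the core schema plus the recommended extra
#' checks: mandatory subfields for each axiom-specification kind, printf
#' template arity, declaration of every referenced variable and quoted
#' entity, dictionary label uniqueness, CURIE prefix resolution (when a
#' context is given), recognised XSD datatypes, a file-name-safe pattern
#' name, and unknown top-level keys (warnings by default, errors under
#' `strict`). Problems are reported, never thrown; the document is valid
#' exactly when the report contains no ERROR rows (see [isValidPattern()]).
#'
#' @param doc a [PatternDocument-class].
#' @param context optional [PrefixContext-class] used to resolve dictionary
#'   CURIEs.
#' @param strict logical; promote style warnings to errors.
#' @return a data.frame with columns `code`, `path`, `severity`, `message`.
#' @export
validatePattern <- function(doc, context = NULL, strict = FALSE) {
  rows <- list()
  add <- function(code, path, severity, message)
    rows[[length(rows) + 1L]] <<- data.frame(
      code = code, path = path, severity = severity, message = message,
      stringsAsFactors = FALSE)

  ## pattern name
  if (!grepl("^[A-Za-z0-9._-]+$", doc@patternName))
    add("BAD_PATTERN_NAME", "pattern_name", "ERROR",
        paste0("pattern_name is not file-name safe: '",
               doc@patternName, "'"))

  ## dictionary label uniqueness across all four dictionaries
  labs <- c(names(doc@classes), names(doc@relations),
            names(doc@annotationProperties), names(doc@dataProperties))
  dictOf <- function(lab) {
    if (lab %in% names(doc@classes)) return(paste0("classes.", lab))
    if (lab %in% names(doc@relations)) return(paste0("relations.", lab))
    if (lab %in% names(doc@annotationProperties))
      return(paste0("annotationProperties.", lab))
    paste0("dataProperties.", lab)
  }
  for (d in unique(labs[duplicated(labs)]))
    add("DUPLICATE_LABEL", dictOf(d), "ERROR",
        paste0("label '", d, "' appears in more than one dictionary ",
               "entry; labels must uniquely identify entities within ",
               "a pattern"))

  ## CURIE resolution
  if (!is.null(context)) {
    dicts <- list(classes = doc@classes, relations = doc@relations,
                  annotationProperties = doc@annotationProperties,
                  dataProperties = doc@dataProperties)
    for (dn in names(dicts)) {
      d <- dicts[[dn]]
      for (i in seq_along(d)) {
        pfx <- .curiePrefix(d[[i]])
        if (!grepl(":", d[[i]], fixed = TRUE) ||
            !(pfx %in% names(context@mapping)))
          add("UNRESOLVED_PREFIX", paste0(dn, ".", names(d)[i]), "ERROR",
              paste0("CURIE '", d[[i]], "' has no resolvable prefix ",
                     "in the context"))
      }
    }
  }

  ## datatypes
  for (i in seq_along(doc@dataListVars)) {
    dt <- doc@dataListVars[[i]]
    if (!(dt %in% .XSD_DATATYPES))
      add("UNKNOWN_DATATYPE",
          paste0("data_list_vars.", names(doc@dataListVars)[i]), "ERROR",
          paste0("'", dt, "' is not a recognised XSD datatype"))
  }

  ## variable ranges parse against the dictionaries
  for (i in seq_along(doc@vars)) {
    vn <- names(doc@vars)[i]
    err <- .exprProblem(doc@vars[[i]], doc)
    if (!is.null(err))
      add(err$code, paste0("vars.", vn), "ERROR", err$message)
  }

  ## axiom specs
  classVars <- names(doc@vars)
  listVars <- names(doc@dataListVars)
  checkSpec <- function(spec, path, nested = FALSE) {
    kind <- spec@specKind
    for (f in .MANDATORY_SUBFIELDS[[kind]]) {
      if (is.null(.specField(spec, f)))
        add("MISSING_FIELD", path, "ERROR",
            paste0("mandatory subfield '", f, "' is missing from a ",
                   kind, " specification"))
    }
    if (nested && !(kind %in% c("printf_annotation", "list_annotation",
                                "printf_annotation_obo",
                                "list_annotation_obo")))
      add("BAD_NESTED_SPEC", path, "ERROR",
          "axiom annotations may only contain annotation-kind specs")
    if (!is.null(spec@text)) {
      nconv <- tryCatch(templateArity(spec@text), error = function(e) NA)
      if (is.na(nconv)) {
        add("INVALID_CONVERSION", paste0(path, ".text"), "ERROR",
            paste0("template text has an unsupported conversion: ",
                   spec@text))
      } else if (!is.null(spec@vars) && nconv != length(spec@vars)) {
        add("ARITY_MISMATCH", paste0(path, ".vars"), "ERROR",
            paste0("template has ", nconv, " conversions but ",
                   length(spec@vars), " vars are listed"))
      }
    }
    if (!is.null(spec@vars))
      for (v in spec@vars)
        if (!(v %in% classVars))
          add("UNDECLARED_VAR", paste0(path, ".vars"), "ERROR",
              paste0("variable '", v, "' is not declared in vars"))
    if (!is.null(spec@value) && !(spec@value %in% listVars))
      add("UNDECLARED_VAR", paste0(path, ".value"), "ERROR",
          paste0("list variable '", spec@value,
                 "' is not declared in data_list_vars"))
    if (kind %in% c("printf_annotation", "list_annotation") &&
        !is.null(spec@annotationProperty) &&
        !(spec@annotationProperty %in% names(doc@annotationProperties)))
      add("UNDECLARED_ENTITY", paste0(path, ".annotationProperty"), "ERROR",
          paste0("annotation property '", spec@annotationProperty,
                 "' is not in the annotationProperties dictionary"))
    if (kind %in% c("printf_owl", "printf_owl_convenience") &&
        !is.null(spec@text) && (is.null(spec@vars) ||
                                all(spec@vars %in% classVars))) {
      err <- .logicalTemplateProblem(spec, doc)
      if (!is.null(err))
        add(err$code, paste0(path, ".text"), "ERROR", err$message)
    }
    if (kind %in% c("printf_annotation_obo", "list_annotation_obo") &&
        doc@extension == "core" && !nested)
      add("OBO_SLOT_IN_CORE", path, "ERROR",
          "OBO convenience slot used in a core-extension document")
    for (j in seq_along(spec@annotations))
      checkSpec(spec@annotations[[j]],
                paste0(path, ".annotations[", j, "]"), nested = TRUE)
  }
  pathFor <- function(spec, i, role) {
    if (!is.null(spec@slotName)) spec@slotName
    else paste0(role, "[", i, "]")
  }
  for (i in seq_along(doc@annotationAxioms))
    checkSpec(doc@annotationAxioms[[i]],
              pathFor(doc@annotationAxioms[[i]], i, "annotations"))
  for (i in seq_along(doc@logicalAxioms))
    checkSpec(doc@logicalAxioms[[i]],
              pathFor(doc@logicalAxioms[[i]], i, "logical_axioms"))

  ## one convenience slot per axiom type
  convTypes <- unlist(lapply(doc@logicalAxioms, function(s)
    if (s@specKind == "printf_owl_convenience" && !is.null(s@axiomType))
      s@axiomType else NULL))
  for (d in unique(convTypes[duplicated(convTypes)]))
    add("DUPLICATE_CONVENIENCE", d, "ERROR",
        paste0("more than one convenience slot of type '", d, "'"))

  ## readable identifier must resolve (core documents)
  if (!is.null(doc@readableIdentifier) &&
      !(doc@readableIdentifier %in% names(doc@annotationProperties)))
    add("UNDECLARED_ENTITY", "readable_identifier", "ERROR",
        paste0("readable_identifier '", doc@readableIdentifier,
               "' is not in the annotationProperties dictionary"))

  ## unknown top-level keys
  for (k in names(doc@extras))
    add("UNKNOWN_KEY", k, if (strict) "ERROR" else "WARNING",
        paste0("unknown top-level key '", k, "'"))

  if (length(rows) == 0L)
    return(data.frame(code = character(0), path = character(0),
                      severity = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

## parse problems for a Manchester expression, reported not thrown
.exprProblem <- function(text, doc) {
  tryCatch({
    parseClassExpression(text, classes = doc@classes,
                         relations = doc@relations)
    NULL
  },
  dosdp_undeclared_entity = function(e)
    list(code = "UNDECLARED_ENTITY", message = conditionMessage(e)),
  dosdp_unsupported_construct = function(e)
    list(code = "UNSUPPORTED_CONSTRUCT", message = conditionMessage(e)),
  dosdp_parse_error = function(e)
    list(code = "INVALID_EXPRESSION", message = conditionMessage(e)))
}

## substitute placeholders for the conversions, then parse; placeholder
## labels are injected into the class dictionary
.logicalTemplateProblem <- function(spec, doc) {
  pf <- tryCatch(.parsePrintf(spec@text), error = function(e) NULL)
  if (is.null(pf)) return(NULL)
  vars <- if (is.null(spec@vars)) character(0) else spec@vars
  if (length(vars) != pf$nconv) return(NULL)  # arity reported separately
  ph <- paste0("var placeholder ", seq_len(pf$nconv))
  text <- pf$segments[1L]
  for (k in seq_len(pf$nconv))
    text <- paste0(text, "'", ph[k], "'", pf$segments[k + 1L])
  doc2 <- doc
  doc2@classes <- c(doc@classes,
                    setNames(paste0("_var_:", seq_len(pf$nconv)), ph))
  parts <- if (identical(spec@axiomType, "GCI"))
    strsplit(text, " SubClassOf: ", fixed = TRUE)[[1]] else text
  for (p in parts) {
    err <- .exprProblem(p, doc2)
    if (!is.null(err)) return(err)
  }
  NULL
}

#' Is a pattern document valid?
#'
#' @param doc a [PatternDocument-class] (or a report from
#'   [validatePattern()]).
#' @param context optional [PrefixContext-class].
#' @return `TRUE` when the validation report has no ERROR rows.
#' @export
isValidPattern <- function(doc, context = NULL) {
  rep <- if (is.data.frame(doc)) doc else validatePattern(doc, context)
  !any(rep$severity == "ERROR")
}

#' Serialise a validation report to JSON
#'
#' @param report a report data.frame from [validatePattern()].
#' @return a JSON string: a list of `{code, path, severity, message}`.
#' @export
reportToJSON <- function(report) {
  jsonlite::toJSON(report, dataframe = "rows", auto_unbox = TRUE,
                   pretty = TRUE)
}
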