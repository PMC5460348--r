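## Markdown documentation for a pattern document: CommonMark pipe tables,
## one page per pattern. Rendering is pure and deterministic.

.mdEscape <- function(x) gsub("|", "\\|", x, fixed = TRUE)

.mdTable <- function(header, rows) {
  out <- c(paste0("| ", paste(header, collapse = " | "), " |"),
           paste0("|", paste(rep(" --- ", length(header)), collapse = "|"),
                  "|"))
  for (r in rows)
    out <- c(out, paste0("| ", paste(.mdEscape(r), collapse = " | "), " |"))
  out
}

.specRow <- function(spec) {
  tmpl <- if (!is.null(spec@text)) spec@text
          else if (!is.null(spec@value)) paste0("list: ", spec@value)
          else ""
  vars <- if (!is.null(spec@vars)) paste(spec@vars, collapse = ", ") else ""
  type <- if (!is.null(spec@slotName)) spec@slotName
          else if (!is.null(spec@axiomType)) spec@axiomType
          else spec@specKind
  c(type, tmpl, vars)
}

#' Render markdown documentation for a pattern
#'
#' Produces a page with the pattern name as the first heading, the
#' description, a dictionary table (label | CURIE | role), a variable
#' table (name | kind | range), the axiom listing (type | template |
#' vars) and, when an example binding is supplied, a worked instantiation
#' showing the rendered label, definition and logical axiom. Invalid
#' documents are refused with the validation report attached to the
#' error.
#'
#' @param doc a [PatternDocument-class].
#' @param example optional [Binding-class] for the worked example.
#' @param context optional [PrefixContext-class] for validation.
#' @return markdown text (single string).
#' @export
renderMarkdown <- function(doc, example = NULL, context = NULL) {
  rep <- validatePattern(doc, context = context)
  if (any(rep$severity == "ERROR"))
    .dosdpError("dosdp_invalid_document",
                paste0("refusing to document an invalid pattern; ",
                       "first violation: ", rep$code[1], " at ",
                       rep$path[1]),
                data = rep)
  lines <- c(paste0("# ", doc@patternName), "")
  if (!is.null(doc@description)) lines <- c(lines, doc@description, "")
  lines <- c(lines, paste0("**IRI:** ", patternIri(doc)), "")

  dictRows <- list()
  addDict <- function(d, role)
    for (i in seq_along(d))
      dictRows[[length(dictRows) + 1L]] <<- c(names(d)[i], d[[i]], role)
  addDict(doc@classes, "class")
  addDict(doc@relations, "relation")
  addDict(doc@annotationProperties, "annotation property")
  addDict(doc@dataProperties, "data property")
  if (length(dictRows))
    lines <- c(lines, "## Dictionary", "",
               .mdTable(c("label", "CURIE", "role"), dictRows), "")

  varRows <- list()
  for (i in seq_along(doc@vars))
    varRows[[length(varRows) + 1L]] <-
      c(names(doc@vars)[i], "class", doc@vars[[i]])
  for (i in seq_along(doc@dataListVars))
    varRows[[length(varRows) + 1L]] <-
      c(names(doc@dataListVars)[i], "data list", doc@dataListVars[[i]])
  if (length(varRows))
    lines <- c(lines, "## Variables", "",
               .mdTable(c("name", "kind", "range"), varRows), "")

  annRows <- lapply(doc@annotationAxioms, .specRow)
  if (length(annRows))
    lines <- c(lines, "## Annotation axioms", "",
               .mdTable(c("type", "template", "vars"), annRows), "")
  logRows <- lapply(doc@logicalAxioms, .specRow)
  if (length(logRows))
    lines <- c(lines, "## Logical axioms", "",
               .mdTable(c("type", "template", "vars"), logRows), "")

  if (!is.null(example)) {
    core <- normalizeObo(doc)
    lines <- c(lines, "## Example", "")
    for (v in names(example@classFillers))
      lines <- c(lines, paste0("- ", v, " = ",
                               example@classFillers[[v]]$label, " (",
                               example@classFillers[[v]]$curie, ")"))
    for (v in names(example@listFillers))
      lines <- c(lines, paste0("- ", v, " = [",
                               paste(example@listFillers[[v]],
                                     collapse = ", "), "]"))
    lines <- c(lines, "")
    for (spec in core@annotationAxioms) {
      if (spec@specKind != "printf_annotation") next
      val <- renderTemplate(spec@text, spec@vars %||% character(0),
                            example, mode = "label")$text
      lines <- c(lines, paste0("**", spec@annotationProperty, ":** ",
                               val), "")
    }
    for (spec in .coreLogicalSpecs(core)) {
      if (spec@specKind != "printf_owl") next
      val <- renderTemplate(spec@text, spec@vars %||% character(0),
                            example, mode = "logical")$text
      lines <- c(lines, paste0("**", spec@axiomType, ":** `", val, "`"), "")
    }
  }
  paste(paste(lines, collapse = "\n"), "\n", sep = "")
}

#' Write the markdown page for a pattern
#'
#' @param doc a [PatternDocument-class].
#' @param dir output directory; the file is named `<pattern_name>.md`.
#' @param example optional [Binding-class].
#' @param context optional [PrefixContext-class].
#' @return the path written, invisibly.
#' @export
writeMarkdown <- function(doc, dir = ".", example = NULL, context = NULL) {
  path <- file.path(dir, paste0(doc@patternName, ".md"))
  writeLines(renderMarkdown(doc, example = example, context = context),
             path, useBytes = TRUE)
  invisible(path)
}
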