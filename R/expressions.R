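## Manchester-syntax class expressions: constructors, canonical keys,
## parser and printer. The grammar covers the pattern language subset:
## quoted or bare entity labels, and / or / not / some, parentheses.
## Other Manchester constructs (only, min, max, exactly, value) are
## recognised and rejected as unsupported.

## constructors --------------------------------------------------------------

#' Construct a named-class expression
#'
#' @param label readable label.
#' @param curie compact identifier; defaults to the label when unknown.
#' @return a [NamedClass-class].
#' @export
namedClass <- function(label, curie = NA_character_) {
  if (is.na(curie)) curie <- label
  new("NamedClass", label = label, curie = curie)
}

.sortExprs <- function(exprs) {
  keys <- vapply(exprs, exprKey, character(1))
  exprs[order(keys)][!duplicated(sort(keys))]
}

#' Construct an intersection (And) expression
#'
#' Operands are flattened, deduplicated and canonically ordered, so
#' `intersectionOf(a, b)` and `intersectionOf(b, a)` are identical. A single
#' distinct operand is returned as-is.
#'
#' @param ... class expressions, or a single list of them.
#' @return a [ClassExpression-class].
#' @export
intersectionOf <- function(...) .nary("AndExpression", list(...))

#' Construct a union (Or) expression
#'
#' @inheritParams intersectionOf
#' @return a [ClassExpression-class].
#' @export
unionOf <- function(...) .nary("OrExpression", list(...))

.nary <- function(cls, ops) {
  if (length(ops) == 1L && is.list(ops[[1]]) && !is(ops[[1]], "ClassExpression"))
    ops <- ops[[1]]
  flat <- list()
  for (o in ops) {
    stopifnot(is(o, "ClassExpression"))
    if (is(o, cls)) flat <- c(flat, o@operands) else flat <- c(flat, list(o))
  }
  flat <- .sortExprs(flat)
  if (length(flat) == 0L) stop("empty operand list")
  if (length(flat) == 1L) return(flat[[1]])
  new(cls, operands = flat)
}

#' Construct a complement (Not) expression
#'
#' @param expr the negated class expression.
#' @return a [NotExpression-class].
#' @export
complementOf <- function(expr) new("NotExpression", operand = expr)

#' Construct an existential restriction
#'
#' @param relationLabel readable label of the object property.
#' @param relationCurie compact identifier of the object property.
#' @param filler filler class expression.
#' @return a [SomeValuesFrom-class].
#' @export
someValuesFrom <- function(relationLabel, filler,
                           relationCurie = NA_character_) {
  if (is.na(relationCurie)) relationCurie <- relationLabel
  new("SomeValuesFrom", relationLabel = relationLabel,
      relationCurie = relationCurie, filler = filler)
}

## canonical key and equality ------------------------------------------------

#' Canonical serialised key of a class expression
#'
#' Structurally equal expressions (modulo And/Or operand order) have equal
#' keys; used for canonical sorting, memoisation and equality.
#'
#' @param expr a [ClassExpression-class].
#' @return a character scalar.
#' @export
exprKey <- function(expr) {
  if (is(expr, "NamedClass")) {
    paste0("n<", expr@curie, ">")
  } else if (is(expr, "SomeValuesFrom")) {
    paste0("s<", expr@relationCurie, ">(", exprKey(expr@filler), ")")
  } else if (is(expr, "AndExpression")) {
    paste0("a(", paste(sort(vapply(expr@operands, exprKey, character(1))),
                       collapse = "|"), ")")
  } else if (is(expr, "OrExpression")) {
    paste0("o(", paste(sort(vapply(expr@operands, exprKey, character(1))),
                       collapse = "|"), ")")
  } else if (is(expr, "NotExpression")) {
    paste0("!(", exprKey(expr@operand), ")")
  } else stop("unknown expression node: ", class(expr))
}

#' Structural equality of class expressions
#'
#' @param a,b class expressions.
#' @return logical scalar.
#' @export
exprEqual <- function(a, b) identical(exprKey(a), exprKey(b))

## printer -------------------------------------------------------------------

.labelToken <- function(label) {
  if (grepl("\\s", label)) paste0("'", label, "'") else label
}

#' Print a class expression in Manchester syntax
#'
#' Deterministic: And/Or operands appear in canonical order; multi-word
#' labels are single-quoted; operands that could be mis-associated are
#' parenthesised. `parseClassExpression(toManchester(x))` reproduces `x`.
#'
#' @param expr a [ClassExpression-class].
#' @return a Manchester-syntax string.
#' @export
toManchester <- function(expr) {
  wrap <- function(e, guard) {
    s <- toManchester(e)
    if (any(vapply(guard, function(g) is(e, g), logical(1))))
      paste0("(", s, ")") else s
  }
  if (is(expr, "NamedClass")) {
    .labelToken(expr@label)
  } else if (is(expr, "SomeValuesFrom")) {
    paste0(.labelToken(expr@relationLabel), " some ",
           wrap(expr@filler, c("AndExpression", "OrExpression",
                               "SomeValuesFrom", "NotExpression")))
  } else if (is(expr, "AndExpression")) {
    paste(vapply(expr@operands, wrap, character(1),
                 guard = c("OrExpression", "SomeValuesFrom",
                           "NotExpression")),
          collapse = " and ")
  } else if (is(expr, "OrExpression")) {
    paste(vapply(expr@operands, wrap, character(1),
                 guard = c("AndExpression", "SomeValuesFrom",
                           "NotExpression")),
          collapse = " or ")
  } else if (is(expr, "NotExpression")) {
    paste0("not ", wrap(expr@operand,
                        c("AndExpression", "OrExpression",
                          "SomeValuesFrom", "NotExpression")))
  } else stop("unknown expression node: ", class(expr))
}

## tokenizer -----------------------------------------------------------------

.MANCHESTER_KEYWORDS <- c("and", "or", "not", "some")
.UNSUPPORTED_KEYWORDS <- c("only", "min", "max", "exactly", "value")

.tokenizeManchester <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  toks <- list()
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "'") {
      j <- i + 1L
      while (j <= n && chars[j] != "'") j <- j + 1L
      if (j > n)
        .dosdpError("dosdp_parse_error",
                    paste0("unbalanced quote at offset ", i,
                           " in: ", text))
      toks[[length(toks) + 1L]] <-
        list(type = "label",
             value = paste(chars[seq(i + 1L, length.out = j - i - 1L)],
                           collapse = ""),
             pos = i)
      i <- j + 1L
    } else if (ch == "(") {
      toks[[length(toks) + 1L]] <- list(type = "(", value = "(", pos = i)
      i <- i + 1L
    } else if (ch == ")") {
      toks[[length(toks) + 1L]] <- list(type = ")", value = ")", pos = i)
      i <- i + 1L
    } else {
      j <- i
      while (j <= n && !grepl("^[\\s()']$", chars[j], perl = TRUE))
        j <- j + 1L
      w <- paste(chars[i:(j - 1L)], collapse = "")
      type <- if (w %in% .MANCHESTER_KEYWORDS) w
              else if (w %in% .UNSUPPORTED_KEYWORDS) "unsupported"
              else "word"
      toks[[length(toks) + 1L]] <- list(type = type, value = w, pos = i)
      i <- j
    }
  }
  toks
}

## parser --------------------------------------------------------------------

#' Parse a Manchester-syntax class expression
#'
#' Entity labels (quoted, or bare single words) are resolved against the
#' supplied dictionaries; unknown labels raise an `UNDECLARED_ENTITY` error.
#' Supported constructs: `and`, `or`, `not`, `some`, parentheses. The
#' Manchester keywords `only`, `min`, `max`, `exactly` and `value` are
#' recognised but rejected as unsupported.
#'
#' @param text a non-empty Manchester-syntax string.
#' @param classes named character: class label -> CURIE.
#' @param relations named character: object property label -> CURIE.
#' @return a canonicalised [ClassExpression-class].
#' @examples
#' parseClassExpression("leucine or serine",
#'                      classes = c(leucine = "EX:0000004",
#'                                  serine = "EX:0000006"))
#' @export
parseClassExpression <- function(text,
                                 classes = setNames(character(0), character(0)),
                                 relations = setNames(character(0), character(0))) {
  if (!nzchar(trimws(text)))
    .dosdpError("dosdp_parse_error", "empty class expression")
  toks <- .tokenizeManchester(text)
  st <- new.env(parent = emptyenv())
  st$i <- 1L; st$toks <- toks; st$text <- text
  st$classes <- classes; st$relations <- relations

  peek <- function() if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
  advance <- function() { t <- peek(); st$i <- st$i + 1L; t }
  fail <- function(msg, tok = peek()) {
    pos <- if (is.null(tok)) nchar(st$text) + 1L else tok$pos
    .dosdpError("dosdp_parse_error",
                paste0(msg, " at offset ", pos, " in: ", st$text))
  }
  resolve <- function(label, role) {
    dict <- if (role == "class") st$classes else st$relations
    if (label %in% names(dict)) return(namedClassRef(label, dict[[label]]))
    .dosdpError("dosdp_undeclared_entity",
                paste0("UNDECLARED_ENTITY: '", label,
                       "' (", role, ") not found in dictionaries"))
  }
  namedClassRef <- function(label, curie) list(label = label, curie = curie)

  parseExpr <- function() {
    parts <- list(parseConj())
    while (!is.null(t <- peek()) && t$type == "or") {
      advance()
      parts[[length(parts) + 1L]] <- parseConj()
    }
    if (length(parts) == 1L) parts[[1]] else unionOf(parts)
  }
  parseConj <- function() {
    parts <- list(parseUnary())
    while (!is.null(t <- peek()) && t$type == "and") {
      advance()
      parts[[length(parts) + 1L]] <- parseUnary()
    }
    if (length(parts) == 1L) parts[[1]] else intersectionOf(parts)
  }
  parseUnary <- function() {
    t <- peek()
    if (is.null(t)) fail("unexpected end of expression")
    if (t$type == "not") {
      advance()
      return(complementOf(parseUnary()))
    }
    parseAtomOrRestriction()
  }
  parseAtomOrRestriction <- function() {
    t <- peek()
    if (is.null(t)) fail("unexpected end of expression")
    if (t$type == "(") {
      open <- advance()
      e <- parseExpr()
      cl <- peek()
      if (is.null(cl) || cl$type != ")")
        fail("unbalanced parenthesis", open)
      advance()
      nxt <- peek()
      if (!is.null(nxt) && nxt$type %in% c("some", "unsupported"))
        fail("property expressions are not supported", nxt)
      return(e)
    }
    if (t$type %in% c("label", "word")) {
      advance()
      nxt <- peek()
      if (!is.null(nxt) && nxt$type == "unsupported")
        .dosdpError("dosdp_unsupported_construct",
                    paste0("unsupported Manchester construct '", nxt$value,
                           "' at offset ", nxt$pos, " in: ", st$text))
      if (!is.null(nxt) && nxt$type == "some") {
        advance()
        rel <- resolve(t$value, "relation")
        filler <- parseUnary()
        return(someValuesFrom(rel$label, filler, rel$curie))
      }
      ref <- resolve(t$value, "class")
      return(namedClass(ref$label, ref$curie))
    }
    if (t$type == ")") fail("unbalanced parenthesis", t)
    if (t$type == "unsupported")
      .dosdpError("dosdp_unsupported_construct",
                  paste0("unsupported Manchester construct '", t$value,
                         "' at offset ", t$pos, " in: ", st$text))
    fail(paste0("unexpected token '", t$value, "'"), t)
  }

  e <- parseExpr()
  if (!is.null(t <- peek())) {
    if (t$type == ")") fail("unbalanced parenthesis", t)
    fail(paste0("trailing input '", t$value, "'"), t)
  }
  e
}
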