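## The printf template engine, both directions. Dialect: only "%s"
## conversions plus the "%%" escape — every printed use of the pattern
## language substitutes strings, and richer conversions would make
## inversion ambiguous.

## Parse template text into literal segments interleaved with conversions:
## segments[1] %s segments[2] %s ... %s segments[n+1]
.parsePrintf <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  segs <- character(0)
  cur <- ""
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "%") {
      if (i == n)
        .dosdpError("dosdp_parse_error",
                    paste0("dangling '%' at end of template: ", text))
      nxt <- chars[i + 1L]
      if (nxt == "%") {
        cur <- paste0(cur, "%")
        i <- i + 2L
      } else if (nxt == "s") {
        segs <- c(segs, cur)
        cur <- ""
        i <- i + 2L
      } else {
        .dosdpError("dosdp_parse_error",
                    paste0("unsupported conversion '%", nxt,
                           "' in template: ", text))
      }
    } else {
      cur <- paste0(cur, ch)
      i <- i + 1L
    }
  }
  segs <- c(segs, cur)
  list(segments = segs, nconv = length(segs) - 1L)
}

#' Count the substitution conversions in a printf template
#'
#' @param text template text using the `%s` / `%%` dialect.
#' @return integer count of `%s` conversions.
#' @export
templateArity <- function(text) .parsePrintf(text)$nconv

#' Render a printf template against a binding
#'
#' Each `%s` conversion is replaced, in order of `vars`, by the bound
#' entity's readable label. In `"logical"` mode labels containing whitespace
#' are single-quoted so the result parses as Manchester syntax; in
#' `"label"` mode labels are substituted verbatim. `%%` renders as a
#' literal `%`.
#'
#' @param text template text.
#' @param vars ordered character vector of variable names.
#' @param binding a [Binding-class] supplying every variable in `vars`.
#' @param mode `"label"` (annotation text) or `"logical"` (Manchester).
#' @return a list with elements `text` (the rendering), `template`, `vars`
#'   and `binding` (the provenance; re-rendering it reproduces `text`).
#' @examples
#' b <- binding(classFillers = list(
#'   cargo = entityRef("leucine", "EX:0000004"),
#'   membrane = entityRef("plasma membrane", "EX:0000009")))
#' renderTemplate("%s transport across the %s", c("cargo", "membrane"), b)$text
#' @export
renderTemplate <- function(text, vars, binding,
                           mode = c("label", "logical")) {
  mode <- match.arg(mode)
  pf <- .parsePrintf(text)
  if (length(vars) != pf$nconv)
    .dosdpError("dosdp_arity_error",
                paste0("ARITY_MISMATCH: template has ", pf$nconv,
                       " conversions but ", length(vars),
                       " vars were listed: ", text))
  fills <- character(pf$nconv)
  for (k in seq_len(pf$nconv)) {
    v <- vars[[k]]
    ref <- binding@classFillers[[v]]
    if (is.null(ref))
      .dosdpError("dosdp_unbound_var",
                  paste0("unbound variable '", v, "' in template: ", text))
    fills[k] <- if (mode == "logical") .labelToken(ref$label) else ref$label
  }
  out <- pf$segments[1L]
  for (k in seq_len(pf$nconv))
    out <- paste0(out, fills[k], pf$segments[k + 1L])
  list(text = out, template = text, vars = vars, binding = binding)
}

#' Invert a printf template against a rendered string
#'
#' Returns every binding that re-renders to `text` exactly (anchored,
#' whole-string matching) and whose captured substrings all resolve in
#' `labelIndex`. Multiple segmentations of an ambiguous string are all
#' returned, ordered by the lexicographic serialisation of the binding;
#' an empty list means no binding exists.
#'
#' @param template template text.
#' @param vars ordered variable names matching the template conversions.
#' @param text the rendered string to invert.
#' @param labelIndex named character: readable label -> CURIE; captured
#'   substrings must be labels in this index.
#' @return list of [Binding-class] candidates (class fillers only).
#' @export
reverseTemplate <- function(template, vars, text, labelIndex) {
  pf <- .parsePrintf(template)
  if (length(vars) != pf$nconv)
    .dosdpError("dosdp_arity_error",
                paste0("ARITY_MISMATCH: template has ", pf$nconv,
                       " conversions but ", length(vars), " vars"))
  segs <- pf$segments
  results <- list()
  nseg <- length(segs)

  recurse <- function(pos, segIdx, captured) {
    seg <- segs[segIdx]
    if (nzchar(seg)) {
      if (substr(text, pos, pos + nchar(seg) - 1L) != seg) return(invisible())
      pos <- pos + nchar(seg)
    }
    if (segIdx == nseg) {
      if (pos == nchar(text) + 1L)
        results[[length(results) + 1L]] <<- captured
      return(invisible())
    }
    nxt <- segs[segIdx + 1L]
    remaining <- nchar(text) - pos + 1L
    if (remaining < 1L) return(invisible())
    if (segIdx + 1L == nseg && !nzchar(nxt)) {
      cap <- substr(text, pos, nchar(text))
      if (nzchar(cap)) recurse(nchar(text) + 1L, nseg, c(captured, cap))
      return(invisible())
    }
    ## try every end position for this capture
    for (end in seq(pos, nchar(text))) {
      cap <- substr(text, pos, end)
      if (!nzchar(cap)) next
      recurse(end + 1L, segIdx + 1L, c(captured, cap))
    }
    invisible()
  }
  recurse(1L, 1L, character(0))

  out <- list()
  seen <- character(0)
  for (caps in results) {
    if (length(caps) != pf$nconv) next
    if (!all(caps %in% names(labelIndex))) next
    ## a variable repeated in the template must capture one value
    consistent <- TRUE
    assign <- list()
    for (k in seq_along(vars)) {
      v <- vars[[k]]
      if (!is.null(assign[[v]]) && assign[[v]] != caps[k]) {
        consistent <- FALSE
        break
      }
      assign[[v]] <- caps[k]
    }
    if (!consistent) next
    cf <- lapply(assign, function(lab) entityRef(lab, labelIndex[[lab]]))
    key <- paste(names(assign), unlist(assign), sep = "=", collapse = ";")
    if (key %in% seen) next
    seen <- c(seen, key)
    out[[length(out) + 1L]] <- binding(classFillers = cf)
  }
  out[order(seen)]
}
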