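---
title: "Design patterns for OWL term generation: the dosdp methods"
author: "dosdp package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design patterns for OWL term generation: the dosdp methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosdp)
```

## The problem this package addresses

Large bio-ontologies such as the Gene Ontology sustain their class
hierarchies by inference: classes carry OWL equivalence axioms (necessary
and sufficient membership conditions) and a reasoner places them. Whole
branches of such ontologies are stereotyped — every "X transport across
the Y membrane" term has the same shape of label, textual definition and
equivalence axiom, differing only in the fillers X and Y. Dead Simple OWL
Design Patterns (DOS-DPs) capture one such stereotype in a single YAML
document that a curator without OWL-API expertise can read and edit, and
that a program can validate, instantiate, invert and document.

This package implements the full DOS-DP lifecycle in R:

* **pattern model** — parse, validate and serialise pattern documents,
  including the OBO convenience extension (`normalizeObo()`);
* **expression language** — a Manchester-syntax class-expression
  parser/printer and a printf template engine that also runs backwards
  (`parseClassExpression()`, `renderTemplate()`, `reverseTemplate()`);
* **generation** — instantiate one binding (`instantiate()`) or a TSV
  filler table (`generateBatch()`) into OWL classes, serialised as OWL
  functional-style syntax (`writeFragment()` / `readFragment()`);
* **matching** — recover the variable fillers of existing classes and
  check conformance (`matchClass()`, `findMatches()`,
  `checkConformance()`);
* **reasonette** — a small structural subsumption engine
  (`subsumes()`, `classify()`) and pattern-hierarchy derivation
  (`patternHierarchy()`);
* **docgen** — markdown documentation per pattern (`renderMarkdown()`);
* **fixtures** — a deterministic, self-contained test corpus;
* **cli** — a `dosdp` wrapper script with one subcommand per capability.

## The document model

A pattern document is the JSON-compatible subset of YAML: anchors,
aliases, merge keys and tags are rejected at parse time, so any
JSON-schema-capable consumer reads the same files. Entities appear
throughout the pattern as quoted, human-readable identifiers; four
dictionaries (`classes`, `relations`, `annotationProperties`,
`dataProperties`) map these labels to CURIEs, and a JSON-LD-like prefix
context maps CURIE prefixes to IRI bases. Labels must be unique within a
document, not globally — identification is scoped to the pattern.

Variables come in two kinds. `vars` range over OWL classes, their ranges
written as Manchester expressions over dictionary labels
(`'chemical entity' or 'transcript'`); `data_list_vars` hold lists of
typed literals (e.g. `def_dbxref`, a list of XSD strings used as
definition cross-references). Output is specified by two core fields —
`annotations` and `logical_axioms` — whose entries are axiom
specifications of six kinds: `printf_owl`, `printf_annotation` and
`list_annotation`, plus the convenience kinds (`equivalentTo`,
`subClassOf`, `disjointWith`, `GCI` slots) and the OBO-extension kinds
behind the `name`, `def`, `comment`, `xrefs` and `exact_synonyms` slots.

`normalizeObo()` rewrites OBO slots into explicit core specs against
fixed OBO-convention properties (rdfs:label; the IAO textual-definition
property IAO:0000115; rdfs:comment; oboInOwl hasDbXref and
hasExactSynonym), defaults the readable-identifier property to the label
property and the identifier base to the OBO PURL convention. The
operation is idempotent and the identity on core documents. A document
key names these mappings nowhere, so a clash with an explicit annotation
spec for the same property is reported as a conflict rather than
silently duplicated.

Validation (`validatePattern()`) reports, rather than throws: each
violation carries a machine-readable code, a path into the document and
a severity. Only ERROR rows make a document invalid; unknown top-level
keys are warnings by default and errors under `strict`, a forward
compatibility choice — schema extensions are expected, typos should
still surface.

## The template engine and its inverse

The printf dialect is deliberately minimal: `%s` conversions and the
`%%` escape, nothing else. Every printed use of the pattern language
substitutes entity labels into strings, and numeric conversions would
make inversion ambiguous. Rendering substitutes the readable label of
each bound entity, in the order of the spec's `vars` list; in logical
mode, labels containing whitespace are single-quoted so the result
parses as Manchester syntax. (Whether logical substitution should
auto-quote is an implementation choice of this package, not mandated by
the format; quoting only multi-word labels keeps rendered axioms
identical to what a curator would type.)

`reverseTemplate()` inverts a rendering: it enumerates every anchored
segmentation of the input string consistent with the template's literal
segments, keeps only candidates whose captured substrings are labels in
the supplied index, and returns all surviving bindings sorted by their
serialised form. Pure regular-expression inversion over-generates
bindings that name no known entity; the label-index filter is what makes
the inverse useful. Ambiguity is possible in principle ("a b c" against
`%s %s` with labels "a", "a b", "b c", "c") and all candidates are
returned — callers decide.

Class-expression matching does not go through text at all. The logical
template is parsed once into an AST whose conversions become variable
leaves, and `matchClass()` unifies that AST against each equivalence
axiom of a candidate class by backtracking bijection over the
canonically ordered operands of `and`/`or`. Matching is purely
structural: the paper's workflow recovers fillers from classes that were
*generated* by a pattern, so syntactic unification modulo
associativity/commutativity is exactly sufficient, decidable and fast;
the reasoner is used only for optional range checks. Variables bind
named classes by default (`complexFillers = TRUE` allows sub-expression
fillers); a variable repeated across axioms must bind identically.

## The structural reasoner

`subsumes()` implements a deliberately incomplete, sound fragment of OWL
subsumption sufficient for the pattern workflow: reflexive-transitive
closure over asserted named subclass axioms; unfolding of definitions
(equivalence axioms) in both directions; conjunction introduction and
elimination; disjunct introduction, with a disjunctive subsumee requiring
every disjunct to be subsumed; and existential monotonicity over declared
sub-properties. There are no property chains, no transitivity of object
properties, no disjointness and no complement reasoning — those are the
province of a full reasoner, which can be swapped in behind the same
operation contract. This fragment reproduces the worked example's
classification (leucine transport under amino-acid transport) and is
enough to order patterns by generality.

`classify()` evaluates all ordered pairs over the fragment plus
background classes, drops mutual (equivalent) pairs, and transitively
reduces the strict relation with a deterministic ordering, returning the
direct subclass pairs. The test suite holds this output equal to an
independent brute-force oracle — Warshall closure plus genus/differentia
normal-form coverage — on 100 random terminologies of up to ~28 classes.

`patternHierarchy()` follows the format's own recipe for relating
patterns without an inheritance mechanism: build one prototype class per
pattern by substituting each variable's *range expression, verbatim* for
the variable ("default fillers"), classify the prototypes, and emit the
transitively reduced edges. Using ranges verbatim (rather than minting
fresh subclasses of the ranges) is an interpretation this package makes
explicitly; it makes the prototype exactly the most general instance the
pattern admits.

## Generation, serialisation, identifiers

`instantiate()` is a pure function of (document, binding, identifier):
annotation templates render in label mode; list specs expand to one
axiom — or one axiom annotation, for nested specs such as definition
cross-references — per list element, typed with the variable's declared
XSD datatype (plain strings stay untyped); logical templates render in
logical mode and are parsed back into expressions, so the stored axiom
is an AST, not a string. In strict mode each class filler is checked
against its variable's range with `subsumes()`; lenient is the default
because range checking needs an ontology that callers may not have.

`generateBatch()` consumes a TSV with one column per variable
(pipe-separated list cells, an optional `iri` column) and mints
identifiers with a zero-padded 7-digit counter under a CURIE prefix —
the OBO numbering convention — unless a row pins its own. Row order
matters only to minted-identifier assignment; duplicate bindings
collapse to one class with a warning; identifier collisions are errors.

Fragments serialise to OWL 2 functional-style syntax (prefix
declarations, then declarations, annotation assertions with inline axiom
annotations, SubClassOf/EquivalentClasses/DisjointClasses). Output is
deterministic: classes sorted by identifier, annotations in stored
order. Reading the writer's output reproduces the fragment exactly when
label annotations for all referenced entities travel along (as in any
merged ontology); a standalone generated file cannot carry the labels of
external entities, so its round trip preserves structure on CURIEs while
labels fall back to identifiers. No other serialisations (RDF/XML,
Turtle, OBO flat file) are supported.

## The fixture corpus — what it emulates, and what it does not

The fixture ontology is a nine-class miniature of the chemistry-backed
transport branch the format's worked example draws on: a
chemical-entity branch (`chemical entity` > `amino acid` >
leucine/glycine/serine), `transcript`, a membrane branch, the process
genus `transport`, and the object properties `transports` and
`crosses`. Entities live in a reserved `EX` namespace rather than real
CHEBI/GO/RO identifiers — pinning real IDs would create false provenance
and external coupling. The transmembrane pattern over it reproduces the
worked example end to end: instantiating (leucine, plasma membrane)
yields the label "leucine transport across the plasma membrane", a
definition carrying one cross-reference axiom annotation per
`def_dbxref` element, and automatic classification under the
(amino acid, plasma membrane) class.

`randomPatterns()` draws one to three class variables per pattern with
ranges from the fixture hierarchy, distinct relations per restriction
slot (which keeps unification unambiguous by construction), and three
bindings per pattern whose expected labels are computed with base
`sprintf`, independently of the template engine. `randomTBox()` draws
primitive DAGs of 10–22 classes, up to three properties and 3–6 defined
classes whose definitions are genus–differentia conjunctions over
primitives only — a restriction that makes the closed-form test oracle
valid. All generators are reproducible from their seed and leave the
caller's RNG state untouched.

What passing these tests shows is that the machinery is internally
consistent and reproduces the published worked example; the corpus does
not emulate real-ontology scale, annotation noise, multiple equivalence
axioms per class, imported-ontology churn, or hand-edited axioms that
only approximately follow a pattern. Matching against such ontologies
will correctly report non-conformance, but the corpus cannot measure how
often real curation produces it. Problem sizes in the suite — a
20-pattern/60-binding inversion corpus, 100 random terminologies,
1000 expression round trips — were chosen as comfortably exercising
every code path while keeping the default test run fast.

## Numerical and design choices

* **Canonical AC order.** `and`/`or` operands are stored sorted by a
  serialised key built from CURIEs, so structurally equal expressions
  are `identical()`; duplicates are removed (idempotence). This is what
  makes byte-determinism of printing and order-independence of matching
  cheap.
* **Tie-breaks.** Reverse-template candidates and match candidates are
  ordered lexicographically by serialised binding; among match
  candidates the first fully annotation-conformant one wins. Transitive
  reduction iterates nodes in sorted order.
* **Degenerate inputs.** Empty list fillers produce zero axioms (not an
  error); a template with zero conversions needs an empty `vars` list;
  empty fragments serialise to a bare prefixed document; cyclic
  definition unfolding in the reasoner is cut off and treated as
  non-derivable (definitions are expected acyclic, asserted hierarchies
  are checked acyclic in fixtures).
* **Pattern identity.** A document may store its `pattern_iri` or derive
  it from a base plus `pattern_name`; both are accepted on input
  (`patternIri()`).
* **Exit codes.** The CLI returns 0 on success, 1 on
  validation/conformance failure (with the JSON report still emitted),
  2 on usage errors; diagnostics go to standard error.

## Known limitations

Inherited from the format by design: no inheritance or composition
between patterns, no optional clauses, and no Manchester constructs
beyond `and`/`or`/`not`/`some` (`only`, cardinalities, `value` and
property expressions are recognised and rejected). Specific to this
implementation: the reasoner's incompleteness documented above;
list-annotation specs carry data, not identity, so they are not required
to match for conformance; and OBO flat-file output is out of scope.
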