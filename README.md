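# dosdp

Tools for authoring, validating and applying **Dead Simple OWL Design
Patterns (DOS-DPs)** — YAML documents that template how classes of a given
kind are named, defined and logically axiomatised in OBO-style
bio-ontologies.

Bio-ontologies such as the Gene Ontology automate large parts of their
classification with OWL equivalence axioms: a class like *leucine
transport across the plasma membrane* is defined by necessary and
sufficient conditions,

```
'transport' and ('transports' some 'leucine') and ('crosses' some 'plasma membrane')
```

and a reasoner places it under *amino acid transport across the plasma
membrane* automatically, because leucine ⊑ amino acid in the chemical
ontology. A DOS-DP captures the whole family of such terms once — a name
template `"%s transport across the %s"`, a definition template with
cross-references, an equivalence template, variables `cargo` (range
`'chemical entity' or 'transcript'`) and `membrane` (range `'membrane'`)
— so that new terms are made by supplying fillers, existing terms can be
matched back to the pattern to recover their fillers, and the pattern
itself is the documentation.

The package is aimed at ontology engineers and pipeline authors. It
provides, in R:

* pattern parsing/validation over the JSON-compatible subset of YAML,
  including the OBO convenience extension (`parsePattern()`,
  `validatePattern()`, `normalizeObo()`);
* a Manchester-syntax class-expression parser/printer and a printf
  template engine that also runs backwards (`parseClassExpression()`,
  `renderTemplate()`, `reverseTemplate()`);
* term generation, singly or in bulk from TSV filler tables, with
  OBO-convention identifier minting (`instantiate()`,
  `generateBatch()`), serialised as OWL functional-style syntax;
* pattern matching and conformance checking (`matchClass()`,
  `findMatches()`, `checkConformance()`);
* a small structural subsumption engine for range checks,
  classification of generated classes and pattern-hierarchy derivation
  (`subsumes()`, `classify()`, `patternHierarchy()`);
* markdown documentation generation (`renderMarkdown()`);
* a deterministic fixture corpus (`makeFixtureOntology()`,
  `makeTransmembranePattern()`, `randomPatterns()`, `randomTBox()`);
* a command-line wrapper (`inst/scripts/dosdp`) with subcommands
  `validate`, `generate`, `match`, `conform`, `docs`, `hierarchy`,
  `fixtures`.

## Worked example

```r
library(dosdp)

pat <- makeTransmembranePattern()     # the transmembrane-transport pattern
ont <- makeFixtureOntology()          # 9-class mini chemistry/membrane ontology

b <- leucineBinding()                 # cargo=leucine, membrane=plasma membrane,
                                      # def_dbxref = PMID:1, GOC:dos
cls <- instantiate(pat, b, "EX:1000001", ontology = ont, strict = TRUE)
cls
#> GeneratedClass <EX:1000001> with 2 annotation and 1 logical axiom(s)

toManchester(cls@logicalAxioms[[1]]$expr)
#> transport and (transports some leucine) and (crosses some 'plasma membrane')
```

The two annotation axioms are the rendered label
(`"leucine transport across the plasma membrane"`) and the rendered
definition, the latter carrying one `oboInOwl:hasDbXref` axiom
annotation per supplied `def_dbxref` element. Generating the amino-acid
counterpart and classifying shows the automated placement — the last
rows are the inferred direct superclasses of the two generated classes:

```r
aa <- instantiate(pat, binding(
  classFillers = list(cargo = entityRef("amino acid", "EX:0000003"),
                      membrane = entityRef("plasma membrane", "EX:0000009")),
  listFillers = list(def_dbxref = character(0))), "EX:1000002")
frag <- ontologyFragment(classes = list("EX:1000001" = cls, "EX:1000002" = aa))
classify(frag, background = ont)
#>          sub      super
#> ...
#> 6 EX:1000001 EX:1000002   # leucine transport < amino acid transport
#> 7 EX:1000002 EX:0000001   # amino acid transport < transport
```

Matching runs the pattern backwards and recovers the fillers exactly:

```r
res <- matchClass(pat, "EX:1000001", mergeFragments(ont, frag))
res
#> MatchResult <EX:1000001>: logicalMatch=TRUE, conformant=TRUE
res@binding
#> Binding
#>   cargo = leucine (EX:0000004)
#>   membrane = plasma membrane (EX:0000009)
#>   def_dbxref = [PMID:1, GOC:dos]
```

From a shell, the same pipeline is:

```sh
dosdp=$(Rscript -e 'cat(system.file("scripts","dosdp",package="dosdp"))')
Rscript $dosdp fixtures --out fx
Rscript $dosdp validate fx/transmembrane_transport.yaml
Rscript $dosdp generate fx/transmembrane_transport.yaml \
    --table fx/transmembrane_fillers.tsv \
    --ontology fx/fixture_ontology.ofn --out out --strict
```

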