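---
title: "Populating ontology design patterns from tabular templates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Populating ontology design patterns from tabular templates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontopop)
```

## The problem

Normalised ontology engineering describes each class of interest as a
*genus* refined by *differentia*: a kidney cell type, say, is a `cell` that
is `part_of` some anatomical structure and `participates_in` some
biological processes. Once such a design pattern is fixed, producing the
ontology is a matter of instantiating it many times — work that is
repetitive for an ontologist and inaccessible to the domain expert who
actually holds the knowledge. `ontopop` splits the work: domain knowledge
is collected in a constrained table (one entity per row, one relationship
type per column), and a short pattern script compiles every row into OWL
axioms. This vignette explains the model implemented by the package, the
choices made where the design was genuinely open, and what the bundled
tests do and do not demonstrate.

## Vocabularies and validation sets

`load_ontology()` reads a vocabulary in OBO flat-file, Turtle or RDF/XML
form into a snapshot indexing its declared classes, individuals and object
properties, their labels, and three asserted edge tables: subclass
(`is_a`/`rdfs:subClassOf`), instance-of, and relationship edges. Part-of
edges are recognised both from OBO `relationship: part_of` tags and from
OWL axioms of the shape `SubClassOf(X, part_of some Y)`; other relationship
types are indexed but not traversed.

There is deliberately **no reasoner**. A column range such as "all
subclasses of *nucleation*" is resolved by `resolve_range()` as a closure
over told edges only. This is a documented limitation, not an
approximation made casually: every range used by the worked examples (all
subclasses of the cell root; subclasses *or parts* of the urinary system;
all subclasses of *biological_process*) is decided by the asserted
hierarchy alone, and keeping resolution syntactic makes validation instant
and deterministic. Four selectors are supported: `all-subclasses`
(reachable by one or more hops over the chosen traversal relations —
subclass and/or part-of), `direct-subclasses`, `all-individuals` and
`direct-individuals`.

Two open points were settled as follows. The root itself is **excluded**
from `all-subclasses` (a column constrained to subclasses of *nucleation*
should not accept "nucleation" as a value); and part-of is traversed
**transitively**, because a cell located in the juxtaglomerular complex is
equally located in the kidney. Cycles in asserted hierarchies — which do
occur in real vocabularies — are tolerated by a visited-set traversal and
reported once as a warning; rejoining diamond paths are silent.

Validation sets are ordered lexicographically by IRI so that every
serialization of a set (hidden worksheet, dropdown list, autocomplete
pool) is reproducible.

## Templates and cell parsing

A template cell may hold several values separated by a vertical bar. Each
piece is trimmed and resolved against the column's validation set — first
by label (case-insensitive, internal whitespace collapsed; matching rules
are unspecified upstream, so the most forgiving convention that cannot
merge distinct terms was chosen), then as a CURIE, then as a full IRI.
Pieces that resolve are *resolved* (green); the rest are *unknown* (red)
and act as placeholders for minting. Invalid content is data, never an
error: a half-filled template must survive validation and generation.

Because ontology labels can themselves contain a bar (GO synonyms do), the
separator supports a backslash escape `\|`; no escape mechanism exists
upstream, so this is a package extension. Duplicate tokens within a cell
are kept (the expansion engine deduplicates conjuncts syntactically
anyway). Auto-completion is substring matching with prefix matches ranked
first; a full regular-expression query mode was considered and left out —
the refinement property (each extra character filters the previous
suggestion list) is what matters for form filling, and it holds for plain
substring matching.

## The pattern language

The package implements the pattern-script subset that template population
actually needs: `CLASS` variables; defined variables whose body is either a
class-expression template over `and`/`some` or the
`createIntersection(?v.VALUES)` macro; and `ADD` actions asserting
`SubClassOf` or `EquivalentTo`. Everything else a full pre-processor
language offers (axiom removal, `SELECT` queries, variable constraints,
property variables) is rejected with an explicit unsupported-construct
error rather than silently ignored.

Expansion semantics, in order:

1. Input variables receive the ordered term lists bound from the row's
   cells; an empty cell is an empty list.
2. A defined variable with an expression body is instantiated once per
   value of each input variable it references (`.VALUES`); several
   referenced variables produce their cartesian product, first variable
   slowest. Zero values give zero instances.
3. `createIntersection` conjoins the instances, flattening nested
   intersections and removing syntactically duplicate conjuncts (first
   occurrence wins). One conjunct stays unwrapped.
4. Each action emits one axiom per subject value. A `SubClassOf` whose
   object is an intersection is **split into one axiom per conjunct**; an
   `EquivalentTo` keeps the intersection whole. Actions over variables
   with zero values emit nothing — partially populated rows must not abort
   a batch.

The splitting rule deserves a note: the genus conjunct (`cell and ...`)
recurs in every macro instance, so after deduplication a three-process row
yields exactly four subclass entries — the genus plus three restrictions —
which is the frame a Manchester rendering of the target ontology actually
shows. Splitting is applied only to `SubClassOf`; equivalence axioms are
semantically destroyed by splitting, and stay intact. Deduplication is
syntactic (identical ground AST), never semantic.

A bare name in a script (e.g. the conjunct `cell`, or the relation
`hasNucleation`) is resolved against the loaded snapshot first as a
CURIE/IRI in the default namespace, then by label. That is how `cell`
grounds to the cell-ontology root `CL_0000000` without the script author
spelling an identifier.

## Minting and provenance

Unknown tokens become fresh terms under a minting policy: base namespace,
prefix label, zero-padded width (default 7) and a strictly increasing
counter; candidates colliding with loaded IRIs are skipped. The registry
maps normalised labels to minted terms, so the same new label in two rows
mints once. Minted terms get a `Declaration` and a label annotation. The
counter start is configurable and the bundled kidney workflow pins it to
1028 so the worked example is bit-reproducible; how the original numbering
arose upstream is unknowable, so pinning is the honest choice.

Every generated logical axiom carries a provenance tag — template id, row
index, script id, timestamp — serialized as `owl:Axiom` annotations under
a small built-in annotation namespace (no standard vocabulary is mandated
upstream). The timestamp is injected, not wall-clock, so identical inputs
produce byte-identical output; callers wanting real timestamps pass one.

## Serialization

Manchester rendering groups axioms into one frame per subject in
first-generation order: `EquivalentTo:` entries, then `SubClassOf:`
entries, comma-separated, with restrictions as `p some X` and parentheses
around complex conjuncts. Keyword casing follows the Manchester standard
spellings; comparisons in the tests are case-insensitive on keywords
because printed renderings vary.

RDF output (Turtle and RDF/XML) uses the standard OWL mapping: blank
`owl:Restriction` nodes, `owl:intersectionOf` lists written as explicit
`rdf:first`/`rdf:rest` chains, equivalence via `owl:equivalentClass`. Both
writers share one triple table, and `read_generated_rdf()` reconstructs
the axiom multiset from either dialect; serialize → parse → serialize is a
fixpoint at the axiom level, which the tests check on randomized
ontologies. The Turtle and OBO parsers cover the constructs the package
emits and the miniature vocabularies use — prefix declarations, prefixed
names, blank nodes, collections, string literals — not the full grammars;
no installed R package parses these formats, so the restricted readers are
part of the package.

Excel workbooks store the template grid on a visible sheet and one record
per validation-set member — covered cell range, term URI, label, source
ontology URI — on a hidden sheet named `_ontology_validation` (no naming
convention exists upstream; the schema implemented is exactly that
three-field record plus the range). Native dropdown validations reference
the hidden label ranges. The TSV dialect (header row of column names,
`|`-separated cell values) is the canonical round-trip surface because
byte-exact assertions on zip-packaged spreadsheets are brittle; `.xls`
compatibility was dropped in favour of `.xlsx`.

## Fixtures and what the tests show

`make_fixtures()` writes miniature vocabularies containing every term the
worked examples mention, each in OBO and Turtle: a cell-type fragment
(root plus ten named cells), a nucleation fragment (quality plus four
subclasses), a kidney partonomy (ten terms, nine part-of edges), a
biological-process fragment, and the relation file. Terms not pinned by a
worked example are invented to be plausible; the bundle is synthetic and
says so in its manifest location, not a redistribution of any source
vocabulary. The kidney template has thirteen rows — twelve valid filler
rows and the juxtaglomerular row (one anatomy value, three process values,
one unknown cell label) — and the nucleation template reproduces the
partially populated sheet with its single invalid cell at row 5, column A.

The randomized suites run at sizes chosen to finish in seconds while still
exercising the structures: reachability oracles on 200-node DAGs, macro
expansion up to five values, fifty random ontologies through the RDF
round-trip. Passing them shows the implementation is faithful to its own
semantics on hierarchies and expressions of realistic shape; it does not
show that full-size reference vocabularies parse (the loaders cover
restricted grammars), that label matching is unambiguous in vocabularies
with near-duplicate labels, or anything about reasoner-inferred
hierarchies, which are explicitly out of scope.

## Known limitations

- No DL reasoning anywhere: range resolution and the generated ontology
  both live on asserted axioms. Classification is downstream work for a
  reasoner-equipped editor.
- Only existential (`some`) restrictions are generated; the worked
  patterns use nothing else.
- One entity per row, one variable per column; non-uniform spreadsheet
  layouts are out of scope.
- Value sets are conjunctions; a union interpretation of multi-valued
  cells would need a different macro.
- The workbook writer shells out to Python's openpyxl; environments
  without it still have the full TSV path.
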