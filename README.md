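# ontopop

Template-based ontology population for R: ontology-constrained tabular
templates are validated against term sets drawn from loaded vocabularies,
then compiled through a small pattern language into OWL axioms with minted
identifiers and provenance annotations.

## Who this is for

Building an application ontology often means instantiating the same axiom
pattern hundreds of times — e.g. describing every cell type of an organ by
its anatomical location and the biological processes it participates in.
`ontopop` separates that work into two roles: a domain expert fills a
spreadsheet-like template whose columns only accept terms from designated
regions of reference vocabularies, and an ontology engineer writes a short
pattern script that turns each row into OWL axioms. The package covers the
whole pipeline: loading OBO/Turtle/RDF-XML vocabularies, resolving column
ranges into validation sets, per-token cell validation with red/green
status, pattern parsing and expansion, identifier minting for unknown
terms, and Manchester-syntax / RDF output.

## The core model

A pattern script declares class variables, optionally defines derived
variables, and adds axioms:

```
?cell:CLASS,
?anatomyPart:CLASS,
?partOfRestriction:CLASS = cell and ro:part_of some ?anatomyPart,
?anatomyIntersection:CLASS = createIntersection(?partOfRestriction.VALUES)
BEGIN
ADD ?cell equivalentTo ?anatomyIntersection
END;
```

Input variables (`?cell`, `?anatomyPart`) are bound to template columns by
name. A cell may hold several values separated by a vertical bar; the
`createIntersection(... .VALUES)` macro instantiates its defining
expression once per bound value and conjoins the results, so a cell listing
three processes becomes three existential restrictions
`ro:participates_in some GO:...`. `ADD ?x SubClassOf <intersection>` emits
one subclass axiom per conjunct (after syntactic deduplication);
`equivalentTo` keeps the intersection whole. Terms absent from every loaded
vocabulary are minted fresh IRIs of the form `PREFIX_NNNNNNN` from a
zero-padded counter, with one registry entry per distinct label.

## Worked example

```r
library(ontopop)
d <- tempfile(); make_fixtures(d)   # miniature vocabularies + templates

ctx <- load_workflow_context(file.path(d, "nucleation_workflow.yaml"))
tpl <- read_template_tsv(file.path(d, "mononucleate_row.tsv"),
                         validations = ctx$validations,
                         snapshot = ctx$snapshot)
onto <- generate(tpl, ctx$scripts, ctx$column_map, ctx$policy,
                 snapshot = ctx$snapshot)
cat(render_manchester(onto))
```

prints (prefix block elided):

```
Class: cto:CL_0000113
    SubClassOf:
        hasNucleation some pato:PATO_0001407
```

i.e. the single row "Mononuclear phagocyte / mononucleate" became one
subclass axiom relating the cell type (`CL_0000113`) to the nucleation
quality `mononucleate` (`PATO_0001407`). The bundled `kup_workflow.yaml`
runs the two-script cell pattern over a kidney template; its
juxtaglomerular row (one anatomy value, three process values, and a cell
label unknown to the cell-type vocabulary) mints `kupo:KUPO_0001028` and
produces one equivalence with `cell:CL_0000000 and (ro:part_of some
MA:MA_0002546)` plus four subclass entries.

The same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/ontopop fixtures -o fixtures/
Rscript inst/cli/ontopop validate fixtures/nucleation_template.tsv \
    --config fixtures/nucleation_workflow.yaml --strict
Rscript inst/cli/ontopop generate fixtures/mononucleate_row.tsv \
    --config fixtures/nucleation_workflow.yaml -o out/
```

`validate` exits non-zero under `--strict` when any token fails its
column's validation set (here: "Proximal tubule epithelial cell" at row 5,
column A); `generate` writes Manchester, Turtle, RDF/XML and a per-row run
report.

## Package layout

- `R/ontology-store.R` — OBO/Turtle/RDF-XML loading, range resolution,
  validation sets
- `R/template-model.R` — templates, multi-valued cell parsing, validation
  reports, auto-completion
- `R/workbook-io.R` — TSV dialect, Excel workbooks with hidden validation
  sheets, workflow configs
- `R/pattern-lang.R` — pattern parser, pretty-printer, expansion engine
- `R/generator.R`, `R/rdf-io.R` — row binding, minting, provenance,
  Manchester and RDF output
- `R/fixtures.R`, `R/cli.R` — fixture bundle, synthetic generators, CLI

See `vignettes/ontology-population.Rmd` for the design and its limits.
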