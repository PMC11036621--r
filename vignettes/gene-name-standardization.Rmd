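---
title: "Standardizing organelle gene names and building synonym-aware searches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardizing organelle gene names and building synonym-aware searches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genesyn)
```

## The model

genesyn treats gene nomenclature as a controlled-vocabulary mapping problem.
The objects are:

* a **canonical vocabulary** (`canonical_genes()`): 16 mitochondrial and 98
  chloroplast HUGO-style short symbols for the markers routinely used in
  phylogenetics — protein-coding (CDS) and ribosomal (rRNA) genes plus the
  mitochondrial control region. The two organelle namespaces are independent:
  `16S` is a valid mitochondrial symbol while the chloroplast 16S rRNA gene
  is `rrn16S`, and a lookup never crosses namespaces. tRNA genes are
  deliberately excluded from the vocabulary and from the genome scanner; this
  package is not suitable for tRNA work.

* a **synonym table** (`syn_table`): a many-to-one map from observed name
  variants to canonical symbols, partitioned by organelle, with a version
  string and build timestamp. Entries are keyed on a *normalized* form of the
  variant.

The central assumption is that variation in deposited annotations comes in
two kinds that must be treated differently. *Mechanical* variation — case,
hyphen vs space vs underscore, stray whitespace, surrounding quotes — is
folded away by `canonicalize_text()`, which is deterministic and idempotent.
*Substantive* variation — alternative symbols (`COX1` for `COI`), different
long forms, genuine typos ("cytchrome", "chytochrome", "cutochrome",
"ATP synthaes") — is never guessed at: each such spelling is stored as an
explicit variant in the table. There is no fuzzy or edit-distance matching
anywhere; an unknown spelling is a *miss*, reported as an `NA` sentinel and
appended to a plain-text miss log for later curation. This makes lookup
behaviour exactly reproducible and keeps the database the single source of
truth about which spellings exist.

Normalization is deliberately conservative about what it folds: digits, dots
and internal punctuation other than hyphen/underscore are preserved, so
`rrn4.5S`, `rrn5S`, and the RNA-polymerase subunits beta, beta' and beta''
remain distinct keys.

## Table invariants

`syn_table()` is a validating constructor; everything downstream relies on
its guarantees:

* each normalized key maps to exactly one symbol per organelle — a
  conflicting duplicate is a hard **ambiguity error** (never a warning),
  because a lookup that could return two symbols is useless for
  standardization; byte-identical duplicates collapse silently;
* every referenced symbol must exist in the canonical vocabulary of that
  organelle (a typo'd *symbol* in a curated file should fail loudly, not
  create a new gene);
* every symbol is present as a variant of itself — self-maps are
  materialized at construction if absent, so canonical names always resolve
  to themselves without special-casing;
* variants may not contain double quotes, because every variant must be
  renderable inside a quoted Entrez query term and no escaping dialect is
  defined for that syntax.

Validation is total: a file either loads completely or raises a typed error;
there is no partially loaded state. The on-disk canonical form is UTF-8 CSV
(`variant,short_name,organelle,category`) with the version inside the file
as a `# version=` comment row rather than in the filename, so the version
survives renames and copies. The JSON export mirrors the same fields plus
the version and timestamp and round-trips exactly through `load_table()`.

`update_table()` refreshes the local database from a URL but is strictly
failure-isolated: the downloaded file is validated in a temporary location
and only then moved over the destination, so a network failure or a corrupt
upstream file can never damage the local table, and no other function in the
package touches the network at all.

## Building the database from genome annotations

`build_from_files()` implements the harvest loop over GenBank flat files:
parse each record, extract the `gene` and `product` qualifiers of every CDS
and rRNA feature, and fold each extraction into a draft table with
product-name deduplication — if the normalized product name already exists
for this organelle the feature contributes nothing; otherwise the pair
(product name → canonical symbol) is inserted. The canonical symbol is
resolved through a *canonical map* (by default the packaged seed table),
trying the `gene` qualifier first — symbol qualifiers like `COX1` are far
closer to the canonical vocabulary than free-text products — and the
`product` qualifier as fallback. An extraction neither qualifier of which
resolves lands in an **unmapped queue** for manual curation rather than in
the draft: the original assignment of new product names to symbols is a
curation decision, and the builder makes that decision explicit instead of
guessing. An extraction whose resolution *disagrees* with the symbol already
stored for its product key is recorded as a conflict and leaves the draft
unchanged.

Keying insertions on the product name means each feature adds at most one
entry, which gives the build its accounting identities (`new_entries +
duplicates_skipped` = resolvable features; `new_entries` = draft growth) and
its algebraic properties: idempotence (rescanning a corpus adds nothing) and
order-insensitivity of the final variant→symbol map (input order only
affects which accession is recorded as first witness). Gene-qualifier
spellings are not inserted as separate draft entries; symbol variants remain
findable because the canonical map is part of the merged result
(`syn_table_merge(draft, canonical_map)`), which keeps the draft a pure
record of what the corpus itself contributed.

Two annotation realities get special handling. The mitochondrial control
region is a standardized marker but is annotated as neither CDS nor rRNA, so
the scanner additionally captures `D-loop` features and `misc_feature`s
whose note mentions "control region" or "D-loop"; without this the marker
would be unreachable by the builder. And because no installed R package
parses GenBank feature tables from local flat files, the package carries its
own small flat-file parser (`read_genbank()`), covering multi-record files,
wrapped qualifier values and gzip input; its output is cross-checked against
Biopython's parser in the test suite.

## Query construction

`build_query()` renders the synonym-aware advanced search: every variant of
a marker as a quoted, field-tagged term (`"..."[All Fields]`, or `[Title]`,
`[Abstract]`, `[MeSH Terms]`), OR-joined, optionally prefixed by an
`[Organism]` clause. Term order is canonical symbol first, then the table's
curation order — a stable order that makes output reproducible and matches
how reference queries are conventionally written (most-recognizable name
first); plain ASCII double quotes are used throughout since Entrez accepts
them and typographic quotes are a typesetting artifact. The GenBank/PMC
distinction does not change term syntax; it selects the database in the
optional `esearch_url()` rendering. `genome_retrieval_query()` provides the
fixed clade-level harvest queries (title and `[filter]` clauses restricting
to mitochondrial or chloroplast genome records). The organism clause is
optional by design: marker-only queries are useful on their own, and callers
composing family-by-family searches supply the taxon per call.

## The synthetic corpus generator

Real harvests run over tens of thousands of genomes and live network
services; the package instead ships `generate_corpus()`, which emulates the
*annotation structure* that matters to the builder, with a known ground
truth. Each synthetic genome carries one feature per canonical marker of its
organelle (CDS for protein genes, rRNA for ribosomal genes, a D-loop feature
for the mitochondrial control region) plus one decoy tRNA that the scanner
must ignore. Product qualifiers are drawn from the packaged long-name
lexicon (the non-self variants of the seed table — editing that CSV changes
both the generator and the resolver) and perturbed per character with:

* `case_flip_rate = 0.1` — case flips, normalization-neutral;
* `hyphenation_rate = 0.1` — hyphen/space swaps, normalization-neutral;
* `typo_rate = 0.02` — deletion, substitution or insertion of a letter, the
  three corruption classes observed in deposited annotations; these create
  genuinely novel variants.

The defaults reflect that mechanical formatting noise is common in real
annotations while outright typos are rare but persistent. Gene qualifiers
receive only case flips (symbol qualifiers are far better behaved in real
records, and the builder's resolution path assumes at least one qualifier is
recognizable), and the control-region note only normalization-neutral
perturbations, since that feature carries no gene qualifier to anchor
resolution. Every emitted product spelling is recorded in the returned truth
map — the generator never emits a variant it does not record — and a
perturbation whose normalized key collides with a variant already planted
for a *different* marker is redrawn (falling back to the unperturbed form),
because a ground-truth map with an ambiguous key would not be a map. The
whole corpus is a pure function of `(n, organelle, seed, rates)`:
byte-identical files and truth map on every run.

What the generator does *not* emulate: biological sequences (ORIGIN blocks
are random placeholder nucleotides), missing or swapped qualifiers,
multi-copy genes, pseudogenes, unresolvable gene qualifiers, or
depositor-specific long forms absent from the lexicon. Passing the
round-trip test therefore demonstrates that the scan–dedup–resolve loop is
correct and lossless under controlled naming noise — not that the packaged
lexicon covers all real-world GenBank variation, which only continued
harvesting and curation can.

## Numerical and scale choices

The test suite and the acceptance script use a 50-genome mitochondrial
corpus (800 harvested features, ~250 distinct variants) for the round-trip
check, 100 random tables for persistence identities and 60 for query
well-formedness — sizes at which every property is exercised many times over
while the full suite runs in well under a minute of compute. Determinism
choices: all randomness flows from explicit integer seeds; the generator
runs on a private RNG stream and restores the caller's; tie-breaks (which
spelling is recorded for a normalized key, which symbol survives a conflict)
are always *first occurrence in input order*, consistently in the builder
and the truth map. Degenerate inputs are defined, not accidental: an empty
table is valid (and exports valid JSON), an empty corpus is valid, an empty
or whitespace name is an argument error rather than a miss, and a marker
with no long forms falls back to its symbol in the generator.

## Known limitations

* The packaged seed lexicon is a curated starting point, not an exhaustive
  inventory of GenBank spellings; misses on real data are expected and are
  exactly what the miss log and the unmapped queue exist to collect.
* One canonical-vocabulary wrinkle is inherited from the source vocabulary:
  `psb30` is listed both among the photosystem genes and the miscellaneous
  chloroplast genes; it is kept once, under the photosystem group.
* Lookup is exact-on-normalized-key by design; names corrupted beyond the
  stored variants will miss until curated in.
* The builder trusts the record's feature kinds; a CDS mis-annotated as
  `misc_feature` (other than control-region style notes) is not harvested.
* No live Entrez searches are performed and no result counts are estimated;
  the package constructs queries and databases, it does not execute
  searches.
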