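# genesyn

Gene-name synonym tools for organelle genomes: build a database of the many
names under which mitochondrial and chloroplast genes are annotated,
standardize any observed spelling to a canonical HUGO-style short symbol, and
render advanced Entrez search queries that OR-join every known synonym of a
marker.

## The problem

GenBank annotations for the same gene are wildly inconsistent. The
mitochondrial cytochrome c oxidase subunit 1 gene appears as `COI`, `COX1`,
`CO1`, "cytochrome oxidase subunit I", "cytochrome c oxidase subunit 1", and
outright typos ("cytchrome", "chytochrome", "cutochrome") across deposited
genomes. This hurts twice:

1. **Database searches undercount.** Searching
   `("Carcharodon Carcharias"[Organism]) AND ("COI"[All Fields])` misses every
   record annotated under a different spelling. The comprehensive query must
   OR-join all synonyms:

   ```
   ("Carcharodon Carcharias"[Organism]) AND ("COI"[All Fields] OR
    "cytochrome oxidase subunit I"[All Fields] OR
    "cytochrome c oxidase subunit 1"[All Fields])
   ```

2. **Comparative analyses break.** Gene-order and rearrangement tools treat
   "cytochrome oxidase subunit I" and "cytochrome c oxidase subunit 1" as
   different genes unless names are standardized first.

genesyn addresses both with a curated many-to-one *synonym table*
(variant → canonical symbol, partitioned into the independent `mt` and `cp`
namespaces), a builder that harvests new variants from genome annotations,
and a query renderer. Lookups match on a conservative normalized key
(lower-case, hyphens/underscores folded to spaces, whitespace collapsed);
typos are never "corrected" — they are stored as genuine variants. The
vocabulary covers coding (CDS) and ribosomal (rRNA) genes plus the
mitochondrial control region; tRNA genes are out of scope.

## Worked example

```r
library(genesyn)

fix_gene_name("COX1", organelle = "mt", verbose = FALSE)
#> [1] "COI"

build_query("COI", organism = "Carcharodon Carcharias") |> cat()
#> ("Carcharodon Carcharias"[Organism]) AND ("COI"[All Fields] OR
#>  "cytochrome oxidase subunit I"[All Fields] OR ... OR "CO1"[All Fields])

# generate a small synthetic corpus and rebuild a synonym table from it
fx <- generate_corpus(5, "mt", seed = 11, dir = tempfile())
b  <- build_from_files(fx$files, organelle = "mt")
b$report
#> <build_report>
#>   genomes scanned:    5
#>   features seen:      80 (plus 0 without any name)
#>   new entries:        60
#>   duplicates skipped: 20
#>   unmapped (queue):   0
#>   conflicts:          0
head(b$table$entries[, c("variant", "short_name")], 3)
#> 1 CyTOcHrome c oxidase suBunIt 1 COI
#> 2 COX2                           COII
#> 3 cytochrome oXIdase subunit-3   COIII
```

Each of the 5 synthetic genomes carries 16 markers (80 features); the 60
distinct perturbed product spellings become new entries, the 20 repeats are
deduplicated, and every entry resolves to its planted canonical symbol.

A command-line interface wraps the same functions
(`inst/exec/genesyn`, or `main()` from R):

```sh
genesyn fix --name "COX1" --type mt          # -> COI, exit 0; unknown names exit 1
genesyn query --gene rbcL --type cp --url
genesyn build-db --input g1.gb,g2.gb --type mt --out build/
```

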