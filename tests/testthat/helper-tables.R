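# Shared fixtures: all built in code, nothing read from disk.

# Small hand-written table: COI with its two classic long forms.
tiny_coi_table <- function() {
  syn_table(data.frame(
    variant = c("cytochrome oxidase subunit I", "cytochrome c oxidase subunit 1"),
    short_name = "COI",
    organelle = "mt"
  ), version = "1.0.1")
}

# Random but always-valid synonym table: canonical symbols drawn from the
# registry, variants random word salads, unique by construction.
random_table <- function(seed, n_entries = 12) {
  set.seed(seed)
  reg <- canonical_genes()
  idx <- sample(nrow(reg), n_entries, replace = TRUE)
  words <- c("cytochrome", "oxidase", "subunit", "synthase", "ribosomal",
             "protein", "chain", "dehydrogenase", "large", "small", "factor")
  variants <- vapply(seq_len(n_entries), function(i) {
    paste(c(sample(words, sample(2:4, 1), replace = TRUE),
            sample(c(as.character(0:9), "I", "II", "III"), 1), as.character(i)),
          collapse = " ")
  }, "")
  syn_table(
    data.frame(variant = variants,
               short_name = reg$short_name[idx],
               organelle = reg$organelle[idx]),
    version = sprintf("0.0.%d", seed)
  )
}

# Minimal GenBank record as a text block, for parser tests.
gb_text_record <- function(accession = "TEST0001",
                           features = list(
                             list(kind = "CDS", gene = "COX1",
                                  product = "cytochrome c oxidase subunit I"),
                             list(kind = "tRNA", gene = "trnF",
                                  product = "tRNA-Phe")
                           )) {
  lines <- c(
    sprintf("LOCUS       %-16s 360 bp    DNA     circular SYN 01-JAN-2026", accession),
    "DEFINITION  Synthetic test record.",
    sprintf("ACCESSION   %s", accession),
    "FEATURES             Location/Qualifiers",
    "     source          1..360",
    "                     /organism=\"synthetic construct\""
  )
  pos <- 1L
  for (f in features) {
    lines <- c(lines, sprintf("     %-15s %d..%d", f$kind, pos, pos + 59L))
    pos <- pos + 60L
    for (q in setdiff(names(f), "kind")) {
      if (!is.na(f[[q]])) {
        lines <- c(lines, sprintf("                     /%s=\"%s\"", q, f[[q]]))
      }
    }
  }
  c(lines, "ORIGIN",
    "        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt",
    "//")
}

write_gb_text <- function(lines, path = tempfile(fileext = ".gb")) {
  writeLines(lines, path)
  path
}
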