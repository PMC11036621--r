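#' Extract gene/product names from one genome record
#'
#' Walks the feature table of a parsed GenBank record (see [read_genbank()])
#' and returns one extraction per coding (`CDS`) and ribosomal (`rRNA`)
#' feature, in feature order. All other feature kinds — tRNAs in particular
#' — are ignored. As the mitochondrial control region is a standardized
#' marker but is annotated as neither CDS nor rRNA, `D-loop` features, and
#' `misc_feature`s whose `note`/`product` mentions "control region" or
#' "D-loop", are additionally captured with kind `control_region`.
#'
#' @param record One record from [read_genbank()].
#' @return A tibble with columns `gene`, `product` (either may be `NA`, not
#'   both), `kind` (`"CDS"`, `"rRNA"`, `"control_region"`) and `accession`.
#'   CDS/rRNA features lacking both qualifiers are skipped; their count is
#'   attached as attribute `"skipped_unnamed"`.
#' @export
scan_genome <- function(record) {
  stopifnot(is.list(record), !is.null(record$features))
  rows <- list()
  skipped <- 0L
  for (f in record$features) {
    q <- f$qualifiers
    gene <- unname(q["gene"])
    product <- unname(q["product"])
    note <- unname(q["note"])
    if (f$kind %in% c("CDS", "rRNA")) {
      if ((is.na(gene) || is.null(gene)) && (is.na(product) || is.null(product))) {
        skipped <- skipped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- list(gene = gene %|na|% NA_character_,
                                        product = product %|na|% NA_character_,
                                        kind = f$kind)
    } else if (f$kind == "D-loop" ||
               (f$kind == "misc_feature" &&
                grepl("control region|d[ -]loop",
                      canonicalize_text(paste(note %|na|% "", product %|na|% "")),
                      ignore.case = TRUE))) {
      name <- product %|na|% note %|na|% "D-loop"
      rows[[length(rows) + 1L]] <- list(gene = gene %|na|% NA_character_,
                                        product = name, kind = "control_region")
    }
  }
  out <- if (length(rows) == 0) {
    tibble::tibble(gene = character(), product = character(), kind = character())
  } else {
    dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  }
  out$accession <- rep(record$accession %||% NA_character_, nrow(out))
  attr(out, "skipped_unnamed") <- skipped
  out
}

`%|na|%` <- function(x, y) if (is.null(x) || length(x) == 0 || is.na(x)) y else x

#' Fold one extraction into a synonym-table draft
#'
#' Implements the deduplication step of the database-construction workflow:
#' the draft is keyed on the (normalized) gene *product* name. If the
#' product name is already present for this organelle, the draft is
#' unchanged. Otherwise the pair (product name, canonical short symbol) is
#' inserted, where the canonical symbol is resolved from the extraction's
#' `gene` qualifier first (symbols like `COX1` are closer to the canonical
#' vocabulary) and its `product` qualifier as fallback, via `canonical_map`.
#' If neither qualifier resolves, the extraction goes to the unmapped
#' curation queue rather than the draft; if the stored symbol for an
#' existing product disagrees with the freshly resolved one, a conflict is
#' reported and the draft stays unchanged.
#'
#' @param draft A [syn_table] draft (possibly empty).
#' @param extraction One row of [scan_genome()] output (list or one-row
#'   data frame with `gene`, `product`, `kind`, `accession`).
#' @param canonical_map A [syn_table] used to resolve names to canonical
#'   symbols (typically [seed_table()]).
#' @param organelle `"mt"` or `"cp"` — one build run covers one organelle.
#' @return A list: `draft` (updated [syn_table]), `delta` (`TRUE` iff an
#'   entry was inserted), and `status` (`"new"`, `"duplicate"`,
#'   `"unmapped"`, or `"conflict"`).
#' @export
accumulate <- function(draft, extraction, canonical_map, organelle = "mt") {
  stopifnot(inherits(draft, "syn_table"), inherits(canonical_map, "syn_table"))
  organelle <- check_organelle(organelle)
  if (is.data.frame(extraction)) extraction <- as.list(extraction[1, ])
  gene <- extraction$gene %|na|% NA_character_
  product <- extraction$product %|na|% NA_character_

  variant <- if (!is.na(product)) product else gene
  key <- canonicalize_text(variant)

  cm <- canonical_map$entries
  resolve <- function(x) {
    if (is.na(x)) return(NA_character_)
    hit <- cm$short_name[cm$norm_key == canonicalize_text(x) &
                           cm$organelle == organelle]
    if (length(hit) > 0) hit[1] else NA_character_
  }
  short <- resolve(gene)
  if (is.na(short)) short <- resolve(product)
  if (is.na(short)) {
    return(list(draft = draft, delta = FALSE, status = "unmapped"))
  }

  e <- draft$entries
  existing <- e$short_name[e$norm_key == key & e$organelle == organelle]
  if (length(existing) > 0) {
    status <- if (existing[1] == short) "duplicate" else "conflict"
    return(list(draft = draft, delta = FALSE, status = status))
  }

  reg <- canonical_genes()
  category <- reg$category[reg$short_name == short & reg$organelle == organelle][1]
  e <- dplyr::bind_rows(e, tibble::tibble(
    variant = variant, short_name = short, organelle = organelle,
    category = category %|na|% NA_character_, norm_key = key
  ))
  draft$entries <- e
  list(draft = draft, delta = TRUE, status = "new")
}

#' Build a synonym-table draft from genome files
#'
#' Scans every record of every GenBank file, in file order, and folds each
#' CDS/rRNA/control-region extraction into a draft synonym table via
#' [accumulate()]. Product-name deduplication makes the build idempotent:
#' processing the same corpus again adds nothing, and reordering the input
#' never changes the final variant-to-symbol map (only which accession is
#' recorded first).
#'
#' @param paths GenBank flat files (`.gb`/`.gbk`, optionally `.gz`).
#' @param organelle `"mt"` or `"cp"`, fixed for the whole run.
#' @param canonical_map A [syn_table] resolving names to canonical symbols;
#'   defaults to [seed_table()].
#' @param draft Optional starting draft (a [syn_table]); defaults to empty.
#' @param skip_bad If `TRUE`, unparseable records are skipped with a warning
#'   instead of aborting the build.
#' @return A list with `table` (the draft [syn_table]) and `report`, a
#'   `build_report`: counts `genomes_scanned`, `features_seen`,
#'   `new_entries`, `duplicates_skipped`, `skipped_unnamed`, plus tibbles
#'   `unmapped` (curation queue) and `conflicts`. For every run,
#'   `new_entries + duplicates_skipped` equals the number of features whose
#'   name resolved, and `new_entries` equals the draft's growth.
#' @export
build_from_files <- function(paths, organelle = "mt",
                             canonical_map = seed_table(), draft = NULL,
                             skip_bad = FALSE) {
  organelle <- check_organelle(organelle)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort_genesyn(sprintf("Input file(s) not readable: %s",
                          paste(missing, collapse = ", ")),
                  "genesyn_io_error")
  }
  if (is.null(draft)) draft <- syn_table()
  stopifnot(inherits(draft, "syn_table"))
  start_size <- nrow(draft$entries)

  genomes <- 0L; features <- 0L; new <- 0L; dup <- 0L; unnamed <- 0L
  unmapped <- list(); conflicts <- list()

  for (p in paths) {
    for (rec in read_genbank(p, skip_bad = skip_bad)) {
      genomes <- genomes + 1L
      ext <- scan_genome(rec)
      unnamed <- unnamed + attr(ext, "skipped_unnamed")
      features <- features + nrow(ext)
      for (i in seq_len(nrow(ext))) {
        res <- accumulate(draft, ext[i, ], canonical_map, organelle)
        draft <- res$draft
        switch(res$status,
               new = { new <- new + 1L },
               duplicate = { dup <- dup + 1L },
               unmapped = { unmapped[[length(unmapped) + 1L]] <- ext[i, ] },
               conflict = { conflicts[[length(conflicts) + 1L]] <- ext[i, ] })
      }
    }
  }

  empty_ext <- tibble::tibble(gene = character(), product = character(),
                              kind = character(), accession = character())
  report <- structure(list(
    genomes_scanned = genomes,
    features_seen = features,
    new_entries = new,
    duplicates_skipped = dup,
    skipped_unnamed = unnamed,
    start_size = start_size,
    final_size = nrow(draft$entries),
    unmapped = if (length(unmapped) > 0) dplyr::bind_rows(unmapped) else empty_ext,
    conflicts = if (length(conflicts) > 0) dplyr::bind_rows(conflicts) else empty_ext
  ), class = "build_report")

  list(table = draft, report = report)
}

#' @export
print.build_report <- function(x, ...) {
  cat("<build_report>\n")
  cat(sprintf("  genomes scanned:    %d\n", x$genomes_scanned))
  cat(sprintf("  features seen:      %d (plus %d without any name)\n",
              x$features_seen, x$skipped_unnamed))
  cat(sprintf("  new entries:        %d\n", x$new_entries))
  cat(sprintf("  duplicates skipped: %d\n", x$duplicates_skipped))
  cat(sprintf("  unmapped (queue):   %d\n", nrow(x$unmapped)))
  cat(sprintf("  conflicts:          %d\n", nrow(x$conflicts)))
  invisible(x)
}

#' Write the outputs of a database build
#'
#' Persists a build as three plain-text artifacts under `out_dir`: the draft
#' table as CSV (`draft.csv`, [save_csv()] schema), the report counts as
#' JSON (`report.json`) and the unmapped curation queue as CSV
#' (`unmapped.csv`).
#'
#' @param build The list returned by [build_from_files()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_build_outputs <- function(build, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  draft_path <- file.path(out_dir, "draft.csv")
  save_csv(build$table, draft_path)
  rep <- build$report
  counts <- rep[c("genomes_scanned", "features_seen", "new_entries",
                  "duplicates_skipped", "skipped_unnamed")]
  counts$unmapped <- nrow(rep$unmapped)
  counts$conflicts <- nrow(rep$conflicts)
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(counts, report_path, auto_unbox = TRUE, pretty = TRUE)
  unmapped_path <- file.path(out_dir, "unmapped.csv")
  readr::write_csv(rep$unmapped, unmapped_path)
  invisible(c(draft = draft_path, report = report_path, unmapped = unmapped_path))
}
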