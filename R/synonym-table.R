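#' Construct and validate a synonym table
#'
#' A synonym table is the package's central data structure: a many-to-one map
#' from observed gene-name variants (long forms, alternative symbols,
#' harvested typos) to canonical HUGO-style short symbols, partitioned by
#' organelle. Construction enforces every structural invariant, so any
#' `syn_table` in circulation supports unambiguous lookups:
#'
#' * every `short_name` is a [canonical_genes()] symbol of the same organelle;
#' * within one organelle each *normalized* variant key (see
#'   [canonicalize_text()]) maps to exactly one `short_name` — conflicting
#'   duplicates are a hard error, identical duplicates are collapsed;
#' * every canonical symbol is present as a variant of itself (self-maps are
#'   materialized automatically if absent), so lookups are total over the
#'   canonical vocabulary;
#' * variants may not contain double quotes (they must be renderable inside
#'   quoted Entrez query terms).
#'
#' @param entries Data frame with columns `variant`, `short_name`,
#'   `organelle` and optionally `category`. Zero rows are allowed.
#' @param version Version string of the database; `"unreleased"` for a
#'   freshly built table.
#' @param built_at ISO-8601 build timestamp; defaults to now (UTC).
#'
#' @return An object of class `syn_table`: a list with elements `entries`
#'   (tibble `variant`, `short_name`, `organelle`, `category`, `norm_key`),
#'   `version` and `built_at`.
#' @seealso [load_table()], [seed_table()], [fix_gene_name()]
#' @examples
#' syn_table(data.frame(
#'   variant = "cytochrome c oxidase subunit 1",
#'   short_name = "COI", organelle = "mt"
#' ))
#' @export
syn_table <- function(entries = NULL, version = "unreleased", built_at = NULL) {
  if (is.null(entries)) {
    entries <- tibble::tibble(variant = character(), short_name = character(),
                              organelle = character(), category = character())
  }
  if (!is.data.frame(entries)) {
    abort_genesyn("`entries` must be a data frame.", "genesyn_schema_error")
  }
  needed <- c("variant", "short_name", "organelle")
  missing_cols <- setdiff(needed, names(entries))
  if (length(missing_cols) > 0) {
    abort_genesyn(
      sprintf("Synonym table is missing column(s): %s.",
              paste(missing_cols, collapse = ", ")),
      "genesyn_schema_error"
    )
  }
  entries <- tibble::as_tibble(entries)
  if (!"category" %in% names(entries)) entries$category <- NA_character_
  entries <- entries[, c("variant", "short_name", "organelle", "category")]
  for (col in names(entries)) entries[[col]] <- as.character(entries[[col]])

  bad_org <- setdiff(unique(entries$organelle), c("mt", "cp"))
  if (length(bad_org) > 0) {
    abort_genesyn(
      sprintf("Unknown organelle code(s): %s (expected \"mt\" or \"cp\").",
              paste(unique(bad_org), collapse = ", ")),
      "genesyn_schema_error"
    )
  }
  quoted <- grepl("[\"“”]", entries$variant)
  if (any(quoted)) {
    abort_genesyn(
      sprintf("Variant(s) contain double quotes and cannot be rendered in queries: %s.",
              paste(unique(entries$variant[quoted]), collapse = "; ")),
      "genesyn_schema_error"
    )
  }

  registry <- canonical_genes()
  reg_id <- paste(registry$short_name, registry$organelle)
  ent_id <- paste(entries$short_name, entries$organelle)
  unknown <- !ent_id %in% reg_id
  if (any(unknown)) {
    abort_genesyn(
      sprintf("short_name(s) not in the canonical vocabulary for their organelle: %s.",
              paste(unique(paste0(entries$short_name[unknown], " (",
                                  entries$organelle[unknown], ")")), collapse = "; ")),
      "genesyn_schema_error"
    )
  }
  # fill missing categories from the registry
  if (nrow(entries) > 0) {
    entries$category <- ifelse(
      is.na(entries$category) | entries$category == "",
      registry$category[match(ent_id, reg_id)],
      entries$category
    )
  }

  # materialize self-maps so canonical symbols always resolve to themselves
  referenced <- unique(entries[, c("short_name", "organelle")])
  if (nrow(referenced) > 0) {
    have_self <- mapply(function(s, o) {
      any(canonicalize_text(entries$variant) == canonicalize_text(s) &
            entries$organelle == o)
    }, referenced$short_name, referenced$organelle)
    if (any(!have_self)) {
      add <- referenced[!have_self, ]
      add_id <- paste(add$short_name, add$organelle)
      entries <- dplyr::bind_rows(entries, tibble::tibble(
        variant = add$short_name,
        short_name = add$short_name,
        organelle = add$organelle,
        category = registry$category[match(add_id, reg_id)]
      ))
    }
  }

  entries$norm_key <- canonicalize_text(entries$variant)
  empty <- entries$norm_key == "" | is.na(entries$norm_key)
  if (any(empty)) {
    abort_genesyn("Variant(s) normalize to an empty key.", "genesyn_schema_error")
  }

  # one short_name per (normalized variant, organelle); collapse exact repeats
  key_id <- paste(entries$norm_key, entries$organelle, sep = "\r")
  by_key <- split(entries$short_name, key_id)
  conflicted <- vapply(by_key, function(s) length(unique(s)) > 1L, logical(1))
  if (any(conflicted)) {
    k <- names(by_key)[conflicted][1]
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    abort_genesyn(
      sprintf(paste0("Ambiguous variant: \"%s\" (%s) maps to multiple short names: %s. ",
                     "Each normalized variant must map to exactly one symbol."),
              parts[1], parts[2],
              paste(unique(by_key[[k]]), collapse = ", ")),
      "genesyn_ambiguity_error"
    )
  }
  entries <- entries[!duplicated(key_id), ]

  if (is.null(built_at)) {
    built_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  structure(
    list(entries = entries, version = as.character(version),
         built_at = as.character(built_at)),
    class = "syn_table"
  )
}

#' @export
print.syn_table <- function(x, ...) {
  n_mt <- sum(x$entries$organelle == "mt")
  n_cp <- sum(x$entries$organelle == "cp")
  cat(sprintf("<syn_table> version %s (built %s)\n", x$version, x$built_at))
  cat(sprintf("  %d entries: %d mitochondrial, %d chloroplast\n",
              nrow(x$entries), n_mt, n_cp))
  invisible(x)
}

#' @export
format.syn_table <- function(x, ...) {
  sprintf("<syn_table v%s, %d entries>", x$version, nrow(x$entries))
}

#' Load a synonym table from disk
#'
#' Reads the canonical CSV form (UTF-8, comma-delimited, header
#' `variant,short_name,organelle,category`, with the version carried in a
#' leading `# version=...` comment row) or the JSON export produced by
#' [export_json()]. Validation is total: the file either loads to a table
#' satisfying every invariant or a typed error is raised — there is no
#' partially loaded state.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"json"`; defaults to guessing from the file
#'   extension (`.json`/`.js` mean JSON, anything else CSV).
#' @return A [syn_table].
#' @export
load_table <- function(path, format = NULL) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    abort_genesyn(sprintf("Synonym table file not found: %s", path),
                  "genesyn_io_error")
  }
  if (is.null(format)) {
    format <- if (grepl("\\.(json|js)$", path, ignore.case = TRUE)) "json" else "csv"
  }
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    meta <- grep("^#", lines, value = TRUE)
    version <- sub("^#\\s*version=\\s*", "",
                   grep("^#\\s*version=", meta, value = TRUE)[1])
    if (is.na(version) || version == "") version <- "unreleased"
    built_at <- sub("^#\\s*built_at=\\s*", "",
                    grep("^#\\s*built_at=", meta, value = TRUE)[1])
    if (is.na(built_at) || built_at == "") built_at <- NULL
    body <- lines[!grepl("^#", lines)]
    entries <- readr::read_csv(I(paste(body, collapse = "\n")),
                               col_types = readr::cols(.default = readr::col_character()),
                               progress = FALSE)
    syn_table(entries, version = version, built_at = built_at)
  } else {
    parsed <- tryCatch(
      jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
      error = function(e) {
        abort_genesyn(sprintf("Not a valid JSON synonym table: %s (%s)",
                              path, conditionMessage(e)),
                      "genesyn_schema_error")
      }
    )
    entries <- parsed$entries
    if (is.null(entries) || length(entries) == 0) {
      entries <- NULL
    }
    syn_table(entries,
              version = parsed$version %||% "unreleased",
              built_at = parsed$built_at)
  }
}

#' Save a synonym table as CSV
#'
#' Writes the canonical on-disk form: a `# version=` (and `# built_at=`)
#' comment header followed by `variant,short_name,organelle,category` rows.
#' `load_table()` on the result reproduces the table.
#'
#' @param table A [syn_table].
#' @param path Output file path.
#' @return The output path, invisibly.
#' @export
save_csv <- function(table, path) {
  stopifnot(inherits(table, "syn_table"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  body <- readr::format_csv(table$entries[, c("variant", "short_name",
                                              "organelle", "category")])
  header <- c(sprintf("# version=%s", table$version),
              sprintf("# built_at=%s", table$built_at))
  ok <- tryCatch({
    writeLines(c(header, sub("\n$", "", body)), path, useBytes = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    abort_genesyn(sprintf("Cannot write synonym table to %s", path),
                  "genesyn_io_error")
  }
  invisible(path)
}

#' Export a synonym table to JSON
#'
#' Writes `{"version": ..., "built_at": ..., "entries": [...]}` so the
#' database can be consumed from other languages (e.g. a JavaScript front
#' end). [load_table()] on the output reproduces the input table exactly.
#'
#' @param table A [syn_table].
#' @param file_name Output file name; default `"genesyn.json"`.
#' @param out_dir Output directory, created if needed; default a `genesyn`
#'   folder in the current working directory.
#' @return The path of the written file.
#' @export
export_json <- function(table, file_name = "genesyn.json", out_dir = "genesyn") {
  stopifnot(inherits(table, "syn_table"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, file_name)
  payload <- list(
    version = table$version,
    built_at = table$built_at,
    entries = table$entries[, c("variant", "short_name", "organelle", "category")]
  )
  res <- tryCatch({
    jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok || !res || !file.exists(path)) {
    abort_genesyn(sprintf("Cannot write JSON export to %s", path),
                  "genesyn_io_error")
  }
  path
}

#' Refresh the local synonym database from a remote source
#'
#' Downloads a synonym table (CSV or JSON), validates it, and only then
#' replaces `destination` atomically (temp file + rename). On any failure —
#' unreachable URL or a file that does not validate — the pre-existing local
#' file is left untouched, so every offline operation keeps working.
#'
#' @param source_url URL (or `file://` path) serving the table.
#' @param destination Local file path to replace.
#' @return The freshly loaded [syn_table], invisibly.
#' @export
update_table <- function(source_url, destination) {
  tmp <- tempfile(fileext = paste0(".", tools::file_ext(destination)))
  on.exit(unlink(tmp), add = TRUE)
  status <- tryCatch(
    suppressWarnings(utils::download.file(source_url, tmp, quiet = TRUE,
                                          mode = "wb")),
    error = function(e) -1L
  )
  if (!identical(status, 0L) || !file.exists(tmp) || file.size(tmp) == 0) {
    abort_genesyn(
      sprintf("Could not download synonym table from %s; local table left untouched.",
              source_url),
      "genesyn_download_error"
    )
  }
  table <- load_table(tmp)  # typed error on invalid content; destination untouched
  dir.create(dirname(destination), recursive = TRUE, showWarnings = FALSE)
  staged <- tempfile(tmpdir = dirname(destination))
  file.copy(tmp, staged, overwrite = TRUE)
  if (!file.rename(staged, destination)) {
    unlink(staged)
    abort_genesyn(sprintf("Cannot replace %s", destination), "genesyn_io_error")
  }
  invisible(table)
}

#' Report the version of a synonym table
#'
#' @param table A [syn_table].
#' @return The stored version string (`"unreleased"` for a freshly built,
#'   unversioned table). Pure: no side effects.
#' @export
version_info <- function(table) {
  stopifnot(inherits(table, "syn_table"))
  table$version
}

#' The packaged seed synonym table
#'
#' Loads the curated table shipped with the package: every canonical symbol
#' of both organelles plus hand-written long-name forms, alternative symbols
#' (e.g. `COX1` for `COI`) and documented annotation typos. This is the
#' default database for [fix_gene_name()] and [build_query()], and the
#' canonical map used to resolve gene qualifiers when building a database
#' from genome records. Available offline; no download required.
#'
#' @return A [syn_table].
#' @export
seed_table <- function() {
  path <- system.file("extdata", "seed_synonyms.csv", package = "genesyn",
                      mustWork = TRUE)
  load_table(path, format = "csv")
}

#' List the known variants of a marker
#'
#' Returns the raw variant spellings registered for one canonical symbol,
#' canonical symbol first and then in table (curation) order, with
#' normalized duplicates removed.
#'
#' @param table A [syn_table].
#' @param short_name Canonical symbol (as in [canonical_genes()]).
#' @param organelle `"mt"` or `"cp"`.
#' @return Character vector of variants; empty if the symbol has no entries.
#' @export
variants_of <- function(table, short_name, organelle = "mt") {
  stopifnot(inherits(table, "syn_table"))
  organelle <- check_organelle(organelle)
  e <- table$entries
  e <- e[e$short_name == short_name & e$organelle == organelle, ]
  if (nrow(e) == 0) return(character())
  self <- e$norm_key == canonicalize_text(short_name)
  e <- rbind(e[self, ], e[!self, ])
  e$variant[!duplicated(e$norm_key)]
}

#' Merge synonym tables
#'
#' Combines tables (later tables first on conflicts are not allowed: a
#' conflicting normalized variant is an ambiguity error, identical entries
#' collapse). Useful for joining a freshly built draft with the canonical
#' map it was resolved against.
#'
#' @param ... [syn_table] objects.
#' @param version Version string for the merged table.
#' @return A [syn_table].
#' @export
syn_table_merge <- function(..., version = "unreleased") {
  tables <- list(...)
  stopifnot(all(vapply(tables, inherits, logical(1), "syn_table")))
  entries <- dplyr::bind_rows(lapply(tables, function(t) {
    t$entries[, c("variant", "short_name", "organelle", "category")]
  }))
  syn_table(entries, version = version)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
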