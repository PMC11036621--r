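#' Standardize a gene name to its canonical short symbol
#'
#' Looks up the normalized form of `name` (see [canonicalize_text()]) among
#' the synonym table's entries for the given organelle and returns the
#' unique canonical symbol, e.g. `"COX1"` or
#' `"cytochrome c oxidase subunit 1"` both standardize to `"COI"` under
#' `organelle = "mt"`.
#'
#' A miss is an expected outcome, not an error: the function returns
#' `NA_character_` and appends one tab-separated line
#' (`timestamp  organelle  raw name`) to `log_path`, so unknown names can be
#' reviewed and curated into the database later. Matching is exact on
#' normalized keys — no fuzzy matching; misspellings are handled by storing
#' them as variants, not by guessing.
#'
#' @param name Raw gene name (non-empty).
#' @param table A [syn_table]; defaults to the packaged [seed_table()].
#' @param organelle `"mt"` (default) or `"cp"`. The two namespaces are
#'   independent: a variant registered only under one organelle is a miss
#'   under the other.
#' @param log_path File receiving one line per failed lookup (append mode).
#' @param verbose Print a progress message; never changes the return value.
#' @return The canonical short name, or `NA_character_` if unknown.
#' @examples
#' fix_gene_name("COX1", organelle = "mt", verbose = FALSE,
#'               log_path = tempfile())
#' @export
fix_gene_name <- function(name, table = seed_table(), organelle = "mt",
                          log_path = "genesyn_unfound.log", verbose = TRUE) {
  if (!is.character(name) || length(name) != 1L || is.na(name) ||
      trimws(name) == "") {
    abort_genesyn("`name` must be a single non-empty string.",
                  "genesyn_argument_error")
  }
  organelle <- check_organelle(organelle)
  stopifnot(inherits(table, "syn_table"))

  key <- canonicalize_text(name)
  e <- table$entries
  hit <- e$short_name[e$norm_key == key & e$organelle == organelle]
  if (length(hit) >= 1L) {
    if (verbose) message(sprintf("'%s' -> '%s' [%s]", name, hit[1], organelle))
    return(hit[1])
  }
  line <- sprintf("%s\t%s\t%s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                  organelle, name)
  cat(line, "\n", sep = "", file = log_path, append = TRUE)
  if (verbose) {
    message(sprintf("'%s' not found in the %s synonym table; logged to %s",
                    name, organelle, log_path))
  }
  NA_character_
}
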