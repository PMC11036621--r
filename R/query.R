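#' Build an Entrez-style advanced search query for a marker
#'
#' Renders the query that OR-joins every known synonym of a canonical
#' marker, each as a quoted term tagged with an Entrez search field, e.g.
#'
#' ```
#' ("Carcharodon Carcharias"[Organism]) AND ("COI"[All Fields] OR
#'  "cytochrome oxidase subunit I"[All Fields] OR
#'  "cytochrome c oxidase subunit 1"[All Fields])
#' ```
#'
#' Terms appear canonical symbol first, then in table (curation) order,
#' each normalized variant exactly once, in plain ASCII double quotes.
#' `short_name` must already be canonical — standardize raw names with
#' [fix_gene_name()] first.
#'
#' @param short_name Canonical marker symbol (e.g. `"COI"`, `"rbcL"`).
#' @param table A [syn_table]; defaults to the packaged [seed_table()].
#' @param organelle `"mt"` (default) or `"cp"`.
#' @param search_field One of `"All Fields"` (default), `"Title"`,
#'   `"Abstract"`, `"MeSH Terms"`.
#' @param organism Optional organism/taxon; when given the query is
#'   prefixed with `("<organism>"[Organism]) AND `.
#' @param target_db `"genbank"` or `"pmc"` — which Entrez database the
#'   query is destined for. The term syntax is identical; the choice only
#'   affects [esearch_url()] and what the CLI prints. No live search is
#'   performed.
#' @return The query string.
#' @examples
#' build_query("COI", organism = "Carcharodon Carcharias")
#' @export
build_query <- function(short_name, table = seed_table(), organelle = "mt",
                        search_field = "All Fields", organism = NULL,
                        target_db = c("genbank", "pmc")) {
  organelle <- check_organelle(organelle)
  target_db <- match.arg(target_db)
  fields <- c("Title", "Abstract", "All Fields", "MeSH Terms")
  if (!is.character(search_field) || length(search_field) != 1L ||
      !search_field %in% fields) {
    abort_genesyn(
      sprintf("`search_field` must be one of: %s.", paste(fields, collapse = ", ")),
      "genesyn_argument_error"
    )
  }
  vars <- variants_of(table, short_name, organelle)
  if (length(vars) == 0) {
    abort_genesyn(
      sprintf(paste0("\"%s\" is not a canonical %s marker in this table; ",
                     "standardize the name with fix_gene_name() first."),
              short_name, organelle),
      "genesyn_unknown_gene_error"
    )
  }
  terms <- sprintf("\"%s\"[%s]", vars, search_field)
  core <- sprintf("(%s)", paste(terms, collapse = " OR "))
  if (!is.null(organism) && nzchar(organism)) {
    sprintf("(\"%s\"[Organism]) AND %s", organism, core)
  } else {
    core
  }
}

#' Genome-harvest retrieval queries
#'
#' The fixed Entrez queries used to retrieve complete organelle genomes of
#' a clade for database construction: title and filter clauses restrict
#' results to mitochondrial or chloroplast genome records.
#'
#' @param clade Taxon name (e.g. `"Chordata"`, `"Embryophyta"`).
#' @param organelle `"mt"` or `"cp"`.
#' @return The query string.
#' @examples
#' genome_retrieval_query("Chordata", "mt")
#' @export
genome_retrieval_query <- function(clade, organelle = "mt") {
  if (!is.character(clade) || length(clade) != 1L || !nzchar(trimws(clade))) {
    abort_genesyn("`clade` must be a single non-empty string.",
                  "genesyn_argument_error")
  }
  organelle <- check_organelle(organelle)
  base <- sprintf("(\"%s\"[Organism] OR \"%s\"[All Fields]) AND (\"Genome\"[Title])",
                  clade, clade)
  if (organelle == "mt") {
    paste0(base,
           " AND (\"mitochondrial\"[Title] OR \"mitochondrion\"[Title])",
           " AND mitochondrion[filter]")
  } else {
    paste0(base, " AND chloroplast[filter]")
  }
}

#' Parse the quoted terms out of a rendered query
#'
#' Inverse of the term rendering in [build_query()]: extracts every
#' `"term"[Field]` pair. Useful for verifying that a query carries exactly
#' the intended synonym set.
#'
#' @param query A query string.
#' @return Tibble with columns `term` and `field`.
#' @export
query_terms <- function(query) {
  m <- gregexpr("\"([^\"]*)\"\\[([^]\\[]+)\\]", query)[[1]]
  if (m[1] == -1L) {
    return(tibble::tibble(term = character(), field = character()))
  }
  hits <- regmatches(query, gregexpr("\"([^\"]*)\"\\[([^]\\[]+)\\]", query))[[1]]
  tibble::tibble(
    term = sub("^\"([^\"]*)\".*$", "\\1", hits),
    field = sub("^.*\\[([^]]+)\\]$", "\\1", hits)
  )
}

#' Render a query as an E-utilities esearch URL
#'
#' @param query Query string (from [build_query()] or
#'   [genome_retrieval_query()]).
#' @param db `"nucleotide"` (GenBank sequence searches) or `"pmc"`.
#' @return A percent-encoded esearch URL.
#' @export
esearch_url <- function(query, db = c("nucleotide", "pmc")) {
  db <- match.arg(db)
  paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/esearch.fcgi?db=", db,
         "&term=", utils::URLencode(query, reserved = TRUE))
}
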