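#' Canonical organelle gene symbols
#'
#' The controlled vocabulary of HUGO-style short symbols for the
#' mitochondrial and chloroplast markers the package standardizes to:
#' protein-coding (CDS) and ribosomal (rRNA) genes plus the mitochondrial
#' control region. tRNA genes are deliberately absent; the package does not
#' handle them.
#'
#' Symbols are unique within an organelle but the two namespaces are
#' independent: the same-looking name may be a valid symbol in one organelle
#' and unknown in the other (mitochondrial `16S` vs chloroplast `rrn16S`).
#'
#' @param organelle `"mt"`, `"cp"`, or `NULL` (default) for both.
#'
#' @return A tibble with columns `short_name`, `organelle` (`"mt"`/`"cp"`)
#'   and `category` (functional group, e.g. `"Mitochondrial Complex IV"`).
#' @examples
#' canonical_genes("mt")
#' @export
canonical_genes <- function(organelle = NULL) {
  genes <- .canonical_gene_registry
  if (!is.null(organelle)) {
    organelle <- check_organelle(organelle)
    genes <- genes[genes$organelle == organelle, ]
  }
  genes
}

.mk_genes <- function(organelle, category, symbols) {
  tibble::tibble(short_name = symbols, organelle = organelle, category = category)
}

.canonical_gene_registry <- local({
  mt <- dplyr::bind_rows(
    .mk_genes("mt", "rRNA", c("12S", "16S")),
    .mk_genes("mt", "Mitochondrial Complex I",
              c("ND1", "ND2", "ND3", "ND4", "ND4L", "ND5", "ND6")),
    .mk_genes("mt", "Mitochondrial Complex III", "CYTB"),
    .mk_genes("mt", "Mitochondrial Complex IV", c("COI", "COII", "COIII")),
    .mk_genes("mt", "Mitochondrial Complex V", c("ATP6", "ATP8")),
    .mk_genes("mt", "Control Region", "Control Region")
  )
  cp <- dplyr::bind_rows(
    .mk_genes("cp", "rRNA", c("rrn16S", "rrn23S", "rrn4.5S", "rrn5S")),
    .mk_genes("cp", "ATP Synthase",
              c("atpA", "atpB", "atpE", "atpF", "atpH", "atpI")),
    .mk_genes("cp", "Cytochrome b/6f Complex",
              c("petA", "petB", "petD", "petE", "petG", "petL", "petN")),
    .mk_genes("cp", "DNA dependent RNA polymerase",
              c("rpoA", "rpoB", "rpoC1", "rpoC2")),
    .mk_genes("cp", "Large Subunit of Ribosome",
              c("rpl2", "rpl14", "rpl16", "rpl20", "rpl22", "rpl23",
                "rpl32", "rpl33", "rpl36")),
    .mk_genes("cp", "NADH-dehydrogenase",
              c("ndhA", "ndhB", "ndhC", "ndhD", "ndhE", "ndhF", "ndhG",
                "ndhH", "ndhI", "ndhJ", "ndhK")),
    .mk_genes("cp", "PhotoSystem I-II",
              c("psaA", "psaB", "psaC", "psaI", "psaJ", "psaM", "psb30",
                "psbA", "psbB", "psbC", "psbD", "psbE", "psbF", "psbH",
                "psbI", "psbJ", "psbK", "psbL", "psbM", "psbN", "psbZ")),
    .mk_genes("cp", "Small Subunit of Ribosome",
              c("rps2", "rps3", "rps4", "rps7", "rps8", "rps11", "rps12",
                "rps14", "rps15", "rps16", "rps18", "rps19")),
    .mk_genes("cp", "Rubisco", "rbcL"),
    # psb30 is also listed among photosystem genes above; kept there once.
    .mk_genes("cp", "Others",
              c("accD", "ccsA", "cemA", "chlB", "chlL", "chlN", "clpP",
                "clpP1", "cysA", "cysT", "ftsH", "infA", "lhbA", "matK",
                "pafI", "pafII", "pbf1", "ycf1", "ycf2", "ycf3", "ycf4",
                "ycf12", "ycf15"))
  )
  dplyr::bind_rows(mt, cp)
})

#' @noRd
check_organelle <- function(organelle, arg = "organelle") {
  if (!is.character(organelle) || length(organelle) != 1L ||
      !organelle %in% c("mt", "cp")) {
    abort_genesyn(
      sprintf("`%s` must be \"mt\" (mitochondrial) or \"cp\" (chloroplast), not %s.",
              arg, deparse1(organelle)),
      class = "genesyn_argument_error"
    )
  }
  organelle
}

#' @noRd
abort_genesyn <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "genesyn_error"), ...)
}
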