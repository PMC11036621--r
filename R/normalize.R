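#' Normalize a raw gene-name string to its lookup key
#'
#' All synonym lookups match on a normalized key rather than the raw
#' annotation string, so that trivially different spellings of the same name
#' ("ATP synthase", "ATP-synthase", "atp  synthase") collapse to one entry.
#'
#' The normalization is deliberately conservative — it never tries to repair
#' typos (those are treated as genuine variants to be stored in the table):
#' * surrounding straight or typographic quotes are stripped,
#' * hyphens and underscores become spaces,
#' * the string is lower-cased,
#' * whitespace is trimmed and internal runs collapsed to single spaces.
#'
#' Digits, dots and all other characters are preserved, so keys like
#' `"rrn4.5s"` or `"ribulose 1,5 bisphosphate ..."` stay distinct.
#' The function is idempotent and vectorized.
#'
#' @param raw Character vector of raw names.
#' @return Character vector of normalized keys (empty input gives an empty
#'   key, which lookups reject).
#' @examples
#' canonicalize_text("ATP-synthase")
#' canonicalize_text("  Cytochrome   b ")
#' @export
canonicalize_text <- function(raw) {
  x <- as.character(raw)
  x <- trimws(x)
  # strip quotes only when they wrap the whole string (keeps apostrophes in
  # names like the RNA polymerase beta' subunit)
  repeat {
    y <- sub("^[\"'“”‘’](.*)[\"'“”‘’]$", "\\1", x)
    if (identical(y, x)) break
    x <- trimws(y)
  }
  x <- gsub("[-_]", " ", x)
  x <- tolower(x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}
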