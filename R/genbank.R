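#' Read GenBank flat-file records
#'
#' A targeted parser for the GenBank flat-file dialect
#' (`LOCUS`/`DEFINITION`/`ACCESSION`/`FEATURES`/`ORIGIN`/`//`) covering what
#' the database builder needs: the feature table with its qualifiers.
#' Multi-record files are supported; files ending in `.gz` are decompressed
#' transparently. Sequence data under `ORIGIN` is not retained — the builder
#' analyzes annotations, not sequences.
#'
#' @param path Path to a `.gb`/`.gbk` file (optionally gzipped).
#' @param skip_bad If `TRUE`, a record that fails to parse is dropped with a
#'   warning instead of aborting the whole file.
#' @return A list of records; each record is a list with `accession`,
#'   `name`, `definition`, and `features` (a list of
#'   `list(kind, location, qualifiers)` with `qualifiers` a named character
#'   vector), in file order.
#' @export
read_genbank <- function(path, skip_bad = FALSE) {
  if (!file.exists(path)) {
    abort_genesyn(sprintf("GenBank file not found: %s", path), "genesyn_io_error")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, warn = FALSE)

  starts <- grep("^LOCUS", lines)
  if (length(starts) == 0) {
    abort_genesyn(sprintf("No LOCUS line found; not a GenBank flat file: %s", path),
                  "genesyn_format_error")
  }
  ends <- c(starts[-1] - 1L, length(lines))
  records <- vector("list", length(starts))
  keep <- logical(length(starts))
  for (i in seq_along(starts)) {
    chunk <- lines[starts[i]:ends[i]]
    rec <- tryCatch(parse_gb_record(chunk), error = function(e) e)
    if (inherits(rec, "error")) {
      if (skip_bad) {
        warning(sprintf("Skipping unparseable record %d in %s: %s",
                        i, path, conditionMessage(rec)), call. = FALSE)
      } else {
        abort_genesyn(
          sprintf("Record %d in %s failed to parse: %s", i, path,
                  conditionMessage(rec)),
          "genesyn_format_error"
        )
      }
    } else {
      records[[i]] <- rec
      keep[i] <- TRUE
    }
  }
  records[keep]
}

#' @noRd
parse_gb_record <- function(chunk) {
  locus_fields <- strsplit(trimws(chunk[1]), "[[:space:]]+")[[1]]
  name <- if (length(locus_fields) >= 2) locus_fields[2] else NA_character_

  acc_line <- grep("^ACCESSION", chunk, value = TRUE)
  accession <- if (length(acc_line) > 0) {
    strsplit(trimws(sub("^ACCESSION", "", acc_line[1])), "[[:space:]]+")[[1]][1]
  } else {
    name
  }

  def_start <- grep("^DEFINITION", chunk)
  definition <- NA_character_
  if (length(def_start) > 0) {
    j <- def_start[1]
    def <- sub("^DEFINITION\\s*", "", chunk[j])
    while (j < length(chunk) && grepl("^ {10,}\\S", chunk[j + 1])) {
      j <- j + 1L
      def <- paste(def, trimws(chunk[j]))
    }
    definition <- def
  }

  feat_start <- grep("^FEATURES", chunk)
  features <- list()
  if (length(feat_start) > 0) {
    j <- feat_start[1] + 1L
    term <- grep("^(ORIGIN|CONTIG|BASE COUNT|//)", chunk)
    feat_end <- if (any(term > feat_start[1])) min(term[term > feat_start[1]]) - 1L else length(chunk)
    flines <- chunk[seq(j, feat_end)]
    flines <- flines[nzchar(trimws(flines))]
    features <- parse_gb_features(flines)
  }

  list(accession = accession, name = name, definition = definition,
       features = features)
}

#' @noRd
parse_gb_features <- function(flines) {
  features <- list()
  cur <- NULL
  qual_name <- NULL
  qual_open <- FALSE  # inside a multi-line quoted qualifier value

  flush_feature <- function() {
    if (!is.null(cur)) features[[length(features) + 1L]] <<- cur
    cur <<- NULL
  }

  for (line in flines) {
    if (grepl("^ {5}\\S", line) && !grepl("^ {6}", line)) {
      # new feature: key at column 6, location at column 22
      flush_feature()
      key <- trimws(substr(line, 6, 20))
      loc <- trimws(substr(line, 21, nchar(line)))
      cur <- list(kind = key, location = loc, qualifiers = character())
      qual_name <- NULL
      qual_open <- FALSE
    } else if (grepl("^ {21}/[A-Za-z_0-9]+", line) && !qual_open) {
      if (is.null(cur)) stop("qualifier line before any feature")
      body <- sub("^ {21}/", "", line)
      eq <- regexpr("=", body, fixed = TRUE)
      if (eq == -1L) {
        qual_name <- body
        val <- ""
      } else {
        qual_name <- substr(body, 1, eq - 1L)
        val <- substr(body, eq + 1L, nchar(body))
        if (startsWith(val, "\"")) {
          if (nchar(val) > 1 && endsWith(val, "\"")) {
            val <- substr(val, 2, nchar(val) - 1L)
          } else {
            val <- substr(val, 2, nchar(val))
            qual_open <- TRUE
          }
        }
      }
      q <- cur$qualifiers
      q[[qual_name]] <- val
      cur$qualifiers <- q
    } else if (grepl("^ {21,}\\S", line)) {
      # continuation of a qualifier value or of a location
      if (is.null(cur)) stop("continuation line before any feature")
      frag <- trimws(line)
      if (!is.null(qual_name)) {
        if (qual_open && endsWith(frag, "\"")) {
          frag <- substr(frag, 1, nchar(frag) - 1L)
          qual_open <- FALSE
        }
        sep <- if (qual_name == "translation") "" else " "
        cur$qualifiers[[qual_name]] <- paste(cur$qualifiers[[qual_name]],
                                             frag, sep = sep)
      } else {
        cur$location <- paste0(cur$location, frag)
      }
    } else {
      stop(sprintf("malformed feature-table line: %s", trimws(line)))
    }
  }
  flush_feature()
  features
}
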