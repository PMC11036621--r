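#' Generate a synthetic organelle-genome corpus with known ground truth
#'
#' Emits GenBank flat-file records that emulate the *annotation* structure
#' the database builder consumes — not biology: every genome carries one
#' CDS or rRNA feature per canonical marker of the organelle (mitochondrial
#' genomes also carry a D-loop control-region feature, plus one decoy tRNA
#' that the builder must ignore), with gene/product qualifiers drawn from
#' the packaged long-name lexicon and then perturbed the way real
#' depositor-written annotations vary:
#'
#' * case flips (per-character probability `case_flip_rate`),
#' * hyphen/space swaps (`hyphenation_rate`), and
#' * single-character typos — deletion, substitution or insertion, the
#'   corruption classes seen in deposited genomes ("cytchrome",
#'   "chytochrome", "cutochrome") — at per-character rate `typo_rate`.
#'
#' Product qualifiers receive all three perturbation classes; gene
#' qualifiers only case flips, and the control-region note only
#' normalization-neutral ones, mirroring the observation that symbol
#' qualifiers are far better behaved than free-text product names.
#'
#' Every emitted product variant is recorded in the returned ground-truth
#' map (the generator never emits a variant it does not record), and the
#' whole corpus is a pure function of `(n_genomes, organelle, seed,
#' params)`: identical inputs give byte-identical files and truth map.
#'
#' @param n_genomes Number of genome records to generate (each in its own
#'   `.gb` file).
#' @param organelle `"mt"` or `"cp"`.
#' @param seed Integer seed driving all randomness.
#' @param params List of perturbation rates in `[0, 1]`: `case_flip_rate`
#'   (default 0.1), `hyphenation_rate` (0.1), `typo_rate` (0.02).
#' @param dir Output directory; created if needed.
#' @return A list: `files` (paths, in order), `truth` (list with `mapping`
#'   — a tibble `variant`, `short_name`, `organelle`, deduplicated on
#'   normalized key, first occurrence kept — plus `seed` and `params`), and
#'   `dir`. A `truth.json` copy is written beside the genomes.
#' @export
generate_corpus <- function(n_genomes, organelle = "mt", seed = 1L,
                            params = list(), dir = tempfile("corpus")) {
  organelle <- check_organelle(organelle)
  if (!is.numeric(n_genomes) || length(n_genomes) != 1L || n_genomes < 0) {
    abort_genesyn("`n_genomes` must be a single non-negative number.",
                  "genesyn_argument_error")
  }
  defaults <- list(case_flip_rate = 0.1, hyphenation_rate = 0.1, typo_rate = 0.02)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown) > 0) {
    abort_genesyn(sprintf("Unknown perturbation parameter(s): %s",
                          paste(unknown, collapse = ", ")),
                  "genesyn_argument_error")
  }
  params <- utils::modifyList(defaults, params)
  rates <- unlist(params)
  if (any(!is.finite(rates) | rates < 0 | rates > 1)) {
    abort_genesyn("Perturbation rates must lie in [0, 1].",
                  "genesyn_argument_error")
  }

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  # run under a private, seeded RNG stream; leave the caller's RNG alone
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)

  lexicon <- fixture_lexicon(organelle)
  markers <- unique(lexicon$short_name)

  # The truth map must be a function: a perturbation that collides (on
  # normalized key) with a variant already planted for a DIFFERENT marker
  # would make the ground truth ambiguous, so it is re-drawn (deterministic:
  # same RNG stream), falling back to the unperturbed base form.
  planted <- new.env(parent = emptyenv())
  plant <- function(base, m, case_r, hyph_r, typo_r) {
    for (try in 1:5) {
      cand <- perturb_name(base, case_r, hyph_r, typo_r)
      key <- canonicalize_text(cand)
      owner <- planted[[key]]
      if (is.null(owner) || identical(owner, m)) {
        planted[[key]] <- m
        return(cand)
      }
    }
    base_key <- canonicalize_text(base)
    if (is.null(planted[[base_key]])) planted[[base_key]] <- m
    base
  }

  files <- character(0)
  truth_rows <- list()
  for (g in seq_len(n_genomes)) {
    feats <- list()
    for (m in markers) {
      forms <- lexicon$variant[lexicon$short_name == m]
      base <- if (length(forms) == 1) forms else sample(forms, 1)
      kind <- marker_kind(m, organelle)
      if (kind == "control_region") {
        prod <- plant(base, m, params$case_flip_rate, params$hyphenation_rate, 0)
        feats[[length(feats) + 1L]] <- list(kind = "D-loop", gene = NA, note = prod)
      } else {
        prod <- plant(base, m, params$case_flip_rate, params$hyphenation_rate,
                      params$typo_rate)
        gene <- perturb_name(m, params$case_flip_rate, 0, 0)
        feats[[length(feats) + 1L]] <- list(kind = kind, gene = gene, product = prod)
      }
      truth_rows[[length(truth_rows) + 1L]] <-
        tibble::tibble(variant = prod, short_name = m, organelle = organelle)
    }
    # decoy tRNA: the builder must not harvest it
    feats[[length(feats) + 1L]] <- list(kind = "tRNA", gene = "trnF",
                                        product = "tRNA-Phe")
    path <- file.path(dir, sprintf("genome_%04d.gb", g))
    write_gb_record(path, sprintf("GSYN%04d", g), organelle, feats)
    files <- c(files, path)
  }

  mapping <- if (length(truth_rows) > 0) {
    m <- dplyr::bind_rows(truth_rows)
    m[!duplicated(paste(canonicalize_text(m$variant), m$organelle)), ]
  } else {
    tibble::tibble(variant = character(), short_name = character(),
                   organelle = character())
  }
  truth <- list(mapping = mapping, seed = seed, params = params)
  jsonlite::write_json(list(seed = seed, params = params, mapping = mapping),
                       file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(files = files, truth = truth, dir = dir)
}

#' @noRd
marker_kind <- function(short_name, organelle) {
  reg <- canonical_genes(organelle)
  cat_ <- reg$category[reg$short_name == short_name][1]
  if (identical(cat_, "rRNA")) return("rRNA")
  if (identical(short_name, "Control Region")) return("control_region")
  "CDS"
}

#' The long-name lexicon behind the fixture generator
#'
#' Base (unperturbed) product-name forms for each canonical marker: the
#' non-self variants of the packaged [seed_table()]. Editing the seed CSV
#' therefore changes both what the generator plants and what the canonical
#' map can resolve.
#'
#' @param organelle `"mt"` or `"cp"`.
#' @return Tibble `variant`, `short_name` of long forms per marker (falls
#'   back to the symbol itself for markers with no long form).
#' @export
fixture_lexicon <- function(organelle = "mt") {
  organelle <- check_organelle(organelle)
  s <- seed_table()$entries
  s <- s[s$organelle == organelle, ]
  long <- s[s$norm_key != canonicalize_text(s$short_name), c("variant", "short_name")]
  markers <- unique(s$short_name)
  missing <- setdiff(markers, unique(long$short_name))
  if (length(missing) > 0) {
    long <- dplyr::bind_rows(long, tibble::tibble(variant = missing,
                                                  short_name = missing))
  }
  long
}

#' @noRd
perturb_name <- function(s, case_flip_rate, hyphenation_rate, typo_rate) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  # case flips
  is_alpha <- grepl("[A-Za-z]", ch)
  flip <- is_alpha & stats::runif(length(ch)) < case_flip_rate
  ch[flip] <- ifelse(ch[flip] %in% letters, toupper(ch[flip]), tolower(ch[flip]))
  # hyphen <-> space swaps
  swap <- ch %in% c(" ", "-") & stats::runif(length(ch)) < hyphenation_rate
  ch[swap] <- ifelse(ch[swap] == " ", "-", " ")
  # single-character typos on letters: deletion, substitution, insertion
  if (typo_rate > 0) {
    out <- character(0)
    for (c0 in ch) {
      if (grepl("[A-Za-z]", c0) && stats::runif(1) < typo_rate) {
        op <- sample(c("del", "sub", "ins"), 1)
        if (op == "del") next
        rnd <- sample(letters, 1)
        if (c0 %in% LETTERS) rnd <- toupper(rnd)
        out <- c(out, if (op == "sub") rnd else c(c0, rnd))
      } else {
        out <- c(out, c0)
      }
    }
    ch <- out
  }
  res <- paste(ch, collapse = "")
  if (canonicalize_text(res) == "") s else res
}

#' @noRd
write_gb_record <- function(path, accession, organelle, feats) {
  span <- 60L
  n_feat <- length(feats)
  seq_len_bp <- span * (n_feat + 1L)
  seq_chars <- sample(c("a", "c", "g", "t"), seq_len_bp, replace = TRUE)

  org_name <- if (organelle == "mt") "mitochondrion" else "chloroplast"
  lines <- c(
    sprintf("LOCUS       %-16s %d bp    DNA     circular SYN 01-JAN-2026",
            accession, seq_len_bp),
    sprintf("DEFINITION  Synthetic %s genome %s; generated fixture, not a real",
            org_name, accession),
    "            organism.",
    sprintf("ACCESSION   %s", accession),
    sprintf("VERSION     %s.1", accession),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", seq_len_bp),
    "                     /organism=\"synthetic construct\"",
    sprintf("                     /note=\"synthetic %s fixture\"", org_name)
  )

  pos <- 1L
  for (f in feats) {
    loc <- sprintf("%d..%d", pos, pos + span - 1L)
    pos <- pos + span
    lines <- c(lines, sprintf("     %-15s %s", f$kind, loc))
    if (!is.null(f$gene) && !is.na(f$gene)) {
      lines <- c(lines, sprintf("                     /gene=\"%s\"", f$gene))
    }
    if (!is.null(f$product) && !is.na(f$product)) {
      lines <- c(lines, sprintf("                     /product=\"%s\"", f$product))
    }
    if (!is.null(f$note) && !is.na(f$note)) {
      lines <- c(lines, sprintf("                     /note=\"%s\"", f$note))
    }
  }

  lines <- c(lines, "ORIGIN")
  for (start in seq(1L, seq_len_bp, by = 60L)) {
    block <- seq_chars[start:min(start + 59L, seq_len_bp)]
    groups <- split(block, ceiling(seq_along(block) / 10))
    lines <- c(lines, sprintf("%9d %s", start,
                              paste(vapply(groups, paste, "", collapse = ""),
                                    collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
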