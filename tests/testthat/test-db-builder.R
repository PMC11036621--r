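test_that("scan_genome harvests CDS and rRNA only, in feature order", {
  rec <- read_genbank(write_gb_text(gb_text_record(features = list(
    list(kind = "CDS", gene = "COX1", product = "cytochrome c oxidase subunit I"),
    list(kind = "tRNA", gene = "trnF", product = "tRNA-Phe")
  ))))[[1]]
  ext <- scan_genome(rec)
  expect_equal(nrow(ext), 1)
  expect_identical(ext$gene, "COX1")
  expect_identical(ext$product, "cytochrome c oxidase subunit I")
  expect_identical(ext$kind, "CDS")
  expect_identical(ext$accession, "TEST0001")

  rec2 <- read_genbank(write_gb_text(gb_text_record(features = list(
    list(kind = "rRNA", product = "16S ribosomal RNA")
  ))))[[1]]
  ext2 <- scan_genome(rec2)
  expect_equal(nrow(ext2), 1)
  expect_identical(ext2$kind, "rRNA")
  expect_true(is.na(ext2$gene))

  # no CDS/rRNA at all -> empty
  rec3 <- read_genbank(write_gb_text(gb_text_record(features = list(
    list(kind = "tRNA", gene = "trnF", product = "tRNA-Phe")
  ))))[[1]]
  expect_equal(nrow(scan_genome(rec3)), 0)
})

test_that("control-region features are captured despite being neither CDS nor rRNA", {
  lines <- gb_text_record(features = list(
    list(kind = "D-loop", note = "control region"),
    list(kind = "misc_feature", note = "putative control region"),
    list(kind = "misc_feature", note = "repeat region")  # not a control region
  ))
  ext <- scan_genome(read_genbank(write_gb_text(lines))[[1]])
  expect_equal(nrow(ext), 2)
  expect_true(all(ext$kind == "control_region"))
  # and the builder maps them to the canonical marker
  b <- build_from_files(write_gb_text(lines), "mt")
  expect_true("Control Region" %in% b$table$entries$short_name)
})

test_that("features with no usable name are skipped and counted", {
  lines <- gb_text_record(features = list(
    list(kind = "CDS", gene = "COX1", product = "cytochrome c oxidase subunit I"),
    list(kind = "CDS", note = "orphan open reading frame")
  ))
  ext <- scan_genome(read_genbank(write_gb_text(lines))[[1]])
  expect_equal(nrow(ext), 1)
  expect_equal(attr(ext, "skipped_unnamed"), 1L)
})

test_that("accumulate implements the product-name dedup loop", {
  seed <- seed_table()
  draft <- syn_table()

  res <- accumulate(draft, list(gene = "COX1",
                                product = "cytochrome oxidase subunit I",
                                kind = "CDS", accession = "A1"),
                    seed, "mt")
  expect_true(res$delta)
  expect_identical(res$status, "new")
  expect_equal(nrow(res$draft$entries), 1)
  expect_identical(res$draft$entries$short_name, "COI")

  # same product again (any spelling that normalizes identically): unchanged
  res2 <- accumulate(res$draft, list(gene = "COI",
                                     product = "Cytochrome-Oxidase subunit I",
                                     kind = "CDS", accession = "A2"),
                     seed, "mt")
  expect_false(res2$delta)
  expect_identical(res2$status, "duplicate")
  expect_equal(nrow(res2$draft$entries), 1)

  # unresolvable extraction goes to the unmapped path, draft untouched
  res3 <- accumulate(res$draft, list(gene = "orfX", product = "hypothetical protein",
                                     kind = "CDS", accession = "A3"),
                     seed, "mt")
  expect_false(res3$delta)
  expect_identical(res3$status, "unmapped")
  expect_equal(nrow(res3$draft$entries), 1)

  # a product key whose resolution disagrees with the stored symbol: conflict
  res4 <- accumulate(res$draft, list(gene = "CYTB",
                                     product = "cytochrome oxidase subunit I",
                                     kind = "CDS", accession = "A4"),
                     seed, "mt")
  expect_identical(res4$status, "conflict")
  expect_equal(nrow(res4$draft$entries), 1)
  expect_identical(res4$draft$entries$short_name, "COI")
})

test_that("counting on a constructed corpus matches the report contract", {
  prods <- c("cytochrome c oxidase subunit I", "cytochrome c oxidase subunit II",
             "cytochrome c oxidase subunit III", "cytochrome b",
             "NADH dehydrogenase subunit 1", "NADH dehydrogenase subunit 2",
             "NADH dehydrogenase subunit 3", "NADH dehydrogenase subunit 4",
             "NADH dehydrogenase subunit 4L", "NADH dehydrogenase subunit 5",
             "NADH dehydrogenase subunit 6", "ATP synthase F0 subunit 6",
             "ATP synthase F0 subunit 8")
  genes <- c("COX1", "COX2", "COX3", "CYTB", paste0("ND", c(1:4, "4L", 5, 6)),
             "ATP6", "ATP8")
  feats <- c(
    lapply(seq_along(prods), function(i) list(kind = "CDS", gene = genes[i],
                                              product = prods[i])),
    list(list(kind = "rRNA", product = "12S ribosomal RNA"),
         list(kind = "rRNA", product = "16S ribosomal RNA"))
  )
  path <- write_gb_text(gb_text_record("CORPUS01", feats))
  b <- build_from_files(path, "mt")
  expect_equal(b$report$genomes_scanned, 1)
  expect_equal(b$report$features_seen, 15)
  expect_equal(b$report$new_entries, 15)
  expect_equal(b$report$duplicates_skipped, 0)
  expect_equal(nrow(b$table$entries), 15)

  # the same corpus concatenated with itself: identical draft, all dupes
  b2 <- build_from_files(c(path, path), "mt")
  expect_equal(nrow(b2$table$entries), 15)
  expect_identical(sort(paste(b2$table$entries$norm_key, b2$table$entries$short_name)),
                   sort(paste(b$table$entries$norm_key, b$table$entries$short_name)))
  expect_equal(b2$report$new_entries, 15)
  expect_equal(b2$report$duplicates_skipped, 15)
  expect_equal(b2$report$new_entries + b2$report$duplicates_skipped,
               b2$report$features_seen)
})

test_that("the final map is order-insensitive and equals the brute-force oracle", {
  fx <- generate_corpus(12, "mt", seed = 31)
  seed <- seed_table()
  fwd <- build_from_files(fx$files, "mt", seed)
  rev <- build_from_files(rev(fx$files), "mt", seed)
  map_of <- function(b) sort(paste(b$table$entries$norm_key,
                                   b$table$entries$short_name))
  expect_identical(map_of(fwd), map_of(rev))

  # brute force: unique normalized product names across all extractions,
  # each resolved gene-first through the canonical map in one pass
  ext <- dplyr::bind_rows(lapply(fx$files, function(p) {
    dplyr::bind_rows(lapply(read_genbank(p), scan_genome))
  }))
  cm <- seed$entries
  resolve1 <- function(g, p) {
    for (x in c(g, p)) {
      if (!is.na(x)) {
        hit <- cm$short_name[cm$norm_key == canonicalize_text(x) &
                               cm$organelle == "mt"]
        if (length(hit) > 0) return(hit[1])
      }
    }
    NA_character_
  }
  name <- ifelse(is.na(ext$product), ext$gene, ext$product)
  keys <- canonicalize_text(name)
  first <- !duplicated(keys)
  oracle <- sort(paste(keys[first],
                       mapply(resolve1, ext$gene[first], ext$product[first])))
  expect_identical(map_of(fwd), oracle)

  # monotonicity: adding genomes never removes entries
  half <- build_from_files(fx$files[1:6], "mt", seed)
  expect_true(all(paste(half$table$entries$norm_key, half$table$entries$short_name)
                  %in% map_of(fwd)))
  # conservation: growth equals new_entries
  expect_equal(fwd$report$new_entries,
               fwd$report$final_size - fwd$report$start_size)
})

test_that("unreadable inputs name the failing path", {
  err <- expect_error(build_from_files(c("/nope/missing.gb"), "mt"),
                      class = "genesyn_io_error")
  expect_match(conditionMessage(err), "missing.gb")
})

test_that("build outputs persist as draft CSV, report JSON and unmapped queue", {
  lines <- gb_text_record(features = list(
    list(kind = "CDS", gene = "COX1", product = "cytochrome c oxidase subunit I"),
    list(kind = "CDS", gene = "orfX", product = "hypothetical protein")
  ))
  b <- build_from_files(write_gb_text(lines), "mt")
  expect_equal(nrow(b$report$unmapped), 1)
  out <- tempfile()
  paths <- write_build_outputs(b, out)
  expect_true(all(file.exists(paths)))
  reloaded <- load_table(paths[["draft"]])
  expect_true("COI" %in% reloaded$entries$short_name)
  rep <- jsonlite::fromJSON(paths[["report"]])
  expect_equal(rep$new_entries, 1)
  expect_equal(rep$unmapped, 1)
  queue <- readr::read_csv(paths[["unmapped"]], show_col_types = FALSE)
  expect_identical(queue$product, "hypothetical protein")
})
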