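test_that("organism strings parse into genus, epithet and qualifier", {
  tn <- parse_taxon_name(c("Bufo bufo", "Hyla cf. arborea", "Rana sp. 2",
                           "Hyla aff arborea", "Rana ssp.",
                           "Bufo bufo spinosus",
                           "Bufo bufo (Linnaeus, 1758)",
                           "incertae"))
  expect_equal(tn$genus[1:7],
               c("Bufo", "Hyla", "Rana", "Hyla", "Rana", "Bufo", "Bufo"))
  expect_equal(tn$qualifier, c("none", "cf", "sp", "aff", "ssp", "none",
                               "none", "none"))
  expect_equal(tn$epithet[1:3], c("bufo", "arborea", ""))
  # trinomial truncated to binomial, noted
  expect_equal(tn$epithet[6], "bufo")
  expect_match(tn$note[6], "trinomial_truncated")
  # author strings stripped, noted
  expect_equal(tn$epithet[7], "bufo")
  expect_match(tn$note[7], "extra_tokens_stripped")
  # lowercase-only string is unparseable
  expect_true(tn$parse_error[8])
  expect_equal(nrow(parse_taxon_name(character(0))), 0L)
})

test_that("FASTA parsing follows the header convention and metadata sidecar", {
  f <- write_fasta_tmp(c("AB123456 Bufo bufo", "XY000001 Hyla cf. arborea",
                         "XY000002 Rana sp. 2", "NC_000001 Bufo bufo"),
                       c("ACGTACGT", "ACGT", "AACC", "ACGTACGT"))
  rec <- parse_records(f)
  expect_equal(nrow(rec), 4L)
  expect_equal(rec$accession[1], "AB123456")
  expect_equal(rec$genus[1], "Bufo")
  expect_equal(rec$epithet[1], "bufo")
  expect_equal(rec$qualifier, c("none", "cf", "sp", "none"))
  expect_equal(rec$is_refseq, c(FALSE, FALSE, FALSE, TRUE))
  # metadata overrides the inline organism
  meta <- tempfile(fileext = ".tsv")
  write.table(data.frame(accession = "AB123456",
                         organism = "Epidalea calamita",
                         definition = "cytb"),
              meta, sep = "\t", quote = FALSE, row.names = FALSE)
  rec2 <- parse_records(f, meta)
  expect_equal(rec2$genus[1], "Epidalea")
  expect_equal(rec2$epithet[1], "calamita")
  # accession-only header becomes a record-level parse error, not a crash
  f3 <- write_fasta_tmp("ZZ999999", "ACGT")
  rec3 <- parse_records(f3)
  expect_true(rec3$parse_error[1])
  # empty file -> zero rows
  f4 <- tempfile(); file.create(f4)
  expect_equal(nrow(parse_records(f4)), 0L)
})

test_that("curated labels render Genus_epithet_ACCESSION and round-trip", {
  f <- write_fasta_tmp(c("AB123456 Bufo bufo", "XY000001 Hyla cf. arborea"),
                       c("ACGT", "ACGT"))
  rec <- parse_records(f)
  lab <- record_label(rec)
  expect_equal(lab[1], "Bufo_bufo_AB123456")
  expect_true(is.na(lab[2]))  # non-binomial records get no curated label
  parts <- strsplit(lab[1], "_")[[1]]
  expect_equal(parts, c(rec$genus[1], rec$epithet[1], rec$accession[1]))
})

test_that("deduplication drops RefSeq twins and nothing else", {
  base <- data.frame(
    accession = c("NC_000001", "AB123456"),
    raw_name = "Bufo bufo", genus = "Bufo", epithet = "bufo",
    qualifier = "none", definition = "", seq = "ACGTACGT",
    is_refseq = c(TRUE, FALSE), parse_error = FALSE, note = "",
    stringsAsFactors = FALSE)
  dd <- deduplicate(base)
  expect_equal(dd$kept$accession, "AB123456")
  expect_equal(dd$dropped$accession, "NC_000001")
  expect_equal(dd$dropped$partner, "AB123456")
  # terminal-N padding and case do not defeat the identity check
  pad <- base; pad$seq[1] <- "NNacgtacgtNNN"
  expect_equal(deduplicate(pad)$dropped$accession, "NC_000001")
  # a lone RefSeq record is retained
  solo <- base[1, , drop = FALSE]
  expect_equal(nrow(deduplicate(solo)$dropped), 0L)
  # identical RefSeq-only group keeps exactly one
  twins <- base; twins$accession <- c("NC_000002", "NC_000001")
  twins$is_refseq <- TRUE
  dd2 <- deduplicate(twins)
  expect_equal(dd2$kept$accession, "NC_000001")
})

test_that("deduplication matches a brute-force oracle and is idempotent", {
  set.seed(11)
  seqs <- replicate(7, random_dna(60))
  sp <- sample(c("Bufo bufo", "Rana rana"), 7, TRUE)
  rec <- data.frame(
    accession = sprintf("AB%06d", 1:7), raw_name = sp,
    genus = sub(" .*", "", sp), epithet = sub(".* ", "", sp),
    qualifier = "none", definition = "", seq = seqs,
    is_refseq = FALSE, parse_error = FALSE, note = "",
    stringsAsFactors = FALSE)
  twins <- rec[sample(7, 3), ]
  twins$accession <- sprintf("NC_%06d", 1:3)
  twins$is_refseq <- TRUE
  all_rec <- rbind(rec, twins)[sample(10), ]
  dd <- deduplicate(all_rec)
  expect_equal(nrow(dd$kept), 7L)
  expect_equal(sort(dd$dropped$accession), sprintf("NC_%06d", 1:3))
  # oracle: every drop has an identical-sequence same-species partner kept
  for (i in seq_len(nrow(dd$dropped))) {
    row <- all_rec[all_rec$accession == dd$dropped$accession[i], ]
    partners <- dd$kept[dd$kept$seq == row$seq &
                        dd$kept$genus == row$genus &
                        dd$kept$epithet == row$epithet, ]
    expect_gte(nrow(partners), 1L)
  }
  # idempotent; non-RefSeq never removed; species set preserved
  dd2 <- deduplicate(dd$kept)
  expect_equal(nrow(dd2$dropped), 0L)
  expect_true(all(rec$accession %in% dd$kept$accession))
  expect_setequal(unique(paste(dd$kept$genus, dd$kept$epithet)),
                  unique(paste(all_rec$genus, all_rec$epithet)))
})

test_that("taxonomy reconciliation rewrites synonyms idempotently", {
  tf <- tempfile(fileext = ".tsv")
  write.table(data.frame(raw_name = c("Bufo calamita", "Epidalea calamita"),
                         accepted_name = "Epidalea calamita",
                         family = "Bufonidae"),
              tf, sep = "\t", quote = FALSE, row.names = FALSE)
  tax <- read_taxonomy(tf)
  f <- write_fasta_tmp(c("A1 Bufo calamita", "A2 Epidalea calamita",
                         "A3 Rana rana"), c("ACGT", "ACGT", "ACGT"))
  rec <- parse_records(f)
  upd <- apply_taxonomy(rec, tax)
  expect_equal(upd$records$genus, c("Epidalea", "Epidalea", "Rana"))
  expect_equal(upd$changelog$action, c("updated", "confirmed", "unmatched"))
  # double application changes nothing
  upd2 <- apply_taxonomy(upd$records, tax)
  expect_identical(upd2$records, upd$records)
  expect_true(all(upd2$changelog$action != "updated"))
  # non-binomial accepted name is a configuration error
  bad <- tempfile(fileext = ".tsv")
  write.table(data.frame(raw_name = "X y", accepted_name = "justlowercase"),
              bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_taxonomy(bad), "binomial")
})

test_that("planted synonyms are all recovered in the changelog", {
  set.seed(21)
  n <- 100
  sp <- paste(sample(c("Bufo", "Rana", "Hyla", "Salamandra"), n, TRUE),
              sample(c("alpha", "beta", "gamma"), n, TRUE))
  planted <- sort(sample(n, 20))
  rec_names <- sp
  rec_names[planted] <- paste0("Old", sp[planted])  # outdated genus name
  tf <- tempfile(fileext = ".tsv")
  write.table(unique(data.frame(raw_name = rec_names[planted],
                                accepted_name = sp[planted])), tf,
              sep = "\t", quote = FALSE, row.names = FALSE)
  f <- write_fasta_tmp(paste(sprintf("AC%06d", 1:n), rec_names),
                       replicate(n, random_dna(30)))
  upd <- apply_taxonomy(parse_records(f), read_taxonomy(tf))
  expect_equal(sum(upd$changelog$action == "updated"), 20L)
  expect_equal(upd$changelog$accession[upd$changelog$action == "updated"],
               sprintf("AC%06d", planted))
  expect_equal(paste(upd$records$genus, upd$records$epithet), sp)
})

test_that("binomial/uncertain partition is exact and exhaustive", {
  f <- write_fasta_tmp(c("A1 Bufo bufo", "A2 Hyla cf. arborea", "A3 Rana sp."),
                       c("ACGT", "ACGT", "ACGT"))
  rec <- parse_records(f)
  part <- partition_binomial(rec)
  expect_equal(part$binomial$accession, "A1")
  expect_equal(nrow(part$uncertain), 2L)
  expect_equal(nrow(part$binomial) + nrow(part$uncertain), nrow(rec))
  expect_length(intersect(part$binomial$accession,
                          part$uncertain$accession), 0L)
  # all-binomial input -> empty uncertain set
  part2 <- partition_binomial(rec[1, , drop = FALSE])
  expect_equal(nrow(part2$uncertain), 0L)
  # generator-planted qualifiers are recovered exactly
  cfg <- synthetic_config(seed = 5, n_genera = 5, species_per_genus = 2,
                          seqs_per_species = 5,
                          planted = list(non_binomial = 10))
  sim <- simulate_records(cfg, REF, dir = tempfile())
  rec3 <- parse_records(sim$paths$fasta)
  part3 <- partition_binomial(rec3)
  expect_equal(nrow(part3$uncertain), 10L)
  expect_setequal(part3$uncertain$accession,
                  sim$truth$accession[sim$truth$error_class == "non_binomial"])
})
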