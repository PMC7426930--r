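#' @title Record parsing, deduplication and taxonomic reconciliation
#' @name records
#' @description
#' Records are held in a plain `data.frame` with one row per sequence and
#' columns `accession`, `raw_name` (the organism string as submitted),
#' `genus`, `epithet`, `qualifier` (one of `"none"`, `"cf"`, `"aff"`,
#' `"sp"`, `"ssp"`), `definition`, `seq`, `is_refseq`, `parse_error` and
#' `note`. A record is a complete binomial exactly when
#' `qualifier == "none"`, the epithet is non-empty and parsing succeeded.
NULL

QUALIFIERS <- c("cf", "aff", "sp", "ssp")

#' Parse an organism string into genus, epithet and open-nomenclature
#' qualifier
#'
#' Open-nomenclature markers (`cf.`, `aff.`, `sp.`, `ssp.`, with or without
#' the trailing period, case-insensitive) are detected as standalone
#' tokens. Subspecific trinomials are truncated to the binomial and noted.
#' Trailing tokens that are neither a lowercase epithet nor a qualifier
#' (author strings, years, isolate codes) are stripped and noted.
#'
#' @param x character vector of organism strings.
#' @return data.frame with columns `genus`, `epithet`, `qualifier`,
#'   `parse_error`, `note`, one row per input string.
#' @export
parse_taxon_name <- function(x) {
  n <- length(x)
  out <- data.frame(genus = character(n), epithet = character(n),
                    qualifier = rep("none", n), parse_error = logical(n),
                    note = character(n), stringsAsFactors = FALSE)
  for (i in seq_along(x)) {
    toks <- strsplit(trimws(x[i]), "\\s+")[[1]]
    if (length(toks) == 0L || !grepl("^[A-Z][a-zA-Z]+$", toks[1])) {
      out$parse_error[i] <- TRUE
      out$note[i] <- "unparseable_name"
      next
    }
    out$genus[i] <- toks[1]
    qual <- "none"; epithet <- ""; extra <- 0L; n_lower <- 0L
    for (tok in toks[-1]) {
      low <- tolower(sub("\\.$", "", tok))
      if (low %in% QUALIFIERS && grepl("^[A-Za-z]+\\.?$", tok)) {
        if (qual == "none") qual <- low
      } else if (grepl("^[a-z]+$", tok)) {
        n_lower <- n_lower + 1L
        if (epithet == "") epithet <- tok
      } else {
        extra <- extra + 1L
      }
    }
    out$qualifier[i] <- qual
    out$epithet[i] <- epithet
    notes <- character(0)
    if (qual == "none" && n_lower > 1L) notes <- c(notes, "trinomial_truncated")
    if (extra > 0L) notes <- c(notes, "extra_tokens_stripped")
    out$note[i] <- paste(notes, collapse = ";")
  }
  out
}

#' Read sequence records from a FASTA file
#'
#' Headers are expected to follow the `>ACCESSION Organism ...` convention;
#' alternatively (or additionally) a metadata TSV with columns `accession`,
#' `organism` and optionally `definition` supplies the organism string for
#' each accession. Records whose organism cannot be determined are kept
#' with `parse_error = TRUE` rather than aborting the run.
#'
#' @param fasta path to a (multi-)FASTA file.
#' @param metadata optional path to a tab-separated metadata table.
#' @return a records data.frame (see [records]); empty file gives zero rows.
#' @export
parse_records <- function(fasta, metadata = NULL) {
  stopifnot(file.exists(fasta))
  dss <- Biostrings::readBStringSet(fasta)
  headers <- names(dss)
  seqs <- toupper(as.character(dss))
  meta <- NULL
  if (!is.null(metadata)) {
    meta <- read.delim(metadata, stringsAsFactors = FALSE)
    stopifnot(all(c("accession", "organism") %in% names(meta)))
  }
  n <- length(seqs)
  acc <- sub("\\s.*$", "", headers)
  rest <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  organism <- rest
  definition <- rest
  if (!is.null(meta)) {
    idx <- match(acc, meta$accession)
    organism <- ifelse(is.na(idx), rest, meta$organism[idx])
    if ("definition" %in% names(meta))
      definition <- ifelse(is.na(idx), rest, meta$definition[idx])
  }
  tn <- parse_taxon_name(organism)
  rec <- data.frame(accession = acc, raw_name = organism,
                    genus = tn$genus, epithet = tn$epithet,
                    qualifier = tn$qualifier, definition = definition,
                    seq = unname(seqs),
                    is_refseq = startsWith(acc, "NC_"),
                    parse_error = tn$parse_error, note = tn$note,
                    stringsAsFactors = FALSE)
  rownames(rec) <- NULL
  if (n == 0L) rec <- rec[0, , drop = FALSE]
  rec
}

#' Curated label for binomial records
#'
#' Renders the `Genus_epithet_ACCESSION` label used throughout the curated
#' outputs (e.g. `Bufo_bufo_AB123456`).
#'
#' @param records records data.frame.
#' @return character vector of labels (NA for non-binomial records).
#' @export
record_label <- function(records) {
  ok <- records$qualifier == "none" & records$epithet != "" & !records$parse_error
  ifelse(ok, paste(records$genus, records$epithet, records$accession, sep = "_"),
         NA_character_)
}

species_key <- function(records) paste(records$genus, records$epithet)

# sequence identity for deduplication: case-insensitive, ignoring leading
# and trailing runs of N
.norm_seq <- function(s) gsub("^N+|N+$", "", toupper(s))

#' Remove RefSeq duplicates
#'
#' A RefSeq record (accession prefix `NC_`) is dropped when another record
#' of the same species carries an identical nucleotide sequence (identity
#' ignores case and terminal N padding). When all identical copies are
#' RefSeq records, the first by accession order is retained so no unique
#' sequence is ever lost. The operation is idempotent.
#'
#' @param records records data.frame.
#' @return list with `kept` (records data.frame) and `dropped` (data.frame
#'   `accession`, `reason`, `partner`).
#' @export
deduplicate <- function(records) {
  dropped <- data.frame(accession = character(0), reason = character(0),
                        partner = character(0), stringsAsFactors = FALSE)
  if (nrow(records) == 0L)
    return(list(kept = records, dropped = dropped))
  key <- paste(species_key(records), .norm_seq(records$seq), sep = "\r")
  drop <- logical(nrow(records))
  partner <- rep(NA_character_, nrow(records))
  for (grp in split(seq_len(nrow(records)), key)) {
    if (length(grp) < 2L) next
    nc <- grp[records$is_refseq[grp]]
    if (length(nc) == 0L) next
    non_nc <- setdiff(grp, nc)
    if (length(non_nc) > 0L) {
      keep_partner <- records$accession[non_nc[1]]
      drop[nc] <- TRUE
      partner[nc] <- keep_partner
    } else {
      ord <- nc[order(records$accession[nc])]
      drop[ord[-1]] <- TRUE
      partner[ord[-1]] <- records$accession[ord[1]]
    }
  }
  if (any(drop))
    dropped <- data.frame(accession = records$accession[drop],
                          reason = "refseq_duplicate",
                          partner = partner[drop], stringsAsFactors = FALSE)
  list(kept = records[!drop, , drop = FALSE], dropped = dropped)
}

#' Load a taxonomy synonymy table
#'
#' Tab-separated columns `raw_name`, `accepted_name` and optionally
#' `family` (the family of the accepted genus). Accepted names must be
#' complete binomials; a table whose accepted names are themselves mapped
#' to something else would make application non-idempotent and is rejected.
#'
#' @param path TSV file path.
#' @return list with `synonyms` (named character vector raw -> accepted)
#'   and `family` (named character vector genus -> family, possibly empty).
#' @export
read_taxonomy <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("raw_name", "accepted_name") %in% names(tab)))
  ok <- grepl("^[A-Z][a-zA-Z]+ [a-z]+$", tab$accepted_name)
  if (!all(ok))
    stop("taxonomy table: accepted_name must be a complete binomial; offending: ",
         paste(utils::head(tab$accepted_name[!ok], 3), collapse = ", "))
  syn <- setNames(tab$accepted_name, tab$raw_name)
  bad <- intersect(tab$accepted_name, tab$raw_name)
  bad <- bad[syn[bad] != bad]
  if (length(bad))
    stop("taxonomy table not idempotent: accepted name remapped: ",
         paste(bad, collapse = ", "))
  fam <- character(0)
  if ("family" %in% names(tab)) {
    gen <- sub(" .*$", "", tab$accepted_name)
    keep <- !is.na(tab$family) & tab$family != ""
    fam <- setNames(tab$family[keep], gen[keep])
    fam <- fam[!duplicated(names(fam))]
  }
  list(synonyms = syn, family = fam)
}

#' Reconcile record names against a taxonomy table
#'
#' Every parsed binomial found in the synonymy map is rewritten to its
#' accepted binomial; names absent from the map pass through unchanged and
#' appear in the changelog with action `"unmatched"`. Applying the table
#' twice changes nothing.
#'
#' @param records records data.frame.
#' @param taxonomy result of [read_taxonomy()] (or a compatible list).
#' @return list with `records` (updated) and `changelog` (data.frame
#'   `accession`, `old`, `new`, `action`).
#' @export
apply_taxonomy <- function(records, taxonomy) {
  syn <- taxonomy$synonyms
  old <- paste(records$genus, records$epithet)
  hit <- !is.na(match(old, names(syn))) & records$epithet != "" &
    !records$parse_error
  new <- old
  new[hit] <- unname(syn[old[hit]])
  changed <- hit & new != old
  if (any(changed)) {
    parts <- strsplit(new[changed], " ", fixed = TRUE)
    records$genus[changed] <- vapply(parts, `[`, "", 1)
    records$epithet[changed] <- vapply(parts, `[`, "", 2)
  }
  changelog <- data.frame(
    accession = records$accession,
    old = old, new = new,
    action = ifelse(changed, "updated", ifelse(hit, "confirmed", "unmatched")),
    stringsAsFactors = FALSE)
  list(records = records, changelog = changelog)
}

#' Partition records into complete binomials and uncertain taxonomy
#'
#' Records carrying an open-nomenclature qualifier (cf./aff./sp./ssp.), a
#' missing epithet or a parse failure are routed to the uncertain set, to
#' be reported rather than silently discarded; the two sets partition the
#' input.
#'
#' @param records records data.frame.
#' @return list with `binomial` and `uncertain` records data.frames.
#' @export
partition_binomial <- function(records) {
  ok <- records$qualifier == "none" & records$epithet != "" & !records$parse_error
  list(binomial = records[ok, , drop = FALSE],
       uncertain = records[!ok, , drop = FALSE])
}

#' Write records to FASTA with curated headers
#'
#' Binomial records are written with `Genus_epithet_ACCESSION` headers;
#' others keep their accession as header.
#'
#' @param records records data.frame.
#' @param path output file path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_records_fasta <- function(records, path, width = 70) {
  lab <- record_label(records)
  lab[is.na(lab)] <- records$accession[is.na(lab)]
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", lab[i]), con)
    s <- records$seq[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}
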