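#' @title Synthetic repository-like data with planted errors
#' @name fixtures
#' @description
#' A seeded generator produces record sets that emulate a public-repository
#' download for one locus: per-genus species lineages are simulated by
#' mutating the reference, conspecific sequences by mutating the species
#' ancestor, and a configurable number of records receive planted errors
#' of the classes the curation pipeline is built to catch (cross-genus
#' misidentifications, backward-read submissions, RefSeq duplicates,
#' open-nomenclature names, terminal ambiguity runs, mitogenome
#' embeddings, frameshifting deletions). A truth table records every
#' plant, so recall and precision of each pipeline stage are computable
#' exactly.
NULL

# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Deterministic synthetic reference locus
#'
#' A uniform-random ACGT sequence of the approximate length of
#' cytochrome-b, generated under a fixed seed; a stand-in for a real
#' reference locus when none is supplied.
#'
#' @param length locus length in nt.
#' @param seed RNG seed.
#' @return `reference_locus`.
#' @export
synthetic_reference <- function(length = 1140, seed = 104729) {
  seq <- with_seed(seed, paste(sample(c("A", "C", "G", "T"), length,
                                      replace = TRUE), collapse = ""))
  reference_locus(seq, accession = "SYNREF")
}

#' Synthetic-data configuration
#'
#' Defaults describe the benchmark conditions used throughout the package
#' tests: 10 genera x 3 species x 8 sequences, conspecific substitution
#' proportion 1% and per-species lineage divergence 8% from the reference
#' — well separated around the 3% flagging threshold. `planted` gives the
#' number of records per error class (all zero by default).
#'
#' @param seed integer seed; fully determines the output.
#' @param n_genera,species_per_genus,seqs_per_species set dimensions.
#' @param intra_div per-site substitution proportion conspecific vs
#'   species ancestor.
#' @param inter_div per-site substitution proportion species ancestor vs
#'   reference.
#' @param planted named list of planted counts: `misidentified`,
#'   `revcomp`, `refseq_duplicate`, `non_binomial`, `terminal_ambiguity`,
#'   `mitogenome_embedded`, `frameshift_gap`.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1, n_genera = 10, species_per_genus = 3,
                             seqs_per_species = 8, intra_div = 0.01,
                             inter_div = 0.08, planted = list()) {
  default <- list(misidentified = 0, revcomp = 0, refseq_duplicate = 0,
                  non_binomial = 0, terminal_ambiguity = 0,
                  mitogenome_embedded = 0, frameshift_gap = 0)
  unknown <- setdiff(names(planted), names(default))
  if (length(unknown)) stop("unknown planted class: ",
                            paste(unknown, collapse = ", "))
  default[names(planted)] <- planted
  cfg <- list(seed = seed, n_genera = n_genera,
              species_per_genus = species_per_genus,
              seqs_per_species = seqs_per_species,
              intra_div = intra_div, inter_div = inter_div,
              planted = default)
  n_rec <- n_genera * species_per_genus * seqs_per_species
  n_planted <- sum(unlist(default[setdiff(names(default), "refseq_duplicate")]))
  if (n_planted > n_rec)
    stop("planted counts exceed the number of records")
  if (default$refseq_duplicate > n_rec)
    stop("more RefSeq duplicates requested than source records")
  if (default$misidentified > 0 && n_genera < 2)
    stop("misidentifications need at least two genera")
  structure(cfg, class = "synthetic_config")
}

.SYL <- c("ba", "ce", "di", "fo", "gu", "he", "li", "mo",
          "nu", "pe", "ra", "se", "ti", "vo", "xa", "zu")

.genus_name <- function(i) {
  a <- .SYL[((i - 1) %/% 16) %% 16 + 1]
  b <- .SYL[(i - 1) %% 16 + 1]
  n <- paste0(a, b, "gena")
  paste0(toupper(substr(n, 1, 1)), substr(n, 2, nchar(n)))
}

.epithet_name <- function(j) paste0(.SYL[(j - 1) %% 16 + 1],
                                    .SYL[((j - 1) %/% 16) %% 16 + 1], "ensis")

# independent per-site substitution, uniform alternative base
mutate_seq <- function(seq, p) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < p)
  for (i in hit) {
    alt <- setdiff(c("A", "C", "G", "T"), ch[i])
    ch[i] <- alt[sample.int(3, 1)]
  }
  paste(ch, collapse = "")
}

#' Generate a synthetic record set with planted errors
#'
#' Species ancestors are the reference mutated at `inter_div`; conspecific
#' sequences are the ancestor mutated at `intra_div` (independent per-site
#' substitutions, uniform alternative base, no indels except planted
#' ones). Misidentifications are planted as cross-genus relabelings, so
#' each is recoverable without dragging true-label partners into the flag
#' set. Identical seeds give byte-identical output.
#'
#' @param config `synthetic_config`.
#' @param ref `reference_locus` (default [synthetic_reference()]).
#' @param dir optional output directory; when given, `records.fasta`,
#'   `metadata.tsv` and `truth.tsv` are written there.
#' @return list with `records` (data.frame `accession`, `organism`,
#'   `definition`, `seq`), `truth` (one row per record: `accession`,
#'   `true_species`, `assigned_species`, `error_class`, `orientation`,
#'   `embed_offset`, `n_head`, `n_tail`), and — when `dir` is given —
#'   `paths`.
#' @export
simulate_records <- function(config, ref = synthetic_reference(), dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    G <- config$n_genera; S <- config$species_per_genus
    K <- config$seqs_per_species
    species_tab <- expand.grid(s = seq_len(S), g = seq_len(G))[, c("g", "s")]
    species_tab$genus <- .genus_name(species_tab$g)
    species_tab$epithet <- .epithet_name((species_tab$g - 1) * S + species_tab$s)
    species_tab$binomial <- paste(species_tab$genus, species_tab$epithet)
    ancestors <- vapply(seq_len(nrow(species_tab)), function(i)
      mutate_seq(ref$seq, config$inter_div), "")

    n_rec <- G * S * K
    rec <- data.frame(accession = sprintf("SY%06d", seq_len(n_rec)),
                      species_idx = rep(seq_len(nrow(species_tab)), each = K),
                      stringsAsFactors = FALSE)
    rec$true_species <- species_tab$binomial[rec$species_idx]
    rec$assigned_idx <- rec$species_idx
    rec$seq <- vapply(rec$species_idx, function(i)
      mutate_seq(ancestors[i], config$intra_div), "")
    rec$error_class <- "none"
    rec$orientation <- "forward"
    rec$embed_offset <- NA_integer_
    rec$n_head <- 0L
    rec$n_tail <- 0L
    rec$qualifier <- "none"

    pl <- config$planted
    pool <- sample.int(n_rec)
    take <- function(k) {
      if (k == 0) return(integer(0))
      out <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      out
    }

    for (i in take(pl$misidentified)) {
      g_true <- species_tab$g[rec$species_idx[i]]
      cand <- which(species_tab$g != g_true)
      rec$assigned_idx[i] <- cand[sample.int(length(cand), 1)]
      rec$error_class[i] <- "misidentified"
    }
    for (i in take(pl$revcomp)) {
      rec$seq[i] <- revcomp(rec$seq[i])
      rec$orientation[i] <- "reverse"
      rec$error_class[i] <- "revcomp"
    }
    for (i in take(pl$non_binomial)) {
      rec$qualifier[i] <- sample(c("cf", "aff", "sp", "ssp"), 1)
      rec$error_class[i] <- "non_binomial"
    }
    for (i in take(pl$terminal_ambiguity)) {
      rec$n_head[i] <- sample(3:20, 1)
      rec$n_tail[i] <- sample(3:20, 1)
      rec$seq[i] <- paste0(strrep("N", rec$n_head[i]), rec$seq[i],
                           strrep("N", rec$n_tail[i]))
      rec$error_class[i] <- "terminal_ambiguity"
    }
    for (i in take(pl$mitogenome_embedded)) {
      bg <- paste(sample(c("A", "C", "G", "T"), 16000, replace = TRUE),
                  collapse = "")
      off <- sample.int(16000 - 1L, 1)
      rec$seq[i] <- paste0(substr(bg, 1, off), rec$seq[i],
                           substr(bg, off + 1L, 16000))
      rec$embed_offset[i] <- off
      rec$error_class[i] <- "mitogenome_embedded"
    }
    for (i in take(pl$frameshift_gap)) {
      n <- nchar(rec$seq[i])
      pos <- sample(101:(n - 100L), 1)
      rec$seq[i] <- paste0(substr(rec$seq[i], 1, pos - 1L),
                           substr(rec$seq[i], pos + 1L, n))
      rec$error_class[i] <- "frameshift_gap"
    }

    # RefSeq twins duplicate an unplanted source record's sequence
    nc <- NULL
    if (pl$refseq_duplicate > 0) {
      src <- take(pl$refseq_duplicate)
      nc <- rec[src, , drop = FALSE]
      nc$accession <- sprintf("NC_%06d", seq_len(nrow(nc)))
      nc$error_class <- "refseq_duplicate"
    }
    all_rec <- rbind(rec, nc)

    assigned <- species_tab$binomial[all_rec$assigned_idx]
    organism <- assigned
    q <- all_rec$qualifier
    genus_only <- sub(" .*$", "", assigned)
    epithet_only <- sub("^.* ", "", assigned)
    organism[q %in% c("cf", "aff")] <-
      paste(genus_only, paste0(q, "."), epithet_only)[q %in% c("cf", "aff")]
    organism[q %in% c("sp", "ssp")] <-
      paste(genus_only, paste0(q, "."))[q %in% c("sp", "ssp")]

    records <- data.frame(accession = all_rec$accession, organism = organism,
                          definition = paste("synthetic", organism, "locus record"),
                          seq = all_rec$seq, stringsAsFactors = FALSE)
    truth <- data.frame(accession = all_rec$accession,
                        true_species = all_rec$true_species,
                        assigned_species = assigned,
                        error_class = all_rec$error_class,
                        orientation = all_rec$orientation,
                        embed_offset = all_rec$embed_offset,
                        n_head = all_rec$n_head, n_tail = all_rec$n_tail,
                        stringsAsFactors = FALSE)
    out <- list(records = records, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      fasta <- file.path(dir, "records.fasta")
      con <- file(fasta, "w")
      for (i in seq_len(nrow(records))) {
        writeLines(paste0(">", records$accession[i], " ",
                          records$organism[i]), con)
        writeLines(records$seq[i], con)
      }
      close(con)
      meta <- file.path(dir, "metadata.tsv")
      write.table(records[, c("accession", "organism", "definition")],
                  meta, sep = "\t", quote = FALSE, row.names = FALSE)
      tr <- file.path(dir, "truth.tsv")
      write.table(truth, tr, sep = "\t", quote = FALSE, row.names = FALSE)
      out$paths <- list(fasta = fasta, metadata = meta, truth = tr)
    }
    out
  })
}
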