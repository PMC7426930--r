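#' @title Per-species multiple alignment and gap resolution
#' @name msa
#' @description
#' Conspecific sequences are aligned with a deterministic center-star
#' strategy (center = longest sequence; every other sequence aligned
#' semi-globally against the center; merged on center coordinates). The
#' target locus is protein-coding under the vertebrate mitochondrial code,
#' so internal gap runs whose length is not a multiple of three are
#' sequencing artefacts: such positions are filled with the column
#' consensus when the column shows no diversity, and with `N` otherwise.
#' Ambiguous (non-ACGT) run-ins at row ends are converted to terminal gaps.
NULL

#' Species alignment container
#'
#' @param species binomial (\code{"Genus epithet"}).
#' @param labels row labels.
#' @param seqs equal-length gapped sequences (character vector).
#' @param frame_offset column index (0-2) of the first codon position
#'   relative to the reference reading frame, when known.
#' @return object of class `species_alignment`.
#' @export
species_alignment <- function(species, labels, seqs, frame_offset = NA_integer_) {
  stopifnot(length(labels) == length(seqs))
  if (length(seqs) > 1 && length(unique(nchar(seqs))) != 1L)
    stop("species_alignment: rows must have equal length")
  structure(list(species = species, labels = labels,
                 seqs = toupper(seqs), frame_offset = frame_offset),
            class = "species_alignment")
}

#' @export
print.species_alignment <- function(x, ...) {
  cat(sprintf("<species_alignment> %s: %d sequence(s), %d column(s)\n",
              x$species, length(x$seqs),
              if (length(x$seqs)) nchar(x$seqs[1]) else 0L))
  invisible(x)
}

#' Align conspecific sequences (center-star)
#'
#' The longest input (ties: first) is the center; every other sequence is
#' aligned pairwise against it by semi-global dynamic programming, and the
#' pairwise alignments are merged on center coordinates (insertions
#' between the same center positions share columns, left-aligned). Row
#' order is input order. A single sequence is returned as a one-row
#' alignment. For two sequences the result is exactly the optimal pairwise
#' alignment.
#'
#' @param seqs ungapped sequences (character vector, all one species,
#'   forward orientation).
#' @param labels row labels (default names of `seqs`).
#' @param species binomial for the container.
#' @param params [refmap_params()] alignment scores.
#' @param ref_starts optional 0-based reference start positions per
#'   sequence, used to record the codon frame offset.
#' @return `species_alignment`.
#' @export
align_species <- function(seqs, labels = names(seqs), species = "",
                          params = refmap_params(), ref_starts = NULL) {
  stopifnot(length(seqs) >= 1L)
  if (is.null(labels)) labels <- paste0("seq", seq_along(seqs))
  seqs <- toupper(seqs)
  frame_offset <- NA_integer_
  if (!is.null(ref_starts) && length(ref_starts) && all(!is.na(ref_starts)))
    frame_offset <- (3L - min(ref_starts) %% 3L) %% 3L
  if (length(seqs) == 1L)
    return(species_alignment(species, labels, seqs, frame_offset))

  ci <- which.max(nchar(seqs))
  center <- seqs[ci]
  Lc <- nchar(center)
  others <- setdiff(seq_along(seqs), ci)

  # per sequence: character aligned at each center position, plus insert
  # strings after p center characters (p = 0..Lc)
  aligned_at <- list()
  inserts <- list()
  for (k in others) {
    aln <- align_semiglobal(seqs[k], center, params)
    at <- rep("-", Lc)
    ins <- vector("list", Lc + 1L)
    ins[] <- list(character(0))
    q <- strsplit(aln$aln_query, "")[[1]]
    c_chars <- strsplit(aln$aln_ref, "")[[1]]
    # unaligned query head goes immediately before the aligned region
    head_chars <- if (aln$q_start > 0)
      strsplit(substr(seqs[k], 1, aln$q_start), "")[[1]] else character(0)
    ins[[aln$ref_start + 1L]] <- head_chars
    cpos <- aln$ref_start
    for (col in seq_along(q)) {
      if (c_chars[col] != "-") {
        cpos <- cpos + 1L
        at[cpos] <- q[col]
      } else {
        ins[[cpos + 1L]] <- c(ins[[cpos + 1L]], q[col])
      }
    }
    tail_chars <- if (aln$q_end < nchar(seqs[k]))
      strsplit(substr(seqs[k], aln$q_end + 1L, nchar(seqs[k])), "")[[1]]
    else character(0)
    ins[[cpos + 1L]] <- c(ins[[cpos + 1L]], tail_chars)
    aligned_at[[as.character(k)]] <- at
    inserts[[as.character(k)]] <- ins
  }

  maxins <- integer(Lc + 1L)
  for (k in others) {
    lens <- lengths(inserts[[as.character(k)]])
    maxins <- pmax(maxins, lens)
  }

  build_row <- function(at, ins) {
    parts <- character(0)
    for (p in 0:Lc) {
      blk <- ins[[p + 1L]]
      pad <- maxins[p + 1L] - length(blk)
      parts <- c(parts, blk, rep("-", pad),
                 if (p < Lc) at[p + 1L] else character(0))
    }
    paste(parts, collapse = "")
  }
  center_row <- build_row(strsplit(center, "")[[1]],
                          rep(list(character(0)), Lc + 1L))
  rows <- character(length(seqs))
  rows[ci] <- center_row
  for (k in others)
    rows[k] <- build_row(aligned_at[[as.character(k)]],
                         inserts[[as.character(k)]])
  species_alignment(species, labels, rows, frame_offset)
}

# maximal internal gap runs of one row; returns data.frame(start, len)
.gap_runs <- function(chars) {
  nong <- which(chars != "-")
  out <- data.frame(start = integer(0), len = integer(0))
  if (length(nong) < 2L) return(out)
  lo <- nong[1]; hi <- nong[length(nong)]
  r <- rle(chars[lo:hi] == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  gap <- which(r$values)
  if (!length(gap)) return(out)
  data.frame(start = starts[gap] + lo - 1L, len = r$lengths[gap])
}

#' Resolve frame-breaking gaps
#'
#' For every maximal internal gap run whose length is not a multiple of
#' three (with `strict_three = TRUE`: not exactly three), each gapped
#' position is replaced by the column consensus base when all non-gap
#' characters in that column agree, and by `N` when the column shows
#' diversity. In-frame runs and terminal gaps are untouched. The operation
#' is idempotent and never changes a non-gap character.
#'
#' @param aln `species_alignment`.
#' @param strict_three read the frame rule as "length other than exactly
#'   3" instead of "length not a multiple of 3".
#' @return `species_alignment`.
#' @export
resolve_gaps <- function(aln, strict_three = FALSE) {
  mat <- do.call(rbind, strsplit(aln$seqs, ""))
  if (is.null(mat) || ncol(mat) == 0L) return(aln)
  offending <- if (strict_three) function(len) len != 3L
               else function(len) len %% 3L != 0L
  for (r in seq_len(nrow(mat))) {
    runs <- .gap_runs(mat[r, ])
    if (!nrow(runs)) next
    for (g in seq_len(nrow(runs))) {
      if (!offending(runs$len[g])) next
      for (pos in runs$start[g]:(runs$start[g] + runs$len[g] - 1L)) {
        col <- mat[, pos]
        obs <- unique(col[col != "-"])
        mat[r, pos] <- if (length(obs) == 1L) obs else "N"
      }
    }
  }
  aln$seqs <- apply(mat, 1L, paste, collapse = "")
  aln
}

#' Trim ambiguous row ends
#'
#' Leading and trailing runs consisting only of non-ACGT characters are
#' converted to terminal gaps, row by row; internal ambiguities are left
#' alone. Column count is unchanged.
#'
#' @param aln `species_alignment`.
#' @return `species_alignment`.
#' @export
trim_ambiguous_ends <- function(aln) {
  trim_one <- function(s) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    i <- 1L
    while (i <= n && !(ch[i] %in% c("A", "C", "G", "T"))) {
      ch[i] <- "-"; i <- i + 1L
    }
    j <- n
    while (j >= i && !(ch[j] %in% c("A", "C", "G", "T"))) {
      ch[j] <- "-"; j <- j - 1L
    }
    paste(ch, collapse = "")
  }
  aln$seqs <- vapply(aln$seqs, trim_one, "", USE.NAMES = FALSE)
  aln
}

#' Write a species alignment as FASTA
#'
#' @param aln `species_alignment`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$seqs)) {
    writeLines(paste0(">", aln$labels[i]), con)
    writeLines(aln$seqs[i], con)
  }
  invisible(path)
}
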