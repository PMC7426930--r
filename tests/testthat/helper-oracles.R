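# shared fixtures and independent oracles

REF <- synthetic_reference()  # 1140 nt, fixed seed

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

random_gapped <- function(n, p_gap = 0.05, p_amb = 0.05) {
  paste(sample(c("A", "C", "G", "T", "-", "N", "R"), n, TRUE,
               prob = c(rep((1 - p_gap - p_amb) / 4, 4), p_gap,
                        p_amb / 2, p_amb / 2)), collapse = "")
}

# site-by-site enumeration oracle for uncorrected divergence with
# pairwise deletion
oracle_pdist <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(ca) == length(cb))
  comp <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  n <- sum(comp)
  list(d = if (n > 0) sum(ca[comp] != cb[comp]) / n else NA_real_, n = n)
}

# independent semi-global alignment scorer (Biostrings); same scoring
# scheme: match +1, mismatch -1, gap run of length k costs -(4 + k)
oracle_overlap_score <- function(query, ref) {
  mat <- matrix(-1, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")))
  diag(mat) <- 1
  Biostrings::pairwiseAlignment(query, ref, type = "overlap",
                                substitutionMatrix = mat,
                                gapOpening = 4, gapExtension = 1,
                                scoreOnly = TRUE)
}

oracle_local_score <- function(query, ref) {
  mat <- matrix(-1, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T")))
  diag(mat) <- 1
  Biostrings::pairwiseAlignment(query, ref, type = "local",
                                substitutionMatrix = mat,
                                gapOpening = 4, gapExtension = 1,
                                scoreOnly = TRUE)
}

# brute-force best-region scan, written independently of the package
oracle_best_region <- function(counts_sp, counts_seq, window) {
  L <- length(counts_sp)
  best <- NULL
  for (s in seq_len(L - window + 1)) {
    w_sp <- min(counts_sp[s:(s + window - 1)])
    w_sq <- min(counts_seq[s:(s + window - 1)])
    key <- c(w_sp, w_sq)
    if (is.null(best) || key[1] > best$key[1] ||
        (key[1] == best$key[1] && key[2] > best$key[2]))
      best <- list(start = s - 1L, key = key)
  }
  best
}

# mutate a sequence at per-site probability p (uniform alternative base);
# independent of the generator's internal helper
mutate_at <- function(seq, p) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(ch)) < p)
  for (i in hit) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

write_fasta_tmp <- function(headers, seqs) {
  f <- tempfile(fileext = ".fasta")
  con <- file(f, "w")
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", headers[i]), con)
    writeLines(seqs[i], con)
  }
  close(con)
  f
}
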