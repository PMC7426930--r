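#' @title Coverage profiling and database summary statistics
#' @name coverage_summary
NULL

#' Per-position coverage profile on the reference
#'
#' Position `i` (0-based) is covered by a record iff `i` lies in its
#' mapped span and the aligned character there is A, C, G or T.
#' `counts_seq` tallies sequences, `counts_sp` distinct species.
#'
#' @param mapped data.frame with `species`, `ref_start`, `ref_end`,
#'   `ref_aligned` (as from [map_records()] plus a species column).
#' @param ref_length reference length `L`.
#' @return data.frame `position` (0-based), `counts_seq`, `counts_sp`.
#' @export
coverage_profile <- function(mapped, ref_length) {
  counts_seq <- integer(ref_length)
  sp_cov <- list()
  for (i in seq_len(nrow(mapped))) {
    if (is.na(mapped$ref_start[i])) next
    ch <- strsplit(mapped$ref_aligned[i], "")[[1]]
    pos <- mapped$ref_start[i] + which(ch %in% c("A", "C", "G", "T"))
    if (!length(pos)) next
    counts_seq[pos] <- counts_seq[pos] + 1L
    sp <- mapped$species[i]
    if (is.null(sp_cov[[sp]])) sp_cov[[sp]] <- logical(ref_length)
    sp_cov[[sp]][pos] <- TRUE
  }
  counts_sp <- integer(ref_length)
  for (v in sp_cov) counts_sp <- counts_sp + v
  data.frame(position = seq_len(ref_length) - 1L,
             counts_seq = counts_seq, counts_sp = as.integer(counts_sp))
}

#' Best locus region of a given window length
#'
#' Exhaustive scan over all `L - window + 1` start positions; the score of
#' a window is lexicographic: first the minimum species count over the
#' window, then the minimum sequence count, ties broken by the smallest
#' start. The window minimum guarantees the region is usable end-to-end.
#'
#' @param profile result of [coverage_profile()].
#' @param window window length in nt (`0 < window <= L`).
#' @return list `start`, `end` (0-based half-open), `n_species`,
#'   `n_seqs` (the window minima).
#' @export
best_region <- function(profile, window) {
  L <- nrow(profile)
  if (window <= 0 || window > L)
    stop("best_region: window must be in 1..L")
  best <- NULL
  for (s in 0:(L - window)) {
    i <- (s + 1):(s + window)
    sp <- min(profile$counts_sp[i])
    sq <- min(profile$counts_seq[i])
    if (is.null(best) || sp > best$n_species ||
        (sp == best$n_species && sq > best$n_seqs)) {
      best <- list(start = s, end = s + window, n_species = sp, n_seqs = sq)
    }
  }
  best
}

# linear-interpolation percentiles (R's default type 7)
.med_iqr <- function(x) {
  if (!length(x)) return(c(median = NA_real_, q25 = NA_real_, q75 = NA_real_))
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(median = q[2], q25 = q[1], q75 = q[3])
}

#' Summary statistics of a curated record set
#'
#' Sequences per species, species per genus and (when a genus-to-family
#' map is supplied) species per family, each with median and quartiles
#' (linear interpolation between order statistics).
#'
#' @param records curated records data.frame (binomials).
#' @param family_map optional named character vector genus -> family.
#' @return list with data.frames `per_species`, `per_genus`,
#'   `per_family`, and a `stats` data.frame of medians/quartiles.
#' @export
summarize_taxa <- function(records, family_map = NULL) {
  if (nrow(records) == 0L) {
    empty <- data.frame(group = character(0), n = integer(0))
    return(list(per_species = empty, per_genus = empty, per_family = empty,
                stats = data.frame(grouping = character(0), median = numeric(0),
                                   q25 = numeric(0), q75 = numeric(0))))
  }
  sp <- species_key(records)
  per_species <- as.data.frame(table(group = sp), stringsAsFactors = FALSE)
  names(per_species) <- c("group", "n")
  uspecies <- unique(data.frame(genus = records$genus, species = sp,
                                stringsAsFactors = FALSE))
  per_genus <- as.data.frame(table(group = uspecies$genus),
                             stringsAsFactors = FALSE)
  names(per_genus) <- c("group", "n")
  per_family <- data.frame(group = character(0), n = integer(0))
  if (!is.null(family_map) && length(family_map)) {
    fam <- unname(family_map[uspecies$genus])
    keep <- !is.na(fam)
    if (any(keep)) {
      per_family <- as.data.frame(table(group = fam[keep]),
                                  stringsAsFactors = FALSE)
      names(per_family) <- c("group", "n")
    }
  }
  stats <- rbind(
    data.frame(grouping = "sequences_per_species",
               t(.med_iqr(per_species$n))),
    data.frame(grouping = "species_per_genus", t(.med_iqr(per_genus$n))),
    if (nrow(per_family))
      data.frame(grouping = "species_per_family", t(.med_iqr(per_family$n))))
  rownames(stats) <- NULL
  list(per_species = per_species, per_genus = per_genus,
       per_family = per_family, stats = stats)
}
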