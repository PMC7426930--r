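#' @title Uncorrected pairwise divergence
#' @name divergence
#' @description
#' Genetic distance between two aligned sequences is the uncorrected
#' p-distance: the proportion of mismatching sites among comparable sites,
#' with pairwise deletion of any site where either sequence carries a gap,
#' `N` or another ambiguity code. No substitution-model correction is
#' applied. Distances with fewer comparable sites than `min_overlap` are
#' reported missing (`NA`) rather than trusted.
NULL

#' Uncorrected p-distance between two aligned sequences
#'
#' @param a,b equal-length (same alignment) gapped sequences.
#' @param min_overlap minimum comparable sites for a defined distance;
#'   the pairwise utility defaults to 0, matrix builders default to 100.
#' @return list with `d` (proportion, `NA` if overlap insufficient) and
#'   `n` (comparable sites).
#' @export
p_distance <- function(a, b, min_overlap = 0) {
  v <- pdist_pair_cpp(toupper(a), toupper(b))
  d <- if (v[2] >= max(min_overlap, 1L)) v[1] / v[2] else NA_real_
  list(d = d, n = v[2])
}

#' Divergence matrix container
#'
#' Symmetric uncorrected-divergence matrix with per-pair comparable-site
#' counts; entries with fewer than `min_overlap` comparable sites are
#' `NA` ("insufficient overlap").
#'
#' @param labels sequence labels.
#' @param species species of each sequence.
#' @param d symmetric numeric matrix of proportions.
#' @param n_sites symmetric integer matrix of comparable sites.
#' @param min_overlap overlap floor used.
#' @return object of class `divergence_matrix`.
#' @export
divergence_matrix <- function(labels, species, d, n_sites, min_overlap) {
  stopifnot(length(labels) == nrow(d), nrow(d) == ncol(d),
            length(species) == length(labels))
  dimnames(d) <- list(labels, labels)
  dimnames(n_sites) <- list(labels, labels)
  structure(list(labels = labels, species = species, d = d,
                 n_sites = n_sites, min_overlap = min_overlap),
            class = "divergence_matrix")
}

#' @export
print.divergence_matrix <- function(x, ...) {
  cat(sprintf("<divergence_matrix> %d sequence(s), %d species, min_overlap=%d\n",
              length(x$labels), length(unique(x$species)), x$min_overlap))
  invisible(x)
}

.pdist_matrix <- function(seqs, min_overlap) {
  res <- pdist_all_cpp(toupper(seqs))
  n <- length(seqs)
  d <- matrix(0, n, n)
  ok <- res$comparable >= min_overlap
  d <- ifelse(ok, res$mismatches / pmax(res$comparable, 1L), NA_real_)
  diag(d) <- 0
  list(d = d, n_sites = res$comparable)
}

#' Within-species divergence matrix
#'
#' All-pairs p-distances over the rows of one species alignment.
#'
#' @param aln `species_alignment`.
#' @param min_overlap minimum comparable sites for a defined distance.
#' @return `divergence_matrix`.
#' @export
species_matrix <- function(aln, min_overlap = 100) {
  m <- .pdist_matrix(aln$seqs, min_overlap)
  divergence_matrix(aln$labels, rep(aln$species, length(aln$labels)),
                    m$d, m$n_sites, min_overlap)
}

# project a mapped record onto full reference coordinates: positions
# outside the mapped span become gaps
project_to_reference <- function(ref_aligned, ref_start, ref_end, L) {
  paste0(strrep("-", ref_start), ref_aligned, strrep("-", L - ref_end))
}

#' Genus-level divergence matrix
#'
#' Full symmetric matrix over all sequences of one genus. Conspecific
#' pairs are measured on the species alignment; heterospecific pairs on
#' reference-coordinate projections of the mapped sequences (deterministic
#' and free of cross-species re-alignment artifacts).
#'
#' @param alignments list of `species_alignment`, one per species of the
#'   genus, with labels matching `mapped$label`.
#' @param mapped data.frame with columns `label`, `species`,
#'   `ref_start`, `ref_end`, `ref_aligned` for every sequence.
#' @param ref_length reference locus length.
#' @param min_overlap minimum comparable sites for a defined distance.
#' @return `divergence_matrix`.
#' @export
genus_matrix <- function(alignments, mapped, ref_length, min_overlap = 100) {
  labels <- mapped$label
  species <- mapped$species
  n <- length(labels)
  proj <- mapply(project_to_reference, mapped$ref_aligned,
                 mapped$ref_start, mapped$ref_end,
                 MoreArgs = list(L = ref_length))
  cross <- .pdist_matrix(proj, min_overlap)
  d <- cross$d
  ns <- cross$n_sites
  # overwrite conspecific blocks with the species-alignment distances
  for (aln in alignments) {
    idx <- match(aln$labels, labels)
    stopifnot(!anyNA(idx))
    if (length(idx) < 2L) next
    m <- .pdist_matrix(aln$seqs, min_overlap)
    d[idx, idx] <- m$d
    ns[idx, idx] <- m$n_sites
  }
  diag(d) <- 0
  divergence_matrix(labels, species, d, ns, min_overlap)
}

#' Long-format table of a divergence matrix
#'
#' One row per unordered pair, suitable for TSV export; `d_percent` is
#' rounded to two decimals for reporting while all threshold logic uses
#' the exact values in the matrix.
#'
#' @param dm `divergence_matrix`.
#' @return data.frame `label_i`, `label_j`, `species_i`, `species_j`,
#'   `d`, `d_percent`, `n_sites`.
#' @export
divergence_long <- function(dm) {
  n <- length(dm$labels)
  if (n < 2L)
    return(data.frame(label_i = character(0), label_j = character(0),
                      species_i = character(0), species_j = character(0),
                      d = numeric(0), d_percent = numeric(0),
                      n_sites = integer(0), stringsAsFactors = FALSE))
  idx <- which(upper.tri(dm$d), arr.ind = TRUE)
  data.frame(label_i = dm$labels[idx[, 1]], label_j = dm$labels[idx[, 2]],
             species_i = dm$species[idx[, 1]], species_j = dm$species[idx[, 2]],
             d = dm$d[idx], d_percent = round(100 * dm$d[idx], 2),
             n_sites = dm$n_sites[idx], stringsAsFactors = FALSE)
}
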