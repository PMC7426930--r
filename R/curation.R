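#' @title Threshold-based conflict flagging
#' @name curation
#' @description
#' A single divergence threshold `t` (default 3%, a conservative value for
#' amphibian cytochrome-b; re-estimate for other loci and groups) drives
#' two complementary screens. Within a species, sequences are accepted at
#' divergence `<= t` and flagged above it: single-linkage clusters at `t`
#' are formed and every member of every non-largest cluster is flagged
#' (ties keep the cluster containing the lexicographically smallest
#' label). Within a genus, heterospecific pairs are accepted at divergence
#' `> t` and flagged at `<= t`. Pairs with insufficient comparable sites
#' neither accept nor flag. Final verdicts (misidentification,
#' contamination, hybridization, submission error) require literature
#' review and stay as empty annotation columns.
NULL

.empty_flags <- function() {
  data.frame(label = character(0), accession = character(0),
             species = character(0), category = character(0),
             partner = character(0), d = numeric(0), n_sites = integer(0),
             threshold = numeric(0), stringsAsFactors = FALSE)
}

.acc_from_label <- function(label) sub("^.*_", "", label)

# connected components of the graph with edges d <= t (defined pairs only)
.single_linkage <- function(d, t) {
  n <- nrow(d)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      nb <- which(!is.na(d[v, ]) & d[v, ] <= t & comp == 0L)
      queue <- c(queue, setdiff(nb, v))
    }
  }
  comp
}

#' Flag divergent conspecific sequences
#'
#' Operates on the divergence matrix of one species. Sequences are grouped
#' by single-linkage at threshold `t` over defined distances; if more than
#' one cluster results, all members outside the largest cluster are
#' flagged (`intraspecific_divergent`), the tie among equally large
#' clusters being broken in favour of the cluster containing the
#' lexicographically smallest label. Evidence on each flag is the nearest
#' conspecific and its distance. A single-sequence species cannot be
#' assessed; sequences with no defined distance at all are likewise
#' excluded and listed in the `unassessable` attribute.
#'
#' @param dm `divergence_matrix` covering one species.
#' @param t divergence threshold (proportion, default 0.03).
#' @return flag data.frame (`label`, `accession`, `species`, `category`,
#'   `partner`, `d`, `n_sites`, `threshold`), with attribute
#'   `unassessable` (labels without evidence).
#' @export
flag_intraspecific <- function(dm, t = 0.03) {
  stopifnot(t > 0, t < 1)
  if (length(unique(dm$species)) > 1L)
    stop("flag_intraspecific: matrix must cover a single species")
  n <- length(dm$labels)
  flags <- .empty_flags()
  if (n < 2L) {
    attr(flags, "unassessable") <- if (n == 1L) dm$labels else character(0)
    return(flags)
  }
  d <- dm$d
  diag(d) <- NA_real_
  defined <- rowSums(!is.na(d)) > 0L
  unassessable <- dm$labels[!defined]
  idx <- which(defined)
  if (length(idx) >= 2L) {
    sub <- d[idx, idx, drop = FALSE]
    comp <- .single_linkage(sub, t)
    sizes <- tabulate(comp)
    big <- which(sizes == max(sizes))
    if (length(big) > 1L) {
      first_lab <- vapply(big, function(k) min(dm$labels[idx][comp == k]), "")
      big <- big[order(first_lab)][1]
    }
    flagged <- idx[comp != big]
    if (length(flagged)) {
      nearest <- vapply(flagged, function(i) {
        j <- which.min(d[i, ])
        c(j, d[i, j], dm$n_sites[i, j])
      }, numeric(3))
      flags <- data.frame(
        label = dm$labels[flagged],
        accession = .acc_from_label(dm$labels[flagged]),
        species = dm$species[flagged],
        category = "intraspecific_divergent",
        partner = dm$labels[nearest[1, ]],
        d = nearest[2, ], n_sites = as.integer(nearest[3, ]),
        threshold = t, stringsAsFactors = FALSE)
      rownames(flags) <- NULL
    }
  }
  attr(flags, "unassessable") <- unassessable
  flags
}

#' Flag suspiciously similar heterospecific sequences
#'
#' Every heterospecific pair in the genus matrix with defined divergence
#' `<= t` contributes a flag to each member (`intrageneric_similar`),
#' deduplicated per sequence keeping the smallest-distance partner as
#' evidence. Conspecific pairs are ignored here.
#'
#' @param dm genus-level `divergence_matrix`.
#' @param t divergence threshold (proportion); `t = 0` flags only
#'   identical heterospecific pairs.
#' @return flag data.frame as in [flag_intraspecific()].
#' @export
flag_intrageneric <- function(dm, t = 0.03) {
  stopifnot(t >= 0, t < 1)
  n <- length(dm$labels)
  flags <- .empty_flags()
  if (n < 2L || length(unique(dm$species)) < 2L) return(flags)
  d <- dm$d
  diag(d) <- NA_real_
  hetero <- outer(dm$species, dm$species, "!=")
  cand <- !is.na(d) & hetero & d <= t
  hit <- which(rowSums(cand) > 0L)
  if (length(hit)) {
    best <- vapply(hit, function(i) {
      js <- which(cand[i, ])
      j <- js[which.min(d[i, js])]
      c(j, d[i, j], dm$n_sites[i, j])
    }, numeric(3))
    flags <- data.frame(
      label = dm$labels[hit],
      accession = .acc_from_label(dm$labels[hit]),
      species = dm$species[hit],
      category = "intrageneric_similar",
      partner = dm$labels[best[1, ]],
      d = best[2, ], n_sites = as.integer(best[3, ]),
      threshold = t, stringsAsFactors = FALSE)
    rownames(flags) <- NULL
  }
  flags
}

#' Assemble the conflict report
#'
#' One row per flagged sequence with category, evidence and threshold,
#' plus empty annotation columns (`verdict`, `rationale`, `reference`)
#' for the literature-based review that the tool deliberately does not
#' automate. Mapping failures, non-binomial records and dropped RefSeq
#' duplicates are carried as their own categories so the report mirrors
#' the full error taxonomy.
#'
#' @param flags divergence-based flag data.frame(s), e.g. `rbind` of
#'   [flag_intraspecific()] and [flag_intrageneric()] results.
#' @param mapping_failures data.frame with `accession`, `species`
#'   (optional) of unmappable records.
#' @param non_binomials records data.frame of uncertain-taxonomy records.
#' @param duplicates `dropped` data.frame from [deduplicate()].
#' @param threshold threshold used, for the report column.
#' @return list with `report` (data.frame) and `counts` (data.frame
#'   `category`, `n`).
#' @export
build_conflict_report <- function(flags = NULL, mapping_failures = NULL,
                                  non_binomials = NULL, duplicates = NULL,
                                  threshold = 0.03) {
  rows <- list()
  if (!is.null(flags) && nrow(flags))
    rows$flags <- data.frame(
      accession = flags$accession, species = flags$species,
      category = flags$category, partner = flags$partner,
      d_percent = round(100 * flags$d, 2), n_sites = flags$n_sites,
      threshold_percent = 100 * flags$threshold,
      stringsAsFactors = FALSE)
  if (!is.null(mapping_failures) && nrow(mapping_failures))
    rows$map <- data.frame(
      accession = mapping_failures$accession,
      species = if ("species" %in% names(mapping_failures))
        mapping_failures$species
      else paste(mapping_failures$genus, mapping_failures$epithet),
      category = "mapping_failure", partner = NA_character_,
      d_percent = NA_real_, n_sites = NA_integer_,
      threshold_percent = 100 * threshold, stringsAsFactors = FALSE)
  if (!is.null(non_binomials) && nrow(non_binomials))
    rows$nb <- data.frame(
      accession = non_binomials$accession,
      species = non_binomials$raw_name,
      category = "non_binomial", partner = NA_character_,
      d_percent = NA_real_, n_sites = NA_integer_,
      threshold_percent = 100 * threshold, stringsAsFactors = FALSE)
  if (!is.null(duplicates) && nrow(duplicates))
    rows$dup <- data.frame(
      accession = duplicates$accession, species = NA_character_,
      category = "duplicate", partner = duplicates$partner,
      d_percent = NA_real_, n_sites = NA_integer_,
      threshold_percent = 100 * threshold, stringsAsFactors = FALSE)
  report <- if (length(rows)) do.call(rbind, rows) else
    data.frame(accession = character(0), species = character(0),
               category = character(0), partner = character(0),
               d_percent = numeric(0), n_sites = integer(0),
               threshold_percent = numeric(0), stringsAsFactors = FALSE)
  report$verdict <- character(nrow(report))
  report$rationale <- character(nrow(report))
  report$reference <- character(nrow(report))
  rownames(report) <- NULL
  tab <- table(report$category)
  counts <- data.frame(category = names(tab), n = as.integer(tab),
                       stringsAsFactors = FALSE)
  list(report = report, counts = counts)
}
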