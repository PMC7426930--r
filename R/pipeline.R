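#' @title End-to-end curation pipeline
#' @name pipeline
#' @description
#' Orchestrates the stages records -> reference mapping -> per-species
#' alignment -> divergence -> conflict flagging -> coverage/summary,
#' writing one artifact per stage plus a run manifest that reconciles
#' record counts. All stages are deterministic: identical inputs and
#' configuration give byte-identical output directories.
NULL

#' Pipeline configuration
#'
#' @param input_fasta path to the record FASTA.
#' @param reference path to the single-record reference locus FASTA, or a
#'   `reference_locus` object.
#' @param out_dir output directory (created if absent).
#' @param metadata optional metadata TSV (accession, organism, definition).
#' @param taxonomy optional taxonomy synonymy TSV (see [read_taxonomy()]).
#' @param threshold divergence threshold as a proportion (default 0.03).
#' @param min_overlap minimum comparable sites for a defined distance.
#' @param window coverage best-region window length (nt).
#' @param policy `"exclude"` drops flagged sequences from the curated set;
#'   `"annotate"` keeps them and only reports.
#' @param strict_three gap-resolution frame rule variant (see
#'   [resolve_gaps()]).
#' @param params alignment/mapping parameters from [refmap_params()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_fasta, reference, out_dir,
                            metadata = NULL, taxonomy = NULL,
                            threshold = 0.03, min_overlap = 100,
                            window = 400, policy = c("exclude", "annotate"),
                            strict_three = FALSE,
                            params = refmap_params()) {
  policy <- match.arg(policy)
  stopifnot(threshold > 0, threshold < 1)
  structure(list(input_fasta = input_fasta, reference = reference,
                 out_dir = out_dir, metadata = metadata,
                 taxonomy = taxonomy, threshold = threshold,
                 min_overlap = min_overlap, window = window,
                 policy = policy, strict_three = strict_three,
                 params = params),
            class = "pipeline_config")
}

.write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full curation pipeline
#'
#' Stages: parse and normalise records, drop RefSeq duplicates, reconcile
#' taxonomy, partition binomials from uncertain names, orient and extract
#' the locus against the reference, align each species, resolve
#' frame-breaking gaps and trim ambiguous ends, compute genus divergence
#' matrices, flag conflicts at the threshold, and profile coverage and
#' summary statistics over the curated set. Flagged sequences never cause
#' a failure; only configuration and I/O problems stop the run.
#'
#' @param config `pipeline_config`.
#' @param quiet suppress stage messages.
#' @return invisibly, a list with every stage product (`records`,
#'   `dropped`, `changelog`, `uncertain`, `mapped`, `alignments`,
#'   `genus_matrices`, `flags`, `report`, `curated`, `coverage`,
#'   `best_region`, `summary`, `manifest`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  ref <- if (inherits(config$reference, "reference_locus")) config$reference
         else read_reference(config$reference)
  L <- ref$length

  say("records: parsing %s", config$input_fasta)
  rec <- parse_records(config$input_fasta, config$metadata)
  n_in <- nrow(rec)

  dd <- deduplicate(rec)
  rec <- dd$kept
  .write_tsv(dd$dropped, file.path(out, "dropped_duplicates.tsv"))

  changelog <- NULL
  family_map <- NULL
  if (!is.null(config$taxonomy)) {
    tax <- read_taxonomy(config$taxonomy)
    upd <- apply_taxonomy(rec, tax)
    rec <- upd$records
    changelog <- upd$changelog
    family_map <- tax$family
    .write_tsv(changelog, file.path(out, "taxonomy_changelog.tsv"))
  }

  part <- partition_binomial(rec)
  .write_tsv(data.frame(accession = part$uncertain$accession,
                        raw_name = part$uncertain$raw_name,
                        qualifier = part$uncertain$qualifier),
             file.path(out, "uncertain_taxonomy.tsv"))

  say("refmap: orienting %d record(s) against %s (%d nt)",
      nrow(part$binomial), ref$accession, L)
  mapped <- map_records(part$binomial, ref, config$params)
  mapped$species <- paste(mapped$genus, mapped$epithet)
  mapped$label <- paste(mapped$genus, mapped$epithet, mapped$accession,
                        sep = "_")
  ok <- mapped[mapped$status == "ok", , drop = FALSE]
  failed <- mapped[mapped$status != "ok", , drop = FALSE]
  .write_tsv(mapped[, c("accession", "orientation", "ref_start", "ref_end",
                        "identity", "score_fwd", "score_rev", "source",
                        "status")],
             file.path(out, "orientation.tsv"))

  say("msa: aligning %d species", length(unique(ok$species)))
  aln_dir <- file.path(out, "alignments")
  dir.create(aln_dir, showWarnings = FALSE)
  alignments <- list()
  for (sp in sort(unique(ok$species))) {
    rows <- ok[ok$species == sp, , drop = FALSE]
    aln <- align_species(rows$oriented_seq, labels = rows$label,
                         species = sp, params = config$params,
                         ref_starts = rows$ref_start)
    aln <- trim_ambiguous_ends(resolve_gaps(aln, config$strict_three))
    alignments[[sp]] <- aln
    write_alignment_fasta(aln, file.path(aln_dir,
                                         paste0(gsub(" ", "_", sp), ".fasta")))
  }

  say("divergence: %d genus matrices", length(unique(ok$genus)))
  dist_dir <- file.path(out, "distances")
  dir.create(dist_dir, showWarnings = FALSE)
  genus_matrices <- list()
  intra_flags <- list()
  inter_flags <- list()
  unassessable <- character(0)
  for (g in sort(unique(ok$genus))) {
    rows <- ok[ok$genus == g, , drop = FALSE]
    alns <- alignments[unique(rows$species)]
    gm <- genus_matrix(alns, rows, L, config$min_overlap)
    genus_matrices[[g]] <- gm
    .write_tsv(divergence_long(gm), file.path(dist_dir, paste0(g, ".tsv")))
    for (sp in unique(rows$species)) {
      sm <- species_matrix(alignments[[sp]], config$min_overlap)
      fl <- flag_intraspecific(sm, config$threshold)
      unassessable <- c(unassessable, attr(fl, "unassessable"))
      intra_flags[[sp]] <- fl
    }
    inter_flags[[g]] <- flag_intrageneric(gm, config$threshold)
  }
  flags <- do.call(rbind, c(intra_flags, inter_flags))
  if (is.null(flags)) flags <- .empty_flags()
  rownames(flags) <- NULL
  .write_tsv(data.frame(label = sort(unique(unassessable))),
             file.path(out, "unassessable.tsv"))

  rep <- build_conflict_report(flags, mapping_failures = failed,
                               non_binomials = part$uncertain,
                               duplicates = dd$dropped,
                               threshold = config$threshold)
  .write_tsv(rep$report, file.path(out, "conflict_report.tsv"))
  .write_tsv(rep$counts, file.path(out, "conflict_counts.tsv"))

  flagged_acc <- unique(flags$accession)
  curated <- ok
  if (config$policy == "exclude")
    curated <- ok[!(ok$accession %in% flagged_acc), , drop = FALSE]
  curated_rec <- data.frame(accession = curated$accession,
                            genus = curated$genus, epithet = curated$epithet,
                            qualifier = rep("none", nrow(curated)),
                            parse_error = rep(FALSE, nrow(curated)),
                            seq = curated$oriented_seq,
                            stringsAsFactors = FALSE)
  write_records_fasta(curated_rec, file.path(out, "curated.fasta"))

  say("coverage: profiling %d curated record(s)", nrow(curated))
  cov <- coverage_profile(curated, L)
  .write_tsv(cov, file.path(out, "coverage.tsv"))
  br <- if (config$window <= L && nrow(curated) > 0)
    best_region(cov, config$window) else NULL
  if (!is.null(br))
    .write_tsv(as.data.frame(br), file.path(out, "best_region.tsv"))

  summ <- summarize_taxa(curated_rec, family_map)
  .write_tsv(summ$stats, file.path(out, "summary_statistics.tsv"))
  .write_tsv(summ$per_species, file.path(out, "sequences_per_species.tsv"))
  .write_tsv(summ$per_genus, file.path(out, "species_per_genus.tsv"))

  n_flag_excluded <- if (config$policy == "exclude")
    sum(ok$accession %in% flagged_acc) else 0L
  manifest <- data.frame(
    stage = c("input", "dropped_duplicates", "uncertain_taxonomy",
              "unmappable", "flagged_excluded", "curated"),
    n = c(n_in, nrow(dd$dropped), nrow(part$uncertain), nrow(failed),
          n_flag_excluded, nrow(curated)),
    stringsAsFactors = FALSE)
  .write_tsv(manifest, file.path(out, "manifest.tsv"))

  cfg_dump <- config
  cfg_dump$reference <- if (inherits(config$reference, "reference_locus"))
    config$reference$accession else config$reference
  class(cfg_dump) <- NULL
  yaml::write_yaml(cfg_dump, file.path(out, "config.yaml"))

  say("done: %d in, %d curated, %d flagged", n_in, nrow(curated),
      length(flagged_acc))
  invisible(list(records = rec, dropped = dd$dropped, changelog = changelog,
                 uncertain = part$uncertain, mapped = mapped,
                 alignments = alignments, genus_matrices = genus_matrices,
                 flags = flags, report = rep$report, counts = rep$counts,
                 curated = curated_rec, coverage = cov, best_region = br,
                 summary = summ, manifest = manifest))
}
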