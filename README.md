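# seqcurate

Reproducible curation of public-repository nucleotide records around a
single target locus.

Repositories such as GenBank mix correct records with mislabeled
species, sequences submitted in backward-read orientation, redundant
RefSeq (`NC_`) copies, names under open nomenclature (cf./aff./sp./ssp.)
and frameshift-bearing sequencing artefacts. For heavily sequenced
markers — the package's defaults target mitochondrial cytochrome-b
(Cytb, ~1,140 nt) — these errors are common enough to matter for
phylogenetics, DNA barcoding and conservation genetics. seqcurate turns
the curation of such a corpus into a deterministic, offline pipeline
whose every step can be re-run byte for byte, and whose conflict report
hands the one genuinely human step (deciding *why* a sequence conflicts)
to the reader with the evidence attached.

## The method in brief

Records are parsed and normalised to `Genus_epithet_ACCESSION` labels,
RefSeq duplicates dropped, names reconciled against a user-supplied
synonymy table, and non-binomial records routed to an
uncertain-taxonomy report. Each remaining sequence and its reverse
complement are aligned to a reference locus with an affine-gap aligner
(match +1, mismatch −1, gap run of length *k* costs −4 − *k*, IUPAC
ambiguity codes neutral); the better strand fixes the orientation and
the aligned span extracts the locus, also from whole mitochondrial
genomes (located first by 12-mer seeding). Conspecific sequences are
aligned by a deterministic center-star MSA; internal gap runs whose
length is not a multiple of three are resolved under the vertebrate
mitochondrial code — filled with the column consensus where the column
is uniform, `N` where it is diverse — and ambiguous row ends are
trimmed.

The screen itself uses the uncorrected p-distance *d* (mismatches over
comparable sites, pairwise deletion of gaps/N/ambiguities) and one
threshold *t* (default 3%):

* within a species, accept *d* ≤ *t*; single-linkage clusters at *t*
  flag every member outside the largest cluster;
* within a genus, accept heterospecific *d* > *t*; pairs at *d* ≤ *t*
  flag both members.

Flagged sequences, mapping failures, duplicates and non-binomials form
the conflict report (with empty verdict/rationale/reference columns for
literature review); the curated FASTA excludes them by default.
Coverage profiling then reports, per reference position, sequence and
species counts, the best window of a given length (maximising the
window minimum of species then sequence coverage), and summary
statistics (sequences/species, species/genus, species/family, medians
with interpolated quartiles).

A seeded generator (`simulate_records()`) produces repository-like test
corpora with planted errors of every class and a truth table, so recall
and precision of each stage are measurable exactly.

## Worked example

```r
library(seqcurate)
ref <- synthetic_reference()      # 1,140-nt deterministic stand-in reference
cfg <- synthetic_config(seed = 7, n_genera = 4, species_per_genus = 2,
                        seqs_per_species = 4,
                        planted = list(misidentified = 2, revcomp = 2,
                                       refseq_duplicate = 1, non_binomial = 1))
sim <- simulate_records(cfg, ref, dir = "example_in")
res <- run_pipeline(pipeline_config("example_in/records.fasta", ref,
                                    out_dir = "example_out"))
res$manifest
#>                stage  n
#> 1              input 33
#> 2 dropped_duplicates  1
#> 3 uncertain_taxonomy  1
#> 4         unmappable  0
#> 5   flagged_excluded  2
#> 6            curated 29
res$flags[, c("label", "species", "category", "partner", "d")]
#>                         label            species                category
#> 1 Babagena_babaensis_SY000017 Babagena babaensis intraspecific_divergent
#> 2 Babagena_cebaensis_SY000011 Babagena cebaensis intraspecific_divergent
#>                       partner         d
#> 1 Babagena_babaensis_SY000001 0.1666667
#> 2 Babagena_cebaensis_SY000005 0.1766784
```

The 33 inputs (32 records + 1 RefSeq twin) reconcile exactly: the twin
is dropped, the open-nomenclature record goes to the uncertain report,
both planted reverse complements are silently re-oriented (see
`example_out/orientation.tsv`), and the two records the generator
mislabeled — and only those — are flagged: each sits ~17% from its
nearest supposed conspecific, far beyond the 3% threshold. The curated
set keeps the remaining 29 sequences. `example_out/` holds one artifact
per stage (curated FASTA, orientation table, per-species alignments,
per-genus distance tables, conflict report, coverage profile, summary
statistics, manifest, and the serialised configuration).

A command-line front end with the same capabilities ships in
`inst/scripts/seqcurate.R` (subcommands `curate` and `simulate`).

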