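#!/usr/bin/env Rscript
# Simulate the synthetic study cohort: a 20-gene toy genome with one planted
# alternative-splicing event per gene, bulk junction counts for 10 tumor and
# 10 normal samples, single-cell reads over five cell types, a peptide
# database seeded with the planted junction peptides, and patient HLA
# serotypes. Everything is written under results/cohort/ so later stages
# can run from files alone.

library(neosplice)

cfg <- sim_config(seed = 20260930L)
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ann <- generate_reference(cfg)
write_cohort(ann, out)
message("reference: ", length(ann$genome), " contigs, ",
        nrow(ann$events), " planted events (",
        sum(ann$events$tumor_only), " tumor-only)")

counts <- simulate_junction_counts(cfg, ann)
write_junction_counts(counts, file.path(out, "junction_counts.tsv"))
message("bulk counts: ", nrow(counts), " junctions x ",
        ncol(counts) - 1, " samples")

sc <- simulate_sc_reads(cfg, ann)
write_fastq_reads(sc$reads, file.path(out, "sc_reads.fastq"))
write_tsv(sc$cells, file.path(out, "cells.tsv"))
message("single cell: ", nrow(sc$reads), " reads over ",
        nrow(sc$cells), " cells")

db <- simulate_peptide_db(cfg, ann)
writeLines(db, file.path(out, "peptide_db.txt"))
sero <- simulate_serotypes(cfg)
write_tsv(sero, file.path(out, "serotypes.tsv"))
message("peptide db: ", length(db), " entries; serotypes for ",
        length(unique(sero$patient_id)), " patients")
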