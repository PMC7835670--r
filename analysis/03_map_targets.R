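#!/usr/bin/env Rscript
# Project tumor-specific neojunctions onto protein space and screen them in
# the single-cell compartment. A junction is CAR-relevant when it lands in
# an extracellular domain of a cell-surface protein and its junction
# sequence is seen in neoplastic cells but in zero glia/immune/endothelial
# cells. Writes results/targets/.

library(neosplice)

cohort <- "results/cohort"
out <- "results/targets"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ann <- read_cohort(cohort)
calls <- read_tsv("results/quant/junction_calls.tsv")
candidates <- calls$junction_id[calls$passes]
message(length(candidates), " tumor-specific candidates")

reps <- representative_transcripts(ann)
jt <- ann$junctions
loci <- do.call(rbind, lapply(candidates, function(jid) {
  p <- parse_junction_id(jid)
  gene <- jt$gene_id[match(jid, jt$junction_id)]
  loc <- junction_protein_locus(list(junction_id = jid, donor = p$donor,
                                     acceptor = p$acceptor),
                                reps[[gene]], ann$domains)
  data.frame(junction_id = jid, gene_id = gene, status = loc$status,
             aa_position = loc$aa_position, domain_label = loc$domain_label,
             is_surface_protein = loc$is_surface_protein)
}))
write_tsv(loci, file.path(out, "protein_loci.tsv"))
surf <- loci[loci$is_surface_protein, ]
message(nrow(surf), " on surface proteins; ",
        sum(surf$domain_label == "extracellular"), " extracellular (",
        sprintf("%.1f%%", 100 * mean(surf$domain_label == "extracellular")), ")")

# single-cell specificity screen against 600-nt junction references
reads <- read_fastq_reads(file.path(cohort, "sc_reads.fastq"))
cells <- read_tsv(file.path(cohort, "cells.tsv"))
refs <- junction_references(ann, candidates, flank = 300)
mat <- match_sc_reads(reads, refs, cells, min_overhang = 10)
write_cell_junction_matrix(mat, file.path(out, "cell_junction"))
freq <- cell_type_frequencies(mat)
write_tsv(freq, file.path(out, "cell_type_frequencies.tsv"))

specific <- vapply(candidates, neoplastic_specific, TRUE, frequencies = freq)
stem <- vapply(candidates, stem_enrichment, 0, frequencies = freq)
screen <- data.frame(junction_id = candidates,
                     neoplastic_specific = specific,
                     stem_enrichment = stem)
write_tsv(screen, file.path(out, "sc_screen.tsv"))
message(sum(specific), " junctions are neoplastic-specific in the ",
        "single-cell screen")

shortlist <- merge(loci, screen, by = "junction_id")
shortlist$car_shortlisted <- shortlist$is_surface_protein &
  shortlist$domain_label == "extracellular" & shortlist$neoplastic_specific
write_tsv(shortlist, file.path(out, "car_shortlist.tsv"))
message(sum(shortlist$car_shortlisted), " junction(s) shortlisted as CAR targets")
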