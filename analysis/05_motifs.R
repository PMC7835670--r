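#!/usr/bin/env Rscript
# Scan differentially spliced genes for RNA-binding-protein motifs (toy PWM
# set bundled with the package), summarize hits by gene region and motif,
# and measure motif enrichment in the alternatively spliced exon of the
# top differential gene — the splicing-factor analysis mirrored on
# synthetic data. Writes results/motifs/.

library(neosplice)

cohort <- "results/cohort"
out <- "results/motifs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ann <- read_cohort(cohort)
dpsi <- read_tsv("results/quant/dpsi.tsv")
jt <- ann$junctions
sig_genes <- unique(jt$gene_id[jt$junction_id %in%
                                 dpsi$junction_id[dpsi$significant]])
message(length(sig_genes), " differentially spliced genes to scan")

motifs <- read_pwms(system.file("extdata", "toy_motifs.txt",
                                package = "neosplice"))
hits <- do.call(rbind, lapply(sig_genes, function(g)
  scan_gene(ann, g, motifs)))
write_hits_bed(hits, file.path(out, "motif_hits.bed"))

s <- summarize_motif_hits(hits)
write_tsv(data.frame(region = names(s$region_distribution),
                     fraction = as.numeric(s$region_distribution)),
          file.path(out, "region_distribution.tsv"))
write_tsv(s$motif_ranking, file.path(out, "motif_ranking.tsv"))
message("region distribution: ",
        paste(sprintf("%s %.2f", names(s$region_distribution),
                      s$region_distribution), collapse = ", "))
message("top motif by genes hit: ", s$motif_ranking$rbp_name[1])

# enrichment of the top motif in the alternatively spliced (cassette) exon
# of the first significant cassette gene
ev <- ann$events
cass <- ev[ev$gene_id %in% sig_genes & ev$kind == "cassette", ]
if (nrow(cass) > 0) {
  g <- cass$gene_id[1]
  # the cassette exon: in the reference isoform but not the alt isoform
  ex1 <- ann$transcripts[[cass$transcript_ref[1]]]$exons
  ex2 <- ann$transcripts[[cass$transcript_alt[1]]]$exons
  skip <- ex1[!paste(ex1$start, ex1$end) %in% paste(ex2$start, ex2$end), ][1, ]
  top <- motifs[[s$motif_ranking$motif_id[1]]]
  enr <- exon_motif_enrichment(ann, g, skip$start, skip$end, top)
  message(sprintf("%s enrichment in the cassette exon of %s: %.2f",
                  top$rbp_name, g,
                  ifelse(is.na(enr$enrichment), NA, enr$enrichment)))
  write_tsv(data.frame(gene_id = g, motif = top$motif_id,
                       exon_density = enr$exon_density,
                       gene_density = enr$gene_density,
                       enrichment = enr$enrichment),
            file.path(out, "cassette_exon_enrichment.tsv"))
}
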