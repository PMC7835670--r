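#!/usr/bin/env Rscript
# Derive junction-spanning peptides for the tumor-specific candidates,
# confirm them against the peptide database with reversed-decoy FDR 0.05,
# and enumerate HLA class-I neoantigen candidates (8-11-mers) filtered to
# strong binders (percent rank < 0.5) per patient serotype through the
# deterministic mock predictor. Writes results/immuno/.

library(neosplice)

cohort <- "results/cohort"
out <- "results/immuno"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ann <- read_cohort(cohort)
calls <- read_tsv("results/quant/junction_calls.tsv")
candidates <- calls$junction_id[calls$passes]
reps <- representative_transcripts(ann)
jt <- ann$junctions

window_of <- function(jid, flank) {
  p <- parse_junction_id(jid)
  gene <- jt$gene_id[match(jid, jt$junction_id)]
  junction_window(ann$genome, reps[[gene]],
                  list(junction_id = jid, donor = p$donor,
                       acceptor = p$acceptor), flank)
}

# --- 48-nt windows -> 3-frame peptides -> decoy-FDR confirmation ---------
peps <- do.call(rbind, lapply(candidates, function(jid) {
  w <- window_of(jid, 24)
  if (w$status != "ok") return(NULL)
  np <- derive_neopeptides(w)
  if (nrow(np$peptides) == 0) return(NULL)
  cbind(junction_id = jid, np$peptides)
}))
write_windows_fasta(peps, file.path(out, "neopeptides.fa"))
db <- read_peptide_db(file.path(cohort, "peptide_db.txt"))
conf <- confirm_peptides(peps, db, fdr_threshold = 0.05, seed = 1)
write_tsv(conf, file.path(out, "confirmations.tsv"))
message(sum(conf$passes_fdr), " of ", nrow(conf),
        " peptides confirmed at decoy FDR <= 0.05 (estimate ",
        sprintf("%.3f", attr(conf, "fdr_estimate")), ")")

counts <- read_junction_counts(file.path(cohort, "junction_counts.tsv"))
cc <- per_case_confirmations(conf, counts, grep("^tumor", names(counts), value = TRUE))
message(sprintf("%.0f%% of cases express >= 1 confirmed neojunction; %.1f per case",
                100 * cc$fraction_cases_confirmed, cc$mean_confirmed_per_case))
write_tsv(data.frame(fraction_cases_confirmed = cc$fraction_cases_confirmed,
                     mean_confirmed_per_case = cc$mean_confirmed_per_case),
          file.path(out, "per_case_confirmations.tsv"))

# --- 50-nt windows -> candidate 8-11-mers -> strong binders per patient --
cand <- do.call(rbind, lapply(candidates, function(jid) {
  w <- window_of(jid, 25)
  if (w$status != "ok") return(NULL)
  enumerate_candidates(w)
}))
sero <- read_serotypes(file.path(cohort, "serotypes.tsv"))
strong <- filter_strong_binders(cand, sero, mock_binding_predictor(),
                                threshold = 0.5, background_size = 10000,
                                seed = 1)
write_tsv(strong, file.path(out, "neoantigens.tsv"))
message(nrow(strong), " strong-binder neoantigen records across ",
        length(unique(strong$patient_id)), " patients (",
        length(unique(strong$peptide)), " distinct peptides)")
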