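test_that("generation is fully deterministic under a fixed seed", {
  cfg <- tiny_config(seed = 42)
  a1 <- generate_reference(cfg)
  a2 <- generate_reference(cfg)
  expect_identical(a1$genome, a2$genome)
  expect_identical(a1$events, a2$events)
  expect_identical(simulate_junction_counts(cfg, a1),
                   simulate_junction_counts(cfg, a2))
  expect_identical(simulate_sc_reads(cfg, a1), simulate_sc_reads(cfg, a2))
  expect_identical(simulate_peptide_db(cfg, a1), simulate_peptide_db(cfg, a2))
  expect_identical(simulate_serotypes(cfg), simulate_serotypes(cfg))
  a3 <- generate_reference(tiny_config(seed = 43))
  expect_false(identical(a1$genome, a3$genome))
})

test_that("generated gene models satisfy the construction invariants", {
  ann <- generate_reference(tiny_config(seed = 5, n_genes = 10))
  for (tx in ann$transcripts) {
    # intervals within contig bounds, half-open, non-overlapping
    L <- nchar(ann$genome[[tx$contig]])
    expect_true(all(tx$exons$start >= 0 & tx$exons$end <= L))
    expect_true(all(tx$exons$start < tx$exons$end))
    if (nrow(tx$cds) > 0) {
      cds_len <- sum(tx$cds$end - tx$cds$start)
      expect_identical(cds_len %% 3L, 0L)
      span <- neosplice:::cds_transcript_span(tx)
      s <- spliced_seq(tx, ann$genome)
      cds_seq <- substr(s, span["t_start"] + 1, span["t_start"] + span["length"])
      aa <- oracle_translate(cds_seq, 0)
      expect_identical(substr(aa, 1, 1), "M")
      expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
      expect_false(grepl("[*]", substr(aa, 1, nchar(aa) - 1)))
    }
  }
})

test_that("minus-strand transcript exon order reverses genomic order", {
  ann <- generate_reference(tiny_config(seed = 8, n_genes = 10))
  minus <- Filter(function(tx) tx$strand == "-", ann$transcripts)
  expect_gt(length(minus), 0)
  tx <- minus[[1]]
  # first transcript base must be the genomically-last exonic base
  expect_identical(genomic_to_transcript(tx, max(tx$exons$end) - 1L)$offset, 0L)
  # and exon order in transcript coordinates is the reverse of genomic order
  first_of_each <- vapply(rev(seq_len(nrow(tx$exons))), function(i)
    genomic_to_transcript(tx, tx$exons$end[i] - 1L)$offset, 1L)
  expect_identical(first_of_each, sort(first_of_each))
})

test_that("surface-protein domain partitions cover every residue exactly once", {
  ann <- generate_reference(tiny_config(seed = 3, n_genes = 12))
  for (pid in unique(ann$domains$protein_id)) {
    d <- ann$domains[ann$domains$protein_id == pid, ]
    tx <- Filter(function(t) identical(t$protein_id, pid), ann$transcripts)[[1]]
    n_aa <- sum(tx$cds$end - tx$cds$start) / 3 - 1  # minus stop codon
    cover <- integer(n_aa)
    for (k in seq_len(nrow(d))) {
      cover[d$aa_start[k]:d$aa_end[k]] <- cover[d$aa_start[k]:d$aa_end[k]] + 1L
    }
    expect_true(all(cover == 1L))
  }
})

test_that("junction counts follow the planted PSI truth", {
  # degenerate truth 1/0: the alternative junction gets zero reads anywhere
  ev <- plant_events(2, n_tumor_only = 1, seed = 1)
  ev$psi_tumor <- c(0, 0.5); ev$psi_normal <- c(0, 0.5)
  ev$tumor_only <- c(FALSE, FALSE)
  cfg <- tiny_config(seed = 2, n_genes = 2, events = ev)
  ann <- generate_reference(cfg)
  counts <- simulate_junction_counts(cfg, ann)
  alt1 <- counts[counts$junction_id == ann$events$junction_id[1], -1]
  expect_true(all(alt1 == 0))

  # pooled empirical PSI concentrates on the truth (law of large numbers)
  ev2 <- plant_events(1, n_tumor_only = 1, seed = 1)
  ev2$tumor_only <- FALSE
  ev2$psi_tumor <- 0.5; ev2$psi_normal <- 0.5
  cfg2 <- sim_config(seed = 9, n_genes = 1, n_tumor_samples = 25,
                     n_normal_samples = 25, mean_lsv_coverage = 10000,
                     psi_concentration = 1e6, events = ev2)
  ann2 <- generate_reference(cfg2)
  c2 <- simulate_junction_counts(cfg2, ann2)
  alt <- sum(c2[c2$junction_id == ann2$events$junction_id[1], -1])
  ref <- sum(c2[c2$junction_id == ann2$events$ref_junction_id[1], -1])
  expect_lt(abs(alt / (alt + ref) - 0.5), 0.05)

  # tumor-only planting: column sums over normal samples are exactly zero
  cfg3 <- tiny_config(seed = 21, n_genes = 10)
  ann3 <- generate_reference(cfg3)
  c3 <- simulate_junction_counts(cfg3, ann3)
  planted <- ann3$events[ann3$events$tumor_only, ]
  expect_gt(nrow(planted), 0)
  norm_cols <- grep("^normal", names(c3), value = TRUE)
  for (j in planted$junction_id) {
    expect_identical(sum(c3[c3$junction_id == j, norm_cols]), 0L)
  }
})

test_that("count simulation rejects a non-positive concentration", {
  expect_error(sim_config(psi_concentration = 0), "concentration")
  expect_error(sim_config(psi_concentration = -2), "concentration")
})

test_that("single-cell reads are exact substrings of spliced transcripts", {
  cfg <- tiny_config(seed = 13, n_genes = 5)
  ann <- generate_reference(cfg)
  sc <- simulate_sc_reads(cfg, ann)
  spliced <- vapply(ann$transcripts, spliced_seq, "", genome = ann$genome)
  found <- vapply(sc$reads$sequence, function(s)
    any(vapply(spliced, function(t) grepl(s, t, fixed = TRUE), TRUE)),
    TRUE, USE.NAMES = FALSE)
  expect_true(all(found))
  expect_true(all(sc$reads$barcode %in% sc$cells$barcode))
  expect_true(all(sc$cells$cell_type %in%
                    c("neoplastic-stem", "neoplastic-differentiated",
                      "glia", "immune", "endothelial")))
})

test_that("neoplastic-only junction reads never carry a non-malignant barcode", {
  cfg <- tiny_config(seed = 17, n_genes = 8)
  ann <- generate_reference(cfg)
  sc <- simulate_sc_reads(cfg, ann)
  nonmal <- sc$cells$barcode[sc$cells$cell_type %in%
                               c("glia", "immune", "endothelial")]
  planted <- ann$events[ann$events$neoplastic_only, ]
  expect_gt(nrow(planted), 0)
  for (i in seq_len(nrow(planted))) {
    tx2 <- ann$transcripts[[planted$transcript_alt[i]]]
    s2 <- spliced_seq(tx2, ann$genome)
    jp <- parse_junction_id(planted$junction_id[i])
    pos <- neosplice:::junction_transcript_pos(tx2, jp$donor, jp$acceptor)
    # the junction-crossing 20-mer is unique to the alternative isoform
    probe <- substr(s2, pos$t_down - 9, pos$t_down + 10)
    carriers <- sc$reads$barcode[grepl(probe, sc$reads$sequence, fixed = TRUE)]
    expect_length(intersect(carriers, nonmal), 0)
  }
})

test_that("peptide database contains planted peptides and excludes the rest", {
  cfg <- tiny_config(seed = 23, n_genes = 10)
  ann <- generate_reference(cfg)
  db <- simulate_peptide_db(cfg, ann)
  ev <- ann$events
  reps <- representative_transcripts(ann)
  peps_of <- function(i) {
    jp <- parse_junction_id(ev$junction_id[i])
    w <- junction_window(ann$genome, reps[[ev$gene_id[i]]],
                         list(junction_id = ev$junction_id[i],
                              donor = jp$donor, acceptor = jp$acceptor), 24)
    derive_neopeptides(w)$peptides$peptide
  }
  expect_gt(sum(ev$in_peptide_db), 0)
  for (i in which(ev$in_peptide_db)) {
    expect_true(all(peps_of(i) %in% db))
  }
  for (i in which(!ev$in_peptide_db)) {
    expect_false(any(peps_of(i) %in% db))
  }
})

test_that("a cohort written to disk reloads equal (round trip)", {
  cfg <- tiny_config(seed = 31, n_genes = 6)
  ann <- generate_reference(cfg)
  dir <- withr::local_tempdir()
  write_cohort(ann, dir)
  back <- read_cohort(dir)
  expect_identical(back$genome, ann$genome)
  expect_identical(names(back$transcripts), names(ann$transcripts))
  for (tid in names(ann$transcripts)) {
    a <- ann$transcripts[[tid]]; b <- back$transcripts[[tid]]
    expect_identical(b$exons$start, a$exons$start)
    expect_identical(b$exons$end, a$exons$end)
    expect_identical(b$cds$start, a$cds$start)
    expect_identical(b$cds$end, a$cds$end)
    expect_identical(b$strand, a$strand)
    expect_identical(b$protein_id, a$protein_id)
  }
  expect_equal(back$domains, ann$domains)
  expect_equal(back$events, ann$events, tolerance = 1e-12)

  counts <- simulate_junction_counts(cfg, ann)
  p <- file.path(dir, "counts.tsv")
  write_junction_counts(counts, p)
  expect_equal(read_junction_counts(p), counts)

  sc <- simulate_sc_reads(cfg, ann)
  fq <- file.path(dir, "reads.fastq")
  write_fastq_reads(sc$reads, fq)
  expect_identical(read_fastq_reads(fq), sc$reads)
})
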