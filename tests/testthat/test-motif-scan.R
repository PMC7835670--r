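consensus_of <- function(motif) {
  paste(c("A", "C", "G", "T")[apply(motif$pwm, 2, which.max)], collapse = "")
}

test_that("PWM scanning scores log-odds with the expected extremes", {
  motifs <- read_pwms(system.file("extdata", "toy_motifs.txt",
                                  package = "neosplice"))
  expect_length(motifs, 4)
  for (m in motifs) expect_true(all(abs(colSums(m$pwm) - 1) < 1e-9))

  m <- motifs[[1]]
  cons <- consensus_of(m)
  sc <- scan_pwm(cons, m)
  expect_equal(sc$score[1], m$max_score, tolerance = 1e-9)
  expect_true(sc$hit[1])

  # uniform PWM equal to background: all scores are exactly 0
  uni <- motif_model("uni", "uni", matrix(0.25, 4, 5))
  sc0 <- scan_pwm(paste(rep("ACGT", 10), collapse = ""), uni)
  expect_true(all(abs(sc0$score) < 1e-12))

  # ambiguous bases contribute zero
  scn <- scan_pwm(paste0("NN", cons, "NN"), m)
  expect_equal(scn$score[3], m$max_score, tolerance = 1e-9)
})

test_that("scanning agrees with a brute-force rescoring oracle", {
  motifs <- read_pwms(system.file("extdata", "toy_motifs.txt",
                                  package = "neosplice"))
  withr::with_seed(41, {
    for (rep in 1:5) {
      seq <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
      m <- motifs[[sample(length(motifs), 1)]]
      sc <- scan_pwm(seq, m)
      W <- ncol(m$pwm)
      oracle <- vapply(seq_len(nchar(seq) - W + 1), function(off) {
        tot <- 0
        for (i in seq_len(W)) {
          b <- substr(seq, off + i - 1, off + i - 1)
          tot <- tot + log2(m$pwm[b, i] / m$background[match(b, c("A", "C", "G", "T"))])
        }
        tot
      }, 0)
      expect_equal(sc$score, oracle, tolerance = 1e-9)
      expect_identical(sc$hit, oracle >= m$score_threshold)
    }
  })
})

test_that("concatenating two PWMs adds their scores at aligned offsets", {
  withr::with_seed(43, {
    p1 <- matrix(stats::runif(4 * 3) + 0.1, 4)
    p2 <- matrix(stats::runif(4 * 4) + 0.1, 4)
    m1 <- motif_model("m1", "m1", p1)
    m2 <- motif_model("m2", "m2", p2)
    m12 <- motif_model("m12", "m12", cbind(m1$pwm, m2$pwm))
    seq <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    s1 <- scan_pwm(seq, m1)$score
    s2 <- scan_pwm(seq, m2)$score
    s12 <- scan_pwm(seq, m12)$score
    for (off in seq_along(s12)) {
      expect_equal(s12[off], s1[off] + s2[off + 3], tolerance = 1e-9)
    }
  })
})

test_that("hit summaries rank motifs by genes then hits", {
  hits <- data.frame(
    motif_id = c("mA", "mA", "mA", "mB"),
    rbp_name = c("A", "A", "A", "B"),
    gene_id = c("g1", "g2", "g3", "g1"),
    contig = "c", start = 0L, end = 6L, strand = "+", score = 5,
    region_class = c("CDS", "CDS", "CDS", "CDS"))
  s <- summarize_motif_hits(hits)
  expect_equal(unname(s$region_distribution["CDS"]), 1)
  expect_identical(s$motif_ranking$motif_id, c("mA", "mB"))
  expect_equal(sum(s$region_distribution), 1)
})

test_that("gene scanning maps hits to genomic coordinates with region classes", {
  ann <- generate_reference(tiny_config(seed = 47, n_genes = 4))
  motifs <- read_pwms(system.file("extdata", "toy_motifs.txt",
                                  package = "neosplice"))
  # plant the consensus of motif 1 inside a CDS exon of gene 1
  tx <- representative_transcripts(ann)[["GENE001"]]
  cons <- consensus_of(motifs[[1]])
  big <- tx$cds[which.max(tx$cds$end - tx$cds$start), ]
  pos <- big$start + 5L
  contig <- ann$genome[[tx$contig]]
  planted <- if (tx$strand == "+") cons else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  substr(contig, pos + 1L, pos + nchar(cons)) <- planted
  ann$genome[[tx$contig]] <- contig
  hits <- scan_gene(ann, "GENE001", motifs[1])
  hit <- hits[hits$start == pos, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$region_class, "CDS")
  expect_equal(hit$score, motifs[[1]]$max_score, tolerance = 1e-9)
})

test_that("exon enrichment reflects hit placement", {
  ann <- generate_reference(tiny_config(seed = 53, n_genes = 3))
  tx <- representative_transcripts(ann)[["GENE002"]]
  g <- ann$genes[ann$genes$gene_id == "GENE002", ]
  motifs <- read_pwms(system.file("extdata", "toy_motifs.txt",
                                  package = "neosplice"))
  m <- motifs[[2]]
  cons <- consensus_of(m)
  # plant hits only inside one exon -> enrichment equals length ratio
  ex <- tx$exons[which.max(tx$exons$end - tx$exons$start), ]
  contig <- ann$genome[[tx$contig]]
  planted <- if (tx$strand == "+") cons else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  p1 <- ex$start + 3L
  substr(contig, p1 + 1L, p1 + nchar(cons)) <- planted
  ann$genome[[tx$contig]] <- contig
  r <- exon_motif_enrichment(ann, "GENE002", ex$start, ex$end, m)
  if (r$gene_density > 0 && r$exon_density > 0 &&
      sum(scan_gene(ann, "GENE002", list(m), mode = "premrna")$start >= ex$start) ==
      nrow(scan_gene(ann, "GENE002", list(m), mode = "premrna"))) {
    expect_equal(r$enrichment, (g$end - g$start) / (ex$end - ex$start),
                 tolerance = 1e-9)
  }
  # an all-background motif hits everywhere (threshold 0): enrichment ~ 1
  uni <- motif_model("uni", "uni", matrix(0.25, 4, 4))
  r2 <- exon_motif_enrichment(ann, "GENE002", ex$start, ex$end, uni)
  expect_lt(abs(r2$enrichment - 1), 0.15)
  # a motif that can never hit: no hits anywhere -> undefined
  never <- motif_model("never", "never", matrix(0.25, 4, 4),
                       score_threshold = 999)
  r3 <- exon_motif_enrichment(ann, "GENE002", ex$start, ex$end, never)
  expect_true(is.na(r3$enrichment))
})
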