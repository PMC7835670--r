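test_that("junction windows take spliced flanks in coding orientation", {
  # upstream exon ends ...ATGGCC | downstream begins AAATGA...
  genome <- c(c1 = paste0(strrep("G", 10), "ATGGCC", strrep("T", 20),
                          "AAATGA", strrep("C", 10)))
  exons <- data.frame(start = c(10L, 36L), end = c(16L, 42L))
  tx <- transcript_model("t", "g", "c1", "+", exons)
  w <- junction_window(genome, tx, list(donor = 16L, acceptor = 36L), flank = 3)
  expect_identical(w$sequence, "GCCAAA")
  expect_identical(w$midpoint, 3L)

  # truncation at transcript ends is recorded
  w2 <- junction_window(genome, tx, list(donor = 16L, acceptor = 36L), flank = 300)
  expect_identical(w2$actual_left, 6L)
  expect_identical(w2$actual_right, 6L)
  expect_identical(nchar(w2$sequence), w2$actual_left + w2$actual_right)

  # incompatible junction gives a typed result
  w3 <- junction_window(genome, tx, list(donor = 5L, acceptor = 36L), flank = 3)
  expect_identical(w3$status, "incompatible")
})

test_that("windows of event junctions occur verbatim in the alternative isoform", {
  ann <- generate_reference(tiny_config(seed = 91, n_genes = 10))
  reps <- representative_transcripts(ann)
  ev <- ann$events
  for (i in seq_len(nrow(ev))) {
    p <- parse_junction_id(ev$junction_id[i])
    w <- junction_window(ann$genome, reps[[ev$gene_id[i]]],
                         list(donor = p$donor, acceptor = p$acceptor), 24)
    expect_identical(w$status, "ok")
    alt_seq <- spliced_seq(ann$transcripts[[ev$transcript_alt[i]]], ann$genome)
    expect_true(grepl(w$sequence, alt_seq, fixed = TRUE))
  }
})

test_that("neopeptide derivation translates three frames and enforces the span rule", {
  # frame 0 of "ATGAAA|TTTTAG" -> MKF then stop
  w <- list(status = "ok", junction_id = "j", flank = 6L,
            sequence = "ATGAAATTTTAG", actual_left = 6L, actual_right = 6L,
            midpoint = 6L)
  np <- derive_neopeptides(w)
  f0 <- np$peptides[np$peptides$frame == 0, ]
  expect_identical(f0$peptide, "MKF")

  # a stop immediately before the midpoint blocks that frame
  w2 <- list(status = "ok", junction_id = "j", flank = 6L,
             sequence = "ATGTAATTTAAA", actual_left = 6L, actual_right = 6L,
             midpoint = 6L)
  np2 <- derive_neopeptides(w2)
  expect_false(0 %in% np2$peptides$frame)

  # all retained peptides span the junction and carry no stop
  expect_true(all(np$peptides$spans_junction))
  expect_false(any(grepl("[*]", np$peptides$peptide)))
})

test_that("three-frame derivation agrees with a brute-force oracle on random windows", {
  ann <- generate_reference(tiny_config(seed = 95, n_genes = 12))
  reps <- representative_transcripts(ann)
  jt <- ann$junctions
  n_checked <- 0L
  for (i in seq_len(nrow(jt))) {
    p <- jt[i, ]
    w <- junction_window(ann$genome, reps[[p$gene_id]],
                         list(donor = p$donor, acceptor = p$acceptor), 24)
    if (w$status != "ok") next
    np <- derive_neopeptides(w)
    # oracle: literal per-frame translation, split on stops, span check
    expected <- character(0)
    for (frame in 0:2) {
      aa <- oracle_translate(w$sequence, frame)
      if (nchar(aa) == 0) next
      pieces <- strsplit(aa, "*", fixed = TRUE)[[1]]
      idx <- 1
      for (pc in pieces) {
        if (nchar(pc) > 0) {
          nt_start <- frame + 3 * (idx - 1)
          nt_end <- nt_start + 3 * nchar(pc)
          if (nt_start < w$midpoint && nt_end > w$midpoint) {
            expected <- c(expected, pc)
          }
        }
        idx <- idx + nchar(pc) + 1
      }
    }
    expect_setequal(np$peptides$peptide, expected)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 30L)
})

test_that("peptide confirmation applies the decoy FDR rule", {
  # database contains the peptide; reversed decoy misses -> pass
  res <- confirm_peptides(data.frame(junction_id = "j1", peptide = "MKVLW"),
                          peptide_db = c("MKVLW", "AAAAA"))
  expect_true(res$matched)
  expect_false(res$decoy_hit)
  expect_true(res$passes_fdr)

  # decoys hit but no targets -> nothing passes
  res2 <- confirm_peptides(data.frame(junction_id = "j1", peptide = "MKVLW"),
                           peptide_db = c("WLVKM"))
  expect_false(res2$matched)
  expect_false(res2$passes_fdr)
  expect_true(res2$decoy_hit)

  # planted cohort: 10 true peptides in db among 100 queries
  withr::with_seed(5, {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    mk <- function(n) vapply(seq_len(n), function(i)
      paste(sample(aa, 9, replace = TRUE), collapse = ""), "")
    true_p <- mk(10); absent <- mk(90)
    q <- data.frame(junction_id = sprintf("j%03d", 1:100),
                    peptide = c(true_p, absent))
    res3 <- confirm_peptides(q, peptide_db = c(true_p, mk(50)))
    expect_setequal(res3$peptide[res3$passes_fdr], true_p)
  })

  expect_error(confirm_peptides(data.frame(junction_id = "j", peptide = "MK"),
                                character(0)), "non-empty")
})

test_that("in-frame windows translate consistently with the full protein", {
  # frame-0 peptide of an in-frame coding window is a substring of the
  # protein translated from the full spliced CDS of the alternative isoform
  ann <- generate_reference(tiny_config(seed = 97, n_genes = 10))
  ev <- ann$events
  reps <- representative_transcripts(ann)
  checked <- 0L
  for (i in which(ev$surface & ev$kind == "cassette")) {
    tx2 <- ann$transcripts[[ev$transcript_alt[i]]]
    if (nrow(tx2$cds) == 0) next
    span <- neosplice:::cds_transcript_span(tx2)
    s2 <- spliced_seq(tx2, ann$genome)
    protein <- oracle_translate(substr(s2, span["t_start"] + 1,
                                       span["t_start"] + span["length"]), 0)
    p <- parse_junction_id(ev$junction_id[i])
    w <- junction_window(ann$genome, reps[[ev$gene_id[i]]],
                         list(donor = p$donor, acceptor = p$acceptor), 24)
    np <- derive_neopeptides(w)
    # the cassette is a multiple of 3 inside the CDS, so one frame is in
    # frame with the protein; at least one peptide must appear in it
    expect_true(any(vapply(np$peptides$peptide, function(pep)
      grepl(pep, protein, fixed = TRUE), TRUE)))
    checked <- checked + 1L
  }
  expect_gte(checked, 3L)
})

test_that("per-case confirmation summary matches direct counting", {
  counts <- data.frame(junction_id = c("j1", "j2", "j3"),
                       tumor01 = c(5L, 0L, 2L), tumor02 = c(0L, 0L, 0L),
                       tumor03 = c(1L, 1L, 0L))
  conf <- data.frame(junction_id = c("j1", "j2", "j3"),
                     peptide = c("A", "B", "C"),
                     matched = c(TRUE, TRUE, FALSE),
                     decoy_hit = FALSE,
                     passes_fdr = c(TRUE, TRUE, FALSE))
  s <- per_case_confirmations(conf, counts, c("tumor01", "tumor02", "tumor03"))
  # confirmed junctions are j1, j2; cases with >= 1: tumor01 (j1), tumor03 (both)
  expect_equal(s$fraction_cases_confirmed, 2 / 3)
  expect_equal(s$mean_confirmed_per_case, (1 + 0 + 2) / 3)
})
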