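# Independent brute-force oracles used across tests. These deliberately take
# the slow, literal route (per-base walks, codon-by-codon translation,
# exhaustive scans) so they share no code path with the implementation.

CODON_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(sapply(bases, function(b1)
    sapply(bases, function(b2) paste0(b1, b2, bases))))
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aas, codons)
})

# codon-by-codon translation, independent of Biostrings
oracle_translate <- function(seq, frame = 0) {
  seq <- toupper(seq)
  out <- character(0)
  i <- frame + 1
  while (i + 2 <= nchar(seq)) {
    cod <- substr(seq, i, i + 2)
    aa <- CODON_TABLE[[cod]]
    out <- c(out, if (is.null(aa) || is.na(aa)) "X" else aa)
    i <- i + 3
  }
  paste(out, collapse = "")
}

# per-base exon walk: transcript offset of a genomic position
oracle_offset <- function(tx, gpos) {
  positions <- integer(0)
  for (i in seq_len(nrow(tx$exons))) {
    positions <- c(positions, tx$exons$start[i]:(tx$exons$end[i] - 1))
  }
  if (tx$strand == "-") positions <- rev(positions)
  w <- which(positions == gpos)
  if (length(w) == 0) NA_integer_ else w - 1L
}

# full-CDS translation oracle: residue index of the first coding base at or
# after the acceptor side of a junction, walking bases one by one
oracle_locus <- function(ann, tx, donor, acceptor, domains) {
  gpos <- integer(0)
  for (i in seq_len(nrow(tx$exons))) {
    gpos <- c(gpos, tx$exons$start[i]:(tx$exons$end[i] - 1))
  }
  if (tx$strand == "-") gpos <- rev(gpos)
  in_cds <- vapply(gpos, function(p)
    any(tx$cds$start <= p & tx$cds$end > p), TRUE)
  if (!any(in_cds)) return(list(domain_label = "noncoding", aa = NA_integer_))
  acc_base <- if (tx$strand == "+") acceptor else donor - 1L
  t_down <- which(gpos == acc_base)
  if (length(t_down) == 0) return(list(domain_label = NA_character_, aa = NA_integer_))
  cds_idx <- which(in_cds)
  if (t_down < min(cds_idx)) return(list(domain_label = "UTR5", aa = NA_integer_))
  if (t_down > max(cds_idx)) return(list(domain_label = "UTR3", aa = NA_integer_))
  aa <- ceiling(which(cds_idx == t_down) / 3)
  lab <- NA_character_
  d <- domains[domains$protein_id == tx$protein_id, , drop = FALSE]
  for (k in seq_len(nrow(d))) {
    if (d$aa_start[k] <= aa && aa <= d$aa_end[k]) lab <- d$domain_label[k]
  }
  if (is.na(lab)) lab <- "cytoplasmic"
  list(domain_label = lab, aa = as.integer(aa))
}

# per-base region classification against the representative transcript
oracle_region <- function(ann, contig, start, end) {
  reps <- representative_transcripts(ann)
  vapply(start:(end - 1), function(pos) {
    g <- ann$genes[ann$genes$contig == contig & ann$genes$start <= pos &
                     ann$genes$end > pos, , drop = FALSE]
    if (nrow(g) == 0) return("intergenic")
    tx <- reps[[g$gene_id[1]]]
    if (any(tx$cds$start <= pos & tx$cds$end > pos)) return("CDS")
    off <- oracle_offset(tx, pos)
    if (is.na(off)) return("intron")
    if (nrow(tx$cds) == 0) return("intron")
    cds_off <- vapply(seq_len(nrow(tx$cds)), function(i)
      oracle_offset(tx, if (tx$strand == "+") tx$cds$start[i] else tx$cds$end[i] - 1L),
      1L)
    if (off < min(cds_off)) "UTR5" else "UTR3"
  }, "")
}

# exhaustive read-vs-reference matcher (scan every read against every
# reference, both orientations, all occurrences)
oracle_match <- function(reads, refs, min_overhang) {
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  assign_of <- function(seq) {
    best <- data.frame(jid = character(0), ov = integer(0))
    for (k in seq_len(nrow(refs))) {
      for (s in c(seq, revcomp(seq))) {
        occ <- gregexpr(s, refs$sequence[k], fixed = TRUE)[[1]]
        if (occ[1] == -1) next
        for (o in occ) {
          left <- refs$midpoint[k] - o + 1
          right <- o + nchar(s) - 1 - refs$midpoint[k]
          ov <- min(left, right)
          if (ov >= min_overhang) {
            best <- rbind(best, data.frame(jid = refs$junction_id[k], ov = ov))
          }
        }
      }
    }
    if (nrow(best) == 0) return(NA_character_)
    best <- aggregate(ov ~ jid, best, max)
    best[order(-best$ov, best$jid), "jid"][1]
  }
  vapply(reads$sequence, assign_of, "", USE.NAMES = FALSE)
}

# all junction-spanning stop-free k-mers by literal enumeration
oracle_kmers <- function(sequence, midpoint, lengths = 8:11) {
  out <- character(0)
  for (frame in 0:2) {
    aa <- oracle_translate(sequence, frame)
    for (k in lengths) {
      if (nchar(aa) < k) next
      for (i in 1:(nchar(aa) - k + 1)) {
        nt_start <- frame + 3 * (i - 1)
        nt_end <- nt_start + 3 * k
        pep <- substr(aa, i, i + k - 1)
        if (nt_start < midpoint && nt_end > midpoint &&
            !grepl("[*X]", pep)) {
          out <- c(out, pep)
        }
      }
    }
  }
  unique(out)
}

# small default config used by several tests
tiny_config <- function(seed = 11, n_genes = 6, ...) {
  sim_config(seed = seed, n_genes = n_genes,
             n_cells_per_type = c("neoplastic-stem" = 20L,
                                  "neoplastic-differentiated" = 20L,
                                  "glia" = 20L, "immune" = 20L,
                                  "endothelial" = 10L), ...)
}

# a hand-built two-exon transcript for convention checks
two_exon_tx <- function(strand = "+") {
  transcript_model("txA", "gA", "c1", strand,
                   exons = data.frame(start = c(10L, 50L), end = c(20L, 65L)),
                   cds = NULL)
}
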