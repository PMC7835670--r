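#' Simulation configuration for a synthetic splicing cohort
#'
#' Bundles every knob of the synthetic-cohort generator. The defaults define
#' a toy-scale study: 20 multi-exon genes (one alternative-splicing event
#' each), 10 tumor + 10 normal bulk samples at ~50 reads per local splice
#' variation (LSV), and a five-type single-cell compartment of a few hundred
#' cells. Between-sample PSI heterogeneity follows a Beta/Dirichlet
#' distribution with the given concentration; LSV depth is Poisson.
#'
#' @param seed Integer seed; fully determines all generator outputs.
#' @param n_genes Number of genes (one planted splice event per gene).
#' @param n_tumor_samples,n_normal_samples Bulk cohort sizes.
#' @param mean_lsv_coverage Mean reads per LSV per sample (Poisson).
#' @param psi_concentration Dirichlet/Beta concentration for per-sample PSI
#'   around the group truth; larger = less between-sample spread.
#' @param n_cells_per_type Named integer vector of cells per single-cell
#'   type; names must be the five supported types.
#' @param read_length Single-cell read length (bases).
#' @param events Optional planted-event plan from [plant_events()]; when NULL
#'   a plan is drawn from the seed.
#' @param sc_expr_fraction Fraction of permitted cells expressing a planted
#'   junction.
#' @param sc_reads_per_cell Junction-spanning reads emitted per expressing
#'   cell.
#' @param sc_background_reads Non-junction background reads per cell.
#' @param sc_overhang Minimum bases on each side of the junction in emitted
#'   junction-spanning reads.
#' @param n_noise_peptides Decoy-like noise peptides added to the synthetic
#'   peptide database.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_genes = 20L,
                       n_tumor_samples = 10L, n_normal_samples = 10L,
                       mean_lsv_coverage = 50, psi_concentration = 50,
                       n_cells_per_type = c("neoplastic-stem" = 60L,
                                            "neoplastic-differentiated" = 60L,
                                            "glia" = 60L, "immune" = 60L,
                                            "endothelial" = 30L),
                       read_length = 60L, events = NULL,
                       sc_expr_fraction = 0.3, sc_reads_per_cell = 2L,
                       sc_background_reads = 2L, sc_overhang = 10L,
                       n_noise_peptides = 50L) {
  stopifnot(n_genes >= 1L, n_tumor_samples >= 1L, n_normal_samples >= 1L,
            mean_lsv_coverage > 0)
  if (psi_concentration <= 0) stop("psi_concentration must be positive")
  if (read_length < 2L * sc_overhang) {
    stop("read_length must be at least twice sc_overhang")
  }
  types <- c("neoplastic-stem", "neoplastic-differentiated", "glia",
             "immune", "endothelial")
  if (!setequal(names(n_cells_per_type), types)) {
    stop("n_cells_per_type must name exactly the five supported cell types")
  }
  if (!is.null(events)) {
    bad <- events$psi_tumor < 0 | events$psi_tumor > 1 |
      events$psi_normal < 0 | events$psi_normal > 1
    if (any(bad)) stop("planted PSI values must lie in [0,1]")
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_tumor_samples = as.integer(n_tumor_samples),
                 n_normal_samples = as.integer(n_normal_samples),
                 mean_lsv_coverage = mean_lsv_coverage,
                 psi_concentration = psi_concentration,
                 n_cells_per_type = n_cells_per_type[types],
                 read_length = as.integer(read_length), events = events,
                 sc_expr_fraction = sc_expr_fraction,
                 sc_reads_per_cell = as.integer(sc_reads_per_cell),
                 sc_background_reads = as.integer(sc_background_reads),
                 sc_overhang = as.integer(sc_overhang),
                 n_noise_peptides = as.integer(n_noise_peptides)),
            class = "sim_config")
}

# integer uniform on [a, b], avoiding sample()'s scalar pitfall
rint <- function(a, b) a + floor(stats::runif(1) * (b - a + 1))

#' Draw a planted-event plan
#'
#' One alternative-splicing event is planted per gene: a cassette exon, an
#' alternative 5' or an alternative 3' splice site. A subset of events is
#' tumor-only (the alternative junction has PSI 0 in every normal sample and
#' is therefore supported by exactly zero normal reads); planted attributes
#' (surface-domain label, neoplastic-cell restriction, presence in the
#' peptide database, annotation status, stem-cell emission bias) drive the
#' downstream recovery tests.
#'
#' @param n_genes Number of genes/events.
#' @param n_tumor_only Number of tumor-only events.
#' @param seed Integer seed.
#' @param frac_alt Fraction of events that are alt-5'/alt-3' (split evenly);
#'   the rest are cassette exons.
#' @param p_extracellular,p_transmembrane,p_cytoplasmic,p_utr,p_noncoding
#'   Mixture over planted domain labels (renormalised).
#' @param frac_denovo Fraction of alternative isoforms left out of the GFF3
#'   (their junctions are de novo).
#' @param frac_differential Fraction of shared (non-tumor-only) events with a
#'   planted tumor-vs-normal PSI shift.
#' @return data.frame with one row per gene.
#' @export
plant_events <- function(n_genes, n_tumor_only = max(1L, round(0.25 * n_genes)),
                         seed = 1L, frac_alt = 0.3,
                         p_extracellular = 0.40, p_transmembrane = 0.15,
                         p_cytoplasmic = 0.30, p_utr = 0.10, p_noncoding = 0.05,
                         frac_denovo = 0.15, frac_differential = 0.25) {
  stopifnot(n_tumor_only <= n_genes)
  withr::with_seed(seed, {
    kind <- sample(c("cassette", "alt5", "alt3"), n_genes, replace = TRUE,
                   prob = c(1 - frac_alt, frac_alt / 2, frac_alt / 2))
    pl <- c(p_extracellular, p_transmembrane, p_cytoplasmic, p_utr, p_noncoding)
    domain_label <- sample(c("extracellular", "transmembrane", "cytoplasmic",
                             "UTR", "noncoding"),
                           n_genes, replace = TRUE, prob = pl / sum(pl))
    tumor_only <- rep(FALSE, n_genes)
    tumor_only[sample.int(n_genes, n_tumor_only)] <- TRUE
    psi_normal <- stats::runif(n_genes, 0.2, 0.8)
    psi_tumor <- psi_normal
    diff_ev <- !tumor_only & stats::runif(n_genes) < frac_differential
    shift <- stats::runif(n_genes, 0.15, 0.3) * sign(stats::runif(n_genes) - 0.5)
    psi_tumor[diff_ev] <- pmin(0.95, pmax(0.05, psi_normal[diff_ev] + shift[diff_ev]))
    psi_normal[tumor_only] <- 0
    psi_tumor[tumor_only] <- stats::runif(sum(tumor_only), 0.3, 0.6)
    data.frame(
      gene_index = seq_len(n_genes),
      kind = kind,
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      tumor_only = tumor_only,
      domain_label = domain_label,
      surface = domain_label %in% c("extracellular", "transmembrane", "cytoplasmic"),
      neoplastic_only = tumor_only & stats::runif(n_genes) < 0.85,
      in_peptide_db = tumor_only & stats::runif(n_genes) < 0.75,
      denovo = stats::runif(n_genes) < frac_denovo,
      stem_ratio = 1,
      psi_tumor = psi_tumor,
      psi_normal = psi_normal,
      stringsAsFactors = FALSE
    )
  })
}

# Make the excised region's boundary bases discriminating so that any
# junction-crossing k-mer (even with a single-base overhang) is absent from
# the reference isoform: the first excised base must differ from the first
# base after the junction, and the last excised base from the last base
# before it. Mutations stay inside the excised region and never create a
# stop codon in the reference frame (excision bounds are codon-aligned for
# coding events).
fix_excision_boundaries <- function(mrna, a, b, coding) {
  ch <- function(i) substr(mrna, i, i)
  bases <- c("A", "C", "G", "T")
  if (ch(a + 1L) == ch(b + 1L)) {
    cand <- setdiff(bases, c(ch(a + 1L), ch(b + 1L)))
    if (coding) {
      tail2 <- substr(mrna, a + 2L, a + 3L)
      cand <- cand[!paste0(cand, tail2) %in% STOP_CODONS]
    }
    substr(mrna, a + 1L, a + 1L) <- cand[1L]
  }
  if (ch(b) == ch(a)) {
    cand <- setdiff(bases, c(ch(b), ch(a)))
    if (coding) {
      head2 <- substr(mrna, b - 2L, b - 1L)
      cand <- cand[!paste0(head2, cand) %in% STOP_CODONS]
    }
    substr(mrna, b, b) <- cand[1L]
  }
  mrna
}

# map a spliced-space interval [s, e) to genomic intervals, given exons with
# columns gstart (genomic start) and mstart/mend (spliced-space, plus strand)
spliced_to_genomic <- function(exons, s, e) {
  out <- list()
  for (i in seq_len(nrow(exons))) {
    lo <- max(s, exons$mstart[i]); hi <- min(e, exons$mend[i])
    if (lo < hi) {
      g0 <- exons$gstart[i] + (lo - exons$mstart[i])
      out[[length(out) + 1L]] <- c(start = g0, end = g0 + (hi - lo))
    }
  }
  do.call(rbind, out)
}

# build one gene in virtual plus orientation; returns all records needed by
# generate_reference (flipping to minus strand happens there)
build_gene <- function(plan, gi) {
  gene_id <- sprintf("GENE%03d", gi)
  contig <- sprintf("ctg%03d", gi)
  noncoding <- plan$domain_label == "noncoding"
  utr_event <- plan$domain_label == "UTR"
  kind <- plan$kind

  if (noncoding) {
    n_aa <- NA_integer_
    u5 <- 0L; cds_nt <- 0L
    mrna <- random_dna(rint(500L, 700L))
  } else {
    n_aa <- rint(100L, 180L)
    cds_nt <- 3L * (n_aa + 1L)  # includes stop codon
    u5 <- rint(30L, 80L)
    u3 <- rint(120L, 200L)
    cds <- paste0("ATG",
                  paste(sample(nonstop_codons(), n_aa - 1L, replace = TRUE),
                        collapse = ""),
                  sample(STOP_CODONS, 1L))
    mrna <- paste0(random_dna(u5), cds, random_dna(u3))
  }
  L <- nchar(mrna)

  # place the event in spliced space -------------------------------------
  if (kind == "cassette") {
    aa_len <- if (noncoding || utr_event) rint(8L, 14L) else rint(8L, 20L)
    clen <- 3L * aa_len
    if (noncoding) {
      cstart <- rint(150L, L - clen - 150L)
      aa_event <- NA_integer_
    } else if (utr_event) {
      cstart <- u5 + cds_nt + rint(10L, 30L)
      stopifnot(cstart + clen + 40L <= L)
      aa_event <- NA_integer_
    } else {
      ca1 <- rint(5L, n_aa - aa_len - 12L)
      cstart <- u5 + 3L * (ca1 - 1L)
      aa_event <- ca1 + aa_len  # acceptor-side codon on the inclusion isoform
    }
    mrna <- fix_excision_boundaries(mrna, cstart, cstart + clen,
                                    coding = !noncoding && !utr_event)
    # spliced exon boundaries of the inclusion isoform
    dstart <- cstart + clen
    split_d <- if (L - dstart >= 100L) dstart + rint(40L, L - dstart - 40L) else NA_integer_
    bounds1 <- c(0L, cstart, dstart, if (!is.na(split_d)) split_d, L)
    bounds2 <- c(0L, cstart, if (!is.na(split_d)) split_d, L)  # skip isoform
    cassette_exon_idx <- 2L
  } else {
    d_aa <- rint(4L, 10L)
    d <- 3L * d_aa
    if (noncoding) {
      p <- rint(150L, L - 150L)
      aa_event <- NA_integer_
    } else if (utr_event) {
      p <- u5 + cds_nt + rint(10L, 30L)
      stopifnot(p + d + 40L <= L)
      aa_event <- NA_integer_
    } else {
      pa <- rint(8L, n_aa - d_aa - 12L)
      p <- u5 + 3L * (pa - 1L)
      aa_event <- if (kind == "alt3") pa + d_aa else pa
    }
    exc <- if (kind == "alt3") c(p, p + d) else c(p - d, p)
    mrna <- fix_excision_boundaries(mrna, exc[1], exc[2],
                                    coding = !noncoding && !utr_event)
    split_r <- if (L - (p + d) >= 120L) p + d + rint(60L, L - p - d - 40L) else NA_integer_
    bounds1 <- c(0L, p, if (!is.na(split_r)) split_r, L)
    bounds2 <- bounds1  # same exon count; isoform B shifts one boundary
  }

  exon_df <- function(bounds) {
    data.frame(mstart = bounds[-length(bounds)], mend = bounds[-1L])
  }
  ex1 <- exon_df(bounds1)

  # genomic placement of isoform-1 exons (virtual plus orientation)
  flank <- 100L
  cursor <- flank
  ex1$gstart <- NA_integer_
  intron_seqs <- character(0)
  contig_parts <- list(random_dna(flank))
  for (i in seq_len(nrow(ex1))) {
    ex1$gstart[i] <- cursor
    contig_parts[[length(contig_parts) + 1L]] <-
      substr(mrna, ex1$mstart[i] + 1L, ex1$mend[i])
    cursor <- cursor + (ex1$mend[i] - ex1$mstart[i])
    if (i < nrow(ex1)) {
      ilen <- rint(80L, 200L)
      contig_parts[[length(contig_parts) + 1L]] <- random_dna(ilen)
      cursor <- cursor + ilen
    }
  }
  contig_parts[[length(contig_parts) + 1L]] <- random_dna(flank)
  contig_seq <- paste(unlist(contig_parts), collapse = "")
  ex1$gend <- ex1$gstart + (ex1$mend - ex1$mstart)

  # isoform-2 exons in genomic space
  if (kind == "cassette") {
    ex2 <- ex1[-cassette_exon_idx, , drop = FALSE]
  } else if (kind == "alt3") {
    ex2 <- ex1
    ex2$gstart[2L] <- ex2$gstart[2L] + d
    ex2$mstart[2L] <- ex2$mstart[2L] + d
  } else { # alt5
    ex2 <- ex1
    ex2$gend[1L] <- ex2$gend[1L] - d
    ex2$mend[1L] <- ex2$mend[1L] - d
  }

  # CDS genomic intervals per isoform
  cds1 <- cds2 <- NULL
  if (!noncoding) {
    cds1 <- spliced_to_genomic(ex1, u5, u5 + cds_nt)
    if (utr_event) {
      cds2 <- cds1
    } else if (kind == "cassette") {
      g <- spliced_to_genomic(ex1, u5, u5 + cds_nt)
      drop <- spliced_to_genomic(ex1, cstart, cstart + clen)
      cds2 <- subtract_intervals(g, drop)
    } else if (kind == "alt3") {
      g <- spliced_to_genomic(ex1, u5, u5 + cds_nt)
      drop <- spliced_to_genomic(ex1, p, p + d)
      cds2 <- subtract_intervals(g, drop)
    } else {
      g <- spliced_to_genomic(ex1, u5, u5 + cds_nt)
      drop <- spliced_to_genomic(ex1, p - d, p)
      cds2 <- subtract_intervals(g, drop)
    }
  }

  # adjacency junctions (virtual plus): ref junction and alt junction
  adj <- function(ex) {
    if (nrow(ex) < 2L) return(NULL)
    cbind(donor = ex$gend[-nrow(ex)], acceptor = ex$gstart[-1L])
  }
  j1 <- adj(ex1); j2 <- adj(ex2)
  if (kind == "cassette") {
    ref_j <- j1[1L, ]                       # upstream-exon -> cassette
    alt_j <- j2[1L, ]                       # upstream-exon -> downstream (skip)
    anchor <- "donor"
  } else if (kind == "alt3") {
    ref_j <- j1[1L, ]; alt_j <- j2[1L, ]; anchor <- "donor"
  } else {
    ref_j <- j1[1L, ]; alt_j <- j2[1L, ]; anchor <- "acceptor"
  }

  list(gene_id = gene_id, contig = contig, contig_seq = contig_seq,
       strand = plan$strand, n_aa = n_aa, aa_event = aa_event,
       ex1 = ex1, ex2 = ex2, cds1 = cds1, cds2 = cds2,
       j1 = j1, j2 = j2, ref_j = ref_j, alt_j = alt_j, anchor = anchor,
       noncoding = noncoding)
}

# interval subtraction on a matrix of [start, end) rows
subtract_intervals <- function(iv, drop) {
  if (is.null(drop)) return(iv)
  out <- list()
  for (i in seq_len(nrow(iv))) {
    segs <- list(c(iv[i, 1], iv[i, 2]))
    for (j in seq_len(nrow(drop))) {
      segs <- unlist(lapply(segs, function(s) {
        if (drop[j, 1] >= s[2] || drop[j, 2] <= s[1]) return(list(s))
        pieces <- list()
        if (drop[j, 1] > s[1]) pieces <- c(pieces, list(c(s[1], drop[j, 1])))
        if (drop[j, 2] < s[2]) pieces <- c(pieces, list(c(drop[j, 2], s[2])))
        pieces
      }), recursive = FALSE)
    }
    out <- c(out, segs)
  }
  m <- do.call(rbind, out)
  colnames(m) <- c("start", "end")
  m[order(m[, 1]), , drop = FALSE]
}

flip_interval <- function(start, end, L) cbind(start = L - end, end = L - start)

#' Generate a synthetic genome, annotation and planted truth
#'
#' Builds one contig per gene, a two-isoform gene model per planted event
#' (reference isoform plus cassette-skip or alternative-splice-site isoform),
#' CDS features valid by construction (length divisible by 3, start and stop
#' codons, no internal stops), a topological-domain partition for every
#' cell-surface protein, and the planted-truth table. Fully deterministic
#' under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An annotation object (list of class `ns_annotation`) with elements
#'   `genome` (named character vector), `genes`, `transcripts`, `junctions`,
#'   `domains`, `events` (planted truth) and `lsvs` (per-gene ref/alt
#'   junction pair used by the count simulator).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  events <- config$events
  if (is.null(events)) {
    events <- plant_events(config$n_genes,
                           seed = (config$seed + 1009L) %% .Machine$integer.max)
  }
  stopifnot(nrow(events) == config$n_genes)
  withr::with_seed(config$seed, {
    genome <- character(0)
    genes <- list(); transcripts <- list(); junc_rows <- list()
    domains <- list(); truth <- list(); lsvs <- list()
    for (gi in seq_len(config$n_genes)) {
      plan <- events[gi, ]
      g <- build_gene(plan, gi)
      Lc <- nchar(g$contig_seq)
      minus <- g$strand == "-"
      if (minus) g$contig_seq <- reverse_complement(g$contig_seq)
      genome[g$contig] <- g$contig_seq

      fix_ex <- function(ex) {
        if (!minus) return(data.frame(start = ex$gstart, end = ex$gend))
        f <- flip_interval(ex$gstart, ex$gend, Lc)
        data.frame(start = f[, "start"], end = f[, "end"])
      }
      fix_cds <- function(cds) {
        if (is.null(cds)) return(NULL)
        if (!minus) return(data.frame(start = cds[, "start"], end = cds[, "end"]))
        f <- flip_interval(cds[, "start"], cds[, "end"], Lc)
        data.frame(start = f[, "start"], end = f[, "end"])
      }
      fix_j <- function(j) {
        if (is.null(j)) return(NULL)
        j <- rbind(j)
        if (!minus) return(j)
        cbind(donor = Lc - j[, "acceptor"], acceptor = Lc - j[, "donor"])
      }

      pid1 <- if (g$noncoding) NA_character_ else sprintf("P%03d", gi)
      pid2 <- if (g$noncoding || is.null(g$cds2)) NA_character_ else sprintf("P%03db", gi)
      t1 <- transcript_model(paste0(g$gene_id, ".t1"), g$gene_id, g$contig,
                             g$strand, fix_ex(g$ex1), fix_cds(g$cds1), pid1)
      t2 <- transcript_model(paste0(g$gene_id, ".t2"), g$gene_id, g$contig,
                             g$strand, fix_ex(g$ex2), fix_cds(g$cds2), pid2)
      transcripts[[t1$transcript_id]] <- t1
      transcripts[[t2$transcript_id]] <- t2

      all_ex <- rbind(t1$exons, t2$exons)
      genes[[gi]] <- data.frame(gene_id = g$gene_id, contig = g$contig,
                                strand = g$strand,
                                start = min(all_ex$start), end = max(all_ex$end),
                                surface = plan$surface,
                                stringsAsFactors = FALSE)

      jmat1 <- fix_j(g$j1); jmat2 <- fix_j(g$j2)
      ref_j <- fix_j(g$ref_j); alt_j <- fix_j(g$alt_j)
      ref_id <- junction_id(g$contig, ref_j[1, "donor"], ref_j[1, "acceptor"], g$strand)
      alt_id <- junction_id(g$contig, alt_j[1, "donor"], alt_j[1, "acceptor"], g$strand)
      jall <- unique(rbind(jmat1, jmat2))
      jids <- junction_id(g$contig, jall[, "donor"], jall[, "acceptor"], g$strand)
      ann1 <- junction_id(g$contig, jmat1[, "donor"], jmat1[, "acceptor"], g$strand)
      ann2 <- junction_id(g$contig, jmat2[, "donor"], jmat2[, "acceptor"], g$strand)
      annotated_ids <- if (plan$denovo) ann1 else c(ann1, ann2)
      junc_rows[[gi]] <- data.frame(
        junction_id = jids, contig = g$contig,
        donor = jall[, "donor"], acceptor = jall[, "acceptor"],
        strand = g$strand, gene_id = g$gene_id,
        annotated = jids %in% annotated_ids,
        role = ifelse(jids == alt_id, "alt", ifelse(jids == ref_id, "ref", "const")),
        stringsAsFactors = FALSE)

      if (plan$surface) {
        aa_j <- g$aa_event
        n_aa <- g$n_aa
        lab <- plan$domain_label
        seg <- if (lab == "extracellular") 1L else if (lab == "transmembrane") 2L else 3L
        if (seg == 1L) {
          b1 <- rint(aa_j, n_aa - 2L); b2 <- rint(b1 + 1L, n_aa - 1L)
        } else if (seg == 2L) {
          b1 <- rint(1L, aa_j - 1L); b2 <- rint(aa_j, n_aa - 1L)
        } else {
          b2 <- rint(2L, aa_j - 1L); b1 <- rint(1L, b2 - 1L)
        }
        labs <- character(3L)
        labs[seg] <- lab
        labs[-seg] <- sample(setdiff(c("extracellular", "transmembrane",
                                       "cytoplasmic"), lab))
        domains[[length(domains) + 1L]] <- data.frame(
          protein_id = pid1,
          domain_label = labs,
          aa_start = c(1L, b1 + 1L, b2 + 1L),
          aa_end = c(b1, b2, n_aa),
          stringsAsFactors = FALSE)
      }

      truth[[gi]] <- data.frame(
        gene_id = g$gene_id, junction_id = alt_id, ref_junction_id = ref_id,
        transcript_ref = t1$transcript_id, transcript_alt = t2$transcript_id,
        kind = plan$kind, strand = g$strand, anchor = g$anchor,
        tumor_only = plan$tumor_only, domain_label = plan$domain_label,
        surface = plan$surface, neoplastic_only = plan$neoplastic_only,
        in_peptide_db = plan$in_peptide_db, denovo = plan$denovo,
        stem_ratio = plan$stem_ratio,
        psi_tumor = plan$psi_tumor, psi_normal = plan$psi_normal,
        aa_position = if (is.na(g$aa_event)) NA_integer_ else g$aa_event,
        stringsAsFactors = FALSE)
      lsvs[[gi]] <- data.frame(gene_id = g$gene_id, ref_junction_id = ref_id,
                               alt_junction_id = alt_id,
                               stringsAsFactors = FALSE)
    }
    structure(list(genome = genome,
                   genes = do.call(rbind, genes),
                   transcripts = transcripts,
                   junctions = do.call(rbind, junc_rows),
                   domains = if (length(domains)) do.call(rbind, domains) else
                     data.frame(protein_id = character(0), domain_label = character(0),
                                aa_start = integer(0), aa_end = integer(0)),
                   events = do.call(rbind, truth),
                   lsvs = do.call(rbind, lsvs),
                   config = config),
              class = "ns_annotation")
  })
}

#' Simulate bulk junction-count tables
#'
#' For each gene's event LSV and each sample: LSV depth is
#' Poisson(`mean_lsv_coverage`), the sample-level PSI of the alternative
#' junction is Beta-distributed around the group truth with concentration
#' `psi_concentration` (degenerate at 0 or 1 when the truth is 0 or 1, so
#' tumor-only events have exactly zero alternative-junction reads in every
#' normal sample), and junction counts are binomial splits of the depth.
#' Constitutive junctions receive independent Poisson counts.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [generate_reference()].
#' @return data.frame: first column `junction_id`, then one integer column
#'   per sample (`tumor01..`, `normal01..`).
#' @export
simulate_junction_counts <- function(config, annotation) {
  stopifnot(inherits(annotation, "ns_annotation"))
  if (config$psi_concentration <= 0) stop("psi_concentration must be positive")
  samples <- c(sprintf("tumor%02d", seq_len(config$n_tumor_samples)),
               sprintf("normal%02d", seq_len(config$n_normal_samples)))
  groups <- rep(c("tumor", "normal"),
                c(config$n_tumor_samples, config$n_normal_samples))
  jids <- annotation$junctions$junction_id
  counts <- matrix(0L, nrow = length(jids), ncol = length(samples),
                   dimnames = list(jids, samples))
  withr::with_seed((config$seed + 2003L) %% .Machine$integer.max, {
    for (gi in seq_len(nrow(annotation$events))) {
      ev <- annotation$events[gi, ]
      conc <- config$psi_concentration
      for (si in seq_along(samples)) {
        depth <- stats::rpois(1L, config$mean_lsv_coverage)
        p <- if (groups[si] == "tumor") ev$psi_tumor else ev$psi_normal
        psi_s <- if (p <= 0) 0 else if (p >= 1) 1 else
          stats::rbeta(1L, conc * p, conc * (1 - p))
        alt <- stats::rbinom(1L, depth, psi_s)
        counts[ev$junction_id, si] <- alt
        counts[ev$ref_junction_id, si] <- depth - alt
      }
    }
    const <- annotation$junctions$junction_id[annotation$junctions$role == "const"]
    # cassette downstream-inclusion junction mirrors the inclusion count
    for (gi in seq_len(nrow(annotation$events))) {
      ev <- annotation$events[gi, ]
      if (ev$kind != "cassette") next
      gene_j <- annotation$junctions[annotation$junctions$gene_id == ev$gene_id, ]
      tx1 <- annotation$transcripts[[ev$transcript_ref]]
      # the other inclusion junction: annotated-only junction of t1 not the ref
      incl2 <- setdiff(intersect(gene_j$junction_id[gene_j$role == "const"],
                                 transcript_junction_ids(tx1)),
                       transcript_junction_ids(annotation$transcripts[[ev$transcript_alt]]))
      if (length(incl2)) {
        counts[incl2[1], ] <- counts[ev$ref_junction_id, ]
        const <- setdiff(const, incl2[1])
      }
    }
    for (j in const) counts[j, ] <- stats::rpois(length(samples),
                                                 config$mean_lsv_coverage)
  })
  data.frame(junction_id = jids, counts, check.names = FALSE,
             stringsAsFactors = FALSE, row.names = NULL)
}

# junction ids of adjacent exon pairs of a transcript (genomic gaps)
transcript_junction_ids <- function(tx) {
  ex <- tx$exons
  if (nrow(ex) < 2L) return(character(0))
  junction_id(tx$contig, ex$end[-nrow(ex)], ex$start[-1L], tx$strand)
}

#' Simulate single-cell junction reads
#'
#' Emits error-free reads that are exact substrings of spliced transcript
#' sequences. Junction-spanning reads for a planted event come only from
#' cells of permitted types (all five types, or only neoplastic cells when
#' the event is planted neoplastic-only), with a configurable stem-vs-
#' differentiated emission bias; every cell also receives background reads
#' from the reference isoform.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [generate_reference()].
#' @return list with `reads` (data.frame: `read_id`, `barcode`, `sequence`)
#'   and `cells` (data.frame: `barcode`, `cell_type`).
#' @export
simulate_sc_reads <- function(config, annotation) {
  stopifnot(config$read_length >= 2L * config$sc_overhang)
  types <- names(config$n_cells_per_type)
  cells <- do.call(rbind, lapply(types, function(ty) {
    n <- config$n_cells_per_type[[ty]]
    if (n == 0L) return(NULL)
    data.frame(barcode = sprintf("%s_%03d", gsub("[^a-z]", "", ty), seq_len(n)),
               cell_type = ty, stringsAsFactors = FALSE)
  }))
  rl <- config$read_length; ov <- config$sc_overhang
  reads <- list(); rid <- 0L
  withr::with_seed((config$seed + 3001L) %% .Machine$integer.max, {
    for (gi in seq_len(nrow(annotation$events))) {
      ev <- annotation$events[gi, ]
      tx2 <- annotation$transcripts[[ev$transcript_alt]]
      s2 <- spliced_seq(tx2, annotation$genome)
      jp <- parse_junction_id(ev$junction_id)
      pos <- junction_transcript_pos(tx2, jp$donor, jp$acceptor)
      stopifnot(pos$status == "ok")
      m <- pos$t_down  # 0-based offset of first 3' base; junction before it
      permitted <- if (ev$neoplastic_only) {
        c("neoplastic-stem", "neoplastic-differentiated")
      } else types
      for (ci in seq_len(nrow(cells))) {
        ty <- cells$cell_type[ci]
        if (!ty %in% permitted) next
        f <- config$sc_expr_fraction
        if (ty == "neoplastic-stem") f <- min(1, f * ev$stem_ratio)
        if (stats::runif(1) >= f) next
        for (k in seq_len(config$sc_reads_per_cell)) {
          lo <- max(0L, m - rl + ov); hi <- min(m - ov, nchar(s2) - rl)
          if (hi < lo) next
          st <- rint(lo, hi)
          rid <- rid + 1L
          reads[[rid]] <- c(sprintf("read%06d", rid), cells$barcode[ci],
                            substr(s2, st + 1L, st + rl))
        }
      }
    }
    # background reads from the reference isoform, all cells
    for (ci in seq_len(nrow(cells))) {
      gidx <- rint(1L, nrow(annotation$events))
      tx1 <- annotation$transcripts[[annotation$events$transcript_ref[gidx]]]
      s1 <- spliced_seq(tx1, annotation$genome)
      for (k in seq_len(config$sc_background_reads)) {
        st <- rint(0L, nchar(s1) - rl)
        rid <- rid + 1L
        reads[[rid]] <- c(sprintf("read%06d", rid), cells$barcode[ci],
                          substr(s1, st + 1L, st + rl))
      }
    }
  })
  rd <- as.data.frame(do.call(rbind, reads), stringsAsFactors = FALSE)
  names(rd) <- c("read_id", "barcode", "sequence")
  list(reads = rd, cells = cells)
}

#' Simulate a peptide database (mass-spectrometry stand-in)
#'
#' Contains the three-frame junction-spanning peptides of every event planted
#' `in_peptide_db`, plus seeded random noise peptides guaranteed not to
#' collide (by equality or substring containment) with any true junction
#' peptide of any planted event.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [generate_reference()].
#' @param flank Bases per side of the junction window used to derive the true
#'   peptides (default 24, i.e. 48-nt windows).
#' @return Character vector of peptides.
#' @export
simulate_peptide_db <- function(config, annotation, flank = 24L) {
  ev <- annotation$events
  all_pep <- function(rows) {
    unlist(lapply(rows, function(i) {
      tx <- annotation$transcripts[[ev$transcript_ref[i]]]
      jp <- parse_junction_id(ev$junction_id[i])
      w <- junction_window(annotation$genome, tx, jp, flank = flank)
      if (w$status != "ok") return(character(0))
      derive_neopeptides(w)$peptides$peptide
    }))
  }
  true_pep <- unique(all_pep(which(ev$in_peptide_db)))
  avoid <- unique(all_pep(seq_len(nrow(ev))))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed((config$seed + 4001L) %% .Machine$integer.max, {
    noise <- character(0)
    while (length(noise) < config$n_noise_peptides) {
      p <- paste(sample(aa, rint(8L, 16L), replace = TRUE), collapse = "")
      collides <- any(vapply(avoid, function(t)
        grepl(t, p, fixed = TRUE) || grepl(p, t, fixed = TRUE), TRUE))
      if (!collides) noise <- c(noise, p)
    }
    c(true_pep, noise)
  })
}

#' Simulate patient HLA class-I serotypes
#'
#' Each tumor sample is treated as a patient and receives 4-6 distinct
#' class-I alleles from a small fixed pool.
#'
#' @param config A [sim_config()].
#' @return data.frame with columns `patient_id`, `allele` (long format).
#' @export
simulate_serotypes <- function(config) {
  pool <- c("HLA-A*01:01", "HLA-A*02:01", "HLA-B*07:02", "HLA-B*08:01",
            "HLA-C*04:01", "HLA-C*07:01", "HLA-A*03:01", "HLA-B*44:02")
  withr::with_seed((config$seed + 5003L) %% .Machine$integer.max, {
    do.call(rbind, lapply(seq_len(config$n_tumor_samples), function(i) {
      n <- rint(4L, 6L)
      data.frame(patient_id = sprintf("tumor%02d", i),
                 allele = sample(pool, n), stringsAsFactors = FALSE)
    }))
  })
}
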