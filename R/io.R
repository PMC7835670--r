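#' Write a synthetic cohort reference to disk
#'
#' Serializes an annotation object: genome as FASTA, gene models as GFF3
#' (1-based inclusive, gene/mRNA/exon/CDS features with ID/Parent links),
#' surface domains, planted-truth and LSV tables as TSV.
#'
#' @param annotation Annotation object from [generate_reference()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(annotation, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  genome <- Biostrings::DNAStringSet(annotation$genome)
  Biostrings::writeXStringSet(genome, file.path(dir, "genome.fa"))
  write_annotation_gff3(annotation, file.path(dir, "annotation.gff3"))
  write_tsv(annotation$domains, file.path(dir, "domains.tsv"))
  write_tsv(annotation$events, file.path(dir, "truth.tsv"))
  write_tsv(annotation$lsvs, file.path(dir, "lsvs.tsv"))
  invisible(dir)
}

#' Write gene models as GFF3
#'
#' @param annotation Annotation object.
#' @param path Output path.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  rows <- list()
  add <- function(contig, start0, end0, type, strand, id = NA, parent = NA,
                  phase = NA_integer_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      contig = contig, start = start0 + 1L, end = end0, type = type,
      strand = strand, id = id, parent = parent, phase = phase,
      stringsAsFactors = FALSE)
  }
  g <- annotation$genes
  for (i in seq_len(nrow(g))) {
    add(g$contig[i], g$start[i], g$end[i], "gene", g$strand[i], id = g$gene_id[i])
  }
  for (tx in annotation$transcripts) {
    add(tx$contig, min(tx$exons$start), max(tx$exons$end), "mRNA", tx$strand,
        id = tx$transcript_id, parent = tx$gene_id)
    for (e in seq_len(nrow(tx$exons))) {
      add(tx$contig, tx$exons$start[e], tx$exons$end[e], "exon", tx$strand,
          parent = tx$transcript_id)
    }
    if (nrow(tx$cds) > 0L) {
      ord <- if (tx$strand == "+") seq_len(nrow(tx$cds)) else
        rev(seq_len(nrow(tx$cds)))
      cum <- 0L
      for (c in ord) {
        add(tx$contig, tx$cds$start[c], tx$cds$end[c], "CDS", tx$strand,
            parent = tx$transcript_id, phase = (3L - cum %% 3L) %% 3L)
        cum <- cum + (tx$cds$end[c] - tx$cds$start[c])
      }
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$id
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$parent), "", df$parent)
  S4Vectors::mcols(gr)$phase <- df$phase
  # protein ids travel on mRNA features
  pid <- rep(NA_character_, nrow(df))
  for (tx in annotation$transcripts) {
    sel <- df$type == "mRNA" & !is.na(df$id) & df$id == tx$transcript_id
    pid[sel] <- tx$protein_id
  }
  S4Vectors::mcols(gr)$protein_id <- pid
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a synthetic cohort reference from disk
#'
#' Inverse of [write_cohort()]: rebuilds the annotation object (genome,
#' genes, transcript models, annotated junctions, domains, planted truth,
#' LSV plan) from `genome.fa`, `annotation.gff3` and the TSV tables.
#'
#' @param dir Directory written by [write_cohort()].
#' @return An `ns_annotation` object.
#' @export
read_cohort <- function(dir) {
  genome_set <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  genome <- stats::setNames(as.character(genome_set),
                            sub("\\s.*$", "", names(genome_set)))
  gr <- rtracklayer::import(file.path(dir, "annotation.gff3"))
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(S4Vectors::mcols(gr)$type),
    id = as.character(S4Vectors::mcols(gr)$ID),
    stringsAsFactors = FALSE)
  parent <- S4Vectors::mcols(gr)$Parent
  df$parent <- vapply(seq_along(parent), function(i) {
    p <- parent[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p[1])
  }, "")
  df$protein_id <- if ("protein_id" %in% names(S4Vectors::mcols(gr))) {
    as.character(S4Vectors::mcols(gr)$protein_id)
  } else NA_character_

  domains <- read_tsv(file.path(dir, "domains.tsv"))
  events <- read_tsv(file.path(dir, "truth.tsv"))
  lsvs <- read_tsv(file.path(dir, "lsvs.tsv"))

  gdf <- df[df$type == "gene", , drop = FALSE]
  mdf <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  transcripts <- list()
  for (i in seq_len(nrow(mdf))) {
    tid <- mdf$id[i]
    ex <- df[df$type == "exon" & df$parent == tid, c("start", "end")]
    cds <- df[df$type == "CDS" & df$parent == tid, c("start", "end")]
    pid <- mdf$protein_id[i]
    if (!is.null(pid) && !is.na(pid) && pid == "") pid <- NA_character_
    transcripts[[tid]] <- transcript_model(
      tid, mdf$parent[i], mdf$contig[i], mdf$strand[i],
      ex, if (nrow(cds)) cds else NULL, pid)
  }
  genes <- data.frame(gene_id = gdf$id, contig = gdf$contig,
                      strand = gdf$strand, start = gdf$start, end = gdf$end,
                      stringsAsFactors = FALSE)
  # surface flag from domain table via each gene's representative protein
  prot_gene <- vapply(transcripts, function(tx) tx$gene_id, "")
  prot_ids <- vapply(transcripts, function(tx)
    if (is.na(tx$protein_id)) "" else tx$protein_id, "")
  genes$surface <- vapply(genes$gene_id, function(gid) {
    any(prot_ids[prot_gene == gid] %in% domains$protein_id)
  }, TRUE)

  # junction table: annotated adjacencies plus planted alt junctions
  jrows <- list()
  for (tx in transcripts) {
    jid <- transcript_junction_ids(tx)
    if (length(jid) == 0L) next
    p <- parse_junction_id(jid)
    p$gene_id <- tx$gene_id
    p$annotated <- TRUE
    jrows[[length(jrows) + 1L]] <- p
  }
  jt <- unique(do.call(rbind, jrows))
  extra <- setdiff(events$junction_id, jt$junction_id)
  if (length(extra)) {
    p <- parse_junction_id(extra)
    p$gene_id <- events$gene_id[match(extra, events$junction_id)]
    p$annotated <- FALSE
    jt <- rbind(jt, p)
  }
  jt$role <- ifelse(jt$junction_id %in% events$junction_id, "alt",
                    ifelse(jt$junction_id %in% events$ref_junction_id, "ref",
                           "const"))
  rownames(jt) <- NULL
  structure(list(genome = genome, genes = genes, transcripts = transcripts,
                 junctions = jt, domains = domains, events = events,
                 lsvs = lsvs, config = NULL),
            class = "ns_annotation")
}

#' Write / read junction-count tables
#'
#' Rows are junctions keyed `contig:donor-acceptor:strand`; columns are
#' samples.
#'
#' @param counts data.frame from [simulate_junction_counts()].
#' @param path TSV path.
#' @export
write_junction_counts <- function(counts, path) write_tsv(counts, path)

#' @rdname write_junction_counts
#' @export
read_junction_counts <- function(path) read_tsv(path)

#' Write single-cell reads as FASTQ
#'
#' Cell barcodes are embedded in the read name (`read_id|barcode`);
#' qualities are uniform since the generator is error-free.
#'
#' @param reads data.frame with `read_id`, `barcode`, `sequence`.
#' @param path FASTQ path.
#' @export
write_fastq_reads <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- paste0(reads$read_id, "|", reads$barcode)
  quals <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read single-cell reads from FASTQ
#'
#' @param path FASTQ path written by [write_fastq_reads()].
#' @return data.frame with `read_id`, `barcode`, `sequence`.
#' @export
read_fastq_reads <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  ids <- sub("\\s.*$", "", names(seqs))
  parts <- strsplit(ids, "|", fixed = TRUE)
  data.frame(read_id = vapply(parts, `[`, "", 1L),
             barcode = vapply(parts, `[`, "", 2L),
             sequence = unname(as.character(seqs)), stringsAsFactors = FALSE)
}

#' Write a cell-by-junction matrix as sparse MTX with index files
#'
#' @param matrix A `cell_junction_matrix` from [match_sc_reads()].
#' @param dir Output directory; writes `matrix.mtx`, `barcodes.tsv`
#'   (barcode + cell type), `junctions.tsv`.
#' @export
write_cell_junction_matrix <- function(matrix, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(matrix$counts, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  write_tsv(data.frame(barcode = rownames(matrix$counts),
                       cell_type = unname(matrix$cell_types[rownames(matrix$counts)])),
            file.path(dir, "barcodes.tsv"))
  write_tsv(data.frame(junction_id = colnames(matrix$counts)),
            file.path(dir, "junctions.tsv"))
  invisible(dir)
}

#' Write junction windows or peptides as FASTA
#'
#' Headers carry the junction id (and frame for peptides).
#'
#' @param windows list of [junction_window()] results, or a data.frame of
#'   peptides with `junction_id`, `frame`, `peptide`.
#' @param path FASTA path.
#' @export
write_windows_fasta <- function(windows, path) {
  if (is.data.frame(windows)) {
    seqs <- Biostrings::AAStringSet(windows$peptide)
    names(seqs) <- paste0(windows$junction_id, "|frame", windows$frame)
  } else {
    ok <- Filter(function(w) w$status == "ok", windows)
    seqs <- Biostrings::DNAStringSet(vapply(ok, `[[`, "", "sequence"))
    names(seqs) <- vapply(ok, `[[`, "", "junction_id")
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write motif hits as BED
#'
#' 0-based half-open intervals; the BED score column is bits x 100, rounded.
#'
#' @param hits data.frame from [scan_gene()].
#' @param path BED path.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(hits$contig, hits$start, hits$end, hits$motif_id,
                    round(hits$score * 100), hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a peptide database (one peptide per line)
#' @param path Plain-text path.
#' @return Character vector.
#' @export
read_peptide_db <- function(path) {
  p <- readLines(path)
  p[nzchar(trimws(p))]
}

#' Read patient HLA serotypes
#'
#' Long-format TSV with columns `patient_id`, `allele`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_serotypes <- function(path) read_tsv(path)
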