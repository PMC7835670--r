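#' Junction-spanning reference sequences
#'
#' Builds the per-junction reference used for single-cell read matching: up
#' to `flank` (default 300, i.e. 600-nt references) spliced bases per side of
#' the junction on the gene's representative transcript, with the junction at
#' the recorded midpoint.
#'
#' @param annotation Annotation object.
#' @param junction_ids Junctions to build references for.
#' @param flank Bases per side (default 300).
#' @return data.frame: `junction_id`, `sequence`, `midpoint` (bases left of
#'   the junction).
#' @export
junction_references <- function(annotation, junction_ids, flank = 300L) {
  reps <- representative_transcripts(annotation)
  jt <- annotation$junctions
  out <- lapply(junction_ids, function(jid) {
    row <- jt[jt$junction_id == jid, , drop = FALSE]
    if (nrow(row) == 0L) row <- parse_junction_id(jid)
    gene <- if (!is.null(row$gene_id)) row$gene_id[1] else {
      g <- annotation$genes
      g$gene_id[g$contig == row$contig[1]][1]
    }
    tx <- reps[[gene]]
    w <- junction_window(annotation$genome, tx,
                         list(junction_id = jid, donor = row$donor[1],
                              acceptor = row$acceptor[1]), flank = flank)
    if (w$status != "ok") return(NULL)
    data.frame(junction_id = jid, sequence = w$sequence,
               midpoint = w$midpoint, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Match single-cell reads to junction references
#'
#' A read counts for a junction iff it matches the reference exactly (as a
#' substring, either orientation) with at least `min_overhang` bases on each
#' side of the junction midpoint. A read counts for at most one junction;
#' ties break by longest minimum overhang, then lexicographic junction id.
#'
#' @param reads data.frame with `barcode`, `sequence` (and optionally
#'   `read_id`), e.g. from [simulate_sc_reads()] or [read_fastq_reads()].
#' @param references data.frame from [junction_references()].
#' @param cells data.frame with `barcode`, `cell_type` covering every read
#'   barcode.
#' @param min_overhang Minimum bases on each side of the midpoint.
#' @return A `cell_junction_matrix`: list with `counts` (sparse barcodes x
#'   junctions matrix) and `cell_types` (named character vector).
#' @export
match_sc_reads <- function(reads, references, cells, min_overhang = 10L) {
  stopifnot(all(nchar(reads$sequence) >= 2L * min_overhang))
  if (!all(reads$barcode %in% cells$barcode)) {
    stop("read barcode missing from cell annotation")
  }
  refs <- references$sequence
  mids <- references$midpoint
  jids <- references$junction_id
  counts <- Matrix::Matrix(0, nrow = nrow(cells), ncol = length(jids),
                           dimnames = list(cells$barcode, jids), sparse = TRUE)
  best_overhang <- function(seq, ref, m) {
    L <- nchar(seq)
    occ <- gregexpr(seq, ref, fixed = TRUE)[[1]]
    if (occ[1] == -1L) return(0L)
    left <- m - occ + 1L
    right <- occ + L - 1L - m
    mo <- pmin(left, right)
    max(0L, max(mo))
  }
  for (ri in seq_len(nrow(reads))) {
    s <- reads$sequence[ri]
    rc <- reverse_complement(s)
    ov <- vapply(seq_along(refs), function(k) {
      max(best_overhang(s, refs[k], mids[k]),
          best_overhang(rc, refs[k], mids[k]))
    }, 0L)
    ok <- which(ov >= min_overhang)
    if (length(ok) == 0L) next
    pick <- ok[order(-ov[ok], jids[ok])][1]
    counts[reads$barcode[ri], pick] <- counts[reads$barcode[ri], pick] + 1
  }
  structure(list(counts = counts,
                 cell_types = stats::setNames(cells$cell_type, cells$barcode)),
            class = "cell_junction_matrix")
}

#' Expression frequency of each junction per cell type
#'
#' Fraction of cells of each type with at least one junction-spanning read.
#' Cell types with zero cells give NA.
#'
#' @param matrix A `cell_junction_matrix` from [match_sc_reads()].
#' @return data.frame: `junction_id`, `cell_type`, `n_cells`,
#'   `n_expressing`, `fraction`.
#' @export
cell_type_frequencies <- function(matrix) {
  stopifnot(inherits(matrix, "cell_junction_matrix"))
  types <- sort(unique(matrix$cell_types))
  expressed <- matrix$counts >= 1
  out <- list()
  for (ty in types) {
    bc <- names(matrix$cell_types)[matrix$cell_types == ty]
    n <- length(bc)
    n_exp <- if (n > 0L) Matrix::colSums(expressed[bc, , drop = FALSE]) else
      rep(NA_integer_, ncol(expressed))
    out[[ty]] <- data.frame(junction_id = colnames(matrix$counts),
                            cell_type = ty, n_cells = n,
                            n_expressing = as.integer(n_exp),
                            fraction = if (n > 0L) as.numeric(n_exp) / n else NA_real_,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

NEOPLASTIC_TYPES <- c("neoplastic-stem", "neoplastic-differentiated")
NONMALIGNANT_TYPES <- c("glia", "immune", "endothelial")

#' Neoplastic-cell specificity call
#'
#' TRUE iff at least `min_neoplastic_cells` neoplastic cells (stem +
#' differentiated) express the junction AND zero glia, immune and endothelial
#' cells do. The non-malignant veto is absolute: a single read in any
#' non-malignant cell fails the call.
#'
#' @param junction_id Junction to test.
#' @param frequencies Output of [cell_type_frequencies()].
#' @param min_neoplastic_cells Minimum expressing neoplastic cells
#'   (default 1).
#' @return logical.
#' @export
neoplastic_specific <- function(junction_id, frequencies,
                                min_neoplastic_cells = 1L) {
  f <- frequencies[frequencies$junction_id == junction_id, , drop = FALSE]
  if (nrow(f) == 0L) return(FALSE)
  neo <- sum(f$n_expressing[f$cell_type %in% NEOPLASTIC_TYPES], na.rm = TRUE)
  nonmal <- sum(f$n_expressing[f$cell_type %in% NONMALIGNANT_TYPES], na.rm = TRUE)
  neo >= min_neoplastic_cells && nonmal == 0L
}

#' Stem-like vs differentiated expression enrichment
#'
#' Ratio of the stem-like expression fraction to the differentiated one.
#' Differentiated fraction 0 with stem > 0 reports Inf; both zero (or either
#' undefined) reports NA.
#'
#' @param junction_id Junction to test.
#' @param frequencies Output of [cell_type_frequencies()].
#' @return numeric ratio (possibly Inf or NA).
#' @export
stem_enrichment <- function(junction_id, frequencies) {
  f <- frequencies[frequencies$junction_id == junction_id, , drop = FALSE]
  fs <- f$fraction[f$cell_type == "neoplastic-stem"]
  fd <- f$fraction[f$cell_type == "neoplastic-differentiated"]
  if (length(fs) == 0L || length(fd) == 0L || is.na(fs) || is.na(fd)) return(NA_real_)
  if (fs == 0 && fd == 0) return(NA_real_)
  if (fd == 0) return(Inf)
  fs / fd
}
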