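#' Transcript models and junction-to-protein projection
#'
#' All internal coordinates are 0-based half-open on the contig. Exons of a
#' transcript are stored sorted by genomic start; transcript (5'->3')
#' orientation follows the strand, so for minus-strand transcripts the last
#' genomic exon is the first transcript exon.
#'
#' @param transcript_id,gene_id,protein_id Identifiers (`protein_id = NA` for
#'   non-coding transcripts).
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (0-based half-open),
#'   non-overlapping.
#' @param cds Optional data.frame like `exons` restricted to coding sequence
#'   (includes the stop codon); empty or NULL for non-coding transcripts.
#' @return A `transcript_model` list.
#' @export
transcript_model <- function(transcript_id, gene_id, contig, strand, exons,
                             cds = NULL, protein_id = NA_character_) {
  stopifnot(strand %in% c("+", "-"), nrow(exons) >= 1L,
            all(exons$start < exons$end))
  exons <- data.frame(start = as.integer(exons$start),
                      end = as.integer(exons$end))
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] < exons$end[-nrow(exons)])) {
    stop("overlapping exons in transcript ", transcript_id)
  }
  if (!is.null(cds) && nrow(cds) > 0L) {
    cds <- data.frame(start = as.integer(cds$start), end = as.integer(cds$end))
    cds <- cds[order(cds$start), , drop = FALSE]
    rownames(cds) <- NULL
    if (sum(cds$end - cds$start) %% 3L != 0L) {
      stop("CDS length not divisible by 3 in transcript ", transcript_id)
    }
  } else {
    cds <- data.frame(start = integer(0), end = integer(0))
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 protein_id = protein_id, contig = contig, strand = strand,
                 exons = exons, cds = cds),
            class = "transcript_model")
}

# exon row indices in transcript (5'->3') orientation
tx_exon_order <- function(tx) {
  if (tx$strand == "+") seq_len(nrow(tx$exons)) else rev(seq_len(nrow(tx$exons)))
}

#' Spliced length of a transcript
#' @param tx A [transcript_model()].
#' @return Integer number of spliced bases.
#' @export
spliced_length <- function(tx) sum(tx$exons$end - tx$exons$start)

#' Map a genomic position to a transcript offset
#'
#' The offset counts spliced bases 5'->3' in transcript orientation, starting
#' at 0 for the first transcript base. Intronic or out-of-transcript positions
#' yield a typed `not_exonic` result rather than an error.
#'
#' @param tx A [transcript_model()].
#' @param genomic_pos 0-based genomic position.
#' @return list with `status` (`"ok"` or `"not_exonic"`) and `offset`
#'   (integer, NA when not exonic).
#' @export
genomic_to_transcript <- function(tx, genomic_pos) {
  cum <- 0L
  for (i in tx_exon_order(tx)) {
    s <- tx$exons$start[i]; e <- tx$exons$end[i]
    if (genomic_pos >= s && genomic_pos < e) {
      off <- if (tx$strand == "+") cum + (genomic_pos - s) else cum + (e - 1L - genomic_pos)
      return(list(status = "ok", offset = as.integer(off)))
    }
    cum <- cum + (e - s)
  }
  list(status = "not_exonic", offset = NA_integer_)
}

#' Map a transcript offset back to a genomic position
#'
#' Inverse of [genomic_to_transcript()]; exact round trip on every exonic
#' position.
#'
#' @param tx A [transcript_model()].
#' @param offset 0-based transcript offset.
#' @return 0-based genomic position (integer), or NA if offset out of range.
#' @export
transcript_to_genomic <- function(tx, offset) {
  cum <- 0L
  for (i in tx_exon_order(tx)) {
    s <- tx$exons$start[i]; e <- tx$exons$end[i]
    len <- e - s
    if (offset < cum + len) {
      within <- offset - cum
      return(as.integer(if (tx$strand == "+") s + within else e - 1L - within))
    }
    cum <- cum + len
  }
  NA_integer_
}

#' Spliced transcript sequence
#'
#' @param tx A [transcript_model()].
#' @param genome Named character vector of contig sequences (or coercible
#'   `DNAStringSet`).
#' @return Character string, transcript (coding) orientation.
#' @export
spliced_seq <- function(tx, genome) {
  contig <- as.character(genome[[tx$contig]])
  parts <- substring(contig, tx$exons$start + 1L, tx$exons$end)
  s <- paste(parts, collapse = "")
  if (tx$strand == "-") reverse_complement(s) else s
}

# CDS span in transcript offsets: c(t_start, length); NULL for non-coding.
cds_transcript_span <- function(tx) {
  if (nrow(tx$cds) == 0L) return(NULL)
  first_base <- if (tx$strand == "+") min(tx$cds$start) else max(tx$cds$end) - 1L
  r <- genomic_to_transcript(tx, first_base)
  stopifnot(r$status == "ok")
  c(t_start = r$offset, length = sum(tx$cds$end - tx$cds$start))
}

# transcript-space placement of a junction: t_up = offset of the last 5'
# exonic base before the junction, t_down = offset of the first 3' base.
# Compatible when both are exonic and t_down > t_up (acceptor downstream).
junction_transcript_pos <- function(tx, donor, acceptor) {
  if (tx$strand == "+") {
    up <- genomic_to_transcript(tx, donor - 1L)
    down <- genomic_to_transcript(tx, acceptor)
  } else {
    up <- genomic_to_transcript(tx, acceptor)
    down <- genomic_to_transcript(tx, donor - 1L)
  }
  if (up$status != "ok" || down$status != "ok" || down$offset <= up$offset) {
    return(list(status = "incompatible", t_up = NA_integer_, t_down = NA_integer_))
  }
  list(status = "ok", t_up = up$offset, t_down = down$offset)
}

#' Project a junction onto a transcript's protein
#'
#' The junction's residue is defined by the acceptor-side codon: the codon
#' containing the first coding base 3' of the junction in transcript
#' orientation (the junction alters sequence from that residue onward).
#' Junctions landing upstream of the CDS start map to `UTR5`, downstream of
#' the CDS end to `UTR3`; transcripts without CDS give `noncoding`.
#'
#' @param junction list/row with `donor`, `acceptor` (0-based half-open intron
#'   bounds) and optionally `junction_id`.
#' @param tx A [transcript_model()].
#' @param domains data.frame of topological domains (`protein_id`,
#'   `domain_label`, `aa_start`, `aa_end`, 1-based inclusive) for cell-surface
#'   proteins; proteins absent from it are not surface proteins.
#' @return list with `status` (`"ok"`/`"incompatible"`), `junction_id`,
#'   `transcript_id`, `cds_offset`, `aa_position`, `frame`, `domain_label`,
#'   `is_surface_protein`.
#' @export
junction_protein_locus <- function(junction, tx, domains) {
  jid <- if (!is.null(junction$junction_id)) junction$junction_id else
    junction_id(tx$contig, junction$donor, junction$acceptor, tx$strand)
  pos <- junction_transcript_pos(tx, junction$donor, junction$acceptor)
  out <- list(status = pos$status, junction_id = jid,
              transcript_id = tx$transcript_id,
              cds_offset = NA_integer_, aa_position = NA_integer_,
              frame = NA_integer_, domain_label = NA_character_,
              is_surface_protein = !is.na(tx$protein_id) &&
                tx$protein_id %in% domains$protein_id)
  if (pos$status != "ok") return(out)
  span <- cds_transcript_span(tx)
  if (is.null(span)) {
    out$domain_label <- "noncoding"
    return(out)
  }
  t_down <- pos$t_down
  if (t_down < span["t_start"]) {
    out$domain_label <- "UTR5"
  } else if (t_down >= span["t_start"] + span["length"]) {
    out$domain_label <- "UTR3"
  } else {
    cds_offset <- as.integer(t_down - span["t_start"])
    out$cds_offset <- cds_offset
    out$aa_position <- cds_offset %/% 3L + 1L
    out$frame <- cds_offset %% 3L
    hit <- domains$protein_id == tx$protein_id &
      domains$aa_start <= out$aa_position & domains$aa_end >= out$aa_position
    out$domain_label <- if (any(hit)) domains$domain_label[which(hit)[1]] else "cytoplasmic"
  }
  out
}

#' Representative transcript per gene
#'
#' The transcript with the longest total CDS is taken as the gene's
#' representative for domain mapping and region classification; ties break by
#' transcript id.
#'
#' @param annotation Annotation object (see [generate_reference()]).
#' @return Named list of [transcript_model()]s, one per gene.
#' @export
representative_transcripts <- function(annotation) {
  txs <- annotation$transcripts
  by_gene <- split(txs, vapply(txs, `[[`, "", "gene_id"))
  lapply(by_gene, function(group) {
    cds_len <- vapply(group, function(tx) sum(tx$cds$end - tx$cds$start), 0)
    ids <- vapply(group, `[[`, "", "transcript_id")
    group[[order(-cds_len, ids)[1]]]
  })
}

#' Classify a genomic interval by gene region
#'
#' Per-base classification into `CDS`, `UTR5`, `UTR3`, `intron` or
#' `intergenic`, using the longest-CDS transcript of the overlapping gene;
#' exonic bases of non-coding transcripts count as `intron` (non-coding gene
#' body). The interval summary is its majority class (ties break in the
#' order above).
#'
#' @param annotation Annotation object.
#' @param contig Contig name.
#' @param start,end 0-based half-open interval.
#' @return list with `per_base` (character vector, one element per base) and
#'   `majority` (single class).
#' @export
classify_region <- function(annotation, contig, start, end) {
  stopifnot(end > start)
  if (!contig %in% names(annotation$genome)) {
    stop("unknown contig: ", contig)
  }
  reps <- representative_transcripts(annotation)
  classes <- rep("intergenic", end - start)
  genes <- annotation$genes
  g <- genes[genes$contig == contig & genes$start < end & genes$end > start, , drop = FALSE]
  for (gi in seq_len(nrow(g))) {
    tx <- reps[[g$gene_id[gi]]]
    span <- cds_transcript_span(tx)
    for (pos in max(start, g$start[gi]):(min(end, g$end[gi]) - 1L)) {
      idx <- pos - start + 1L
      in_cds <- any(tx$cds$start <= pos & tx$cds$end > pos)
      if (in_cds) {
        classes[idx] <- "CDS"
      } else {
        r <- genomic_to_transcript(tx, pos)
        if (r$status == "ok" && !is.null(span)) {
          classes[idx] <- if (r$offset < span["t_start"]) "UTR5" else "UTR3"
        } else {
          classes[idx] <- "intron"
        }
      }
    }
  }
  tab <- table(factor(classes, levels = c("CDS", "UTR5", "UTR3", "intron", "intergenic")))
  list(per_base = classes, majority = names(tab)[which.max(tab)])
}
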