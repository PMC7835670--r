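#' Construct an RNA-binding-protein motif model
#'
#' @param motif_id,rbp_name Identifiers.
#' @param pwm 4 x W probability matrix, rows A/C/G/T (U read as T); columns
#'   must sum to 1 (counts are normalised). Zero entries get a small
#'   pseudocount before log-odds scoring.
#' @param background Base frequencies (length 4, sums to 1).
#' @param score_threshold Log-odds hit threshold in bits; default 80% of the
#'   maximal achievable PWM score.
#' @return A `motif_model` list with the log-odds matrix precomputed.
#' @export
motif_model <- function(motif_id, rbp_name, pwm,
                        background = rep(0.25, 4), score_threshold = NULL) {
  stopifnot(nrow(pwm) == 4L, ncol(pwm) >= 1L, length(background) == 4L,
            abs(sum(background) - 1) < 1e-6)
  pwm <- sweep(pwm, 2, colSums(pwm), "/")
  if (any(pwm == 0)) {
    pwm <- sweep(pwm + 1e-4, 2, colSums(pwm + 1e-4), "/")
  }
  rownames(pwm) <- c("A", "C", "G", "T")
  lods <- log2(pwm / background)
  max_score <- sum(apply(lods, 2, max))
  if (is.null(score_threshold)) {
    score_threshold <- if (max_score > 0) 0.8 * max_score else 0
  }
  structure(list(motif_id = motif_id, rbp_name = rbp_name, pwm = pwm,
                 background = background, lods = lods,
                 max_score = max_score, score_threshold = score_threshold),
            class = "motif_model")
}

#' Read motif PWMs from tabular text
#'
#' JASPAR-like format: a header line `>motif_id rbp_name` followed by four
#' rows `A 1 2 3 ...`, `C ...`, `G ...`, `T ...` (or `U`), holding counts or
#' probabilities; columns are normalised.
#'
#' @param path Input file.
#' @param score_threshold Optional shared threshold override.
#' @return list of [motif_model()]s.
#' @export
read_pwms <- function(path, score_threshold = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0L) stop("no motif headers ('>') found in ", path)
  out <- list()
  for (si in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[si]])
    parts <- strsplit(hdr, "\\s+")[[1]]
    motif_id <- parts[1]
    rbp_name <- if (length(parts) > 1L) parts[2] else parts[1]
    rows <- lines[(starts[si] + 1L):(starts[si] + 4L)]
    vals <- lapply(rows, function(r) {
      toks <- strsplit(trimws(r), "[\\s\\[\\]:]+", perl = TRUE)[[1]]
      list(base = toupper(toks[1]), v = as.numeric(toks[-1]))
    })
    bases <- vapply(vals, `[[`, "", "base")
    bases[bases == "U"] <- "T"
    m <- do.call(rbind, lapply(vals, `[[`, "v"))
    rownames(m) <- bases
    m <- m[c("A", "C", "G", "T"), , drop = FALSE]
    out[[motif_id]] <- motif_model(motif_id, rbp_name, m,
                                   score_threshold = score_threshold)
  }
  out
}

#' Scan a sequence with a PWM
#'
#' Log-odds score `sum(log2(pwm[b_i, i] / background[b_i]))` at every offset
#' on the given (sense) sequence; ambiguous bases contribute 0. Offsets are
#' 0-based.
#'
#' @param sequence Character sequence (length >= motif width).
#' @param motif A [motif_model()].
#' @return data.frame: `offset` (0-based), `score` (bits), `hit`
#'   (`score >= score_threshold`).
#' @export
scan_pwm <- function(sequence, motif) {
  W <- ncol(motif$lods)
  n <- nchar(sequence)
  stopifnot(n >= W)
  idx <- match(strsplit(toupper(sequence), "")[[1]], c("A", "C", "G", "T"))
  n_off <- n - W + 1L
  scores <- numeric(n_off)
  for (i in seq_len(W)) {
    contrib <- motif$lods[, i][idx[i:(i + n_off - 1L)]]
    contrib[is.na(contrib)] <- 0
    scores <- scores + contrib
  }
  data.frame(offset = seq_len(n_off) - 1L, score = scores,
             hit = scores >= motif$score_threshold)
}

# scannable segments of a gene: exons of the representative transcript plus
# intron flanks (mode "spliced_flanks"), or the full pre-mRNA span
# (mode "premrna"); each segment is genomically contiguous, sense strand
gene_scan_segments <- function(annotation, gene_id, mode = c("spliced_flanks", "premrna"),
                               intron_flank = 250L) {
  mode <- match.arg(mode)
  tx <- representative_transcripts(annotation)[[gene_id]]
  if (is.null(tx)) stop("unknown gene: ", gene_id)
  segs <- list()
  if (mode == "premrna") {
    g <- annotation$genes[annotation$genes$gene_id == gene_id, ]
    segs[[1]] <- c(start = g$start, end = g$end)
  } else {
    ex <- tx$exons
    for (i in seq_len(nrow(ex))) segs[[length(segs) + 1L]] <- c(start = ex$start[i], end = ex$end[i])
    if (nrow(ex) > 1L) {
      for (i in seq_len(nrow(ex) - 1L)) {
        is_ <- ex$end[i]; ie <- ex$start[i + 1L]
        if (ie - is_ <= 2L * intron_flank) {
          segs[[length(segs) + 1L]] <- c(start = is_, end = ie)
        } else {
          segs[[length(segs) + 1L]] <- c(start = is_, end = is_ + intron_flank)
          segs[[length(segs) + 1L]] <- c(start = ie - intron_flank, end = ie)
        }
      }
    }
  }
  contig_seq <- annotation$genome[[tx$contig]]
  do.call(rbind, lapply(segs, function(s) {
    seq <- substr(contig_seq, s["start"] + 1L, s["end"])
    if (tx$strand == "-") seq <- reverse_complement(seq)
    data.frame(contig = tx$contig, start = s["start"], end = s["end"],
               strand = tx$strand, sequence = seq, stringsAsFactors = FALSE)
  }))
}

#' Scan a gene for motif hits
#'
#' Scans the gene's sense-strand sequence universe — by default the spliced
#' exons of the representative transcript plus `intron_flank` nt on each
#' side of every intron; alternatively the full pre-mRNA span — and maps
#' hits back to genomic coordinates with region classes.
#'
#' @param annotation Annotation object.
#' @param gene_id Gene to scan.
#' @param motifs list of [motif_model()]s.
#' @param mode `"spliced_flanks"` (default) or `"premrna"`.
#' @param intron_flank Intron flank length in nt (default 250).
#' @return data.frame of hits: `motif_id`, `rbp_name`, `gene_id`, `contig`,
#'   `start`, `end` (0-based half-open genomic), `strand`, `score`,
#'   `region_class`.
#' @export
scan_gene <- function(annotation, gene_id, motifs,
                      mode = c("spliced_flanks", "premrna"),
                      intron_flank = 250L) {
  mode <- match.arg(mode)
  segs <- gene_scan_segments(annotation, gene_id, mode, intron_flank)
  out <- list()
  for (mi in seq_along(motifs)) {
    mot <- motifs[[mi]]
    W <- ncol(mot$lods)
    for (si in seq_len(nrow(segs))) {
      if (nchar(segs$sequence[si]) < W) next
      sc <- scan_pwm(segs$sequence[si], mot)
      hits <- sc[sc$hit, , drop = FALSE]
      if (nrow(hits) == 0L) next
      # map sense-sequence offset to genomic interval
      if (segs$strand[si] == "+") {
        gs <- segs$start[si] + hits$offset
      } else {
        gs <- segs$end[si] - hits$offset - W
      }
      out[[length(out) + 1L]] <- data.frame(
        motif_id = mot$motif_id, rbp_name = mot$rbp_name, gene_id = gene_id,
        contig = segs$contig[si], start = gs, end = gs + W,
        strand = segs$strand[si], score = hits$score,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(motif_id = character(0), rbp_name = character(0),
                      gene_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      region_class = character(0)))
  }
  res <- unique(do.call(rbind, out))
  res$region_class <- vapply(seq_len(nrow(res)), function(i) {
    classify_region(annotation, res$contig[i], res$start[i], res$end[i])$majority
  }, "")
  rownames(res) <- NULL
  res
}

#' Summarize motif hits by region and by motif
#'
#' @param hits data.frame from [scan_gene()] (rows may span several genes).
#' @return list with `region_distribution` (named fractions over CDS, UTR5,
#'   UTR3, intron; sums to 1 when hits exist) and `motif_ranking`
#'   (data.frame ranked by number of genes hit, ties by total hits then
#'   motif id).
#' @export
summarize_motif_hits <- function(hits) {
  classes <- c("CDS", "UTR5", "UTR3", "intron")
  tab <- table(factor(hits$region_class, levels = classes))
  dist <- if (sum(tab) > 0) as.numeric(tab) / sum(tab) else rep(0, length(classes))
  names(dist) <- classes
  rk <- do.call(rbind, lapply(split(hits, hits$motif_id), function(h) {
    data.frame(motif_id = h$motif_id[1], rbp_name = h$rbp_name[1],
               n_genes = length(unique(h$gene_id)), n_hits = nrow(h),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(rk)) {
    rk <- rk[order(-rk$n_genes, -rk$n_hits, rk$motif_id), , drop = FALSE]
    rownames(rk) <- NULL
  } else {
    rk <- data.frame(motif_id = character(0), rbp_name = character(0),
                     n_genes = integer(0), n_hits = integer(0))
  }
  list(region_distribution = dist, motif_ranking = rk)
}

#' Motif enrichment of an exon relative to its gene
#'
#' Hit densities (hits per kb) inside the exon and gene-wide (pre-mRNA
#' span); enrichment is their ratio. Returns NA when the gene-wide density
#' is 0.
#'
#' @param annotation Annotation object.
#' @param gene_id Gene.
#' @param exon_start,exon_end 0-based half-open exon interval (within the
#'   gene).
#' @param motif A [motif_model()].
#' @return list: `exon_density`, `gene_density` (hits/kb), `enrichment`.
#' @export
exon_motif_enrichment <- function(annotation, gene_id, exon_start, exon_end,
                                  motif) {
  g <- annotation$genes[annotation$genes$gene_id == gene_id, ]
  stopifnot(nrow(g) == 1L, exon_start >= g$start, exon_end <= g$end)
  hits <- scan_gene(annotation, gene_id, list(motif), mode = "premrna")
  gene_len <- g$end - g$start
  exon_len <- exon_end - exon_start
  in_exon <- hits$start >= exon_start & hits$end <= exon_end
  gene_density <- nrow(hits) / (gene_len / 1000)
  exon_density <- sum(in_exon) / (exon_len / 1000)
  list(exon_density = exon_density, gene_density = gene_density,
       enrichment = if (gene_density == 0) NA_real_ else exon_density / gene_density)
}
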