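#' Junction-spanning nucleotide window
#'
#' Extracts up to `flank` spliced bases on each side of a junction, in
#' transcript (coding) orientation — "symmetrically centered" in mRNA space,
#' so the window always crosses the splice. Any transcript sequence between
#' the junction's donor and acceptor (e.g. a skipped cassette exon when the
#' junction is projected onto the inclusion isoform) is excised. Truncation
#' at transcript ends is recorded in `actual_left`/`actual_right`.
#'
#' @param genome Named character vector of contig sequences.
#' @param tx A [transcript_model()] compatible with the junction.
#' @param junction list/row with `donor`, `acceptor` (0-based half-open) and
#'   optionally `junction_id`.
#' @param flank Bases per side (>= 1). 24 for 48-nt peptide windows, 25 for
#'   50-nt neoantigen windows, 300 for single-cell references.
#' @return list with `status` (`"ok"`/`"incompatible"`), `junction_id`,
#'   `flank`, `sequence`, `actual_left`, `actual_right`, `midpoint`
#'   (= `actual_left`; the junction sits between `midpoint` and
#'   `midpoint + 1`).
#' @export
junction_window <- function(genome, tx, junction, flank) {
  stopifnot(flank >= 1L)
  jid <- if (!is.null(junction$junction_id)) junction$junction_id else
    junction_id(tx$contig, junction$donor, junction$acceptor, tx$strand)
  pos <- junction_transcript_pos(tx, junction$donor, junction$acceptor)
  if (pos$status != "ok") {
    return(list(status = "incompatible", junction_id = jid, flank = flank,
                sequence = NA_character_, actual_left = NA_integer_,
                actual_right = NA_integer_, midpoint = NA_integer_))
  }
  s <- spliced_seq(tx, genome)
  actual_left <- min(flank, pos$t_up + 1L)
  actual_right <- min(flank, nchar(s) - pos$t_down)
  left <- substr(s, pos$t_up + 2L - actual_left, pos$t_up + 1L)
  right <- substr(s, pos$t_down + 1L, pos$t_down + actual_right)
  list(status = "ok", junction_id = jid, flank = as.integer(flank),
       sequence = paste0(left, right),
       actual_left = as.integer(actual_left),
       actual_right = as.integer(actual_right),
       midpoint = as.integer(actual_left))
}

#' Derive junction-spanning neopeptides by three-frame translation
#'
#' Each of the three reading frames of the window is translated; peptides are
#' split at stop codons and only fragments whose codon range covers the
#' junction midpoint are retained, so every output peptide crosses the
#' splice and contains no stop character.
#'
#' @param window A [junction_window()] result with `status == "ok"` and
#'   sequence length >= 6.
#' @return list with `junction_id` and `peptides` (data.frame: `frame`,
#'   `peptide`, `spans_junction`).
#' @export
derive_neopeptides <- function(window) {
  stopifnot(window$status == "ok", nchar(window$sequence) >= 6L)
  m <- window$midpoint  # junction lies between nt m and m+1 (1-based bases)
  out <- list()
  for (frame in 0:2) {
    aa <- translate_frame(window$sequence, frame)
    if (nchar(aa) == 0L) next
    runs <- gregexpr("[^*]+", aa)[[1]]
    if (runs[1] == -1L) next
    lens <- attr(runs, "match.length")
    for (ri in seq_along(runs)) {
      i1 <- runs[ri]; i2 <- runs[ri] + lens[ri] - 1L
      nt_start <- frame + 3L * (i1 - 1L)  # 0-based, inclusive
      nt_end <- frame + 3L * i2           # 0-based, exclusive
      if (nt_start < m && nt_end > m) {
        out[[length(out) + 1L]] <- data.frame(
          frame = frame, peptide = substr(aa, i1, i2), spans_junction = TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }
  peptides <- if (length(out)) do.call(rbind, out) else
    data.frame(frame = integer(0), peptide = character(0),
               spans_junction = logical(0))
  list(junction_id = window$junction_id, peptides = peptides)
}

#' Confirm neopeptides against a peptide database with decoy FDR
#'
#' A query peptide matches when it equals, or is a substring of, a database
#' entry. Decoys are the reversed query peptides (palindromic queries get a
#' seeded shuffle instead, so no decoy equals its target). The FDR of the
#' matched set is estimated as (decoy hits)/(target hits); matches pass only
#' when that estimate is at or below `fdr_threshold`.
#'
#' @param neopeptides data.frame with columns `junction_id`, `peptide`.
#' @param peptide_db Character vector of database peptides (non-empty).
#' @param fdr_threshold Maximum decoy-estimated FDR (default 0.05).
#' @param seed Seed for palindrome shuffling.
#' @return data.frame: `junction_id`, `peptide`, `matched`, `decoy_hit`,
#'   `passes_fdr`; the decoy-estimated FDR is attached as attribute
#'   `fdr_estimate`.
#' @export
confirm_peptides <- function(neopeptides, peptide_db, fdr_threshold = 0.05,
                             seed = 1L) {
  if (length(peptide_db) == 0L) stop("peptide_db must be non-empty")
  q <- unique(neopeptides[, c("junction_id", "peptide")])
  rev_str <- function(x) vapply(x, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), "", USE.NAMES = FALSE)
  decoys <- rev_str(q$peptide)
  pal <- decoys == q$peptide
  if (any(pal)) {
    withr::with_seed(seed, {
      for (i in which(pal)) {
        chars <- strsplit(q$peptide[i], "")[[1]]
        for (try in 1:20) {
          d <- paste(sample(chars), collapse = "")
          if (d != q$peptide[i]) break
        }
        decoys[i] <- d
      }
    })
  }
  hit_db <- function(pep) any(vapply(peptide_db, function(dbp)
    pep == dbp || grepl(pep, dbp, fixed = TRUE), TRUE))
  matched <- vapply(q$peptide, hit_db, TRUE, USE.NAMES = FALSE)
  decoy_hit <- vapply(decoys, hit_db, TRUE, USE.NAMES = FALSE)
  n_target <- sum(matched); n_decoy <- sum(decoy_hit)
  fdr <- if (n_target == 0L) ifelse(n_decoy > 0L, 1, 0) else n_decoy / n_target
  res <- data.frame(junction_id = q$junction_id, peptide = q$peptide,
                    matched = matched, decoy_hit = decoy_hit,
                    passes_fdr = matched & fdr <= fdr_threshold,
                    stringsAsFactors = FALSE)
  attr(res, "fdr_estimate") <- fdr
  res
}

#' Per-case confirmed-neojunction summary
#'
#' Given confirmation results and the junction-count table, computes the
#' fraction of tumor samples with at least one confirmed neojunction
#' (a junction with a peptide passing FDR and >= 1 supporting read in that
#' sample) and the mean number of confirmed neojunctions per sample.
#'
#' @param confirmations Output of [confirm_peptides()].
#' @param counts Junction-count data.frame (column `junction_id` + samples).
#' @param tumor_samples Character vector of tumor sample columns.
#' @return list with `fraction_cases_confirmed` and `mean_confirmed_per_case`.
#' @export
per_case_confirmations <- function(confirmations, counts, tumor_samples) {
  confirmed_j <- unique(confirmations$junction_id[confirmations$passes_fdr])
  sub <- counts[counts$junction_id %in% confirmed_j, tumor_samples, drop = FALSE]
  per_case <- if (nrow(sub)) colSums(sub >= 1L) else
    stats::setNames(rep(0L, length(tumor_samples)), tumor_samples)
  list(fraction_cases_confirmed = mean(per_case >= 1L),
       mean_confirmed_per_case = mean(per_case))
}
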