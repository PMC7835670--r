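#' Enumerate junction-spanning HLA candidate peptides
#'
#' All 8-11-mers (configurable) from the three frame translations of a
#' junction window whose codon span covers the junction midpoint and which
#' contain no stop character, deduplicated.
#'
#' @param window A [junction_window()] result (flank 25 per side for 50-nt
#'   neoantigen windows; shorter windows are used as-is).
#' @param lengths Peptide lengths to enumerate (default 8:11).
#' @return data.frame: `junction_id`, `peptide`, `frame`, `length`,
#'   `nt_start` (0-based offset of the coding k-mer within the window).
#' @export
enumerate_candidates <- function(window, lengths = 8:11) {
  stopifnot(window$status == "ok")
  m <- window$midpoint
  out <- list()
  for (frame in 0:2) {
    aa <- translate_frame(window$sequence, frame)
    n_aa <- nchar(aa)
    for (k in lengths) {
      if (n_aa < k) next
      for (i in seq_len(n_aa - k + 1L)) {
        nt_start <- frame + 3L * (i - 1L)
        nt_end <- nt_start + 3L * k
        if (!(nt_start < m && nt_end > m)) next
        pep <- substr(aa, i, i + k - 1L)
        if (grepl("*", pep, fixed = TRUE) || grepl("X", pep, fixed = TRUE)) next
        out[[length(out) + 1L]] <- data.frame(
          junction_id = window$junction_id, peptide = pep,
          frame = frame, length = k, nt_start = nt_start,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(junction_id = character(0), peptide = character(0),
                      frame = integer(0), length = integer(0),
                      nt_start = integer(0)))
  }
  res <- do.call(rbind, out)
  res[!duplicated(res$peptide), , drop = FALSE]
}

# amino-acid alphabet with approximate natural (UniProt-like) frequencies
AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
AA_FREQS <- c(8.25, 5.53, 4.06, 5.45, 1.38, 3.93, 6.72, 7.07, 2.27, 5.91,
              9.65, 5.80, 2.41, 3.86, 4.74, 6.64, 5.35, 1.10, 2.92, 6.86)

#' Random natural-frequency background peptides
#'
#' Seeded background peptides drawn with natural amino-acid frequencies, the
#' reference set against which percent ranks are computed.
#'
#' @param n Number of peptides.
#' @param length Peptide length.
#' @param seed Integer seed.
#' @return Character vector of length `n`.
#' @export
background_peptides <- function(n, length, seed = 1L) {
  withr::with_seed(seed, {
    m <- matrix(sample(AA_LETTERS, n * length, replace = TRUE,
                       prob = AA_FREQS / sum(AA_FREQS)),
                nrow = n)
    apply(m, 1, paste, collapse = "")
  })
}

#' Deterministic mock HLA binding predictor
#'
#' A stateless, seedless stand-in for an external affinity predictor:
#' position-weight scoring where the weight of each (residue, position) pair
#' is a deterministic hash of the allele name, so scores are allele-specific
#' and identical inputs always give identical scores. Higher scores mean
#' stronger predicted binding. External tools can be plugged in via the same
#' interface: `function(peptides, allele) -> numeric scores`.
#'
#' @return A predictor function `f(peptides, allele)`.
#' @export
mock_binding_predictor <- function() {
  allele_hash <- function(allele) {
    h <- 7
    for (c in utf8ToInt(allele)) h <- (h * 131 + c) %% 1000003
    h
  }
  function(peptides, allele) {
    h <- allele_hash(allele)
    vapply(peptides, function(p) {
      cs <- utf8ToInt(p)
      pos <- seq_along(cs)
      w <- ((h * 26543 + pos * 97 + cs * 1009) %% 100003) / 100003
      mean(w)
    }, 0, USE.NAMES = FALSE)
  }
}

#' Percent rank of a binding score against a background
#'
#' `100 * (#background peptides scoring better-or-equal) / (background
#' size)`; lower is stronger. The background should be length-matched to the
#' scored peptide.
#'
#' @param score Affinity score (higher = stronger).
#' @param allele Allele name.
#' @param background Character vector of background peptides (non-empty).
#' @param predictor Predictor function (see [mock_binding_predictor()]).
#' @param background_scores Optional precomputed `predictor(background,
#'   allele)` to avoid rescoring.
#' @return numeric percent rank in \[0, 100\].
#' @export
percent_rank <- function(score, allele, background, predictor,
                         background_scores = NULL) {
  if (is.null(background_scores)) {
    if (length(background) == 0L) stop("background must be non-empty")
    background_scores <- predictor(background, allele)
  }
  100 * mean(background_scores >= score)
}

#' Filter strong-binding neoantigen candidates per patient
#'
#' For every patient, scores each candidate peptide against each of the
#' patient's class-I alleles, computes the percent rank against a seeded
#' length-matched natural-peptide background, and keeps strong binders
#' (percent rank < `threshold`, default 0.5). A single junction may yield
#' multiple neoantigens (several peptides and/or alleles).
#'
#' @param candidates data.frame from [enumerate_candidates()] (columns
#'   `junction_id`, `peptide`; a `patient_id` column restricts each row to
#'   that patient, otherwise all patients are screened against all
#'   candidates).
#' @param serotypes data.frame with `patient_id`, `allele` (long format).
#' @param predictor Predictor function.
#' @param threshold Percent-rank cutoff (default 0.5).
#' @param background_size Background peptides per (allele, length)
#'   (default 10000).
#' @param seed Seed for the background draw.
#' @param keep_all Keep non-strong records too (default FALSE: only strong
#'   binders are returned, so `threshold = 0` gives an empty result).
#' @return data.frame: `patient_id`, `junction_id`, `peptide`, `allele`,
#'   `affinity_score`, `percent_rank`, `strong_binder`.
#' @export
filter_strong_binders <- function(candidates, serotypes, predictor,
                                  threshold = 0.5, background_size = 10000L,
                                  seed = 1L, keep_all = FALSE) {
  patients <- unique(if (!is.null(candidates$patient_id))
    candidates$patient_id else serotypes$patient_id)
  missing <- setdiff(patients, serotypes$patient_id)
  if (length(missing)) stop("no HLA serotype for patient: ", missing[1])
  alleles_all <- unique(serotypes$allele[serotypes$patient_id %in% patients])
  lens <- sort(unique(nchar(candidates$peptide)))
  # background score distributions per (allele, length)
  bg_scores <- list()
  for (L in lens) {
    bg <- background_peptides(background_size, L, seed = seed + L)
    for (al in alleles_all) {
      bg_scores[[paste(al, L)]] <- predictor(bg, al)
    }
  }
  out <- list()
  for (pt in patients) {
    cand <- if (!is.null(candidates$patient_id))
      candidates[candidates$patient_id == pt, , drop = FALSE] else candidates
    if (nrow(cand) == 0L) next
    alleles <- unique(serotypes$allele[serotypes$patient_id == pt])
    for (al in alleles) {
      scores <- predictor(cand$peptide, al)
      ranks <- vapply(seq_len(nrow(cand)), function(i) {
        percent_rank(scores[i], al, background = NULL, predictor = predictor,
                     background_scores = bg_scores[[paste(al, nchar(cand$peptide[i]))]])
      }, 0)
      out[[length(out) + 1L]] <- data.frame(
        patient_id = pt, junction_id = cand$junction_id,
        peptide = cand$peptide, allele = al, affinity_score = scores,
        percent_rank = ranks, strong_binder = ranks < threshold,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(patient_id = character(0), junction_id = character(0),
               peptide = character(0), allele = character(0),
               affinity_score = numeric(0), percent_rank = numeric(0),
               strong_binder = logical(0))
  rownames(res) <- NULL
  if (keep_all) res else res[res$strong_binder, , drop = FALSE]
}
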