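#' Quantifiability thresholds
#'
#' Read-evidence thresholds for PSI quantification, following the usual
#' splice-graph defaults: an LSV is quantifiable in a sample when its total
#' reads exceed `min_reads_lsv` (> 10); de novo (unannotated) junctions are
#' kept only when their reads across all samples exceed `min_denovo_reads`
#' (> 5); a group is quantifiable when the fraction of quantifiable samples
#' exceeds `min_experiments_fraction` (> 0.5). `prior_min_reads_junction`
#' (> 20) is recorded for completeness; the adjustable empirical prior it
#' feeds elsewhere is not reimplemented here (a symmetric Dirichlet prior is
#' used instead).
#'
#' @param min_reads_lsv,prior_min_reads_junction,min_denovo_reads Counts.
#' @param min_experiments_fraction Fraction in (0, 1].
#' @param n_bins Number of equal PSI bins on \[0,1\] for binned posteriors
#'   (default 80; fine enough that the binned dPSI convolution tracks exact
#'   Monte-Carlo posterior sampling to well under 0.01 even for diffuse,
#'   low-count posteriors).
#' @return A `quant_thresholds` list.
#' @export
quant_thresholds <- function(min_reads_lsv = 10L, prior_min_reads_junction = 20L,
                             min_denovo_reads = 5L,
                             min_experiments_fraction = 0.5, n_bins = 80L) {
  stopifnot(min_reads_lsv >= 0L, prior_min_reads_junction >= 0L,
            min_denovo_reads >= 0L, n_bins >= 2L,
            min_experiments_fraction > 0, min_experiments_fraction <= 1)
  structure(list(min_reads_lsv = min_reads_lsv,
                 prior_min_reads_junction = prior_min_reads_junction,
                 min_denovo_reads = min_denovo_reads,
                 min_experiments_fraction = min_experiments_fraction,
                 n_bins = as.integer(n_bins)),
            class = "quant_thresholds")
}

#' Build local splice variations from a junction table
#'
#' Junctions are grouped by shared donor (source LSVs) and by shared acceptor
#' (target LSVs) on the same contig and strand. Junctions absent from the
#' annotation are flagged de novo and dropped when their total reads across
#' all samples do not exceed `min_denovo_reads` (annotated junctions are
#' retained regardless of reads). Groups with fewer than two surviving
#' junctions are not LSVs.
#'
#' @param annotation Annotation object ([generate_reference()] or
#'   [read_cohort()]); known junctions are the exon adjacencies of its
#'   transcripts.
#' @param junction_table data.frame with `junction_id` column (parsed as
#'   `contig:donor-acceptor:strand`) plus per-sample count columns.
#' @param thresholds A [quant_thresholds()].
#' @return list of LSV objects: `lsv_id`, `gene_id`, `kind`
#'   (`"source"`/`"target"`), `anchor` (shared coordinate), `junctions`
#'   (data.frame with `junction_id`, `donor`, `acceptor`, `strand`,
#'   `denovo`).
#' @export
build_lsvs <- function(annotation, junction_table, thresholds = quant_thresholds()) {
  j <- parse_junction_id(junction_table$junction_id)
  unknown <- !j$contig %in% names(annotation$genome)
  if (any(unknown)) {
    stop("junction on unknown contig: ", j$junction_id[unknown][1])
  }
  known <- unlist(lapply(annotation$transcripts, transcript_junction_ids))
  j$denovo <- !j$junction_id %in% known
  count_cols <- setdiff(names(junction_table), "junction_id")
  total <- rowSums(junction_table[, count_cols, drop = FALSE])
  keep <- !j$denovo | total > thresholds$min_denovo_reads
  j <- j[keep, , drop = FALSE]

  gene_of <- function(contig) {
    g <- annotation$genes
    hit <- g$gene_id[g$contig == contig]
    if (length(hit)) hit[1] else NA_character_
  }
  out <- list()
  for (anchor_col in c("donor", "acceptor")) {
    key <- paste(j$contig, j$strand, j[[anchor_col]], sep = "|")
    for (grp in split(seq_len(nrow(j)), key)) {
      if (length(grp) < 2L) next
      sub <- j[grp, , drop = FALSE]
      sub <- sub[order(sub$donor, sub$acceptor), , drop = FALSE]
      # biological kind: a shared genomic-left coordinate is a shared donor
      # on the plus strand but a shared acceptor on the minus strand
      kind <- if ((anchor_col == "donor") == (sub$strand[1] == "+"))
        "source" else "target"
      lsv_id <- sprintf("%s:%d:%s:%s", sub$contig[1], sub[[anchor_col]][1],
                        sub$strand[1], substr(kind, 1, 1))
      out[[lsv_id]] <- list(
        lsv_id = lsv_id, gene_id = gene_of(sub$contig[1]), kind = kind,
        anchor = sub[[anchor_col]][1],
        junctions = sub[, c("junction_id", "donor", "acceptor", "strand", "denovo")])
    }
  }
  if (length(out) == 0L) return(list())
  out[order(names(out))]
}

#' Bayesian PSI posterior for one LSV in one sample
#'
#' Posterior over junction-selection frequencies is Dirichlet(prior + counts)
#' with a symmetric prior of 1/k per junction. Per-junction expectations are
#' the closed-form posterior means; 95% credible intervals and the binned
#' posterior mass come from the Beta marginal
#' Beta(alpha_j, sum(alpha) - alpha_j).
#'
#' @param counts Non-negative integer reads, one per junction (named vector
#'   or column of the LSV's junctions).
#' @param thresholds A [quant_thresholds()]; `quantifiable` is
#'   `sum(counts) > min_reads_lsv` and the binned mass uses `n_bins` bins.
#' @param lsv_id,scope Identifiers carried through (sample or group label).
#' @return A `psi_posterior` list: `lsv_id`, `scope`, `junctions`, `alpha`,
#'   `e_psi`, `ci_low`, `ci_high`, `binned_mass` (k x B matrix, rows sum
#'   to 1), `reads`, `quantifiable`.
#' @export
estimate_psi <- function(counts, thresholds = quant_thresholds(),
                         lsv_id = NA_character_, scope = NA_character_) {
  if (any(counts < 0)) stop("negative junction counts")
  k <- length(counts)
  stopifnot(k >= 2L)
  alpha <- 1 / k + counts
  a0 <- sum(alpha)
  e_psi <- alpha / a0
  ci_low <- stats::qbeta(0.025, alpha, a0 - alpha)
  ci_high <- stats::qbeta(0.975, alpha, a0 - alpha)
  B <- thresholds$n_bins
  breaks <- seq(0, 1, length.out = B + 1L)
  binned <- t(vapply(seq_len(k), function(i) {
    p <- stats::pbeta(breaks, alpha[i], a0 - alpha[i])
    diff(p)
  }, numeric(B)))
  binned <- binned / rowSums(binned)
  jn <- if (!is.null(names(counts))) names(counts) else
    paste0("j", seq_len(k))
  rownames(binned) <- jn
  structure(list(lsv_id = lsv_id, scope = scope, junctions = jn,
                 alpha = as.numeric(alpha), e_psi = as.numeric(e_psi),
                 ci_low = as.numeric(ci_low), ci_high = as.numeric(ci_high),
                 binned_mass = binned, reads = as.numeric(counts),
                 n_bins = B,
                 quantifiable = sum(counts) > thresholds$min_reads_lsv),
            class = "psi_posterior")
}

bin_centers <- function(B) (seq_len(B) - 0.5) / B

#' Pool per-sample PSI posteriors into a group posterior
#'
#' The group binned mass is the arithmetic mean of the quantifiable samples'
#' binned masses (renormalised per junction); the group expectation is the
#' bin-center mean under that mass, renormalised to sum to 1 over junctions.
#' The group is quantifiable when the fraction of quantifiable samples
#' exceeds `min_experiments_fraction`.
#'
#' @param sample_posteriors Non-empty list of [estimate_psi()] results
#'   sharing `lsv_id` and junction order.
#' @param thresholds A [quant_thresholds()].
#' @param scope Group label.
#' @return A `psi_posterior` for the group (no `alpha`; `reads` is the total
#'   across quantifiable samples).
#' @export
group_psi <- function(sample_posteriors, thresholds = quant_thresholds(),
                      scope = "group") {
  if (length(sample_posteriors) == 0L) stop("no sample posteriors supplied")
  lsv_ids <- vapply(sample_posteriors, `[[`, "", "lsv_id")
  if (length(unique(lsv_ids)) != 1L) stop("posteriors from different LSVs")
  juncs <- sample_posteriors[[1]]$junctions
  ok <- vapply(sample_posteriors, function(p) identical(p$junctions, juncs), TRUE)
  if (!all(ok)) stop("mismatched junction order across samples")
  qflag <- vapply(sample_posteriors, `[[`, TRUE, "quantifiable")
  quantifiable <- mean(qflag) > thresholds$min_experiments_fraction
  use <- if (any(qflag)) sample_posteriors[qflag] else sample_posteriors
  B <- use[[1]]$n_bins
  mass <- Reduce(`+`, lapply(use, `[[`, "binned_mass")) / length(use)
  mass <- mass / rowSums(mass)
  cb <- bin_centers(B)
  e_raw <- as.numeric(mass %*% cb)
  e_psi <- e_raw / sum(e_raw)
  ci <- t(vapply(seq_len(nrow(mass)), function(i) {
    cm <- cumsum(mass[i, ])
    lo <- cb[which(cm >= 0.025)[1]]
    hi <- cb[which(cm >= 0.975)[1]]
    c(max(0, lo - 0.5 / B), min(1, hi + 0.5 / B))
  }, numeric(2)))
  structure(list(lsv_id = use[[1]]$lsv_id, scope = scope, junctions = juncs,
                 alpha = NULL, e_psi = e_psi,
                 ci_low = pmin(ci[, 1], e_psi), ci_high = pmax(ci[, 2], e_psi),
                 binned_mass = mass,
                 reads = Reduce(`+`, lapply(use, `[[`, "reads")),
                 n_bins = B, quantifiable = quantifiable),
            class = "psi_posterior")
}

#' Differential PSI between two group posteriors
#'
#' Per junction, the distribution of dPSI = PSI_a - PSI_b is obtained by
#' discrete cross-correlation of the two binned masses under an independence
#' assumption. Within each bin pair the mass is spread as the difference of
#' two within-bin uniforms (a triangular kernel of half-width one bin) rather
#' than a point mass, which removes the discretisation error at the
#' `|dPSI| > dpsi_threshold` boundary. `e_dpsi` is the expectation (the
#' kernel is mean-zero, so it equals the bin-center expectation), `p_change`
#' the mass where |dPSI| > `dpsi_threshold`, and a junction is significant
#' when |E(dPSI)| > `dpsi_threshold` and `p_change >= confidence`.
#'
#' @param group_a,group_b Quantifiable group posteriors sharing junction
#'   order.
#' @param dpsi_threshold Change threshold (default 0.1).
#' @param confidence Posterior confidence level (default 0.95).
#' @return data.frame: `lsv_id`, `junction_id`, `e_dpsi`, `p_change`,
#'   `significant`.
#' @export
delta_psi <- function(group_a, group_b, dpsi_threshold = 0.1,
                      confidence = 0.95) {
  if (!identical(group_a$junctions, group_b$junctions)) {
    stop("mismatched junction sets between groups")
  }
  B <- group_a$n_bins
  stopifnot(B == group_b$n_bins)
  cb <- bin_centers(B)
  dmat <- outer(cb, cb, `-`)          # dPSI at (bin_a, bin_b)
  w <- 1 / B
  # CDF of the triangular kernel on [-w, w]
  tri_cdf <- function(x) {
    x <- pmin(w, pmax(-w, x))
    ifelse(x <= 0, (x + w)^2 / (2 * w^2), 1 - (w - x)^2 / (2 * w^2))
  }
  t <- dpsi_threshold
  change <- (1 - tri_cdf(t - dmat)) + tri_cdf(-t - dmat)
  res <- lapply(seq_along(group_a$junctions), function(i) {
    joint <- outer(group_a$binned_mass[i, ], group_b$binned_mass[i, ])
    data.frame(lsv_id = group_a$lsv_id,
               junction_id = group_a$junctions[i],
               e_dpsi = sum(joint * dmat),
               p_change = sum(joint * change),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$significant <- abs(out$e_dpsi) > dpsi_threshold & out$p_change >= confidence
  out
}

# posterior mass above a PSI floor from a binned marginal, with fractional
# weight for the bin containing the floor
mass_above <- function(mass_row, floor, B) {
  lo <- seq(0, 1 - 1 / B, by = 1 / B)
  hi <- lo + 1 / B
  frac <- pmin(1, pmax(0, (hi - floor) / (hi - lo)))
  sum(mass_row * frac)
}

#' Tumor-specific neojunction call
#'
#' A junction passes when (1) it has exactly zero supporting reads in every
#' normal sample — the only observable event compatible with PSI = 0 with
#' certainty — and (2) the tumor posterior puts at least `confidence` mass on
#' PSI > `psi_floor`. In `"group"` mode (default) criterion (2) is evaluated
#' on the pooled tumor posterior; in `"per-sample"` mode it must hold in more
#' than half of the quantifiable tumor samples.
#'
#' @param junction_id Junction to call (must be in the posterior).
#' @param normal_counts Named per-normal-sample read counts for the junction.
#' @param tumor_group Pooled tumor `psi_posterior` (group mode), or list of
#'   per-sample posteriors (per-sample mode).
#' @param psi_floor PSI floor (default 0.1, i.e. expected absolute PSI
#'   > 10%).
#' @param confidence Required posterior mass (default 0.95).
#' @param normal_samples Optional full roster of normal sample names; a
#'   missing column is a hard error.
#' @param mode `"group"` or `"per-sample"`.
#' @return list: `junction_id`, `normal_total_reads`,
#'   `tumor_p_psi_gt_threshold`, `group_e_psi`, `passes`.
#' @export
call_tumor_specific <- function(junction_id, normal_counts, tumor_group,
                                psi_floor = 0.1, confidence = 0.95,
                                normal_samples = NULL, mode = c("group", "per-sample")) {
  mode <- match.arg(mode)
  if (!is.null(normal_samples)) {
    missing <- setdiff(normal_samples, names(normal_counts))
    if (length(missing)) {
      stop("missing normal sample column: ", missing[1])
    }
    normal_counts <- normal_counts[normal_samples]
  }
  if (mode == "group") {
    stopifnot(inherits(tumor_group, "psi_posterior"))
    i <- match(junction_id, tumor_group$junctions)
    if (is.na(i)) stop("junction not in tumor posterior: ", junction_id)
    p <- mass_above(tumor_group$binned_mass[i, ], psi_floor, tumor_group$n_bins)
    e <- tumor_group$e_psi[i]
  } else {
    qs <- Filter(function(x) x$quantifiable, tumor_group)
    if (length(qs) == 0L) qs <- tumor_group
    tails <- vapply(qs, function(post) {
      i <- match(junction_id, post$junctions)
      if (is.na(i)) stop("junction not in tumor posterior: ", junction_id)
      mass_above(post$binned_mass[i, ], psi_floor, post$n_bins)
    }, 0)
    p <- mean(tails >= confidence)
    e <- mean(vapply(qs, function(post)
      post$e_psi[match(junction_id, post$junctions)], 0))
  }
  normal_total <- sum(normal_counts)
  passes <- normal_total == 0 &&
    (if (mode == "group") p >= confidence else p > 0.5)
  list(junction_id = junction_id, normal_total_reads = as.integer(normal_total),
       tumor_p_psi_gt_threshold = p, group_e_psi = e, passes = passes)
}
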