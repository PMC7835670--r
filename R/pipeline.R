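#' Quantify PSI, dPSI and tumor specificity across a cohort
#'
#' Builds LSVs from the junction-count table, estimates per-sample and
#' per-group PSI posteriors, computes differential PSI between the two
#' groups, and applies the tumor-specific neojunction filter to every
#' junction of every LSV with a quantifiable tumor group. A junction that
#' appears in both a source and a target LSV is called tumor-specific when
#' it passes in at least one of them (the strongest tumor evidence is
#' reported).
#'
#' @param annotation Annotation object.
#' @param counts Junction-count data.frame (`junction_id` + sample columns).
#' @param tumor_samples,normal_samples Sample column names per group.
#' @param thresholds A [quant_thresholds()].
#' @param psi_floor Tumor-side PSI floor (default 0.1).
#' @param dpsi_threshold,confidence dPSI criterion (default |E(dPSI)| > 0.1
#'   at 95%).
#' @param mode Tumor-evidence mode for [call_tumor_specific()].
#' @return list: `lsvs`, `psi` (per lsv x junction x group table), `dpsi`,
#'   `calls` (per lsv x junction), `junction_calls` (aggregated per
#'   junction).
#' @export
quantify_cohort <- function(annotation, counts, tumor_samples, normal_samples,
                            thresholds = quant_thresholds(), psi_floor = 0.1,
                            dpsi_threshold = 0.1, confidence = 0.95,
                            mode = c("group", "per-sample")) {
  mode <- match.arg(mode)
  missing <- setdiff(c(tumor_samples, normal_samples), names(counts))
  if (length(missing)) stop("missing sample column: ", missing[1])
  lsvs <- build_lsvs(annotation, counts, thresholds)
  cmat <- as.matrix(counts[, c(tumor_samples, normal_samples), drop = FALSE])
  rownames(cmat) <- counts$junction_id
  psi_rows <- list(); dpsi_rows <- list(); call_rows <- list()
  for (lsv in lsvs) {
    jids <- lsv$junctions$junction_id
    sub <- cmat[jids, , drop = FALSE]
    post_of <- function(smp) estimate_psi(
      stats::setNames(sub[, smp], jids), thresholds,
      lsv_id = lsv$lsv_id, scope = smp)
    tum <- lapply(tumor_samples, post_of)
    nor <- lapply(normal_samples, post_of)
    g_tum <- group_psi(tum, thresholds, scope = "tumor")
    g_nor <- group_psi(nor, thresholds, scope = "normal")
    for (g in list(g_tum, g_nor)) {
      psi_rows[[length(psi_rows) + 1L]] <- data.frame(
        lsv_id = lsv$lsv_id, junction_id = g$junctions, scope = g$scope,
        e_psi = g$e_psi, ci_low = g$ci_low, ci_high = g$ci_high,
        quantifiable = g$quantifiable, stringsAsFactors = FALSE)
    }
    if (g_tum$quantifiable && g_nor$quantifiable) {
      dpsi_rows[[length(dpsi_rows) + 1L]] <-
        delta_psi(g_tum, g_nor, dpsi_threshold, confidence)
    }
    if (g_tum$quantifiable) {
      for (jid in jids) {
        cl <- call_tumor_specific(
          jid, normal_counts = sub[jid, normal_samples],
          tumor_group = if (mode == "group") g_tum else tum,
          psi_floor = psi_floor, confidence = confidence,
          normal_samples = normal_samples, mode = mode)
        call_rows[[length(call_rows) + 1L]] <- data.frame(
          lsv_id = lsv$lsv_id, junction_id = jid,
          normal_total_reads = cl$normal_total_reads,
          tumor_p_psi_gt_threshold = cl$tumor_p_psi_gt_threshold,
          group_e_psi = cl$group_e_psi, passes = cl$passes,
          stringsAsFactors = FALSE)
      }
    }
  }
  calls <- if (length(call_rows)) do.call(rbind, call_rows) else
    data.frame(lsv_id = character(0), junction_id = character(0),
               normal_total_reads = integer(0),
               tumor_p_psi_gt_threshold = numeric(0),
               group_e_psi = numeric(0), passes = logical(0))
  jc <- if (nrow(calls)) {
    do.call(rbind, lapply(split(calls, calls$junction_id), function(h) {
      best <- h[order(-h$tumor_p_psi_gt_threshold), , drop = FALSE][1, ]
      data.frame(junction_id = best$junction_id,
                 normal_total_reads = best$normal_total_reads,
                 tumor_p_psi_gt_threshold = best$tumor_p_psi_gt_threshold,
                 group_e_psi = best$group_e_psi, passes = any(h$passes),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(junction_id = character(0), normal_total_reads = integer(0),
               tumor_p_psi_gt_threshold = numeric(0), group_e_psi = numeric(0),
               passes = logical(0))
  }
  rownames(jc) <- NULL
  list(lsvs = lsvs,
       psi = do.call(rbind, psi_rows),
       dpsi = if (length(dpsi_rows)) do.call(rbind, dpsi_rows) else
         data.frame(lsv_id = character(0), junction_id = character(0),
                    e_dpsi = numeric(0), p_change = numeric(0),
                    significant = logical(0)),
       calls = calls, junction_calls = jc)
}

# biological event class of one LSV
classify_lsv <- function(lsv, annotation, ir_junctions = character(0)) {
  if (any(lsv$junctions$junction_id %in% ir_junctions)) return("intron retention")
  jn <- lsv$junctions
  gene <- lsv$gene_id
  exons <- unique(do.call(rbind, lapply(
    Filter(function(tx) tx$gene_id == gene, annotation$transcripts),
    function(tx) tx$exons)))
  widest <- jn[which.max(jn$acceptor - jn$donor), ]
  inside <- exons$start >= widest$donor & exons$end <= widest$acceptor
  if (any(inside)) return("exon skipping")
  strand <- jn$strand[1]
  # varying coordinate: the non-anchor side
  anchor_is_left <- (lsv$kind == "source") == (strand == "+")
  varying <- if (anchor_is_left) jn$acceptor else jn$donor
  same_exon <- function(cs, right_side) {
    hit <- vapply(cs, function(c) {
      w <- if (right_side) which(exons$start <= c & c < exons$end) else
        which(exons$start < c & c <= exons$end)
      if (length(w)) w[1] else NA_integer_
    }, 1L)
    !anyNA(hit) && length(unique(hit)) == 1L
  }
  if (same_exon(varying, right_side = anchor_is_left)) {
    # varying biological acceptors for a source LSV -> alternative 3' site
    return(if (lsv$kind == "source") "alternative 3'" else "alternative 5'")
  }
  "other"
}

#' Proportions of alternative-splicing event types
#'
#' Classifies each LSV from splice-graph geometry: exon skipping (an
#' annotated exon lies fully inside the widest junction), alternative 5'/3'
#' splice sites (the non-anchor coordinates vary within one annotated exon),
#' intron retention (only when supplied pre-called), otherwise "other".
#'
#' @param lsvs list of LSVs from [build_lsvs()].
#' @param annotation Annotation object.
#' @param ir_junctions Junction ids pre-called as intron retention.
#' @return Named numeric vector of proportions (sums to 1).
#' @export
event_type_proportions <- function(lsvs, annotation, ir_junctions = character(0)) {
  if (length(lsvs) == 0L) stop("no events")
  classes <- vapply(lsvs, classify_lsv, "", annotation = annotation,
                    ir_junctions = ir_junctions)
  lev <- c("exon skipping", "alternative 5'", "alternative 3'",
           "intron retention", "other")
  tab <- table(factor(classes, levels = lev))
  as.numeric(tab) / sum(tab) -> p
  stats::setNames(p, lev)
}

#' Run the full target-discovery pipeline on a synthetic cohort
#'
#' Orchestrates simulate -> quantify -> call -> map -> derive -> screen ->
#' filter -> scan with a single config. The nomination cascade applies
#' filters in order: tumor-specific, then surface/extracellular, then
#' neoplastic-specific (when the single-cell stage is on), with
#' peptide-confirmation and strong-binder evidence reported alongside
#' (and required only when `require_confirmed`).
#'
#' @param config A [sim_config()].
#' @param thresholds A [quant_thresholds()].
#' @param psi_floor,dpsi_threshold,confidence Quantification thresholds.
#' @param fdr_threshold Decoy-FDR threshold for peptide confirmation.
#' @param rank_threshold Percent-rank cutoff for strong binders.
#' @param min_overhang Single-cell matcher overhang (nt per side).
#' @param peptide_flank,neoantigen_flank,reference_flank Window half-widths
#'   (nt): 24 (48-nt peptide windows), 25 (50-nt neoantigen windows), 300
#'   (600-nt single-cell references).
#' @param background_size Neoantigen background peptides per (allele,
#'   length).
#' @param predictor Binding predictor (default [mock_binding_predictor()]).
#' @param motifs list of [motif_model()]s; default is the bundled toy set.
#' @param stages Named logical toggles: `sc_screen`, `confirm`, `neoantigen`,
#'   `motifs`.
#' @param require_confirmed Require peptide confirmation for nomination.
#' @param outdir Optional directory; when given, every stage artifact is
#'   written (TSV/FASTA/BED/MTX).
#' @param verbose Emit per-stage record counts via `message()`.
#' @return list with all stage results, `target_report` (per-junction flag
#'   table), `summaries` (event-type proportions, per-case confirmations,
#'   neoantigen counts by patient) and `log` (per-stage record counts).
#' @export
run_pipeline <- function(config, thresholds = quant_thresholds(),
                         psi_floor = 0.1, dpsi_threshold = 0.1,
                         confidence = 0.95, fdr_threshold = 0.05,
                         rank_threshold = 0.5, min_overhang = 10L,
                         peptide_flank = 24L, neoantigen_flank = 25L,
                         reference_flank = 300L, background_size = 10000L,
                         predictor = mock_binding_predictor(), motifs = NULL,
                         stages = list(sc_screen = TRUE, confirm = TRUE,
                                       neoantigen = TRUE, motifs = TRUE),
                         require_confirmed = FALSE, outdir = NULL,
                         verbose = FALSE) {
  log <- list()
  note <- function(stage, n) {
    log[[stage]] <<- n
    if (verbose) message(sprintf("[%s] %d records", stage, n))
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  on <- function(s) isTRUE(stages[[s]])
  if (!is.null(outdir) && !dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  put <- function(df, name) if (!is.null(outdir)) write_tsv(df, file.path(outdir, name))

  annotation <- run_stage("simulate", generate_reference(config))
  note("simulate", nrow(annotation$events))
  counts <- run_stage("counts", simulate_junction_counts(config, annotation))
  note("counts", nrow(counts))
  tumor_samples <- sprintf("tumor%02d", seq_len(config$n_tumor_samples))
  normal_samples <- sprintf("normal%02d", seq_len(config$n_normal_samples))
  if (!is.null(outdir)) {
    write_cohort(annotation, file.path(outdir, "reference"))
    write_junction_counts(counts, file.path(outdir, "junction_counts.tsv"))
  }

  q <- run_stage("quantify", quantify_cohort(
    annotation, counts, tumor_samples, normal_samples, thresholds,
    psi_floor, dpsi_threshold, confidence))
  note("quantify", nrow(q$psi))
  note("dpsi", nrow(q$dpsi))
  put(q$psi, "psi.tsv"); put(q$dpsi, "dpsi.tsv"); put(q$calls, "neojunction_calls.tsv")

  jc <- q$junction_calls
  candidates <- jc$junction_id[jc$passes]
  note("tumor_specific", length(candidates))

  # --- domain mapping on the representative transcript -------------------
  reps <- representative_transcripts(annotation)
  jt <- annotation$junctions
  loci <- run_stage("map_domains", {
    rows <- lapply(candidates, function(jid) {
      row <- jt[jt$junction_id == jid, , drop = FALSE]
      gene <- if (nrow(row)) row$gene_id[1] else {
        p <- parse_junction_id(jid)
        annotation$genes$gene_id[annotation$genes$contig == p$contig][1]
      }
      p <- parse_junction_id(jid)
      loc <- junction_protein_locus(
        list(junction_id = jid, donor = p$donor, acceptor = p$acceptor),
        reps[[gene]], annotation$domains)
      data.frame(junction_id = jid, gene_id = gene,
                 transcript_id = loc$transcript_id, status = loc$status,
                 aa_position = loc$aa_position, frame = loc$frame,
                 domain_label = ifelse(is.null(loc$domain_label), NA, loc$domain_label),
                 is_surface_protein = loc$is_surface_protein,
                 stringsAsFactors = FALSE)
    })
    if (length(rows)) do.call(rbind, rows) else
      data.frame(junction_id = character(0), gene_id = character(0),
                 transcript_id = character(0), status = character(0),
                 aa_position = integer(0), frame = integer(0),
                 domain_label = character(0), is_surface_protein = logical(0))
  })
  note("map_domains", nrow(loci))
  put(loci, "protein_loci.tsv")

  # --- junction peptides + confirmation ----------------------------------
  window_of <- function(jid, flank) {
    row <- loci[loci$junction_id == jid, ]
    p <- parse_junction_id(jid)
    junction_window(annotation$genome, reps[[row$gene_id[1]]],
                    list(junction_id = jid, donor = p$donor, acceptor = p$acceptor),
                    flank)
  }
  confirmations <- NULL; peptides <- NULL; conf_summary <- NULL
  if (on("confirm")) {
    res <- run_stage("confirm", {
      wins <- lapply(candidates, window_of, flank = peptide_flank)
      peps <- do.call(rbind, lapply(wins, function(w) {
        if (w$status != "ok") return(NULL)
        np <- derive_neopeptides(w)
        if (nrow(np$peptides) == 0L) return(NULL)
        cbind(junction_id = np$junction_id, np$peptides)
      }))
      db <- simulate_peptide_db(config, annotation, flank = peptide_flank)
      conf <- if (!is.null(peps) && nrow(peps))
        confirm_peptides(peps, db, fdr_threshold, seed = config$seed) else
        data.frame(junction_id = character(0), peptide = character(0),
                   matched = logical(0), decoy_hit = logical(0),
                   passes_fdr = logical(0))
      list(peptides = peps, confirmations = conf,
           summary = per_case_confirmations(conf, counts, tumor_samples))
    })
    peptides <- res$peptides; confirmations <- res$confirmations
    conf_summary <- res$summary
    note("confirm", nrow(confirmations))
    put(confirmations, "confirmations.tsv")
    if (!is.null(outdir) && !is.null(peptides) && nrow(peptides)) {
      write_windows_fasta(peptides, file.path(outdir, "neopeptides.fa"))
    }
  }

  # --- single-cell specificity screen ------------------------------------
  sc <- NULL; frequencies <- NULL
  if (on("sc_screen")) {
    sc <- run_stage("sc_screen", {
      reads <- simulate_sc_reads(config, annotation)
      refs <- junction_references(annotation, candidates, reference_flank)
      mat <- if (!is.null(refs) && nrow(refs))
        match_sc_reads(reads$reads, refs, reads$cells, min_overhang) else NULL
      freqs <- if (!is.null(mat)) cell_type_frequencies(mat) else NULL
      list(reads = reads, references = refs, matrix = mat, frequencies = freqs)
    })
    frequencies <- sc$frequencies
    note("sc_screen", if (is.null(frequencies)) 0L else nrow(frequencies))
    if (!is.null(outdir) && !is.null(sc$matrix)) {
      write_cell_junction_matrix(sc$matrix, file.path(outdir, "cell_junction"))
      put(frequencies, "cell_type_frequencies.tsv")
      write_fastq_reads(sc$reads$reads, file.path(outdir, "sc_reads.fastq"))
      write_tsv(sc$reads$cells, file.path(outdir, "cells.tsv"))
    }
  }

  # --- HLA neoantigen filtering ------------------------------------------
  neoantigens <- NULL; serotypes <- NULL
  if (on("neoantigen")) {
    res <- run_stage("neoantigen", {
      sero <- simulate_serotypes(config)
      cand <- do.call(rbind, lapply(candidates, function(jid) {
        w <- window_of(jid, neoantigen_flank)
        if (w$status != "ok") return(NULL)
        enumerate_candidates(w)
      }))
      strong <- if (!is.null(cand) && nrow(cand))
        filter_strong_binders(cand, sero, predictor, rank_threshold,
                              background_size, seed = config$seed) else
        filter_strong_binders(data.frame(junction_id = character(0),
                                         peptide = character(0)),
                              sero, predictor, rank_threshold,
                              background_size, seed = config$seed)
      list(serotypes = sero, candidates = cand, strong = strong)
    })
    serotypes <- res$serotypes; neoantigens <- res$strong
    note("neoantigen", nrow(neoantigens))
    put(neoantigens, "neoantigens.tsv")
    if (!is.null(outdir)) put(serotypes, "serotypes.tsv")
  }

  # --- motif scanning over differentially spliced genes ------------------
  motif_hits <- NULL; motif_summary <- NULL
  if (on("motifs")) {
    res <- run_stage("motifs", {
      if (is.null(motifs)) {
        motifs <- read_pwms(system.file("extdata", "toy_motifs.txt",
                                        package = "neosplice"))
      }
      sig_j <- unique(q$dpsi$junction_id[q$dpsi$significant])
      genes <- unique(c(jt$gene_id[jt$junction_id %in% sig_j],
                        loci$gene_id))
      genes <- genes[!is.na(genes)]
      hits <- do.call(rbind, lapply(genes, function(g)
        scan_gene(annotation, g, motifs)))
      list(hits = hits, summary = if (!is.null(hits) && nrow(hits))
        summarize_motif_hits(hits) else NULL)
    })
    motif_hits <- res$hits; motif_summary <- res$summary
    note("motifs", if (is.null(motif_hits)) 0L else nrow(motif_hits))
    if (!is.null(outdir) && !is.null(motif_hits) && nrow(motif_hits)) {
      write_hits_bed(motif_hits, file.path(outdir, "motif_hits.bed"))
    }
  }

  # --- target report ------------------------------------------------------
  report <- run_stage("report", {
    tumor_cols <- as.matrix(counts[, tumor_samples, drop = FALSE])
    rownames(tumor_cols) <- counts$junction_id
    rows <- lapply(seq_len(nrow(jc)), function(i) {
      jid <- jc$junction_id[i]
      ts <- jc$passes[i]
      li <- loci[loci$junction_id == jid, , drop = FALSE]
      surface <- if (nrow(li)) isTRUE(li$is_surface_protein[1]) else NA
      extra <- if (nrow(li)) identical(li$domain_label[1], "extracellular") else NA
      neo_sp <- if (on("sc_screen") && !is.null(frequencies) && ts)
        neoplastic_specific(jid, frequencies) else NA
      conf <- if (on("confirm") && !is.null(confirmations) && ts)
        any(confirmations$passes_fdr[confirmations$junction_id == jid]) else NA
      nsb <- if (on("neoantigen") && !is.null(neoantigens))
        sum(neoantigens$junction_id == jid) else NA_integer_
      popf <- mean(tumor_cols[jid, ] >= 1L)
      nominated <- isTRUE(ts) && isTRUE(surface) && isTRUE(extra) &&
        (!on("sc_screen") || isTRUE(neo_sp)) &&
        (!require_confirmed || isTRUE(conf))
      data.frame(junction_id = jid, tumor_specific = ts,
                 surface_protein = surface, extracellular = extra,
                 neoplastic_specific = neo_sp, confirmed_peptide = conf,
                 n_strong_binders = nsb, population_frequency = popf,
                 car_nominated = nominated, stringsAsFactors = FALSE)
    })
    if (length(rows)) do.call(rbind, rows) else
      data.frame(junction_id = character(0), tumor_specific = logical(0),
                 surface_protein = logical(0), extracellular = logical(0),
                 neoplastic_specific = logical(0), confirmed_peptide = logical(0),
                 n_strong_binders = integer(0), population_frequency = numeric(0),
                 car_nominated = logical(0))
  })
  note("report", nrow(report))
  put(report, "target_report.tsv")

  summaries <- list(
    event_type_proportions = event_type_proportions(q$lsvs, annotation),
    per_case_confirmations = conf_summary,
    neoantigen_counts_by_patient = if (!is.null(neoantigens) && nrow(neoantigens))
      table(neoantigens$patient_id) else NULL,
    n_neoantigens = if (is.null(neoantigens)) NA_integer_ else nrow(neoantigens))

  list(annotation = annotation, counts = counts, quant = q, loci = loci,
       peptides = peptides, confirmations = confirmations, sc = sc,
       serotypes = serotypes, neoantigens = neoantigens,
       motif_hits = motif_hits, motif_summary = motif_summary,
       target_report = report, summaries = summaries, log = log)
}
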