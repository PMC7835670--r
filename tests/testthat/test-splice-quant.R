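test_that("PSI posterior matches the closed-form Dirichlet update", {
  p <- estimate_psi(c(10, 30))
  expect_equal(p$e_psi, c(10.5 / 41, 30.5 / 41), tolerance = 1e-12)
  expect_equal(round(p$e_psi, 4), c(0.2561, 0.7439))
  expect_true(p$quantifiable)

  # zero counts: prior mean, not quantifiable
  p0 <- estimate_psi(c(0, 0))
  expect_equal(p0$e_psi, c(0.5, 0.5))
  expect_false(p0$quantifiable)

  # deep counts concentrate: check against the Beta quantile oracle
  pd <- estimate_psi(c(2500, 7500))
  expect_lt(max(abs(pd$e_psi - c(0.25, 0.75))), 0.001)
  expect_lt(max(pd$ci_high - pd$ci_low), 0.02)
  a <- 0.5 + 2500; b <- 0.5 + 7500
  expect_equal(pd$ci_low[1], qbeta(0.025, a, b), tolerance = 1e-9)
  expect_equal(pd$ci_high[1], qbeta(0.975, a, b), tolerance = 1e-9)

  expect_error(estimate_psi(c(-1, 5)), "negative")
})

test_that("posterior normalisation and monotonicity hold on random counts", {
  withr::with_seed(99, {
    for (rep in 1:30) {
      k <- sample(2:4, 1)
      counts <- rpois(k, lambda = sample(c(0, 3, 40, 400), 1))
      p <- estimate_psi(counts)
      expect_lt(abs(sum(p$e_psi) - 1), 1e-9)
      expect_true(all(abs(rowSums(p$binned_mass) - 1) < 1e-9))
      expect_true(all(p$ci_low <= p$e_psi + 1e-12 &
                        p$e_psi <= p$ci_high + 1e-12))
      # adding reads to junction j never decreases e_psi_j
      j <- sample(k, 1)
      bumped <- counts; bumped[j] <- bumped[j] + sample(1:20, 1)
      expect_gte(estimate_psi(bumped)$e_psi[j], p$e_psi[j])
    }
  })
})

test_that("LSV construction groups junctions by shared splice sites", {
  ann <- generate_reference(tiny_config(seed = 51, n_genes = 4))
  # three junctions sharing one donor on one contig of the toy genome
  ctg <- ann$genes$contig[1]
  strand <- ann$genes$strand[1]
  known <- unlist(lapply(ann$transcripts, neosplice:::transcript_junction_ids))
  known_p <- parse_junction_id(known[startsWith(known, ctg)])
  d <- known_p$donor[1]
  tbl <- data.frame(
    junction_id = c(junction_id(ctg, d, d + 100L, strand),
                    junction_id(ctg, d, d + 200L, strand),
                    junction_id(ctg, d, d + 300L, strand)),
    s1 = c(50L, 40L, 30L))
  # these shifted junctions are unannotated: give them reads above min_denovo
  lsvs <- build_lsvs(ann, tbl)
  src <- Filter(function(l) nrow(l$junctions) == 3L, lsvs)
  expect_length(src, 1)

  # annotated junction with zero reads is retained; de novo low-read dropped
  tbl2 <- data.frame(
    junction_id = c(known_p$junction_id[1], known_p$junction_id[2],
                    junction_id(ctg, known_p$donor[1], known_p$acceptor[1] + 7L, strand)),
    s1 = c(0L, 0L, 5L))
  lsvs2 <- build_lsvs(ann, tbl2)
  all_j <- unlist(lapply(lsvs2, function(l) l$junctions$junction_id))
  expect_true(known_p$junction_id[1] %in% c(all_j, known))
  expect_false(tbl2$junction_id[3] %in% all_j)  # 5 reads <= min_denovo of 5

  # a single-junction group yields no LSV
  tbl3 <- data.frame(junction_id = known_p$junction_id[1], s1 = 100L)
  expect_length(build_lsvs(ann, tbl3), 0)

  # unknown contig is a hard error naming the junction
  tbl4 <- data.frame(junction_id = "nowhere:10-90:+", s1 = 10L)
  expect_error(build_lsvs(ann, tbl4), "nowhere:10-90")
})

test_that("group pooling averages binned posteriors with quantifiability vote", {
  th <- quant_thresholds()
  p <- estimate_psi(c(20, 40), th, lsv_id = "L1", scope = "s1")
  g <- group_psi(list(p, p, p), th)
  expect_equal(g$binned_mass, p$binned_mass, tolerance = 1e-12)
  expect_equal(g$e_psi, p$e_psi, tolerance = 1 / p$n_bins)

  # 2 of 10 quantifiable -> group not quantifiable (0.2 <= 0.5)
  lo <- estimate_psi(c(1, 2), th, lsv_id = "L1", scope = "lo")
  posts <- c(list(p, p), rep(list(lo), 8))
  expect_false(group_psi(posts, th)$quantifiable)
  expect_true(group_psi(rep(list(p), 8), th)$quantifiable)

  # two near-point-masses at 0.2 and 0.8 average to ~0.5
  a <- estimate_psi(c(2000, 8000), th, lsv_id = "L1", scope = "a")
  b <- estimate_psi(c(8000, 2000), th, lsv_id = "L1", scope = "b")
  g2 <- group_psi(list(a, b), th)
  expect_lt(abs(g2$e_psi[1] - 0.5), 1 / g2$n_bins)

  expect_error(group_psi(list()), "no sample posteriors")
  p2 <- estimate_psi(c(5, 5), th, lsv_id = "other", scope = "x")
  expect_error(group_psi(list(p, p2)), "different LSVs")
})

test_that("dPSI convolution is symmetric and matches a Monte-Carlo oracle", {
  th <- quant_thresholds()
  g <- group_psi(list(estimate_psi(c(30, 70), th, lsv_id = "L", scope = "s")), th)
  d0 <- delta_psi(g, g)
  expect_equal(d0$e_dpsi, c(0, 0), tolerance = 1e-12)
  expect_false(any(d0$significant))

  # near-point-masses at 0.9 vs 0.2
  ga <- group_psi(list(estimate_psi(c(9000, 1000), th, lsv_id = "L", scope = "a")), th)
  gb <- group_psi(list(estimate_psi(c(2000, 8000), th, lsv_id = "L", scope = "b")), th)
  d <- delta_psi(ga, gb)
  expect_lt(abs(d$e_dpsi[1] - 0.7), 1 / th$n_bins)
  expect_gt(d$p_change[1], 0.99)

  # Monte-Carlo oracle on moderate posteriors, 1e6 draws
  withr::with_seed(7, {
    for (case in list(c(12, 25, 9, 14), c(4, 4, 5, 6))) {
      pa <- estimate_psi(case[1:2], th, lsv_id = "L", scope = "a")
      pb <- estimate_psi(case[3:4], th, lsv_id = "L", scope = "b")
      d1 <- delta_psi(group_psi(list(pa), th), group_psi(list(pb), th))
      xa <- rbeta(1e6, pa$alpha[1], pa$alpha[2])
      xb <- rbeta(1e6, pb$alpha[1], pb$alpha[2])
      expect_lt(abs(d1$e_dpsi[1] - mean(xa - xb)), 0.01)
      expect_lt(abs(d1$p_change[1] - mean(abs(xa - xb) > 0.1)), 0.01)
    }
  })

  gx <- group_psi(list(estimate_psi(c(1, 2, 3), th, lsv_id = "L", scope = "x")), th)
  expect_error(delta_psi(g, gx), "mismatched")
})

test_that("tumor-specific calls enforce zero normal reads and tumor tail mass", {
  th <- quant_thresholds()
  tumor <- group_psi(list(estimate_psi(stats::setNames(c(5, 55), c("jr", "ja")),
                                       th, lsv_id = "L", scope = "t")), th)
  normals <- stats::setNames(rep(0L, 10), sprintf("normal%02d", 1:10))

  # quadrature oracle for the tumor tail: P(PSI > 0.1) under Beta(55.5, 5.5)
  tail_oracle <- 1 - pbeta(0.1, 55.5, 5.5)
  cl <- call_tumor_specific("ja", normals, tumor)
  expect_true(cl$passes)
  expect_gt(tail_oracle, 0.999)
  expect_lt(abs(cl$tumor_p_psi_gt_threshold - tail_oracle), 0.01)

  # one single normal read vetoes regardless of tumor evidence
  one_read <- normals; one_read[3] <- 1L
  expect_false(call_tumor_specific("ja", one_read, tumor)$passes)

  # weak tumor evidence (1 of 60 reads) fails the 95% tail criterion
  weak <- group_psi(list(estimate_psi(stats::setNames(c(59, 1), c("jr", "ja")),
                                      th, lsv_id = "L", scope = "t")), th)
  cl2 <- call_tumor_specific("ja", normals, weak)
  expect_false(cl2$passes)
  expect_lt(1 - pbeta(0.1, 1.5, 59.5), 0.95)  # oracle agrees the tail is small

  # missing normal sample column is a hard error
  expect_error(call_tumor_specific("ja", normals[1:9], tumor,
                                   normal_samples = names(normals)),
               "normal10")

  # per-sample mode flag
  posts <- lapply(1:6, function(i)
    estimate_psi(stats::setNames(c(5, 55), c("jr", "ja")), th,
                 lsv_id = "L", scope = paste0("t", i)))
  expect_true(call_tumor_specific("ja", normals, posts, mode = "per-sample")$passes)
})

test_that("credible intervals are calibrated on simulated LSVs", {
  # sample-level truth drawn Beta around a group PSI; coverage of the 95% CI
  withr::with_seed(2024, {
    n <- 400; cover <- logical(n)
    for (i in 1:n) {
      p_group <- runif(1, 0.1, 0.9)
      psi_true <- rbeta(1, 50 * p_group, 50 * (1 - p_group))
      depth <- rpois(1, 100)
      alt <- rbinom(1, depth, psi_true)
      post <- estimate_psi(c(depth - alt, alt))
      cover[i] <- post$ci_low[2] <= psi_true & psi_true <= post$ci_high[2]
    }
    expect_gte(mean(cover), 0.90)
    expect_lte(mean(cover), 0.98)
  })
})
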