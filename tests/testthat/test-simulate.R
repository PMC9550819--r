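test_that("the same seed reproduces the cohort byte for byte", {
  co1 <- generate_cohort(cohort_config(seed = 5, n_samples = 30, n_se = 40,
                                       n_active_se_per_cluster = 5,
                                       n_genes = 60,
                                       n_linked_genes_per_cluster = 5,
                                       n_bystander_genes_per_cluster = 5))
  co2 <- generate_cohort(cohort_config(seed = 5, n_samples = 30, n_se = 40,
                                       n_active_se_per_cluster = 5,
                                       n_genes = 60,
                                       n_linked_genes_per_cluster = 5,
                                       n_bystander_genes_per_cluster = 5))
  expect_identical(co1, co2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(co1, d1); write_cohort(co2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("degenerate k = 1 yields a single all-identical labeling", {
  co <- generate_cohort(cohort_config(seed = 2, n_samples = 12, n_clusters = 1,
                                      n_se = 20, n_active_se_per_cluster = 4,
                                      n_genes = 30,
                                      n_linked_genes_per_cluster = 4,
                                      n_bystander_genes_per_cluster = 4,
                                      baseline_hazard = 0.05))
  expect_length(unique(co$truth$labels), 1)
})

test_that("planted links are strongly correlated at the default conditions", {
  co <- cached_cohort(seed = 1, n_samples = 300)
  se_l2 <- unclass(expr_log2(co$se_rna))
  mr_l2 <- unclass(expr_log2(co$mrna))
  r <- vapply(seq_len(nrow(co$truth$links)), function(i) {
    cor(se_l2[co$truth$links$se_id[i], ], mr_l2[co$truth$links$gene_id[i], ])
  }, numeric(1))
  expect_gte(mean(r > 0.5), 0.95)
})

test_that("genomic layout puts true links inside the window and decoys outside", {
  co <- cached_cohort(seed = 1, n_samples = 300)
  pairs <- candidate_pairs(co$se_regions, co$tss_table,
                           window_bp = co$config$window_bp)
  link_keys <- paste(co$truth$links$se_id, co$truth$links$gene_id)
  expect_true(all(link_keys %in% paste(pairs$se_id, pairs$gene_id)))
  decoys <- grep("^G_D", co$tss_table$gene_id, value = TRUE)
  expect_false(any(pairs$gene_id %in% decoys))
})

test_that("driver motifs are planted at the configured rate and recoverable", {
  co <- cached_cohort(seed = 1, n_samples = 300)
  for (c in seq_len(co$config$n_clusters)) {
    linked <- co$truth$links$gene_id[co$truth$links$cluster == c]
    drv <- co$truth$driver_tfs[[c]]
    cons <- pwm_consensus(co$pwms[[drv]])
    frac <- mean(vapply(linked, function(g) {
      grepl(cons, co$promoters[[g]], fixed = TRUE) ||
        grepl(revcomp(cons), co$promoters[[g]], fixed = TRUE)
    }, logical(1)))
    expect_gte(frac, co$config$motif_plant_rate)
  }
  # planted positions are recorded and scanning recovers them
  mp <- co$truth$motif_positions
  row <- mp[1, ]
  hits <- pwm_scan(co$promoters[[row$gene_id]], co$pwms[[row$motif_id]],
                   threshold_frac = 0.9)
  expect_true(row$position %in% hits$position)
})

test_that("plant_motif substitutes the consensus in place", {
  p <- pwm("AC", rbind(c(9, 0, 0, 0), c(0, 9, 0, 0)), pseudocount = 0.001)
  expect_equal(plant_motif("TTTT", p, 0), "ACTT")
  expect_equal(plant_motif("TTTT", p, 2), "TTAC")
  expect_error(plant_motif("TTTT", p, 3), "out of range")
})

test_that("survival generation matches the exponential model", {
  labels <- rep(1L, 10000)
  s <- generate_survival(labels, hazards = 0.1, censor_rate = 0, seed = 4)
  expect_true(all(s$event == 1))
  expect_lt(abs(median(s$time) - log(2) / 0.1) / (log(2) / 0.1), 0.05)
  expect_error(generate_survival(labels, hazards = -1), "hazards")
})

test_that("uniform censoring hits the requested rate in expectation", {
  labels <- rep(1:2, each = 4000)
  s <- generate_survival(labels, hazards = c(0.05, 0.1), censor_rate = 0.3,
                         seed = 8)
  expect_lt(abs(mean(s$event == 0) - 0.3), 0.03)
})

test_that("a zero-effect cohort carries no recoverable cluster structure", {
  co <- generate_cohort(cohort_config(seed = 3, n_samples = 60, n_se = 60,
                                      n_active_se_per_cluster = 8,
                                      n_genes = 60,
                                      n_linked_genes_per_cluster = 5,
                                      n_bystander_genes_per_cluster = 5,
                                      se_activation_effect = 0,
                                      signature_effect = 0,
                                      baseline_hazard = c(0.05, 0.05, 0.05)))
  res <- consensus_cluster(co$se_rna, k = 3, n_resamples = 60, seed = 12,
                           top_features = 60)
  expect_lt(abs(adjusted_rand(res$labels, co$truth$labels)), 0.2)
})
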