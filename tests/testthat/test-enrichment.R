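test_that("overlap test reproduces the closed-form point-mass case", {
  u <- sprintf("g%02d", 1:20)
  res <- fisher_overlap(u[1:5], u[1:5], u)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$n_overlap, 5)

  res0 <- fisher_overlap(u[1:3], u[10:12], u)
  expect_equal(res0$n_overlap, 0)
  expect_equal(res0$p, 1)
  expect_error(fisher_overlap(c(u[1], "zz"), u[1:2], u), "zz")
})

test_that("overlap tail equals brute-force enumeration for small universes", {
  for (n in c(1:10, 15, 20, 25, 30)) {
    u <- sprintf("u%02d", seq_len(n))
    for (a in unique(c(0, 1, n %/% 3, n %/% 2, n))) {
      for (b in unique(c(0, 1, n %/% 2, n))) {
        lo <- max(0, a + b - n)
        for (k in unique(c(lo, (lo + min(a, b)) %/% 2, min(a, b)))) {
          set_a <- u[seq_len(a)]
          set_b <- u[c(seq_len(k), if (b > k) a + seq_len(b - k))]
          res <- fisher_overlap(set_a, set_b, u)
          expect_equal(res$p, hyper_tail_oracle(n, a, b, k),
                       tolerance = 1e-12,
                       info = sprintf("n=%d a=%d b=%d k=%d", n, a, b, k))
        }
      }
    }
  }
})

test_that("SE-regulated calling gates by direction", {
  u <- sprintf("g%d", 1:100)
  spgs <- u[1:10]
  up <- u[5:20]; down <- u[90:100]
  r_up <- se_regulated_genes(spgs, up, down, "up", u)
  expect_setequal(r_up$genes, u[5:10])
  r_down <- se_regulated_genes(spgs, up, down, "down", u)
  expect_length(r_down$genes, 0)
  expect_gte(r_down$overlap$p, 0.5)
  expect_error(se_regulated_genes(spgs, up, down, "up", character()),
               "empty universe")
})

test_that("PWM scanning scores log2-odds with strand symmetry", {
  p <- pwm("AC", rbind(c(97, 1, 1, 1), c(1, 97, 1, 1)), pseudocount = 0)
  hits <- pwm_scan("AC", p, threshold_frac = 1)
  expect_equal(hits$score[hits$strand == "+"], 2 * log2(0.97 / 0.25),
               tolerance = 1e-12)
  # GT is the reverse complement of AC: maximal on the minus strand
  m_hits <- pwm_scan("GT", p, threshold_frac = 1)
  expect_equal(m_hits$strand, "-")
  expect_equal(m_hits$score, 2 * log2(0.97 / 0.25), tolerance = 1e-12)

  expect_equal(nrow(pwm_scan("GGGG", p, threshold_frac = 1)), 0)
  expect_equal(nrow(pwm_scan("A", p)), 0)  # motif longer than sequence
})

test_that("scan scores are involutive under reverse complement", {
  withr::with_seed(17, {
    for (i in 1:10) {
      counts <- matrix(runif(6 * 4, 1, 50), 6, 4)
      p <- pwm(paste0("m", i), counts, pseudocount = 0.01)
      s <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                 collapse = "")
      h1 <- pwm_scan(s, p, threshold_frac = 0.1)
      h2 <- pwm_scan(revcomp(s), p, threshold_frac = 0.1)
      expect_equal(sort(h1$score), sort(h2$score), tolerance = 1e-10)
    }
  })
})

test_that("N bases contribute the background score", {
  p <- pwm("AC", rbind(c(97, 1, 1, 1), c(1, 97, 1, 1)), pseudocount = 0)
  h <- pwm_scan("NC", p, threshold_frac = 0.4)
  expect_equal(max(h$score[h$position == 0 & h$strand == "+"]),
               log2(0.97 / 0.25), tolerance = 1e-12)
})

test_that("planted driver motifs dominate the enrichment ranking", {
  co <- cached_cohort(seed = 1, n_samples = 300)
  for (cl in 1:3) {
    fg <- co$truth$links$gene_id[co$truth$links$cluster == cl]
    en <- motif_enrichment(fg, promoters = co$promoters, pwms = co$pwms)
    expect_equal(en$motif_id[1], co$truth$driver_tfs[[cl]])
    expect_lt(en$q[1], 0.05)
  }
})

test_that("motifs absent from all promoters give p = 1", {
  p <- pwm("ACGTACGT",
           counts = {
             m <- matrix(1, 8, 4)
             m[cbind(1:8, rep(1:4, 2))] <- 97
             m
           }, pseudocount = 0)
  promoters <- c(g1 = "TTTTTTTTTTTT", g2 = "TTTTTTTTTTTT",
                 g3 = "TTTTTTTTTTTT")
  en <- motif_enrichment("g1", promoters = promoters, pwms = list(p),
                         threshold_frac = 1)
  expect_equal(en$fg_hits + en$bg_hits, 0L)
  expect_equal(en$p, 1)
  expect_error(motif_enrichment(c("g1"), c("g1", "g2"), promoters, list(p)),
               "disjoint")
  expect_warning(motif_enrichment(c("g1", "gX"), c("g2", "g3"),
                                  promoters, list(p)), "without a promoter")
})

test_that("enrichment p-values are calibrated under a shared background", {
  co <- cached_cohort(seed = 2)
  frac_sig <- vapply(1:20, function(s) {
    withr::with_seed(100 + s, {
      bg_pool <- names(co$promoters)[!names(co$promoters) %in%
                                       co$truth$links$gene_id]
      fg <- sample(bg_pool, 25)
      bg <- sample(setdiff(bg_pool, fg), 200)
      en <- motif_enrichment(fg, bg, co$promoters, co$pwms)
      mean(en$p <= 0.05)
    })
  }, numeric(1))
  expect_lte(mean(frac_sig), 0.07)
})
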