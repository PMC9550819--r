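surv_tab <- function(time, event, ids = sprintf("s%d", seq_along(time))) {
  tibble::tibble(sample_id = ids, time = time, event = event)
}

test_that("product-limit estimates match hand calculations", {
  all_cens <- km_estimate(surv_tab(c(1, 2, 3), c(0, 0, 0)))
  expect_true(all(all_cens$survival == 1))

  one_event <- km_estimate(surv_tab(c(1, 2, 3, 4), c(1, 0, 0, 0)))
  expect_equal(one_event$survival[one_event$time == 1], 0.75)

  hand <- km_estimate(surv_tab(c(1, 2, 3, 4), c(1, 0, 1, 0)))
  expect_equal(hand$survival[hand$time == 1], 0.75)
  expect_equal(hand$survival[hand$time == 3], 0.375)

  expect_error(km_estimate(surv_tab(numeric(), numeric())), "no survival")
})

test_that("with no censoring the KM curve is the empirical survival function", {
  withr::with_seed(2, {
    t <- round(rexp(40, 0.2), 3)
    km <- km_estimate(surv_tab(t, rep(1, 40)))
    emp <- vapply(km$time, function(u) mean(t > u), numeric(1))
    expect_equal(km$survival, emp, tolerance = 1e-12)
  })
})

test_that("log-rank contracts: null identity, df, and error on empty groups", {
  # two groups with identical time/event patterns
  rec <- surv_tab(rep(c(1, 2, 3, 4), 2), rep(c(1, 0, 1, 1), 2))
  lr <- logrank_test(rec, rep(c("a", "b"), each = 4))
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)

  rec3 <- surv_tab(1:9, rep(1, 9))
  lr3 <- logrank_test(rec3, rep(c("a", "b", "c"), 3))
  expect_equal(lr3$df, 2L)

  expect_error(logrank_test(rec3, rep("a", 9)), ">= 2")
})

test_that("log-rank equals the independent O-E/V oracle to 1e-10", {
  rec <- surv_tab(c(1, 2, 3, 4), c(1, 1, 1, 1))
  grp <- c("A", "A", "B", "B")
  lr <- logrank_test(rec, grp)
  expect_equal(lr$chi2, logrank_oracle(rec$time, rec$event, grp),
               tolerance = 1e-10)

  withr::with_seed(8, {
    for (i in 1:5) {
      n <- 30
      rec <- surv_tab(round(rexp(n, 0.1), 2), rbinom(n, 1, 0.8))
      grp <- sample(c("A", "B", "C"), n, replace = TRUE)
      lr <- logrank_test(rec, grp)
      expect_equal(lr$chi2, logrank_oracle(rec$time, rec$event, grp),
                   tolerance = 1e-8)
    }
  })
})

test_that("two-group chi2 is the squared standardized O-E statistic", {
  withr::with_seed(14, {
    rec <- surv_tab(round(rexp(24, 0.2), 2), rbinom(24, 1, 0.7))
    grp <- rep(c("A", "B"), 12)
    lr <- logrank_test(rec, grp)
    # the oracle computes (O-E)' V^{-1} (O-E), which for k=2 is z^2
    expect_equal(lr$chi2, logrank_oracle(rec$time, rec$event, grp),
                 tolerance = 1e-10)
  })
})

test_that("log-rank is invariant to relabeling and pre-event censoring", {
  withr::with_seed(21, {
    rec <- surv_tab(round(rexp(20, 0.2), 2) + 1, rbinom(20, 1, 0.8))
    grp <- rep(c("A", "B"), 10)
    lr1 <- logrank_test(rec, grp)
    lr2 <- logrank_test(rec, ifelse(grp == "A", "zz", "aa"))
    expect_equal(lr1$chi2, lr2$chi2, tolerance = 1e-12)
    # a sample censored before the first event never enters a risk set
    first_event <- min(rec$time[rec$event == 1])
    rec_plus <- dplyr::bind_rows(rec,
                                 surv_tab(first_event / 2, 0, "early"))
    lr3 <- logrank_test(rec_plus, c(grp, "A"))
    expect_equal(lr3$chi2, lr1$chi2, tolerance = 1e-12)
  })
})

test_that("signature scoring is a mean of per-gene z-scores", {
  m <- matrix(2^matrix(c(5, 6, 7, 4, 6, 8), 2, byrow = TRUE), 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  x <- expr_matrix(m)
  s1 <- signature_score(x, "g1")
  z <- scale(log2(m[1, ] + 1))[, 1]
  expect_equal(s1$score, unname(z))
  expect_equal(s1$n_genes_used, rep(1L, 3), ignore_attr = TRUE)

  # shift invariance: adding a constant to one gene's log2 values
  m2 <- m; m2["g2", ] <- 2^(log2(m["g2", ] + 1) + 3) - 1
  both1 <- signature_score(x, c("g1", "g2"))
  both2 <- signature_score(expr_matrix(m2), c("g1", "g2"))
  expect_equal(both1$score, both2$score, tolerance = 1e-10)

  expect_error(signature_score(x, "absent"), "no signature gene")
  m3 <- rbind(m, g3 = 7)
  expect_warning(s3 <- signature_score(expr_matrix(m3), c("g1", "g3")),
                 "zero-variance")
  expect_equal(s3$n_genes_used, rep(1L, 3), ignore_attr = TRUE)
})

test_that("the planted signature is elevated in the worst-prognosis cluster", {
  co <- cached_cohort(seed = 1, n_samples = 300)
  sc <- signature_score(co$mrna, co$truth$signature_genes)
  worst <- co$truth$labels[sc$sample_id] == co$truth$worst_cluster
  expect_gt(mean(sc$score[worst]), mean(sc$score[!worst]))
  p <- wilcox.test(sc$score[worst], sc$score[!worst],
                   alternative = "greater")$p.value
  expect_lte(p, 0.01)
})

test_that("stratified reports validate ids and group counts", {
  rec <- surv_tab(c(1, 2, 3, 4), c(1, 1, 0, 1))
  expect_error(stratified_km_report(rec, groups = rep("a", 4)), ">= 2 groups")
  expect_error(stratified_km_report(rec,
                                    groups = c(s1 = "a", s2 = "b", s9 = "a")),
               "unmatched|no group")
  expect_error(stratified_km_report(rec), "exactly one")

  idx <- tibble::tibble(sample_id = rec$sample_id, index = c(-1, -2, 3, 4))
  rep <- stratified_km_report(rec, index = idx)
  expect_setequal(unique(rep$groups), c("high", "low"))
  expect_s3_class(rep$logrank, "logrank_result")
})
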