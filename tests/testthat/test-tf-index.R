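tf_ids <- sprintf("TF%02d", 1:20)

# one moderately sized fit shared by the structural tests below
.fit_cache <- new.env(parent = emptyenv())
fit_seed2 <- function() {
  if (is.null(.fit_cache$fit)) {
    co <- cached_cohort(seed = 2)
    .fit_cache$fit <- fit_core_tfs(co$mrna, co$truth$labels,
                                   candidate_tfs = tf_ids, n_folds = 5,
                                   seed = 4)
  }
  .fit_cache$fit
}

test_that("planted drivers are selected as the per-cluster core TFs", {
  co <- cached_cohort(seed = 1, n_samples = 300)
  m <- fit_core_tfs(co$mrna, co$truth$labels, candidate_tfs = tf_ids,
                    seed = 1)
  expect_equal(unname(m$core_tfs),
               unlist(co$truth$driver_tfs), ignore_attr = TRUE)
  expect_true(all(unlist(co$truth$driver_tfs) %in% m$selected_tfs))
  expect_equal(m$index_cluster, 3)
})

test_that("single-cluster labels cannot be fit", {
  co <- cached_cohort(seed = 2)
  expect_error(fit_core_tfs(co$mrna, rep(1, ncol(co$mrna)),
                            candidate_tfs = tf_ids), ">= 2 clusters")
})

test_that("duplicated driver columns: exactly one of the pair is selected", {
  co <- cached_cohort(seed = 2)
  m <- unclass(co$mrna)
  dup <- rbind(m[tf_ids[1:6], ], TF01_copy = m["TF01", ])
  x <- expr_matrix(dup)
  fit <- fit_core_tfs(x, co$truth$labels, n_folds = 5, seed = 3)
  # within the contrast where the duplicated driver is informative, exactly
  # one member of the pair carries the weight
  w1 <- fit$weights[c("TF01", "TF01_copy"), "1"]
  expect_equal(sum(w1 != 0), 1)
})

test_that("noise candidates yield an empty model with a warning", {
  withr::with_seed(77, {
    n <- 60
    m <- matrix(2^rnorm(5 * n, 6), 5,
                dimnames = list(paste0("N", 1:5), sprintf("s%02d", 1:n)))
    labels <- rep(1:2, each = n / 2)
    warns <- capture_warnings(
      fit <- fit_core_tfs(expr_matrix(m), labels, n_folds = 5, seed = 1))
    expect_true(any(grepl("all LASSO weights are zero", warns)))
    expect_true(any(is.na(fit$core_tfs)))
  })
})

manual_model <- function(weights, intercepts, tfs, clusters = c(1, 2)) {
  structure(list(candidate_tfs = tfs, clusters = clusters,
                 weights = weights,
                 intercepts = setNames(intercepts, clusters),
                 lambdas = setNames(rep(0.1, length(clusters)), clusters),
                 center = setNames(rep(6, length(tfs)), tfs),
                 scale = setNames(rep(1, length(tfs)), tfs),
                 core_tfs = setNames(rep(tfs[1], length(clusters)), clusters),
                 selected_tfs = tfs[rowSums(weights != 0) > 0],
                 index_cluster = clusters[length(clusters)]),
            class = "tf_index_model")
}

test_that("the index is the weighted z-score combination it claims to be", {
  tfs <- c("A", "B")
  w <- matrix(c(0, 0, 1, 0), 2, dimnames = list(tfs, c("1", "2")))
  model <- manual_model(w, c(0, 0), tfs)
  expr <- expr_matrix(
    matrix(2^c(5, 7, 6, 6), 2, dimnames = list(tfs, c("s1", "s2"))),
    scale_tag = "raw")
  idx <- build_tf_index(model, expr)
  z <- log2(unclass(expr) + 1)["A", ] - 6
  expect_equal(idx$index, unname(z), tolerance = 1e-12)

  w0 <- matrix(0, 2, 2, dimnames = list(tfs, c("1", "2")))
  model0 <- manual_model(w0, c(0, 0), tfs)
  expect_equal(build_tf_index(model0, expr)$index, c(0, 0))

  missing_expr <- expr_matrix(matrix(2^6, 1, dimnames = list("B", "s1")))
  expect_error(build_tf_index(model, missing_expr), "missing model TF.*A")
})

test_that("identical per-cluster models predict cluster 1 by the tie rule", {
  tfs <- c("A", "B")
  w <- matrix(c(0.5, 0.2, 0.5, 0.2), 2, dimnames = list(tfs, c("1", "2")))
  model <- manual_model(w, c(0.3, 0.3), tfs)
  expr <- expr_matrix(
    matrix(2^c(5, 7, 6, 6), 2, dimnames = list(tfs, c("s1", "s2"))))
  pred <- predict_clusters(model, expr)
  expect_true(all(pred$cluster == 1))
})

test_that("predictions are equivariant under sample permutation", {
  co <- cached_cohort(seed = 2)
  fit <- fit_seed2()
  p1 <- predict_clusters(fit, co$mrna)
  perm <- withr::with_seed(6, sample(ncol(co$mrna)))
  mp <- expr_matrix(unclass(co$mrna)[, perm])
  p2 <- predict_clusters(fit, mp)
  expect_equal(p2$cluster, p1$cluster[perm])
})

test_that("the index separates the worst-prognosis cluster", {
  co <- cached_cohort(seed = 1, n_samples = 300)
  fit <- fit_core_tfs(co$mrna, co$truth$labels, candidate_tfs = tf_ids,
                      seed = 1)
  idx <- build_tf_index(fit, co$mrna)
  lab3 <- co$truth$labels[idx$sample_id] == 3
  auc <- mean(outer(idx$index[lab3], idx$index[!lab3], ">")) +
    0.5 * mean(outer(idx$index[lab3], idx$index[!lab3], "=="))
  expect_gte(auc, 0.95)
  # prediction accuracy: near the Bayes bound (~0.87 at a 2 SD shift)
  pred <- predict_clusters(fit, co$mrna)
  expect_gte(mean(pred$cluster == co$truth$labels[pred$sample_id]), 0.8)
})

test_that("rescaling a non-selected TF leaves the index unchanged", {
  co <- cached_cohort(seed = 2)
  fit <- fit_seed2()
  unused <- setdiff(tf_ids, fit$selected_tfs)[1]
  skip_if(is.na(unused), "all candidate TFs selected")
  idx1 <- build_tf_index(fit, co$mrna)
  m <- unclass(co$mrna)
  m[unused, ] <- m[unused, ] * 5 + 3
  idx2 <- build_tf_index(fit, expr_matrix(m))
  expect_equal(idx2$index, idx1$index, tolerance = 1e-12)
})
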