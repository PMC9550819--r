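# Shared synthetic cohorts, generated once per test run and cached by
# configuration so unit and acceptance tests reuse the same objects.
.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(seed = 1, n_samples = 150, ...) {
  key <- paste(seed, n_samples, paste(deparse(list(...)), collapse = ""),
               sep = "|")
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- generate_cohort(
      cohort_config(seed = seed, n_samples = n_samples, ...))
  }
  .cohort_cache[[key]]
}

# small well-separated 2-D blobs for clustering tests
make_blobs <- function(n_per = 10, centers = rbind(c(0, 0), c(20, 0), c(0, 20)),
                       sd = 0.2, seed = 42) {
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))
    }))
    rownames(x) <- sprintf("S%02d", seq_len(nrow(x)))
    list(x = x, labels = rep(seq_len(nrow(centers)), each = n_per))
  })
}
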