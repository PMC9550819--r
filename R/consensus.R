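#' K-means with k-means++ seeding and restarts
#'
#' Lloyd iterations (via [stats::kmeans()]) from k-means++ initialization,
#' keeping the best of `n_init` restarts by within-cluster sum of squares.
#' Deterministic given `seed`.
#'
#' @param x samples x features numeric matrix.
#' @param k number of clusters; must not exceed the number of distinct rows.
#' @param seed integer seed.
#' @param n_init number of restarts.
#' @param max_iter Lloyd iteration cap per restart.
#' @return list with `labels` (length n), `centers` (k x p), `inertia`
#'   (total within-cluster sum of squares).
#' @export
kmeans_fit <- function(x, k, seed = 1, n_init = 10, max_iter = 100) {
  x <- as.matrix(x)
  if (nrow(x) == 0 || ncol(x) == 0) abort("empty matrix")
  if (any(!is.finite(x))) abort("non-finite values in clustering input")
  n_distinct <- nrow(unique(x))
  if (k > n_distinct) {
    abort(sprintf("k = %d exceeds the %d distinct rows", k, n_distinct))
  }
  best <- NULL
  for (r in seq_len(n_init)) {
    fit <- with_substream(seed, paste0("kmeans_restart_", r), {
      centers <- kmeanspp_init(x, k)
      tryCatch(
        stats::kmeans(x, centers = centers, iter.max = max_iter,
                      algorithm = "Lloyd"),
        error = function(e) NULL,
        warning = function(w) suppressWarnings(
          stats::kmeans(x, centers = centers, iter.max = max_iter,
                        algorithm = "Lloyd")))
    })
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) abort("k-means failed in every restart")
  list(labels = unname(best$cluster), centers = unname(best$centers),
       inertia = best$tot.withinss)
}

# k-means++ seeding: first center uniform, then points with probability
# proportional to squared distance from the nearest chosen center.
#' @noRd
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums(sweep(x, 2, x[idx[1], ], "-")^2)
    for (j in 2:k) {
      if (all(d2 <= 0)) {
        pool <- setdiff(which(!duplicated(x)), idx)
        idx[j] <- if (length(pool) > 1) sample(pool, 1) else pool
      } else {
        idx[j] <- sample.int(n, 1, prob = d2 / sum(d2))
      }
      d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[j], ], "-")^2))
    }
  }
  x[idx, , drop = FALSE]
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement; 1 for identical partitions,
#' about 0 for independent ones.
#'
#' @param labels_a,labels_b equal-length label vectors (any atomic type).
#' @return a number in `[-1, 1]`.
#' @export
adjusted_rand <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort("labelings have different lengths")
  }
  tab <- table(labels_a, labels_b)
  comb2 <- function(m) sum(m * (m - 1) / 2)
  sum_ij <- comb2(tab)
  sum_a <- comb2(rowSums(tab))
  sum_b <- comb2(colSums(tab))
  n_pairs <- comb2(length(labels_a))
  expected <- sum_a * sum_b / n_pairs
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' Feature preparation for clustering
#'
#' log2-transforms a raw matrix, keeps the `top_features` features with the
#' largest median absolute deviation, and z-scores each retained feature.
#' Zero-MAD features are dropped.
#'
#' @param x an [expr_matrix()].
#' @param top_features number of MAD-ranked features to keep.
#' @return samples x features numeric matrix ready for [kmeans_fit()].
#' @export
prep_features <- function(x, top_features = 2000) {
  stopifnot(inherits(x, "expr_matrix"))
  m <- unclass(expr_log2(x))
  mads <- apply(m, 1, mad)
  keep <- order(mads, decreasing = TRUE)[seq_len(min(top_features, nrow(m)))]
  keep <- keep[mads[keep] > 0]
  if (length(keep) == 0) abort("no features with positive MAD")
  m <- m[keep, , drop = FALSE]
  ctr <- rowMeans(m)
  scl <- apply(m, 1, sd)
  t((m - ctr) / scl)
}

#' Consensus clustering at a fixed k
#'
#' Resampled K-means consensus: in each resample, a fraction of samples is
#' drawn without replacement, clustered with [kmeans_fit()], and co-cluster /
#' co-sample counts accumulated. `consensus(i, j)` is the fraction of
#' resamples containing both i and j in which they co-clustered. Final labels
#' come from average-linkage hierarchical clustering of `1 - consensus` cut
#' into k groups (deterministic, no K-means re-run).
#'
#' @param x an [expr_matrix()] (prepared via [prep_features()]) or an already
#'   prepared samples x features matrix.
#' @param k number of clusters.
#' @param n_resamples number of subsampled clustering runs.
#' @param subsample_frac fraction of samples per resample, in (0, 1].
#' @param seed integer seed.
#' @param n_init K-means restarts per resample.
#' @param top_features passed to [prep_features()] when `x` is an
#'   `expr_matrix`.
#' @param pac_lower,pac_upper bounds of the ambiguous consensus band used for
#'   the PAC statistic.
#' @return a `consensus_result`: list with `k`, `consensus`,
#'   `cosample_counts`, `labels` (named by sample), `pac`, `cdf_area`,
#'   `consensus_values` (upper triangle, sorted), `n_resamples`.
#' @export
consensus_cluster <- function(x, k, n_resamples = 1000, subsample_frac = 0.8,
                              seed = 1, n_init = 1, top_features = 2000,
                              pac_lower = 0.1, pac_upper = 0.9) {
  if (inherits(x, "expr_matrix")) x <- prep_features(x, top_features)
  if (n_resamples < 1) abort("n_resamples must be >= 1")
  if (subsample_frac <= 0 || subsample_frac > 1) {
    abort("subsample_frac must be in (0, 1]")
  }
  n <- nrow(x)
  ids <- rownames(x) %||% sprintf("S%03d", seq_len(n))
  m <- ceiling(subsample_frac * n)
  co_cluster <- matrix(0L, n, n)
  co_sample <- matrix(0L, n, n)
  for (r in seq_len(n_resamples)) {
    idx <- with_substream(seed, paste0("subsample_", r),
                          sort(sample.int(n, m)))
    fit <- kmeans_fit(x[idx, , drop = FALSE], k,
                      seed = substream_seed(seed, paste0("fit_", r)),
                      n_init = n_init)
    co_sample[idx, idx] <- co_sample[idx, idx] + 1L
    for (g in seq_len(k)) {
      members <- idx[fit$labels == g]
      co_cluster[members, members] <- co_cluster[members, members] + 1L
    }
  }
  consensus <- matrix(0, n, n)
  seen <- co_sample > 0
  consensus[seen] <- co_cluster[seen] / co_sample[seen]
  if (any(!seen[upper.tri(seen)])) {
    warn("some sample pairs were never co-sampled; their consensus is 0")
  }
  dimnames(consensus) <- list(ids, ids)
  labels <- cutree(hclust(as.dist(1 - consensus), method = "average"), k)
  names(labels) <- ids
  vals <- sort(consensus[upper.tri(consensus)])
  pac <- mean(vals <= pac_upper) - mean(vals <= pac_lower)
  # area under the empirical consensus CDF over [0, 1]
  cdf_area <- mean(1 - vals)
  structure(list(k = k, consensus = consensus, cosample_counts = co_sample,
                 labels = labels, pac = pac, cdf_area = cdf_area,
                 consensus_values = vals, n_resamples = n_resamples,
                 pac_band = c(pac_lower, pac_upper)),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> k = %d, %d samples, %d resamples, PAC = %.4f\n",
              x$k, length(x$labels), x$n_resamples, x$pac))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.consensus_result <- function(x, ...) {
  tibble::tibble(sample_id = names(x$labels), cluster = unname(x$labels))
}

#' @exportS3Method generics::glance
glance.consensus_result <- function(x, ...) {
  tibble::tibble(k = x$k, pac = x$pac, cdf_area = x$cdf_area,
                 n_samples = length(x$labels), n_resamples = x$n_resamples)
}

#' @exportS3Method ggplot2::autoplot
autoplot.consensus_result <- function(object, ...) {
  ord <- hclust(as.dist(1 - object$consensus), method = "average")$order
  df <- tibble::tibble(
    row = rep(seq_along(ord), times = length(ord)),
    col = rep(seq_along(ord), each = length(ord)),
    consensus = as.vector(object$consensus[ord, ord]))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$consensus)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "#08306b",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Consensus matrix, k = %d (PAC = %.3f)",
                                  object$k, object$pac)) +
    ggplot2::theme_minimal()
}

#' Select the number of clusters by PAC minimization
#'
#' Given `consensus_result`s over a contiguous k range, returns the k with
#' the smallest proportion of ambiguous clustering (consensus values inside
#' the intermediate band), ties broken toward smaller k. When the PAC profile
#' is essentially flat (range < `flat_tol`) there is no evidence of structure
#' and the smallest k is returned with a warning.
#'
#' @param results list of [consensus_cluster()] results.
#' @param flat_tol PAC range below which the profile is declared flat.
#' @return the chosen k (integer) with a `metrics` attribute: a tibble of k,
#'   PAC, CDF area and delta-area.
#' @export
select_k <- function(results, flat_tol = 0.02) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, logical(1), "consensus_result")))
  ks <- vapply(results, `[[`, numeric(1), "k")
  results <- results[order(ks)]
  ks <- sort(ks)
  pac <- vapply(results, `[[`, numeric(1), "pac")
  area <- vapply(results, `[[`, numeric(1), "cdf_area")
  delta <- c(area[1], diff(area) / pmax(area[-length(area)], .Machine$double.eps))
  metrics <- tibble::tibble(k = as.integer(ks), pac = pac, cdf_area = area,
                            delta_area = delta)
  if (length(ks) == 1) {
    warn("single k supplied; returning it without selection")
    chosen <- ks[1]
  } else if (max(pac) - min(pac) < flat_tol) {
    warn("PAC profile is flat: no evidence of cluster structure; returning smallest k")
    chosen <- ks[1]
  } else {
    chosen <- ks[which.min(pac)]  # which.min already breaks ties low
  }
  structure(as.integer(chosen), metrics = metrics)
}

#' Run consensus clustering over a k range and pick k
#'
#' Convenience wrapper: [consensus_cluster()] for each k in `k_range`, then
#' [select_k()].
#'
#' @inheritParams consensus_cluster
#' @param k_range integer vector of candidate k (>= 2).
#' @return list with `best_k`, `labels` (for the chosen k), `results` (per
#'   k), `metrics` tibble.
#' @export
consensus_sweep <- function(x, k_range = 2:6, n_resamples = 1000,
                            subsample_frac = 0.8, seed = 1, n_init = 1,
                            top_features = 2000) {
  if (inherits(x, "expr_matrix")) x <- prep_features(x, top_features)
  results <- lapply(k_range, function(k) {
    consensus_cluster(x, k, n_resamples = n_resamples,
                      subsample_frac = subsample_frac, n_init = n_init,
                      seed = substream_seed(seed, paste0("k", k)))
  })
  best <- select_k(results)
  chosen <- results[[match(as.integer(best), k_range)]]
  list(best_k = as.integer(best), labels = chosen$labels, results = results,
       metrics = attr(best, "metrics"))
}
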