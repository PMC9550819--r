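#' One-vs-rest differential expression by Wilcoxon rank-sum
#'
#' Per feature, a two-sided Wilcoxon rank-sum test of the target cluster's
#' samples against the rest, on log2(x+1) values. The exact enumeration is
#' used when both groups have at most 8 samples and there are no ties;
#' otherwise the normal approximation with tie-corrected variance and
#' continuity correction. `log2fc` is the mean log2(x+1) in the cluster minus
#' the rest; q-values are Benjamini-Hochberg across all features of the
#' contrast.
#'
#' @param x an [expr_matrix()] (raw or log2; raw is transformed).
#' @param labels cluster labels aligned with the columns of `x` (if named,
#'   reordered by sample id).
#' @param cluster target cluster label.
#' @return tibble with `feature_id`, `cluster`, `log2fc`, `p`, `q`,
#'   `direction` (`"up"` iff `log2fc > 0`).
#' @export
de_test <- function(x, labels, cluster) {
  stopifnot(inherits(x, "expr_matrix"))
  labels <- align_labels(labels, colnames(x))
  in_grp <- labels == cluster
  if (sum(in_grp) < 3 || sum(!in_grp) < 3) {
    abort(sprintf("cluster '%s' needs >= 3 samples on each side (has %d vs %d)",
                  cluster, sum(in_grp), sum(!in_grp)))
  }
  m <- unclass(expr_log2(x))
  a <- m[, in_grp, drop = FALSE]
  b <- m[, !in_grp, drop = FALSE]
  use_exact <- ncol(a) <= 8 && ncol(b) <= 8
  p <- vapply(seq_len(nrow(m)), function(i) {
    va <- a[i, ]; vb <- b[i, ]
    all_vals <- c(va, vb)
    if (max(all_vals) == min(all_vals)) return(1)
    wt <- suppressWarnings(
      wilcox.test(va, vb, exact = use_exact && !anyDuplicated(all_vals),
                  correct = TRUE))
    min(wt$p.value, 1)
  }, numeric(1))
  lfc <- unname(rowMeans(a) - rowMeans(b))
  tibble::tibble(feature_id = rownames(m), cluster = cluster, log2fc = lfc,
                 p = p, q = bh_adjust(p),
                 direction = ifelse(lfc > 0, "up", "down"))
}

#' @noRd
align_labels <- function(labels, sample_ids) {
  if (!is.null(names(labels))) {
    missing <- setdiff(sample_ids, names(labels))
    if (length(missing)) {
      abort(sprintf("labels missing for samples: %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
    labels <- labels[sample_ids]
  } else if (length(labels) != length(sample_ids)) {
    abort("unnamed labels must match the number of samples")
  }
  unname(labels)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control over a vector of p-values in (0, 1].
#'
#' @param pvals numeric vector of p-values.
#' @return q-values, same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric())
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Up- and down-regulated gene sets from a DE contrast
#'
#' @param results tibble from [de_test()] (a single contrast).
#' @param q_max FDR ceiling.
#' @param lfc_min minimum absolute log2 fold change.
#' @return list with sorted character vectors `up` and `down`.
#' @export
deg_sets <- function(results, q_max = 0.05, lfc_min = 1) {
  list(
    up = sort(results$feature_id[results$q <= q_max &
                                   results$log2fc >= lfc_min]),
    down = sort(results$feature_id[results$q <= q_max &
                                     results$log2fc <= -lfc_min]))
}
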