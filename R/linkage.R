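#' Candidate SE-gene pairs within a genomic window
#'
#' A pair is emitted when the SE and the gene TSS share a chromosome and the
#' distance from the TSS to the SE interval is at most `window_bp`
#' (inclusive). Coordinates are 0-based half-open; a TSS inside the interval
#' (`start <= tss < end`) has distance 0, and the distance of an outside TSS
#' is measured to the nearer interval boundary (`start - tss` upstream,
#' `tss - end` downstream).
#'
#' @param se_regions tibble with `se_id`, `chrom`, `start`, `end`.
#' @param tss_table tibble with `gene_id`, `chrom`, `tss`.
#' @param window_bp window size in bp (default 500 kb).
#' @return tibble with `se_id`, `gene_id`, `distance_bp`.
#' @export
candidate_pairs <- function(se_regions, tss_table, window_bp = 500000) {
  if (nrow(tss_table) == 0) {
    warn("empty TSS table; no candidate pairs")
    return(tibble::tibble(se_id = character(), gene_id = character(),
                          distance_bp = integer()))
  }
  dplyr::inner_join(se_regions, tss_table, by = "chrom",
                    relationship = "many-to-many") |>
    dplyr::mutate(distance_bp = pmax(.data$start - .data$tss,
                                     .data$tss - .data$end, 0L)) |>
    dplyr::filter(.data$distance_bp <= window_bp) |>
    dplyr::select("se_id", "gene_id", "distance_bp") |>
    dplyr::arrange(.data$se_id, .data$gene_id)
}

#' Correlate candidate SE-gene pairs across samples
#'
#' For each candidate pair, correlates seRNA with mRNA across the shared
#' samples on log2 scale. Spearman (default) or Pearson; p-values from the
#' t approximation, or from the exact permutation distribution for Spearman
#' when n <= 9 and there are no ties. Benjamini-Hochberg q-values are
#' computed jointly over all tested pairs.
#'
#' @param pairs tibble from [candidate_pairs()].
#' @param se_rna,mrna [expr_matrix()] objects sharing sample ids (aligned by
#'   id; at least 3 shared samples required).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return tibble with `se_id`, `gene_id`, `distance_bp`, `rho`, `p`, `q`.
#' @export
correlate_links <- function(pairs, se_rna, mrna,
                            method = c("spearman", "pearson")) {
  method <- match.arg(method)
  shared <- intersect(colnames(se_rna), colnames(mrna))
  if (length(shared) < 3) abort("need >= 3 shared samples to correlate")
  se_m <- unclass(expr_log2(se_rna))[, shared, drop = FALSE]
  mr_m <- unclass(expr_log2(mrna))[, shared, drop = FALSE]
  missing_se <- setdiff(unique(pairs$se_id), rownames(se_m))
  missing_g <- setdiff(unique(pairs$gene_id), rownames(mr_m))
  if (length(missing_se) || length(missing_g)) {
    abort(sprintf("features absent from matrices: %s",
                  paste(head(c(missing_se, missing_g), 5), collapse = ", ")))
  }
  n <- length(shared)
  res <- purrr::pmap_dfr(pairs, function(se_id, gene_id, distance_bp, ...) {
    x <- se_m[se_id, ]
    y <- mr_m[gene_id, ]
    if (sd(x) == 0 || sd(y) == 0) {
      warn(sprintf("zero-variance expression for pair (%s, %s); skipped",
                   se_id, gene_id))
      return(NULL)
    }
    exact <- method == "spearman" && n <= 9 &&
      !anyDuplicated(x) && !anyDuplicated(y)
    ct <- suppressWarnings(
      cor.test(x, y, method = method, exact = if (method == "spearman") exact))
    tibble::tibble(se_id = se_id, gene_id = gene_id,
                   distance_bp = distance_bp,
                   rho = unname(ct$estimate), p = min(ct$p.value, 1))
  })
  if (nrow(res) == 0) {
    return(tibble::tibble(se_id = character(), gene_id = character(),
                          distance_bp = integer(), rho = numeric(),
                          p = numeric(), q = numeric()))
  }
  res$q <- bh_adjust(res$p)
  res
}

#' Define SE-regulated potential genes (SPGs)
#'
#' Genes with at least one link passing the sign constraint, the correlation
#' floor and the FDR ceiling.
#'
#' @param links tibble from [correlate_links()].
#' @param rho_min minimum correlation magnitude.
#' @param q_max maximum BH q-value.
#' @param sign `"positive"` (default), `"negative"` or `"both"`.
#' @return sorted character vector of gene ids (possibly empty).
#' @export
define_spgs <- function(links, rho_min = 0.3, q_max = 0.05,
                        sign = c("positive", "negative", "both")) {
  sign <- match.arg(sign)
  keep <- switch(sign,
                 positive = links$rho >= rho_min,
                 negative = links$rho <= -rho_min,
                 both = abs(links$rho) >= rho_min)
  sort(unique(links$gene_id[keep & links$q <= q_max]))
}

#' Cluster-specific super-enhancers
#'
#' SEs specifically activated in one cluster, called by one-vs-rest
#' differential expression on the seRNA matrix (Wilcoxon rank-sum on
#' log2(x+1)) with an FDR and fold-change gate.
#'
#' @param se_rna an [expr_matrix()] of seRNA values.
#' @param labels cluster labels aligned with (or named by) the samples.
#' @param cluster target cluster.
#' @param q_max,lfc_min gate thresholds.
#' @return sorted character vector of SE ids.
#' @export
cluster_specific_ses <- function(se_rna, labels, cluster, q_max = 0.05,
                                 lfc_min = 1) {
  de <- de_test(se_rna, labels, cluster)
  sort(de$feature_id[de$q <= q_max & de$log2fc >= lfc_min])
}
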