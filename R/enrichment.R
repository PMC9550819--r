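#' Fisher's exact test for gene-set overlap
#'
#' One-sided (over-representation) hypergeometric tail probability
#' `P(X >= n_overlap)` for the 2x2 table induced by two gene sets inside a
#' universe, with the table odds ratio (Haldane 0.5 correction when any cell
#' is zero).
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector of all eligible genes.
#' @return an `overlap_result`: list with `n_universe`, `n_a`, `n_b`,
#'   `n_overlap`, `odds_ratio`, `p`, `genes` (the overlap).
#' @export
fisher_overlap <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty universe")
  set_a <- unique(set_a); set_b <- unique(set_b)
  out_a <- setdiff(set_a, universe); out_b <- setdiff(set_b, universe)
  if (length(out_a) || length(out_b)) {
    abort(sprintf("sets contain genes outside the universe: %s",
                  paste(head(c(out_a, out_b), 5), collapse = ", ")))
  }
  n <- length(universe); a <- length(set_a); b <- length(set_b)
  ov <- intersect(set_a, set_b)
  k <- length(ov)
  p <- phyper(k - 1, a, n - a, b, lower.tail = FALSE)
  tab <- c(k, a - k, b - k, n - a - b + k)
  if (any(tab == 0)) tab <- tab + 0.5
  structure(list(n_universe = n, n_a = a, n_b = b, n_overlap = k,
                 odds_ratio = tab[1] * tab[4] / (tab[2] * tab[3]),
                 p = min(p, 1), genes = sort(ov)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("<overlap_result> %d/%d vs %d/%d overlap %d, OR = %.3g, p = %.3g\n",
              x$n_a, x$n_universe, x$n_b, x$n_universe, x$n_overlap,
              x$odds_ratio, x$p))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.overlap_result <- function(x, ...) {
  tibble::tibble(n_universe = x$n_universe, n_a = x$n_a, n_b = x$n_b,
                 n_overlap = x$n_overlap, odds_ratio = x$odds_ratio, p = x$p)
}

#' SE-regulated genes: SPGs intersected with directed DEGs
#'
#' Intersects SE-regulated potential genes with the cluster's differentially
#' expressed set in the stated direction, and tests the overlap against the
#' expressed-gene universe with [fisher_overlap()].
#'
#' @param spgs character vector of SPG gene ids.
#' @param deg_up,deg_down DEG sets from [deg_sets()].
#' @param direction `"up"` for clusters whose SE program activates genes,
#'   `"down"` for repressive ones.
#' @param universe expressed-gene universe.
#' @return list with `genes` (sorted intersection) and `overlap`
#'   (`overlap_result`).
#' @export
se_regulated_genes <- function(spgs, deg_up, deg_down,
                               direction = c("up", "down"), universe) {
  direction <- match.arg(direction)
  degs <- if (direction == "up") deg_up else deg_down
  res <- fisher_overlap(spgs, degs, universe)
  list(genes = res$genes, overlap = res)
}

#' @noRd
encode_dna <- function(sequence) {
  code <- match(strsplit(toupper(sequence), "")[[1]], c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  code
}

# any-hit test on a pre-encoded sequence (hot path of motif_enrichment)
#' @noRd
pwm_any_hit <- function(code, smat, cutoff) {
  L <- ncol(smat)
  n_off <- length(code) - L + 1L
  if (n_off < 1L) return(FALSE)
  sc_f <- numeric(n_off); sc_r <- numeric(n_off)
  rc <- smat[c(4L, 3L, 2L, 1L, 5L), rev(seq_len(L)), drop = FALSE]
  for (j in seq_len(L)) {
    idx <- code[seq_len(n_off) + j - 1L]
    sc_f <- sc_f + smat[idx, j]
    sc_r <- sc_r + rc[idx, j]
  }
  max(sc_f, sc_r) >= cutoff
}

#' @noRd
pwm_score_matrix <- function(pwm) {
  # log2-odds vs uniform background; N contributes 0 (the background odds)
  s <- log2(pmax(pwm$probs, .Machine$double.xmin) / 0.25)
  rbind(t(s), N = 0)  # rows A,C,G,T,N x positions
}

#' Scan a sequence with a PWM on both strands
#'
#' Scores every offset with the log2-odds of the PWM against a uniform
#' background (N bases contribute 0) and reports hits with score at least
#' `threshold_frac` times the maximum achievable score. Minus-strand hits
#' score the reverse complement of the window and are reported at the
#' window's forward-strand offset.
#'
#' @param sequence character scalar over A/C/G/T/N.
#' @param pwm a [pwm()] object.
#' @param threshold_frac fraction of the maximum score, in (0, 1].
#' @return tibble with `position` (0-based window start), `strand`, `score`.
#' @export
pwm_scan <- function(sequence, pwm, threshold_frac = 0.8) {
  if (threshold_frac <= 0 || threshold_frac > 1) {
    abort("threshold_frac must be in (0, 1]")
  }
  L <- nrow(pwm$probs)
  code <- encode_dna(sequence)
  n <- length(code)
  empty <- tibble::tibble(position = integer(), strand = character(),
                          score = numeric())
  if (L > n) return(empty)
  smat <- pwm_score_matrix(pwm)
  max_score <- sum(apply(smat[1:4, , drop = FALSE], 2, max))
  cutoff <- threshold_frac * max_score
  n_off <- n - L + 1L
  score_with <- function(m) {
    sc <- numeric(n_off)
    for (j in seq_len(L)) sc <- sc + m[code[seq_len(n_off) + j - 1L], j]
    unname(sc)
  }
  fwd <- score_with(smat)
  # minus strand: complement the base axis and reverse the positions
  rc <- smat[c(4L, 3L, 2L, 1L, 5L), rev(seq_len(L)), drop = FALSE]
  rev_sc <- score_with(rc)
  hits <- dplyr::bind_rows(
    tibble::tibble(position = which(fwd >= cutoff) - 1L, strand = "+",
                   score = fwd[fwd >= cutoff]),
    tibble::tibble(position = which(rev_sc >= cutoff) - 1L, strand = "-",
                   score = rev_sc[rev_sc >= cutoff]))
  dplyr::arrange(hits, .data$position, .data$strand)
}

#' Promoter motif enrichment between gene sets
#'
#' A gene counts as a hit for a motif when its promoter has at least one
#' [pwm_scan()] hit. Per motif, a one-sided Fisher test compares foreground
#' hit frequency against background; q-values are Benjamini-Hochberg across
#' motifs.
#'
#' @param fg_gene_set foreground gene ids (e.g. a cluster's SE-regulated
#'   genes).
#' @param bg_gene_set background gene ids; defaults to all promoters not in
#'   the foreground. Must be disjoint from the foreground.
#' @param promoters named character vector of promoter sequences.
#' @param pwms list of [pwm()] objects.
#' @param threshold_frac passed to [pwm_scan()].
#' @return tibble with `motif_id`, `fg_hits`, `fg_total`, `bg_hits`,
#'   `bg_total`, `odds_ratio`, `p`, `q`, sorted by q then p.
#' @export
motif_enrichment <- function(fg_gene_set, bg_gene_set = NULL, promoters,
                             pwms, threshold_frac = 0.8) {
  fg_gene_set <- unique(fg_gene_set)
  if (is.null(bg_gene_set)) {
    bg_gene_set <- setdiff(names(promoters), fg_gene_set)
  }
  bg_gene_set <- unique(bg_gene_set)
  if (length(intersect(fg_gene_set, bg_gene_set))) {
    abort("foreground and background gene sets must be disjoint")
  }
  drop_missing <- function(genes, what) {
    miss <- setdiff(genes, names(promoters))
    if (length(miss)) {
      warn(sprintf("%d %s gene(s) without a promoter dropped: %s", length(miss),
                   what, paste(head(miss, 3), collapse = ", ")))
    }
    intersect(genes, names(promoters))
  }
  fg <- drop_missing(fg_gene_set, "foreground")
  bg <- drop_missing(bg_gene_set, "background")
  if (length(fg) == 0 || length(bg) == 0) {
    abort("empty foreground or background after dropping missing promoters")
  }
  codes <- lapply(promoters[c(fg, bg)], encode_dna)
  res <- purrr::map_dfr(pwms, function(p) {
    smat <- pwm_score_matrix(p)
    cutoff <- threshold_frac * sum(apply(smat[1:4, , drop = FALSE], 2, max))
    hit <- function(g) pwm_any_hit(codes[[g]], smat, cutoff)
    fg_hits <- sum(vapply(fg, hit, logical(1)))
    bg_hits <- sum(vapply(bg, hit, logical(1)))
    n_hit <- fg_hits + bg_hits
    pv <- phyper(fg_hits - 1, n_hit, length(fg) + length(bg) - n_hit,
                 length(fg), lower.tail = FALSE)
    tab <- c(fg_hits, length(fg) - fg_hits, bg_hits, length(bg) - bg_hits)
    if (any(tab == 0)) tab <- tab + 0.5
    tibble::tibble(motif_id = p$motif_id, fg_hits = fg_hits,
                   fg_total = length(fg), bg_hits = bg_hits,
                   bg_total = length(bg),
                   odds_ratio = tab[1] * tab[4] / (tab[2] * tab[3]),
                   p = min(pv, 1))
  })
  res$q <- bh_adjust(res$p)
  dplyr::arrange(res, .data$q, .data$p, .data$motif_id)
}
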