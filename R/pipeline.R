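#' Pipeline options
#'
#' Thresholds and settings for [run_pipeline()], mirroring each stage's
#' defaults. All values are recorded in the run report.
#'
#' @param k_range candidate cluster numbers for the consensus sweep.
#' @param n_resamples,subsample_frac,top_features,n_init consensus-clustering
#'   settings (see [consensus_cluster()]).
#' @param window_bp SE-to-TSS linkage window.
#' @param cor_method,rho_min,link_q_max linkage settings (see
#'   [correlate_links()] and [define_spgs()]).
#' @param de_q_max,de_lfc_min differential-expression gates.
#' @param deg_direction `"auto"` picks, per cluster, the direction (up/down)
#'   whose SPG/DEG overlap is more significant; `"up"` or `"down"` force it.
#' @param threshold_frac PWM scan threshold fraction.
#' @param motif_q_max enrichment q ceiling for candidate TFs entering the
#'   LASSO.
#' @param n_folds CV folds for the penalty selection.
#' @param signature_genes optional signature gene set for scoring; when NULL
#'   and the input carries a truth record, its signature genes are used.
#' @return a `pipeline_options` list.
#' @export
pipeline_options <- function(k_range = 2:6, n_resamples = 1000,
                             subsample_frac = 0.8, top_features = 2000,
                             n_init = 1, window_bp = 500000,
                             cor_method = "spearman", rho_min = 0.3,
                             link_q_max = 0.05, de_q_max = 0.05,
                             de_lfc_min = 1, deg_direction = "auto",
                             threshold_frac = 0.8, motif_q_max = 0.05,
                             n_folds = 10, signature_genes = NULL) {
  structure(as.list(environment()), class = "pipeline_options")
}

#' @noRd
run_stage <- function(name, expr) {
  tryCatch(force(expr), error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
          class = "sestrat_stage_error")
  })
}

#' @noRd
resolve_input <- function(x) if (is.function(x)) x() else x

#' Run the full stratification pipeline
#'
#' Executes the analysis end to end, in order: consensus clustering of the
#' seRNA matrix with k selection; cluster-specific SEs (one-vs-rest DE on
#' seRNA); SE-gene linkage by windowed correlation (SPGs); mRNA differential
#' expression per cluster; SE-regulated genes (SPG/DEG intersection with
#' Fisher overlap); promoter motif enrichment; LASSO core-TF selection and
#' the multi-TF index; survival validation (clusters, and index median
#' split); signature scoring. A stage failure aborts with the stage name;
#' outputs of completed stages are preserved in the error's `report` field.
#'
#' @param inputs a `synthetic_cohort` or named list with `se_rna`, `mrna`,
#'   `se_regions`, `tss_table`, `promoters`, `pwms` and optionally
#'   `survival` (elements may be zero-argument functions, resolved lazily at
#'   their stage).
#' @param opts a [pipeline_options()] list.
#' @param seed integer seed for all stochastic stages.
#' @return a `run_report` list (see the fields in the source of
#'   [report_summary()]).
#' @export
run_pipeline <- function(inputs, opts = pipeline_options(), seed = 1) {
  rep <- list(seed = seed, options = unclass(opts), stage_hashes = list())
  note <- function(name, x) {
    rep$stage_hashes[[name]] <<- stage_hash(x)
    x
  }

  se_rna <- run_stage("cluster", resolve_input(inputs$se_rna))
  note("input_se_rna", unclass(se_rna))
  sweep_res <- run_stage("cluster", consensus_sweep(
    se_rna, k_range = opts$k_range, n_resamples = opts$n_resamples,
    subsample_frac = opts$subsample_frac, seed = seed, n_init = opts$n_init,
    top_features = opts$top_features))
  labels <- sweep_res$labels
  k <- sweep_res$best_k
  clusters <- sort(unique(labels))
  rep$chosen_k <- k
  rep$k_metrics <- sweep_res$metrics
  rep$labels <- labels
  rep$cluster_sizes <- as.list(table(labels))
  note("cluster", labels)

  specific_ses <- run_stage("cluster_ses", lapply(clusters, function(cl) {
    cluster_specific_ses(se_rna, labels, cl, q_max = opts$de_q_max,
                         lfc_min = opts$de_lfc_min)
  }))
  names(specific_ses) <- clusters
  rep$specific_se_counts <- lapply(specific_ses, length)
  rep$specific_ses <- specific_ses
  note("cluster_ses", specific_ses)

  mrna <- run_stage("link", resolve_input(inputs$mrna))
  se_regions <- run_stage("link", resolve_input(inputs$se_regions))
  tss_table <- run_stage("link", resolve_input(inputs$tss_table))
  links_by_cluster <- run_stage("link", lapply(clusters, function(cl) {
    regions <- se_regions[se_regions$se_id %in% specific_ses[[as.character(cl)]], ]
    pairs <- candidate_pairs(regions, tss_table, window_bp = opts$window_bp)
    if (nrow(pairs) == 0) return(tibble::tibble())
    correlate_links(pairs, se_rna, mrna, method = opts$cor_method)
  }))
  names(links_by_cluster) <- clusters
  spgs <- lapply(links_by_cluster, function(l) {
    if (nrow(l) == 0) character() else {
      define_spgs(l, rho_min = opts$rho_min, q_max = opts$link_q_max)
    }
  })
  rep$links <- links_by_cluster
  rep$spg_counts <- lapply(spgs, length)
  rep$spgs <- spgs
  note("link", spgs)

  de_results <- run_stage("de", lapply(clusters, function(cl) {
    de_test(mrna, labels, cl)
  }))
  names(de_results) <- clusters
  degs <- lapply(de_results, deg_sets, q_max = opts$de_q_max,
                 lfc_min = opts$de_lfc_min)
  rep$de <- de_results
  rep$deg_counts <- lapply(degs, function(d) {
    list(up = length(d$up), down = length(d$down))
  })
  note("de", degs)

  universe <- rownames(mrna)
  se_reg <- run_stage("overlap", lapply(clusters, function(cl) {
    cl <- as.character(cl)
    dirs <- if (opts$deg_direction == "auto") c("up", "down") else
      opts$deg_direction
    cand <- lapply(dirs, function(d) {
      se_regulated_genes(spgs[[cl]], degs[[cl]]$up, degs[[cl]]$down,
                         direction = d, universe = universe)
    })
    best <- which.min(vapply(cand, function(x) x$overlap$p, numeric(1)))
    c(cand[[best]], list(direction = dirs[best]))
  }))
  names(se_reg) <- clusters
  rep$se_regulated <- lapply(se_reg, function(x) {
    list(direction = x$direction, n_genes = length(x$genes),
         overlap = glance(x$overlap), genes = x$genes)
  })
  note("overlap", lapply(se_reg, `[[`, "genes"))

  promoters <- run_stage("enrich", {
    p <- resolve_input(inputs$promoters)
    if (is.null(p)) abort("promoter sequences are missing")
    p
  })
  pwms <- run_stage("enrich", {
    p <- resolve_input(inputs$pwms)
    if (is.null(p)) abort("PWM library is missing")
    p
  })
  enrich <- run_stage("enrich", lapply(clusters, function(cl) {
    genes <- se_reg[[as.character(cl)]]$genes
    if (length(genes) == 0) return(tibble::tibble())
    motif_enrichment(genes, promoters = promoters, pwms = pwms,
                     threshold_frac = opts$threshold_frac)
  }))
  names(enrich) <- clusters
  rep$motif_enrichment <- enrich
  rep$top_motifs <- lapply(enrich, function(e) {
    if (nrow(e) == 0) NULL else utils::head(e[order(e$q, e$p), ], 3)
  })
  note("enrich", enrich)

  survival_tab <- tryCatch(resolve_input(inputs$survival),
                           error = function(e) NULL)
  worst_cluster <- clusters[length(clusters)]
  if (!is.null(survival_tab)) {
    crude <- vapply(clusters, function(cl) {
      r <- survival_tab[survival_tab$sample_id %in%
                          names(labels)[labels == cl], ]
      sum(r$event) / sum(r$time)
    }, numeric(1))
    worst_cluster <- clusters[which.max(crude)]
  }
  rep$worst_cluster <- worst_cluster

  model <- run_stage("index", {
    cand <- sort(unique(unlist(lapply(enrich, function(e) {
      if (nrow(e) == 0) character() else e$motif_id[e$q <= opts$motif_q_max]
    }))))
    if (length(cand) == 0) abort("no enriched motifs at the candidate gate")
    cand <- intersect(cand, rownames(mrna))
    if (length(cand) == 0) abort("enriched motifs have no matching TF expression")
    fit_core_tfs(mrna, labels, candidate_tfs = cand,
                 index_cluster = worst_cluster, n_folds = opts$n_folds,
                 seed = seed)
  })
  index <- run_stage("index", build_tf_index(model, mrna))
  predicted <- run_stage("index", predict_clusters(model, mrna))
  rep$model <- model
  rep$core_tfs <- model$core_tfs
  rep$index <- index
  rep$predicted_clusters <- predicted
  rep$index_summary <- list(mean = mean(index$index), sd = sd(index$index),
                            by_cluster = tapply(index$index,
                                                labels[index$sample_id], mean))
  note("index", list(model$weights, index))

  if (!is.null(survival_tab)) {
    rep$survival_by_cluster <- run_stage("survival", stratified_km_report(
      survival_tab, groups = labels))
    rep$survival_by_index <- run_stage("survival", stratified_km_report(
      survival_tab, index = index))
    rep$logrank <- list(
      clusters = glance(rep$survival_by_cluster$logrank),
      index_split = glance(rep$survival_by_index$logrank))
    note("survival", rep$logrank)
  }

  sig <- opts$signature_genes %||% inputs$truth$signature_genes
  if (!is.null(sig)) {
    scores <- run_stage("score", signature_score(mrna, sig))
    rep$signature_scores <- scores
    rep$signature_summary <- tibble::tibble(
      cluster = clusters,
      mean_score = vapply(clusters, function(cl) {
        mean(scores$score[labels[scores$sample_id] == cl])
      }, numeric(1)))
    note("score", scores)
  }

  structure(rep, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> seed %d | chosen k = %d | clusters: %s\n",
              x$seed, x$chosen_k,
              paste(names(x$cluster_sizes), x$cluster_sizes, sep = "=",
                    collapse = ", ")))
  cat("  core TFs:", paste(names(x$core_tfs), x$core_tfs, sep = "->",
                           collapse = ", "), "\n")
  if (!is.null(x$logrank)) {
    cat(sprintf("  log-rank by cluster: p = %.3g | by index split: p = %.3g\n",
                x$logrank$clusters$p, x$logrank$index_split$p))
  }
  invisible(x)
}

#' Compact summary of a run report
#'
#' @param report a [run_pipeline()] result.
#' @return a list of plain scalars/tables suitable for JSON serialization.
#' @export
report_summary <- function(report) {
  list(
    seed = report$seed,
    chosen_k = report$chosen_k,
    cluster_sizes = report$cluster_sizes,
    specific_se_counts = report$specific_se_counts,
    spg_counts = report$spg_counts,
    deg_counts = report$deg_counts,
    se_regulated = lapply(report$se_regulated, function(x) {
      x[c("direction", "n_genes", "overlap")]
    }),
    top_motifs = report$top_motifs,
    core_tfs = as.list(report$core_tfs),
    worst_cluster = report$worst_cluster,
    index_summary = report$index_summary,
    logrank = report$logrank,
    signature_summary = report$signature_summary,
    options = report$options,
    stage_hashes = report$stage_hashes)
}

#' Run the pipeline from a directory of files
#'
#' Reads the standard file layout written by [write_cohort()] (inputs are
#' read lazily, so a missing file aborts at the stage that needs it), runs
#' [run_pipeline()], and writes per-stage TSVs plus `report.json` to
#' `outdir`.
#'
#' @param indir input directory.
#' @param outdir output directory (created if needed).
#' @param opts a [pipeline_options()] list.
#' @param seed integer seed.
#' @return the `run_report`, invisibly.
#' @export
run_all <- function(indir, outdir, opts = pipeline_options(), seed = 1) {
  need <- function(file, reader) {
    function() {
      path <- file.path(indir, file)
      if (!file.exists(path)) abort(sprintf("missing input file: %s", path))
      reader(path)
    }
  }
  inputs <- list(
    se_rna = need("se_rna.tsv", read_expression),
    mrna = need("mrna.tsv", read_expression),
    se_regions = need("se_regions.bed", read_bed),
    tss_table = need("tss.tsv", read_tss),
    promoters = need("promoters.fasta", read_promoters),
    pwms = need("motifs.pfm", read_pwm_library),
    survival = if (file.exists(file.path(indir, "survival.tsv"))) {
      need("survival.tsv", read_survival)
    })
  truth_path <- file.path(indir, "truth.json")
  if (is.null(opts$signature_genes) && file.exists(truth_path)) {
    tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    opts$signature_genes <- tr$signature_genes
  }
  report <- run_pipeline(inputs, opts = opts, seed = seed)
  write_report(report, outdir)
  invisible(report)
}

#' @rdname run_all
#' @param report a `run_report`.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(tibble::tibble(sample_id = names(report$labels),
                                  cluster = unname(report$labels)),
                   file.path(dir, "labels.tsv"))
  for (cl in names(report$links)) {
    l <- report$links[[cl]]
    if (nrow(l)) readr::write_tsv(l, file.path(dir,
                                               sprintf("links_cluster%s.tsv", cl)))
    readr::write_tsv(report$de[[cl]], file.path(dir,
                                                sprintf("de_cluster%s.tsv", cl)))
    e <- report$motif_enrichment[[cl]]
    if (!is.null(e) && nrow(e)) {
      readr::write_tsv(e, file.path(dir,
                                    sprintf("motif_enrichment_cluster%s.tsv", cl)))
    }
  }
  readr::write_tsv(report$index, file.path(dir, "index.tsv"))
  readr::write_tsv(report$predicted_clusters,
                   file.path(dir, "predicted_clusters.tsv"))
  if (!is.null(report$signature_scores)) {
    readr::write_tsv(report$signature_scores, file.path(dir, "scores.tsv"))
  }
  jsonlite::write_json(report_summary(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
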