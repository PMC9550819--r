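#' Synthetic cohort configuration
#'
#' Parameters of the built-in cohort generator. The generator emulates the
#' statistical structure every downstream stage assumes: `k` latent patient
#' clusters with cluster-specific active super-enhancers, positively
#' correlated seRNA -> target-gene pairs within a genomic window,
#' cluster-specific differentially expressed genes, driver-TF motifs planted
#' in the promoters of SE-linked genes, cluster-elevated driver-TF
#' expression, a glycolysis-like signature elevated in the worst-prognosis
#' cluster, and cluster-dependent exponential survival with uniform right
#' censoring.
#'
#' Raw expression is log-normal: values are `2^L` with `L` Gaussian on log2
#' scale (`baseline_log2_mean`, `baseline_log2_sd`), and every planted effect
#' is an additive shift on `L` expressed in SD units.
#'
#' @param n_samples number of samples.
#' @param n_clusters number of latent clusters `k`.
#' @param cluster_proportions length-`k` proportions summing to 1 (default
#'   equal).
#' @param n_se total super-enhancer loci.
#' @param n_active_se_per_cluster SEs activated specifically in each cluster.
#' @param n_genes genes in the mRNA matrix, excluding candidate TFs and
#'   signature genes (added on top under their own ids).
#' @param n_linked_genes_per_cluster genes per cluster whose mRNA tracks a
#'   cluster-active seRNA.
#' @param n_bystander_genes_per_cluster genes per cluster placed inside the
#'   linkage window of an active SE but expressed independently (negative
#'   controls for linkage precision).
#' @param n_candidate_tfs candidate transcription factors (each with a PWM).
#' @param n_driver_tfs_per_cluster planted driver TFs per cluster.
#' @param se_activation_effect mean log2 shift of active SEs (and driver TFs)
#'   in their cluster, in units of `baseline_log2_sd`.
#' @param link_noise_sd Gaussian noise SD of the mRNA around its linked seRNA
#'   on log2 scale.
#' @param link_slope positive slope `a` of `mRNA = a * seRNA + noise`
#'   (log2 scale).
#' @param baseline_hazard per-cluster exponential event rates (recycled to
#'   `k`).
#' @param censor_rate expected fraction of censored samples, in `[0, 1)`.
#' @param window_bp SE-to-TSS linkage window (bp).
#' @param promoter_len promoter sequence length (bp).
#' @param motif_plant_rate fraction of each cluster's linked-gene promoters
#'   carrying the driver motif consensus.
#' @param motif_len PWM length (bp).
#' @param n_signature_genes size of the planted glycolysis-like signature.
#' @param signature_effect log2 shift (SD units) of signature genes in the
#'   worst-prognosis (highest-hazard) cluster.
#' @param baseline_log2_mean,baseline_log2_sd baseline of the log2 expression
#'   field.
#' @param seed integer seed; all randomness derives from it through named
#'   substreams, so adding a component never perturbs earlier draws.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 150,
                          n_clusters = 3,
                          cluster_proportions = NULL,
                          n_se = 500,
                          n_active_se_per_cluster = 40,
                          n_genes = 600,
                          n_linked_genes_per_cluster = 30,
                          n_bystander_genes_per_cluster = 30,
                          n_candidate_tfs = 20,
                          n_driver_tfs_per_cluster = 1,
                          se_activation_effect = 2.0,
                          link_noise_sd = 0.5,
                          link_slope = 1.0,
                          baseline_hazard = c(0.02, 0.02, 0.08),
                          censor_rate = 0.3,
                          window_bp = 500000L,
                          promoter_len = 600L,
                          motif_plant_rate = 0.9,
                          motif_len = 8L,
                          n_signature_genes = 22,
                          signature_effect = 1.0,
                          baseline_log2_mean = 6,
                          baseline_log2_sd = 1,
                          seed = 1L) {
  cfg <- as.list(environment())
  k <- cfg$n_clusters
  if (k < 1) config_error("n_clusters must be >= 1")
  if (is.null(cfg$cluster_proportions)) {
    cfg$cluster_proportions <- rep(1 / k, k)
  }
  if (length(cfg$cluster_proportions) != k ||
      abs(sum(cfg$cluster_proportions) - 1) > 1e-8 ||
      any(cfg$cluster_proportions <= 0)) {
    config_error("cluster_proportions must be %d positive values summing to 1",
                 k)
  }
  cfg$baseline_hazard <- rep_len(cfg$baseline_hazard, k)
  if (any(cfg$baseline_hazard <= 0)) config_error("hazards must be > 0")
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1) {
    config_error("censor_rate must be in [0, 1)")
  }
  counts <- c(n_samples, n_se, n_genes, n_candidate_tfs, n_active_se_per_cluster,
              n_linked_genes_per_cluster, promoter_len, motif_len)
  if (any(counts <= 0)) config_error("all counts must be positive")
  if (n_se < k * n_active_se_per_cluster) {
    config_error("n_se smaller than total active SEs (%d < %d)",
                 n_se, k * n_active_se_per_cluster)
  }
  per_cluster <- n_linked_genes_per_cluster + n_bystander_genes_per_cluster
  if (n_genes < k * per_cluster) {
    config_error("n_genes smaller than linked + bystander genes (%d < %d)",
                 n_genes, k * per_cluster)
  }
  if (cfg$motif_plant_rate < 0 || cfg$motif_plant_rate > 1) {
    config_error("motif_plant_rate must be in [0, 1]")
  }
  if (cfg$promoter_len < cfg$motif_len) {
    config_error("promoter_len must be >= motif_len")
  }
  if (cfg$link_slope <= 0) config_error("link_slope must be > 0")
  structure(cfg, class = "cohort_config")
}

# Deterministic genomic layout: one synthetic chromosome per cluster. Each
# active SE owns a slot wide enough that every gene placed in it (linked and
# bystander inside the window, one decoy just beyond it) is farther than
# window_bp from any other SE, making window-boundary behaviour unambiguous.
#' @noRd
cohort_layout <- function(cfg) {
  k <- cfg$n_clusters
  se_len <- 10000L
  window <- as.integer(cfg$window_bp)
  n_active <- cfg$n_active_se_per_cluster
  genes_per_se <- ceiling((cfg$n_linked_genes_per_cluster +
                             cfg$n_bystander_genes_per_cluster) / n_active)
  spacing <- window %/% (genes_per_se + 1L)
  if (spacing < 2L) {
    config_error("window_bp too small for %d genes per SE", genes_per_se)
  }
  max_offset <- se_len + window + 10000L + 20000L
  slot <- max_offset + window + se_len + 10000L

  regions <- list(); tss <- list()
  active_ses <- vector("list", k)
  links <- list()
  n_decoy <- cfg$n_genes - k * (cfg$n_linked_genes_per_cluster +
                                  cfg$n_bystander_genes_per_cluster)
  decoy_ix <- 0L
  for (c in seq_len(k)) {
    chrom <- sprintf("chrS%d", c)
    starts <- (seq_len(n_active) - 1L) * slot + 1000L
    ids <- sprintf("SE_c%d_%02d", c, seq_len(n_active))
    active_ses[[c]] <- ids
    regions[[c]] <- tibble::tibble(se_id = ids, chrom = chrom,
                                   start = starts, end = starts + se_len)
    place <- function(j, kind) {
      se_i <- ((j - 1L) %% n_active) + 1L
      rank <- (j - 1L) %/% n_active
      off <- (rank + 1L) * spacing + if (kind == "B") spacing %/% 3L else 0L
      list(se = ids[se_i], tss = starts[se_i] + se_len + off)
    }
    lk <- lapply(seq_len(cfg$n_linked_genes_per_cluster), place, kind = "L")
    by <- lapply(seq_len(cfg$n_bystander_genes_per_cluster), place, kind = "B")
    lg <- sprintf("G_c%d_L%02d", c, seq_len(cfg$n_linked_genes_per_cluster))
    bg <- sprintf("G_c%d_B%02d", c, seq_len(cfg$n_bystander_genes_per_cluster))
    links[[c]] <- tibble::tibble(
      cluster = c, se_id = vapply(lk, `[[`, character(1), "se"), gene_id = lg)
    # decoys sit 10 kb beyond the window, round-robin over this cluster's SEs
    n_dec_here <- if (c < k) n_decoy %/% k else n_decoy - (k - 1L) * (n_decoy %/% k)
    dg <- if (n_dec_here > 0) sprintf("G_D%03d", decoy_ix + seq_len(n_dec_here)) else character()
    decoy_ix <- decoy_ix + n_dec_here
    dec_tss <- if (n_dec_here > 0) {
      se_i <- ((seq_len(n_dec_here) - 1L) %% n_active) + 1L
      wob <- ((seq_len(n_dec_here) - 1L) %/% n_active) * 997L
      starts[se_i] + se_len + window + 10000L + wob
    } else integer()
    tss[[c]] <- tibble::tibble(
      gene_id = c(lg, bg, dg),
      chrom = chrom,
      tss = c(vapply(lk, function(z) as.integer(z$tss), integer(1)),
              vapply(by, function(z) as.integer(z$tss), integer(1)),
              as.integer(dec_tss)),
      strand = "+")
  }
  # background SEs on their own chromosome, no genes nearby
  n_bg_se <- cfg$n_se - k * n_active
  bg_regions <- if (n_bg_se > 0) {
    st <- (seq_len(n_bg_se) - 1L) * slot + 1000L
    tibble::tibble(se_id = sprintf("SE_bg_%03d", seq_len(n_bg_se)),
                   chrom = "chrB", start = st, end = st + se_len)
  }
  # candidate TFs and signature genes live on auxiliary chromosomes
  tf_ids <- sprintf("TF%02d", seq_len(cfg$n_candidate_tfs))
  sig_ids <- sprintf("GLY%02d", seq_len(cfg$n_signature_genes))
  aux_tss <- tibble::tibble(
    gene_id = c(tf_ids, sig_ids),
    chrom = rep(c("chrT", "chrG"), c(length(tf_ids), length(sig_ids))),
    tss = c((seq_along(tf_ids) - 1L) * slot + 1000L,
            (seq_along(sig_ids) - 1L) * slot + 1000L),
    strand = "+")
  list(
    se_regions = dplyr::bind_rows(c(regions, list(bg_regions))),
    tss_table = dplyr::bind_rows(c(tss, list(aux_tss))),
    active_ses = active_ses,
    links = dplyr::bind_rows(links),
    tf_ids = tf_ids,
    sig_ids = sig_ids)
}

#' @noRd
random_pwm_library <- function(tf_ids, motif_len) {
  bases <- c("A", "C", "G", "T")
  taken <- character()
  consensi <- character(length(tf_ids))
  for (i in seq_along(tf_ids)) {
    repeat {
      cons <- paste(sample(bases, motif_len, replace = TRUE), collapse = "")
      rc <- revcomp(cons)
      if (!cons %in% taken && !rc %in% taken) break
    }
    consensi[i] <- cons
    taken <- c(taken, cons, revcomp(cons))
  }
  pwms <- lapply(seq_along(tf_ids), function(i) {
    letters_i <- strsplit(consensi[i], "")[[1]]
    counts <- matrix(5, nrow = motif_len, ncol = 4,
                     dimnames = list(NULL, bases))
    counts[cbind(seq_len(motif_len), match(letters_i, bases))] <- 85
    pwm(tf_ids[i], counts, pseudocount = 0)
  })
  names(pwms) <- tf_ids
  pwms
}

#' Reverse complement of a DNA string
#' @param x character scalar over A/C/G/T/N.
#' @return character scalar.
#' @export
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

#' Plant a motif consensus into a sequence
#'
#' Replaces the substring at `position` (0-based) with the PWM consensus
#' (argmax base per position); the rest of the sequence is unchanged.
#'
#' @param sequence character scalar.
#' @param pwm a [pwm()] object.
#' @param position 0-based offset; `position + motif length` must not exceed
#'   the sequence length.
#' @return the modified sequence.
#' @export
plant_motif <- function(sequence, pwm, position) {
  cons <- pwm_consensus(pwm)
  L <- nchar(cons)
  if (position < 0 || position + L > nchar(sequence)) {
    abort(sprintf("plant position %d out of range for motif of length %d in sequence of length %d",
                  position, L, nchar(sequence)))
  }
  paste0(substr(sequence, 1, position), cons,
         substr(sequence, position + L + 1, nchar(sequence)))
}

#' Simulate survival records for labelled samples
#'
#' Event times are exponential with the cluster's baseline hazard; censoring
#' times are uniform on `[0, T_max]` with `T_max` solved numerically so the
#' expected censored fraction equals `censor_rate`, independent of event
#' times.
#'
#' @param labels integer cluster labels (1..k), optionally named by sample id.
#' @param hazards per-cluster event rates, all > 0.
#' @param censor_rate expected censored fraction in `[0, 1)`.
#' @param seed integer seed.
#' @return tibble with `sample_id`, `time`, `event` (1 = event, 0 = censored).
#' @export
generate_survival <- function(labels, hazards, censor_rate = 0, seed = 1) {
  if (any(hazards <= 0)) abort("hazards must be > 0")
  if (censor_rate < 0 || censor_rate >= 1) abort("censor_rate must be in [0, 1)")
  k <- max(labels)
  hazards <- rep_len(hazards, k)
  ids <- names(labels) %||% sprintf("S%03d", seq_along(labels))
  lam <- hazards[labels]
  with_substream(seed, "survival", {
    x <- rexp(length(labels), rate = lam)
    if (censor_rate == 0) {
      tibble::tibble(sample_id = ids, time = x, event = 1)
    } else {
      # P(censored | T) averaged over samples = mean (1 - exp(-lam T)) / (lam T)
      f <- function(T) mean((1 - exp(-lam * T)) / (lam * T)) - censor_rate
      t_max <- uniroot(f, lower = 1e-8, upper = 1e8, tol = 1e-10)$root
      u <- runif(length(labels), 0, t_max)
      tibble::tibble(sample_id = ids,
                     time = pmin(x, u),
                     event = as.numeric(x <= u))
    }
  })
}

#' Generate a full synthetic cohort
#'
#' Produces seRNA and mRNA expression matrices, SE regions, TSS annotation,
#' promoter sequences, a PWM library, survival records, and a complete
#' machine-readable `truth` record of every planted effect. See
#' [cohort_config()] for the generative model.
#'
#' @param config a [cohort_config()].
#' @return a `synthetic_cohort` list with elements `se_rna`, `mrna`,
#'   `se_regions`, `tss_table`, `promoters`, `pwms`, `survival`, `truth`,
#'   `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  k <- cfg$n_clusters
  seed <- cfg$seed
  lay <- with_substream(seed, "layout", cohort_layout(cfg))

  counts <- round(cfg$cluster_proportions * cfg$n_samples)
  counts[k] <- cfg$n_samples - sum(counts[-k])
  if (any(counts < 1)) config_error("a cluster received no samples")
  labels <- rep(seq_len(k), times = counts)
  sample_ids <- sprintf("S%03d", seq_len(cfg$n_samples))
  names(labels) <- sample_ids

  mu <- cfg$baseline_log2_mean
  sdv <- cfg$baseline_log2_sd
  eff <- cfg$se_activation_effect * sdv

  # seRNA field: baseline log-normal + activation shift for cluster-active SEs
  se_ids <- lay$se_regions$se_id
  se_l2 <- with_substream(seed, "se_expr", {
    m <- matrix(rnorm(length(se_ids) * cfg$n_samples, mu, sdv),
                nrow = length(se_ids),
                dimnames = list(se_ids, sample_ids))
    for (c in seq_len(k)) {
      m[lay$active_ses[[c]], labels == c] <-
        m[lay$active_ses[[c]], labels == c] + eff
    }
    m
  })

  # driver TFs: last n_driver per cluster taken off the candidate list front
  n_drv <- cfg$n_driver_tfs_per_cluster
  if (k * n_drv > cfg$n_candidate_tfs) {
    config_error("need %d driver TFs but only %d candidates",
                 k * n_drv, cfg$n_candidate_tfs)
  }
  driver_tfs <- lapply(seq_len(k), function(c) {
    lay$tf_ids[((c - 1L) * n_drv + 1L):(c * n_drv)]
  })
  worst <- which.max(cfg$baseline_hazard)

  gene_ids <- c(lay$tss_table$gene_id)
  mrna_l2 <- with_substream(seed, "mrna", {
    m <- matrix(rnorm(length(gene_ids) * cfg$n_samples, mu, sdv),
                nrow = length(gene_ids),
                dimnames = list(gene_ids, sample_ids))
    # linked genes track their seRNA with positive slope + noise
    for (i in seq_len(nrow(lay$links))) {
      g <- lay$links$gene_id[i]; s <- lay$links$se_id[i]
      m[g, ] <- cfg$link_slope * se_l2[s, ] +
        rnorm(cfg$n_samples, 0, cfg$link_noise_sd)
    }
    for (c in seq_len(k)) {
      m[driver_tfs[[c]], labels == c] <- m[driver_tfs[[c]], labels == c] + eff
    }
    m[lay$sig_ids, labels == worst] <- m[lay$sig_ids, labels == worst] +
      cfg$signature_effect * sdv
    m
  })

  pwms <- with_substream(seed, "pwms",
                         random_pwm_library(lay$tf_ids, cfg$motif_len))

  promoters <- with_substream(seed, "promoters", {
    seqs <- vapply(gene_ids, function(g) {
      paste(sample(c("A", "C", "G", "T"), cfg$promoter_len, replace = TRUE),
            collapse = "")
    }, character(1))
    plant <- list()
    for (c in seq_len(k)) {
      linked <- lay$links$gene_id[lay$links$cluster == c]
      n_plant <- ceiling(cfg$motif_plant_rate * length(linked))
      for (tf in driver_tfs[[c]]) {
        chosen <- sample(linked, n_plant)
        pos <- sample.int(cfg$promoter_len - cfg$motif_len + 1L, n_plant,
                          replace = TRUE) - 1L
        for (j in seq_along(chosen)) {
          seqs[chosen[j]] <- plant_motif(seqs[chosen[j]], pwms[[tf]], pos[j])
        }
        plant[[length(plant) + 1L]] <- tibble::tibble(
          cluster = c, motif_id = tf, gene_id = chosen, position = pos)
      }
    }
    list(seqs = seqs, planted = dplyr::bind_rows(plant))
  })

  surv <- generate_survival(labels, cfg$baseline_hazard, cfg$censor_rate,
                            seed = substream_seed(seed, "survival_stage"))

  # genes planted with the full activation effect; the signature genes (at
  # signature_effect, typically weaker) are tracked separately in the truth
  de_genes <- lapply(seq_len(k), function(c) {
    sort(c(lay$links$gene_id[lay$links$cluster == c], driver_tfs[[c]]))
  })

  truth <- list(
    labels = labels,
    active_ses = lay$active_ses,
    links = lay$links,
    de_genes = de_genes,
    driver_tfs = driver_tfs,
    worst_cluster = worst,
    signature_genes = lay$sig_ids,
    motif_positions = promoters$planted)

  structure(list(
    se_rna = expr_matrix(2^se_l2, scale_tag = "raw"),
    mrna = expr_matrix(2^mrna_l2, scale_tag = "raw"),
    se_regions = lay$se_regions,
    tss_table = lay$tss_table,
    promoters = promoters$seqs,
    pwms = pwms,
    survival = surv,
    truth = truth,
    config = cfg), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0(
    "<synthetic_cohort> %d samples in %d clusters\n",
    "  seRNA: %d SEs | mRNA: %d features | %d PWMs | censoring ~%.0f%%\n"),
    ncol(x$se_rna), x$config$n_clusters, nrow(x$se_rna), nrow(x$mrna),
    length(x$pwms), 100 * x$config$censor_rate))
  invisible(x)
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Emits `se_rna.tsv`, `mrna.tsv`, `se_regions.bed`, `tss.tsv`,
#' `promoters.fasta`, `motifs.pfm`, `survival.tsv` and `truth.json`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$se_rna, file.path(dir, "se_rna.tsv"))
  write_expression(cohort$mrna, file.path(dir, "mrna.tsv"))
  write_bed(cohort$se_regions, file.path(dir, "se_regions.bed"))
  write_tss(cohort$tss_table, file.path(dir, "tss.tsv"))
  write_promoters(cohort$promoters, file.path(dir, "promoters.fasta"))
  write_pwm_library(cohort$pwms, file.path(dir, "motifs.pfm"))
  write_survival(cohort$survival, file.path(dir, "survival.tsv"))
  truth <- cohort$truth
  truth$labels <- as.list(truth$labels)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
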