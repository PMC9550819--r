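#' Fit per-cluster core transcription factors by one-vs-rest LASSO
#'
#' For each cluster, fits an L1-penalized logistic regression of
#' cluster-vs-rest membership on standardized log2 TF expression at a
#' cross-validated penalty (1-SE rule), and nominates the cluster's core TF
#' as the nonzero-weight TF with the largest absolute standardized weight.
#'
#' @param expr an [expr_matrix()] containing the candidate TFs as features.
#' @param labels cluster labels aligned with (or named by) the samples; at
#'   least 2 clusters.
#' @param candidate_tfs optional character vector restricting the features
#'   used (e.g. motifs with enrichment q <= 0.05).
#' @param index_cluster cluster whose linear predictor defines the scalar
#'   index; defaults to the highest-numbered cluster (the worst-prognosis
#'   analogue). Pipelines should pass the worst-prognosis cluster explicitly.
#' @param n_folds,seed passed to [cv_select_lambda()].
#' @return a `tf_index_model`: candidate TFs, per-cluster weights and
#'   intercepts, standardization constants, per-cluster core TFs,
#'   `selected_tfs` (union of nonzero-weight TFs) and `index_cluster`.
#' @export
fit_core_tfs <- function(expr, labels, candidate_tfs = NULL,
                         index_cluster = NULL, n_folds = 10, seed = 1) {
  stopifnot(inherits(expr, "expr_matrix"))
  labels <- align_labels(labels, colnames(expr))
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) abort("need >= 2 clusters to fit a contrast")
  m <- unclass(expr_log2(expr))
  if (!is.null(candidate_tfs)) {
    miss <- setdiff(candidate_tfs, rownames(m))
    if (length(miss)) {
      abort(sprintf("candidate TFs absent from expression: %s",
                    paste(head(miss, 5), collapse = ", ")))
    }
    m <- m[candidate_tfs, , drop = FALSE]
  }
  ctr <- rowMeans(m)
  scl <- apply(m, 1, sd)
  if (any(scl == 0)) {
    warn(sprintf("dropping %d zero-variance TF(s)", sum(scl == 0)))
    keep <- scl > 0
    m <- m[keep, , drop = FALSE]; ctr <- ctr[keep]; scl <- scl[keep]
  }
  if (nrow(m) == 0) abort("no usable candidate TFs")
  X <- t((m - ctr) / scl)
  fits <- lapply(clusters, function(cl) {
    y <- as.numeric(labels == cl)
    lam <- cv_select_lambda(X, y, n_folds = n_folds,
                            seed = substream_seed(seed, paste0("cv_", cl)))
    fit <- lasso_logistic(X, y, as.numeric(lam))
    core <- NA_character_
    nz <- which(fit$weights != 0)
    if (length(nz) == 0) {
      warn(sprintf("cluster %s: all LASSO weights are zero; no core TF", cl))
    } else {
      core <- names(fit$weights)[nz[which.max(abs(fit$weights[nz]))]]
    }
    list(fit = fit, core = core, lambda = as.numeric(lam))
  })
  weights <- vapply(fits, function(f) f$fit$weights, numeric(nrow(m)))
  if (is.null(dim(weights))) weights <- matrix(weights, nrow = nrow(m))
  dimnames(weights) <- list(rownames(m), as.character(clusters))
  structure(list(
    candidate_tfs = rownames(m),
    clusters = clusters,
    weights = weights,
    intercepts = setNames(vapply(fits, function(f) f$fit$intercept,
                                 numeric(1)), as.character(clusters)),
    lambdas = setNames(vapply(fits, `[[`, numeric(1), "lambda"),
                       as.character(clusters)),
    center = ctr, scale = scl,
    core_tfs = setNames(vapply(fits, `[[`, character(1), "core"),
                        as.character(clusters)),
    selected_tfs = sort(unique(unlist(lapply(fits, function(f) {
      names(f$fit$weights)[f$fit$weights != 0]
    })))),
    index_cluster = index_cluster %||% clusters[length(clusters)]),
    class = "tf_index_model")
}

#' @export
print.tf_index_model <- function(x, ...) {
  cat(sprintf("<tf_index_model> %d candidate TFs, clusters %s\n",
              length(x$candidate_tfs),
              paste(x$clusters, collapse = ", ")))
  cat("  core TFs:",
      paste(sprintf("%s=%s", names(x$core_tfs), x$core_tfs), collapse = ", "),
      sprintf("| index cluster %s\n", x$index_cluster))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.tf_index_model <- function(x, ...) {
  tibble::tibble(
    cluster = rep(colnames(x$weights), each = nrow(x$weights)),
    tf = rep(rownames(x$weights), times = ncol(x$weights)),
    weight = as.vector(x$weights)) |>
    dplyr::mutate(core = .data$tf == x$core_tfs[.data$cluster]) |>
    dplyr::filter(.data$weight != 0 | .data$core)
}

#' @exportS3Method generics::glance
glance.tf_index_model <- function(x, ...) {
  tibble::tibble(cluster = colnames(x$weights),
                 lambda = unname(x$lambdas),
                 n_nonzero = colSums(x$weights != 0),
                 core_tf = unname(x$core_tfs))
}

#' @exportS3Method ggplot2::autoplot
autoplot.tf_index_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$tf, .data$weight,
                                   fill = .data$core)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~cluster, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#b2182b",
                                          `FALSE` = "grey60"),
                               name = "core TF") +
    ggplot2::labs(x = NULL, y = "standardized LASSO weight") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @noRd
model_z <- function(model, expr, tfs) {
  stopifnot(inherits(expr, "expr_matrix"))
  miss <- setdiff(tfs, rownames(expr))
  if (length(miss)) {
    abort(sprintf("expression is missing model TF(s): %s",
                  paste(miss, collapse = ", ")))
  }
  m <- unclass(expr_log2(expr))[tfs, , drop = FALSE]
  (m - model$center[tfs]) / model$scale[tfs]
}

#' Per-sample multi-TF index
#'
#' The intercept-free linear predictor of the index cluster's model applied
#' to standardized log2 expression. Higher values mean more index-cluster
#' (worst-prognosis-analogue) character.
#'
#' @param model a [fit_core_tfs()] model.
#' @param expr an [expr_matrix()] containing all `selected_tfs`.
#' @return tibble with `sample_id`, `index`.
#' @export
build_tf_index <- function(model, expr) {
  w <- model$weights[, as.character(model$index_cluster)]
  need <- union(model$selected_tfs, names(w)[w != 0])
  z <- model_z(model, expr, if (length(need)) need else model$candidate_tfs)
  idx <- drop(crossprod(z[names(w)[names(w) %in% rownames(z)], , drop = FALSE],
                        w[names(w) %in% rownames(z)]))
  tibble::tibble(sample_id = colnames(expr), index = unname(idx))
}

#' Predict cluster membership from the TF index model
#'
#' Argmax over the per-cluster linear predictors (intercepts included); ties
#' break toward the lower cluster number.
#'
#' @inheritParams build_tf_index
#' @return tibble with `sample_id`, `cluster`.
#' @export
predict_clusters <- function(model, expr) {
  z <- model_z(model, expr, model$candidate_tfs)
  eta <- crossprod(z, model$weights)  # samples x clusters
  eta <- sweep(eta, 2, model$intercepts, "+")
  pick <- apply(eta, 1, which.max)  # which.max takes the first (lowest) tie
  tibble::tibble(sample_id = colnames(expr),
                 cluster = model$clusters[pick])
}
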