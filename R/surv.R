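#' Kaplan-Meier product-limit estimate
#'
#' Product-limit survival curve under right censoring (via
#' [survival::survfit()]). Censored times tied with event times are handled
#' with the standard convention: censoring takes effect after the events at
#' that time.
#'
#' @param records tibble with `sample_id`, `time`, `event`.
#' @return a `km_curve` tibble: `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`, restricted to observed times, plus an `n` attribute.
#' @export
km_estimate <- function(records) {
  if (is.null(records) || nrow(records) == 0) abort("no survival records")
  records <- validate_survival(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  out <- tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, n_censor = fit$n.censor,
                        survival = fit$surv)
  structure(out, n = nrow(records), class = c("km_curve", class(out)))
}

#' k-group log-rank test
#'
#' Observed-minus-expected event counts with hypergeometric covariance summed
#' over event times (via [survival::survdiff()]); the statistic is chi-square
#' with k-1 degrees of freedom.
#'
#' @param records tibble with `sample_id`, `time`, `event`.
#' @param groups group labels aligned with `records` rows (or named by sample
#'   id); every group must be non-empty.
#' @return a `logrank_result` list: `chi2`, `df`, `p`, `n_groups`,
#'   `group_sizes`.
#' @export
logrank_test <- function(records, groups) {
  records <- validate_survival(records)
  if (!is.null(names(groups))) {
    miss <- setdiff(records$sample_id, names(groups))
    if (length(miss)) {
      abort(sprintf("no group for samples: %s",
                    paste(head(miss, 5), collapse = ", ")))
    }
    groups <- groups[records$sample_id]
  }
  if (length(groups) != nrow(records)) {
    abort("groups must align with survival records")
  }
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2) abort("need >= 2 non-empty groups")
  df <- data.frame(time = records$time, event = records$event, g = groups)
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  k <- length(sizes)
  chi2 <- unname(sd_fit$chisq)
  structure(list(chi2 = chi2, df = k - 1L,
                 p = pchisq(chi2, df = k - 1L, lower.tail = FALSE),
                 n_groups = k, group_sizes = c(sizes)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank_result> chi2 = %.4g on %d df, p = %.3g (%d groups)\n",
              x$chi2, x$df, x$p, x$n_groups))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.logrank_result <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, df = x$df, p = x$p, n_groups = x$n_groups)
}

#' Single-sample signature score
#'
#' Mean per-gene z-score on log2 scale over the signature genes present in
#' the matrix. Zero-variance genes are dropped (with a warning) and excluded
#' from `n_genes_used`.
#'
#' @param expr an [expr_matrix()].
#' @param gene_set character vector of signature gene ids; at least one must
#'   be present in `expr`.
#' @return tibble with `sample_id`, `score`, `n_genes_used`.
#' @export
signature_score <- function(expr, gene_set) {
  stopifnot(inherits(expr, "expr_matrix"))
  present <- intersect(unique(gene_set), rownames(expr))
  if (length(present) == 0) abort("no signature gene present in expression")
  m <- unclass(expr_log2(expr))[present, , drop = FALSE]
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping %d zero-variance signature gene(s)", sum(sds == 0)))
    m <- m[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (nrow(m) == 0) abort("all signature genes have zero variance")
  z <- (m - rowMeans(m)) / sds
  tibble::tibble(sample_id = colnames(expr), score = unname(colMeans(z)),
                 n_genes_used = nrow(m))
}

#' Stratified survival report
#'
#' Groups samples either by supplied labels or by dichotomizing a per-sample
#' index (median split by default: above the cohort median is `"high"`),
#' estimates one Kaplan-Meier curve per group, and runs the k-group log-rank
#' test.
#'
#' @param records tibble with `sample_id`, `time`, `event` covering every
#'   grouped sample.
#' @param groups labels named by (or aligned with) sample ids; give either
#'   `groups` or `index`.
#' @param index tibble with `sample_id`, `index` (e.g. from
#'   [build_tf_index()]).
#' @param cut_rule only `"median"` is implemented.
#' @return a `km_report` list: `groups` (named vector), `curves` (tibble of
#'   per-group KM rows), `logrank` (`logrank_result`).
#' @export
stratified_km_report <- function(records, groups = NULL, index = NULL,
                                 cut_rule = "median") {
  records <- validate_survival(records)
  if (is.null(groups) == is.null(index)) {
    abort("supply exactly one of `groups` or `index`")
  }
  if (!is.null(index)) {
    if (cut_rule != "median") abort("only the median cut rule is implemented")
    groups <- setNames(ifelse(index$index > median(index$index),
                              "high", "low"), index$sample_id)
  }
  if (is.null(names(groups))) {
    if (length(groups) != nrow(records)) {
      abort("unnamed groups must align with survival records")
    }
    names(groups) <- records$sample_id
  }
  miss <- setdiff(records$sample_id, names(groups))
  extra <- setdiff(names(groups), records$sample_id)
  if (length(miss) || length(extra)) {
    abort(sprintf("unmatched sample ids between groups and survival: %s",
                  paste(head(c(miss, extra), 5), collapse = ", ")))
  }
  groups <- groups[records$sample_id]
  if (length(unique(groups)) < 2) abort("need >= 2 groups to stratify")
  curves <- dplyr::bind_rows(lapply(split(records, unname(groups)),
                                    function(r) {
    cv <- km_estimate(r)
    tibble::as_tibble(cv)
  }), .id = "group")
  structure(list(groups = groups, curves = curves,
                 logrank = logrank_test(records, groups)),
            class = "km_report")
}

#' @export
print.km_report <- function(x, ...) {
  cat(sprintf("<km_report> %d groups (%s)\n", x$logrank$n_groups,
              paste(names(x$logrank$group_sizes), x$logrank$group_sizes,
                    sep = "=", collapse = ", ")))
  print(x$logrank)
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.km_report <- function(object, ...) {
  df <- dplyr::bind_rows(lapply(split(object$curves, object$curves$group),
                                function(d) {
    tibble::tibble(group = d$group[1], time = c(0, d$time),
                   survival = c(1, d$survival))
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability",
                  subtitle = sprintf("log-rank chi2 = %.3g, df = %d, p = %.3g",
                                     object$logrank$chi2, object$logrank$df,
                                     object$logrank$p)) +
    ggplot2::theme_minimal()
}
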