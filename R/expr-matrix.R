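#' Expression matrix container
#'
#' A light wrapper around a numeric features x samples matrix carrying a scale
#' tag, used for both seRNA (super-enhancer RNA) and mRNA profiles. Raw-scale
#' matrices hold non-negative values; the `log2` tag marks matrices already
#' transformed with `log2(x + 1)` and prevents an accidental double transform.
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   unique rownames (feature ids) and colnames (sample ids).
#' @param scale_tag `"raw"` or `"log2"`.
#' @return an `expr_matrix` object.
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("f1", "f2"), c("s1", "s2")))
#' x <- expr_matrix(m)
#' expr_log2(x)
#' @export
expr_matrix <- function(values, scale_tag = c("raw", "log2")) {
  scale_tag <- match.arg(scale_tag)
  if (!is.matrix(values) || !is.numeric(values)) {
    format_error("expression values must be a numeric matrix")
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    format_error("expression matrix needs feature rownames and sample colnames")
  }
  assert_unique(fid, "feature ids", "expression matrix")
  assert_unique(sid, "sample ids", "expression matrix")
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    format_error("non-finite expression value at feature '%s', sample '%s'",
                 fid[bad[1]], sid[bad[2]])
  }
  if (scale_tag == "raw" && any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    format_error("negative raw-scale value at feature '%s', sample '%s'",
                 fid[bad[1]], sid[bad[2]])
  }
  structure(values, scale_tag = scale_tag,
            class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d features x %d samples [%s scale]\n",
              nrow(x), ncol(x), expr_scale(x)))
  print(head(unclass(x)[, seq_len(min(ncol(x), 6)), drop = FALSE], 4))
  invisible(x)
}

#' @rdname expr_matrix
#' @param x an `expr_matrix`.
#' @export
expr_scale <- function(x) attr(x, "scale_tag") %||% "raw"

#' Log-transform a raw expression matrix
#'
#' Applies `log2(x + 1)` once; a matrix already tagged `log2` is returned
#' unchanged so pipelines may call this idempotently.
#'
#' @param x an `expr_matrix`.
#' @return an `expr_matrix` tagged `log2`.
#' @export
expr_log2 <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (expr_scale(x) == "log2") return(x)
  expr_matrix(log2(unclass(x) + 1), scale_tag = "log2")
}

#' Read an expression matrix from a TSV file
#'
#' Tab-separated, first column feature ids, header row sample ids. Row and
#' column order are preserved. Duplicate ids, non-numeric cells and empty
#' files raise format errors naming the offender.
#'
#' @param path file path.
#' @param scale_tag scale of the stored values (`"raw"` default).
#' @return an `expr_matrix`.
#' @export
read_expression <- function(path, scale_tag = "raw") {
  if (!file.exists(path) || file.size(path) == 0) {
    format_error("empty or missing expression file: %s", path)
  }
  tab <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "")
  if (nrow(tab) == 0 || ncol(tab) < 2) {
    format_error("expression file %s has no data cells", path)
  }
  fid <- tab[[1]]
  sid <- colnames(tab)[-1]
  assert_unique(fid, "feature ids", path)
  assert_unique(sid, "sample ids", path)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (any(is.na(num))) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    format_error("non-numeric expression cell at row '%s', column '%s' in %s",
                 fid[bad[1]], sid[bad[2]], path)
  }
  dimnames(num) <- list(fid, sid)
  expr_matrix(num, scale_tag = scale_tag)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()]: full `%.17g` precision so a write/read
#' round trip reproduces values to better than 1e-12.
#'
#' @param x an `expr_matrix`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  lines <- c(
    paste(c("feature_id", colnames(x)), collapse = "\t"),
    vapply(seq_len(nrow(x)), function(i) {
      paste(c(rownames(x)[i], sprintf("%.17g", unclass(x)[i, ])),
            collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @exportS3Method tibble::as_tibble
as_tibble.expr_matrix <- function(x, ...) {
  tibble::tibble(
    feature_id = rep(rownames(x), times = ncol(x)),
    sample_id = rep(colnames(x), each = nrow(x)),
    value = as.vector(unclass(x))
  )
}
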