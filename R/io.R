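#' Read super-enhancer regions from a BED file
#'
#' BED3+1 (chrom, start, end, name), 0-based half-open coordinates — the
#' convention used for every interval in this package. A missing name column
#' is synthesized as `"chrom:start-end"`. Order is preserved.
#'
#' @param path BED file path.
#' @return tibble with columns `se_id`, `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) format_error("missing BED file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(se_id = character(), chrom = character(),
                          start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (any(n_col < 3)) {
    format_error("BED line %d has fewer than 3 columns in %s",
                 which(n_col < 3)[1], path)
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, character(1), 3)))
  if (any(is.na(start)) || any(is.na(end))) {
    format_error("non-integer BED coordinate in %s", path)
  }
  if (any(start >= end)) {
    i <- which(start >= end)[1]
    format_error("BED interval with start >= end at line %d (%s:%d-%d) in %s",
                 i, chrom[i], start[i], end[i], path)
  }
  se_id <- ifelse(n_col >= 4, vapply(fields, function(f) f[min(4, length(f))],
                                     character(1)),
                  sprintf("%s:%d-%d", chrom, start, end))
  out <- tibble::tibble(se_id = se_id, chrom = chrom, start = start, end = end)
  assert_unique(out$se_id, "SE ids", path)
  out
}

#' @rdname read_bed
#' @param regions tibble with `se_id`, `chrom`, `start`, `end`.
#' @export
write_bed <- function(regions, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", regions$chrom, regions$start,
                     regions$end, regions$se_id), path)
  invisible(path)
}

#' Read a gene TSS annotation table
#'
#' TSV with columns `gene_id`, `chrom`, `tss` (0-based position) and `strand`
#' (`+`/`-`).
#'
#' @param path TSV file path.
#' @return tibble with those four columns.
#' @export
read_tss <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), chrom = readr::col_character(),
    tss = readr::col_integer(), strand = readr::col_character()))
  assert_unique(tab$gene_id, "gene ids", path)
  if (any(tab$tss < 0)) format_error("negative TSS position in %s", path)
  if (!all(tab$strand %in% c("+", "-"))) {
    format_error("strand must be '+' or '-' in %s", path)
  }
  tibble::as_tibble(tab)
}

#' @rdname read_tss
#' @param tss_table tibble as returned by `read_tss()`.
#' @export
write_tss <- function(tss_table, path) {
  readr::write_tsv(tss_table[, c("gene_id", "chrom", "tss", "strand")], path)
  invisible(path)
}

#' Construct a position weight matrix
#'
#' Counts (or probabilities) are normalized per position over the alphabet
#' A, C, G, T after adding a pseudocount, so every row of `probs` sums to one
#' and all-zero columns in the source counts become uniform.
#'
#' @param motif_id motif identifier.
#' @param counts L x 4 non-negative matrix (rows = positions, columns
#'   A, C, G, T).
#' @param pseudocount added to every cell before normalization; must be > 0
#'   unless all positions already have positive mass.
#' @return a `pwm` object: list with `motif_id`, `probs` (L x 4), `pseudocount`.
#' @export
pwm <- function(motif_id, counts, pseudocount = 0.01) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4 || nrow(counts) < 1) {
    format_error("PWM '%s' must be an L x 4 matrix with L >= 1", motif_id)
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    format_error("PWM '%s' has negative or non-finite counts", motif_id)
  }
  if (pseudocount < 0) format_error("pseudocount must be >= 0")
  if (any(rowSums(counts) == 0)) {
    if (pseudocount == 0) {
      format_error("PWM '%s' has an all-zero position and pseudocount 0",
                   motif_id)
    }
    warn(sprintf("PWM '%s': all-zero position made uniform by pseudocount",
                 motif_id))
  }
  padded <- counts + pseudocount
  probs <- padded / rowSums(padded)
  colnames(probs) <- c("A", "C", "G", "T")
  rownames(probs) <- NULL
  structure(list(motif_id = motif_id, probs = probs,
                 pseudocount = pseudocount), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, %d positions, consensus %s\n", x$motif_id,
              nrow(x$probs), pwm_consensus(x)))
  invisible(x)
}

#' Consensus sequence of a PWM (argmax base per position)
#' @param x a `pwm`.
#' @return character scalar.
#' @export
pwm_consensus <- function(x) {
  paste(colnames(x$probs)[apply(x$probs, 1, which.max)], collapse = "")
}

#' Read a JASPAR-style PFM library
#'
#' Plain text: a `>motif_id` header line, then four lines of whitespace- (or
#' bracket-) delimited counts in A, C, G, T order. Counts are normalized to
#' probabilities per position with `pseudocount` added first.
#'
#' @param path PFM text file.
#' @param pseudocount see [pwm()].
#' @return named list of `pwm` objects.
#' @export
read_pwm_library <- function(path, pseudocount = 0.01) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0) format_error("no motif headers ('>') in %s", path)
  bounds <- c(heads, length(lines) + 1L)
  out <- lapply(seq_along(heads), function(i) {
    id <- sub("^>\\s*", "", lines[heads[i]])
    id <- strsplit(id, "\\s+")[[1]][1]
    body <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) != 4) {
      format_error("motif '%s' must have 4 count rows (A,C,G,T), found %d",
                   id, length(body))
    }
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGT]\\s*", "", l)
      l <- gsub("[\\[\\]]", " ", l, perl = TRUE)
      v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      if (any(is.na(v))) format_error("non-numeric count in motif '%s'", id)
      v
    })
    if (length(unique(lengths(rows))) != 1) {
      format_error("motif '%s' has count rows of unequal length", id)
    }
    pwm(id, t(do.call(rbind, rows)), pseudocount = pseudocount)
  })
  names(out) <- vapply(out, `[[`, character(1), "motif_id")
  assert_unique(names(out), "motif ids", path)
  out
}

#' @rdname read_pwm_library
#' @param pwms named list of `pwm` objects.
#' @param counts_scale counts written as `probs * counts_scale` (default 100).
#' @export
write_pwm_library <- function(pwms, path, counts_scale = 100) {
  lines <- unlist(lapply(pwms, function(p) {
    counts <- t(p$probs) * counts_scale
    c(paste0(">", p$motif_id),
      vapply(1:4, function(r) {
        paste0(c("A", "C", "G", "T")[r], " [ ",
               paste(sprintf("%.4f", counts[r, ]), collapse = " "), " ]")
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a survival table
#'
#' TSV with columns `sample_id`, `time` (> 0, unitless but consistent within a
#' cohort) and `event` (1 = event, 0 = right-censored).
#'
#' @param path TSV file path.
#' @return tibble with those three columns.
#' @export
read_survival <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), time = readr::col_double(),
    event = readr::col_double()))
  validate_survival(tibble::as_tibble(tab), where = path)
}

#' @noRd
validate_survival <- function(tab, where = "survival table") {
  assert_unique(tab$sample_id, "sample ids", where)
  if (any(!is.finite(tab$time)) || any(tab$time <= 0)) {
    i <- which(!is.finite(tab$time) | tab$time <= 0)[1]
    format_error("non-positive survival time for sample '%s' in %s",
                 tab$sample_id[i], where)
  }
  if (!all(tab$event %in% c(0, 1))) {
    i <- which(!tab$event %in% c(0, 1))[1]
    format_error("event must be 0 or 1; sample '%s' has %s in %s",
                 tab$sample_id[i], tab$event[i], where)
  }
  tab
}

#' @rdname read_survival
#' @param survival_table tibble with `sample_id`, `time`, `event`.
#' @export
write_survival <- function(survival_table, path) {
  readr::write_tsv(survival_table[, c("sample_id", "time", "event")], path)
  invisible(path)
}

#' Read promoter sequences from FASTA
#'
#' Record ids are gene ids; sequences are returned as a named uppercase
#' character vector over A/C/G/T/N.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_promoters <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  assert_unique(names(out), "promoter ids", path)
  out
}

#' @rdname read_promoters
#' @param promoters named character vector of sequences.
#' @export
write_promoters <- function(promoters, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(promoters), path, width = 80)
  invisible(path)
}
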