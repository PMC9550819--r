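#' @noRd
format_error <- function(msg, ...) {
  abort(paste0(sprintf(msg, ...)), class = "sestrat_format_error")
}

#' @noRd
config_error <- function(msg, ...) {
  abort(paste0(sprintf(msg, ...)), class = "sestrat_config_error")
}

# Derive a reproducible 32-bit sub-seed for one named component of a larger
# seeded computation, so adding a component never perturbs earlier draws.
# Lehmer-style mix over the component name's bytes; result in [1, 2^31 - 2].
#' @noRd
substream_seed <- function(seed, component) {
  m <- 2147483647
  h <- as.double(seed %% m)
  for (b in utf8ToInt(component)) {
    h <- (h * 48271 + b) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate `expr` under a temporary RNG state seeded from (seed, component),
# restoring the caller's RNG state afterwards.
#' @noRd
with_substream <- function(seed, component, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(substream_seed(seed, component))
  force(expr)
}

#' @noRd
assert_unique <- function(x, what, where = "input") {
  d <- unique(x[duplicated(x)])
  if (length(d) > 0) {
    format_error("duplicate %s in %s: %s", what, where,
                 paste(head(d, 5), collapse = ", "))
  }
  invisible(x)
}

#' @noRd
stage_hash <- function(x) {
  unname(rlang::hash(x))
}
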