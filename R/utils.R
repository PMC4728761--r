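stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

DNA_BASES <- c("A", "C", "G", "T")

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single non-missing number", name)
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stopf("'%s' must be in %s%s, %s%s (got %g)", name,
          if (open_lower) "(" else "[", format(lower),
          format(upper), if (open_upper) ")" else "]", x)
  invisible(x)
}

#' Derive reproducible sub-seeds from a master seed
#'
#' Each module of a run draws from its own random substream; the substream
#' seeds are derived deterministically from the single master seed so that
#' one integer reproduces an entire study.
#'
#' @param seed master seed (integer).
#' @param n number of sub-seeds to derive.
#' @return integer vector of `n` seeds, each below 2^31.
#' @export
derive_seeds <- function(seed, n) {
  assert_scalar_number(seed, "seed")
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

## all(x is single A/C/G/T)
is_dna_base <- function(x) {
  is.character(x) & !is.na(x) & x %in% DNA_BASES
}

write_tsv_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_file <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
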