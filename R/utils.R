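#' The 20 standard amino acids
#'
#' One-letter codes of the 20 standard residues, in alphabetical order.
#' This is the alphabet used by the motif engine and the family simulator;
#' `X` (unknown residue) is deliberately not part of it.
#'
#' @return A character vector of length 20.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

## internal error helper: all user-facing validation errors share a class so
## callers (and the CLI) can distinguish bad input from runtime failures
stop_gmrsd <- function(msg, class = "gmrsdkit_validation_error") {
  rlang::abort(msg, class = class)
}

assert_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE,
                          strict_max = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict_min) x > min else x >= min) &&
    (if (strict_max) x < max else x <= max)
  if (!ok) {
    stop_gmrsd(sprintf(
      "`%s` must be a single number in %s%s, %s%s; got %s",
      name, if (strict_min) "(" else "[", format(min),
      format(max), if (strict_max) ")" else "]",
      paste(format(x), collapse = ", ")
    ))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x >= min && x == as.integer(x)
  if (!ok) {
    stop_gmrsd(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

assert_columns <- function(df, cols, name) {
  if (!is.data.frame(df)) {
    stop_gmrsd(sprintf("`%s` must be a data frame", name))
  }
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_gmrsd(sprintf(
      "`%s` is missing required column(s): %s",
      name, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

## seeds handed to downstream set.seed() calls must stay valid R integers
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 104729 * offset) %% .Machine$integer.max)
}
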