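#' Compile a degenerate protein motif pattern
#'
#' Parses the compact notation used for protein signature motifs: fixed
#' upper-case residues, parenthesized slash-separated alternatives such as
#' `(I/L/V)`, and a lower-case `x` wildcard matching any of the 20 standard
#' residues. For example `"NxxFxxKK"` compiles to 8 elements and
#' `"(I/V)(I/V)DGQQRLTT(I/L/V)xLL"` to 14.
#'
#' @param pattern_text Motif in the notation above.
#' @param name Optional motif name; defaults to the pattern text.
#' @return An object of class `motif_pattern`: a list with `name`,
#'   `text` (canonical notation) and `elements`, a list of character vectors
#'   of allowed residues per position (wildcards expand to the full
#'   alphabet).
#' @examples
#' compile_motif("NxxFxxKK")
#' @export
compile_motif <- function(pattern_text, name = pattern_text) {
  if (!is.character(pattern_text) || length(pattern_text) != 1L ||
      !nzchar(pattern_text)) {
    stop_gmrsd("`pattern_text` must be a single non-empty string")
  }
  aa <- aa_alphabet()
  chars <- strsplit(pattern_text, "", fixed = TRUE)[[1]]
  elements <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      close <- which(chars == ")" & seq_len(n) > i)
      if (!length(close)) {
        stop_gmrsd(sprintf("motif parse error at position %d: unclosed '('", i))
      }
      close <- close[1]
      inner <- paste(chars[(i + 1L):(close - 1L)], collapse = "")
      alts <- strsplit(inner, "/", fixed = TRUE)[[1]]
      if (!length(alts) || any(!nzchar(alts)) || any(nchar(alts) != 1L) ||
          any(!alts %in% aa) ||
          grepl("^/|//|/$", inner)) {
        stop_gmrsd(sprintf(
          "motif parse error at position %d: malformed alternative set '(%s)'",
          i, inner
        ))
      }
      elements <- c(elements, list(unique(alts)))
      i <- close + 1L
    } else if (ch == "x" || ch == ".") {
      elements <- c(elements, list(aa))
      i <- i + 1L
    } else if (ch %in% aa) {
      elements <- c(elements, list(ch))
      i <- i + 1L
    } else {
      stop_gmrsd(sprintf(
        "motif parse error at position %d: '%s' is not an amino acid, 'x' or '('",
        i, ch
      ))
    }
  }
  structure(
    list(name = name, text = motif_text_from_elements(elements),
         elements = elements),
    class = "motif_pattern"
  )
}

motif_text_from_elements <- function(elements) {
  aa <- aa_alphabet()
  paste(vapply(elements, function(e) {
    if (length(e) == 1L) e
    else if (setequal(e, aa)) "x"
    else paste0("(", paste(e, collapse = "/"), ")")
  }, character(1)), collapse = "")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s: %s (%d elements)\n",
              x$name, x$text, length(x$elements)))
  invisible(x)
}

#' @export
length.motif_pattern <- function(x) length(x$elements)

#' The GmrS and GmrD family signature motifs
#'
#' The conserved degenerate motifs of the GmrSD family: the GmrS (DUF262)
#' motif whose DGQQR core resembles the DGQHR-domain signature and is tied
#' to the UTPase activity, the three strongly conserved GmrD (DUF1524)
#' motifs of the HNH-endonuclease region, and the weakly conserved
#' tryptophan-flanked GmrD motif.
#'
#' @return A tibble with columns `name`, `region` (`"S"` or `"D"`), `text`,
#'   and `motif` (list-column of compiled [compile_motif()] patterns).
#' @export
gmrsd_motifs <- function() {
  def <- tibble::tribble(
    ~name,           ~region, ~text,
    "gmrs_dgqqr",    "S",     "(I/V)(I/V)DGQQRLTT(I/L/V)xLL",
    "gmrd_edh_pq",   "D",     "(I/L/V)(E/D)H(I/L/V)xPQ",
    "gmrd_lgnl",     "D",     "L(G/A)NLxLLxxxN",
    "gmrd_nxxfxxkk", "D",     "NxxFxxKK",
    "gmrd_w_weak",   "D",     "Wxxxx(I/L/V)xxRxxxLxxxxxx(I/L/V)W"
  )
  def$motif <- purrr::map2(def$text, def$name, compile_motif)
  def
}

#' Scan an ungapped protein sequence for a degenerate motif
#'
#' Reports every (possibly overlapping) start position at which all motif
#' elements match: fixed residues by equality, alternative sets by
#' membership, wildcards by any standard residue. Comparison is
#' case-insensitive; `X` (unknown residue) in the sequence matches nothing.
#'
#' @param sequence A single ungapped amino-acid string.
#' @param pattern A [compile_motif()] pattern (or pattern text).
#' @return A tibble with columns `pattern`, `start`, `end` (1-based,
#'   closed). Sequences shorter than the pattern give zero rows.
#' @examples
#' scan_motif("NAAFGGKK", "NxxFxxKK")
#' @export
scan_motif <- function(sequence, pattern) {
  if (is.character(pattern)) pattern <- compile_motif(pattern)
  if (!inherits(pattern, "motif_pattern")) {
    stop_gmrsd("`pattern` must be a motif_pattern or pattern text")
  }
  if (!is.character(sequence) || length(sequence) != 1L) {
    stop_gmrsd("`sequence` must be a single string")
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  m <- length(pattern$elements)
  L <- length(chars)
  empty <- tibble::tibble(pattern = character(0), start = integer(0),
                          end = integer(0))
  if (L < m) return(empty)
  ok <- rep(TRUE, L - m + 1L)
  for (j in seq_len(m)) {
    ok <- ok & chars[seq.int(j, j + L - m)] %in% pattern$elements[[j]]
  }
  starts <- which(ok)
  tibble::tibble(pattern = rep(pattern$name, length(starts)),
                 start = as.integer(starts),
                 end = as.integer(starts + m - 1L))
}

#' Scan many sequences for many motifs
#'
#' @param sequences Named character vector (or tibble with `seq_id` and
#'   `sequence` columns) of ungapped protein sequences.
#' @param patterns A list of [compile_motif()] patterns, a character vector
#'   of pattern texts, or the tibble returned by [gmrsd_motifs()].
#' @return A tibble with columns `seq_id`, `pattern`, `start`, `end`.
#' @export
scan_motifs <- function(sequences, patterns = gmrsd_motifs()) {
  if (is.data.frame(sequences)) {
    assert_columns(sequences, c("seq_id", "sequence"), "sequences")
    sequences <- setNames(sequences$sequence, sequences$seq_id)
  }
  if (is.null(names(sequences))) {
    names(sequences) <- sprintf("seq%04d", seq_along(sequences))
  }
  patterns <- as_motif_list(patterns)
  out <- purrr::map_dfr(names(sequences), function(id) {
    purrr::map_dfr(patterns, function(p) {
      res <- scan_motif(sequences[[id]], p)
      if (nrow(res)) dplyr::mutate(res, seq_id = id, .before = 1) else NULL
    })
  })
  if (!nrow(out)) {
    out <- tibble::tibble(seq_id = character(0), pattern = character(0),
                          start = integer(0), end = integer(0))
  }
  out
}

as_motif_list <- function(patterns) {
  if (is.data.frame(patterns) && "motif" %in% names(patterns)) {
    return(patterns$motif)
  }
  if (inherits(patterns, "motif_pattern")) return(list(patterns))
  lapply(patterns, function(p) if (is.character(p)) compile_motif(p) else p)
}

#' Locate motifs in an alignment via its consensus
#'
#' Slides each motif along the columns of the alignment and reports windows
#' in which every motif element is satisfied by the column's modal (most
#' frequent non-gap) residue at a frequency of at least `min_column_freq`.
#' This operationalizes reading a signature motif off a family alignment's
#' conservation profile.
#'
#' @param msa An [msa()] object.
#' @param patterns As in [scan_motifs()].
#' @param min_column_freq Minimum modal-residue frequency per column
#'   (fraction of all sequences, gapped rows included in the denominator).
#' @return A tibble with columns `pattern`, `col_start`, `col_end`
#'   (alignment columns, 1-based closed).
#' @export
scan_alignment_consensus <- function(msa, patterns = gmrsd_motifs(),
                                     min_column_freq = 0.9) {
  msa <- as_msa(msa)
  assert_number(min_column_freq, "min_column_freq", min = 0, max = 1)
  prof <- conservation_profile(msa)
  patterns <- as_motif_list(patterns)
  modal <- prof$residue
  freq <- prof$frequency
  W <- nrow(prof)
  purrr::map_dfr(patterns, function(p) {
    m <- length(p$elements)
    if (W < m) return(NULL)
    ok <- rep(TRUE, W - m + 1L)
    for (j in seq_len(m)) {
      col <- seq.int(j, j + W - m)
      ok <- ok & !is.na(modal[col]) & freq[col] >= min_column_freq &
        modal[col] %in% p$elements[[j]]
    }
    starts <- which(ok)
    if (!length(starts)) return(NULL)
    tibble::tibble(pattern = p$name, col_start = as.integer(starts),
                   col_end = as.integer(starts + m - 1L))
  })
}

#' Expected number of chance motif matches in a random sequence
#'
#' Closed-form expectation of the number of match positions for a motif in
#' an i.i.d. residue sequence: `(L - m + 1) * prod_j(p_j)` where `p_j` is
#' the probability that a random residue satisfies element `j` under the
#' given residue distribution.
#'
#' @param pattern A [compile_motif()] pattern (or text).
#' @param seq_length Sequence length L (total positions scanned is
#'   `L - m + 1`).
#' @param residue_freqs Optional named numeric of residue frequencies
#'   (default uniform over the 20 standard residues).
#' @return A single number, the expected match count.
#' @export
expected_motif_matches <- function(pattern, seq_length,
                                   residue_freqs = NULL) {
  if (is.character(pattern)) pattern <- compile_motif(pattern)
  aa <- aa_alphabet()
  if (is.null(residue_freqs)) {
    residue_freqs <- setNames(rep(1 / 20, 20), aa)
  }
  residue_freqs <- residue_freqs / sum(residue_freqs)
  m <- length(pattern$elements)
  if (seq_length < m) return(0)
  p_el <- vapply(pattern$elements, function(e) {
    sum(residue_freqs[intersect(e, names(residue_freqs))])
  }, numeric(1))
  (seq_length - m + 1) * prod(p_el)
}
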