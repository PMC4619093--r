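#' Multiple sequence alignment objects
#'
#' A lightweight container for an aligned protein family: a named character
#' vector of equal-length aligned sequences (gap character `-`) carrying
#' class `msa`. Construct from a named character vector, a tibble with
#' `id`/`seq_id` and `sequence` columns, or an existing `msa`.
#'
#' @param x Sequences as described above.
#' @return An `msa` object.
#' @examples
#' m <- msa(c(a = "AC-D", b = "ACAD"))
#' msa_width(m)
#' @export
msa <- function(x) {
  if (inherits(x, "msa")) return(x)
  if (is.data.frame(x)) {
    idcol <- intersect(c("id", "seq_id"), names(x))[1]
    if (is.na(idcol) || !"sequence" %in% names(x)) {
      stop_gmrsd("a data-frame `x` must have an `id`/`seq_id` and a `sequence` column")
    }
    x <- setNames(x$sequence, x[[idcol]])
  }
  if (!is.character(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    stop_gmrsd("`x` must be a named character vector of aligned sequences")
  }
  if (anyDuplicated(names(x))) {
    stop_gmrsd("alignment ids must be unique")
  }
  w <- unique(nchar(x))
  if (length(x) && length(w) != 1L) {
    stop_gmrsd("all aligned sequences must have the same length")
  }
  structure(toupper(x), class = "msa")
}

as_msa <- msa

#' @export
print.msa <- function(x, n = 6, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", length(x), msa_width(x)))
  ids <- utils::head(names(x), n)
  for (id in ids) {
    s <- unclass(x)[[id]]
    cat(sprintf("  %-20s %s\n", id,
                if (nchar(s) > 50) paste0(substr(s, 1, 50), "...") else s))
  }
  if (length(x) > n) cat(sprintf("  ... and %d more\n", length(x) - n))
  invisible(x)
}

#' @rdname msa
#' @export
msa_width <- function(x) {
  x <- as_msa(x)
  if (!length(x)) 0L else nchar(unclass(x)[[1]])
}

#' @export
as.matrix.msa <- function(x, ...) {
  if (!length(x)) return(matrix(character(0), nrow = 0, ncol = 0))
  m <- do.call(rbind, strsplit(unclass(x), "", fixed = TRUE))
  rownames(m) <- names(x)
  m
}

msa_from_matrix <- function(m) {
  if (!nrow(m)) return(msa(setNames(character(0), character(0))))
  msa(setNames(apply(m, 1, paste, collapse = ""), rownames(m)))
}

#' @rdname msa
#' @param msa An `msa` object.
#' @export
msa_ungap <- function(msa) {
  msa <- as_msa(msa)
  setNames(gsub("-", "", unclass(msa), fixed = TRUE), names(msa))
}

#' Drop alignment columns that are gaps in every sequence
#'
#' @param msa An [msa()] object.
#' @return An `msa` with all-gap columns removed.
#' @export
msa_drop_gap_columns <- function(msa) {
  msa <- as_msa(msa)
  if (!length(msa)) return(msa)
  m <- as.matrix(msa)
  keep <- colSums(m != "-") > 0
  msa_from_matrix(m[, keep, drop = FALSE])
}

#' Restrict an alignment to a subset of sequence ids
#'
#' @param msa An [msa()] object.
#' @param ids Ids to keep, in the order given.
#' @return An `msa` containing only `ids` (columns untouched).
#' @export
msa_restrict <- function(msa, ids) {
  msa <- as_msa(msa)
  missing <- setdiff(ids, names(msa))
  if (length(missing)) {
    stop_gmrsd(sprintf("id(s) not in alignment: %s",
                       paste(missing, collapse = ", ")))
  }
  structure(unclass(msa)[ids], class = "msa")
}

#' Read / write aligned FASTA
#'
#' Thin wrappers over Biostrings for aligned protein FASTA files.
#'
#' @param path File path.
#' @return `read_fasta_msa()` returns an [msa()]; `write_fasta_msa()`
#'   returns `path` invisibly.
#' @export
read_fasta_msa <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop_gmrsd("reading FASTA requires the Biostrings package")
  }
  x <- Biostrings::readBStringSet(path)
  msa(setNames(as.character(x), names(x)))
}

#' @rdname read_fasta_msa
#' @param msa An [msa()] object (or any named character vector of
#'   sequences, for unaligned output).
#' @export
write_fasta_msa <- function(msa, path) {
  seqs <- if (inherits(msa, "msa")) unclass(msa) else msa
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop_gmrsd("writing FASTA requires the Biostrings package")
  }
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

## split an alignment's columns into anchor columns (those carrying at
## least one backbone residue) and the insertion columns between them
anchor_map <- function(m, backbone) {
  bm <- m[backbone, , drop = FALSE]
  is_anchor <- colSums(bm != "-") > 0
  anchors <- which(is_anchor)
  ## slot of every insertion column: number of anchors to its left (0..K)
  slot <- cumsum(is_anchor)
  list(anchors = anchors,
       insertions = split(which(!is_anchor), slot[!is_anchor]))
}

#' Merge two alignments sharing a backbone of identical sequences
#'
#' Implements the bookkeeping used to combine one family alignment extended
#' with GmrS-only sequences and a second extended with GmrD-only sequences:
#' both alignments contain the same backbone (the double-domain sequences,
#' identically aligned), and each adds its own set of single-domain
#' sequences with possible insertion columns. The merge interleaves the two
#' alignments' insertion columns around the shared backbone columns, so
#' stretches of gaps of equal length are inserted identically into every
#' backbone sequence wherever one alignment's additions overflow the other.
#'
#' Restricting the merged alignment to the backbone ids and deleting columns
#' that are all-gap within that restriction reproduces the backbone portion
#' of either input column-for-column, and every sequence's ungapped residues
#' are preserved exactly.
#'
#' @param aln_a,aln_b [msa()] objects sharing `backbone_ids`.
#' @param backbone_ids Ids present in both alignments; their ungapped
#'   sequences must be identical in the two, and the backbone sub-alignments
#'   (after dropping columns that are all-gap within the backbone) must
#'   agree column-for-column.
#' @return An [msa()] containing every id of `aln_a` and `aln_b` once
#'   (rows of `aln_a` first, then the non-backbone rows of `aln_b`).
#' @export
merge_alignments <- function(aln_a, aln_b, backbone_ids) {
  aln_a <- as_msa(aln_a)
  aln_b <- as_msa(aln_b)
  if (!length(backbone_ids)) {
    stop_gmrsd("`backbone_ids` must name at least one shared sequence")
  }
  for (nm in c("aln_a", "aln_b")) {
    aln <- get(nm)
    missing <- setdiff(backbone_ids, names(aln))
    if (length(missing)) {
      stop_gmrsd(sprintf("backbone id(s) missing from `%s`: %s", nm,
                         paste(missing, collapse = ", ")))
    }
  }
  ug_a <- msa_ungap(msa_restrict(aln_a, backbone_ids))
  ug_b <- msa_ungap(msa_restrict(aln_b, backbone_ids))
  bad <- backbone_ids[ug_a != ug_b]
  if (length(bad)) {
    stop_gmrsd(sprintf(
      "backbone sequence(s) differ between the alignments after gap removal: %s",
      paste(bad, collapse = ", ")
    ))
  }

  ma <- as.matrix(aln_a)
  mb <- as.matrix(aln_b)
  am_a <- anchor_map(ma, backbone_ids)
  am_b <- anchor_map(mb, backbone_ids)
  K <- length(am_a$anchors)
  if (length(am_b$anchors) != K ||
      !identical(ma[backbone_ids, am_a$anchors, drop = FALSE],
                 mb[backbone_ids, am_b$anchors, drop = FALSE])) {
    stop_gmrsd("the backbone sub-alignments of `aln_a` and `aln_b` are not identical column-for-column")
  }

  a_only <- names(aln_a)  # backbone rows are taken from A
  b_only <- setdiff(names(aln_b), backbone_ids)
  out_ids <- c(a_only, b_only)
  gap_row <- function(k, nrow) matrix("-", nrow = nrow, ncol = k)

  blocks <- vector("list", 2L * (K + 1L) + K)
  bi <- 0L
  push <- function(block) {
    bi <<- bi + 1L
    blocks[[bi]] <<- block
  }
  ins_cols <- function(am, slot) {
    cols <- am$insertions[[as.character(slot)]]
    if (is.null(cols)) integer(0) else cols
  }
  for (slot in 0:K) {
    ca <- ins_cols(am_a, slot)
    if (length(ca)) {
      push(rbind(ma[a_only, ca, drop = FALSE],
                 gap_row(length(ca), length(b_only))))
    }
    cb <- ins_cols(am_b, slot)
    if (length(cb)) {
      ## B's insertion columns are all-gap in backbone rows by construction
      top <- gap_row(length(cb), length(a_only))
      push(rbind(top, mb[b_only, cb, drop = FALSE]))
    }
    if (slot < K) {
      k_a <- am_a$anchors[slot + 1L]
      k_b <- am_b$anchors[slot + 1L]
      push(rbind(ma[a_only, k_a, drop = FALSE],
                 mb[b_only, k_b, drop = FALSE]))
    }
  }
  out <- do.call(cbind, blocks[seq_len(bi)])
  rownames(out) <- out_ids
  msa_from_matrix(out)
}

#' Per-column conservation profile of an alignment
#'
#' For every column, reports the modal non-gap residue and its frequency
#' over all sequences (gapped rows count in the denominator: conservation
#' is measured over sequences, not over residues present), and marks
#' columns whose modal frequency strictly exceeds the threshold — the
#' `+`-mark convention for residues conserved in more than 95% of family
#' members. `X` (unknown residue) is never a modal candidate.
#'
#' @param msa An [msa()] object.
#' @param threshold Strict lower bound for the `plus_mark` (default 0.95).
#' @return A tibble of class `gmrsd_conservation` with columns `column`,
#'   `residue` (NA for all-gap columns), `frequency` and `plus_mark`.
#' @examples
#' conservation_profile(msa(c(a = "AAC", b = "AAC", c = "A-T")))
#' @export
conservation_profile <- function(msa, threshold = 0.95) {
  msa <- as_msa(msa)
  assert_number(threshold, "threshold", min = 0, max = 1)
  if (!length(msa)) {
    stop_gmrsd("`msa` must contain at least one sequence")
  }
  m <- as.matrix(msa)
  n <- nrow(m)
  aa <- aa_alphabet()
  counts <- vapply(aa, function(res) colSums(m == res), numeric(ncol(m)))
  if (ncol(m) == 1L) counts <- matrix(counts, nrow = 1L,
                                      dimnames = list(NULL, aa))
  best <- max.col(counts, ties.method = "first")
  best_count <- counts[cbind(seq_len(nrow(counts)), best)]
  freq <- best_count / n
  residue <- ifelse(best_count > 0, aa[best], NA_character_)
  out <- tibble::tibble(
    column = seq_len(ncol(m)),
    residue = residue,
    frequency = freq,
    plus_mark = freq > threshold
  )
  class(out) <- c("gmrsd_conservation", class(out))
  attr(out, "threshold") <- threshold
  attr(out, "n_sequences") <- n
  out
}
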