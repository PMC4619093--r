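#' Extract the genomic neighborhood of a focal gene
#'
#' Returns the ORFs with ordinal distance 1..k from the focal gene on the
#' focal gene's contig — the k ORFs upstream and k downstream that define
#' the defense-island window. The focal ORF itself is excluded. The window
#' is truncated (flagged) when a contig boundary cuts either side.
#'
#' @param annotation Ordered-ORF table: tibble with `genome_id`,
#'   `contig_id`, `orf_index`, `protein_id` (e.g. from
#'   [simulate_genomes()] or [read_orf_table()]).
#' @param focal Protein id of the focal gene (must exist in `annotation`).
#' @param k Window half-width in ORFs (default 10).
#' @return A tibble of the neighbor ORF rows with additional columns
#'   `focal_protein_id`, `distance` (signed ordinal offset) and `truncated`
#'   (constant per window).
#' @examples
#' sim <- simulate_genomes(genome_sim_spec(n_genomes = 1, seed = 1))
#' focal <- sim$truth$focal$protein_id[1]
#' nrow(extract_neighborhood(sim$annotation, focal, k = 10))
#' @export
extract_neighborhood <- function(annotation, focal, k = 10) {
  assert_columns(annotation, c("genome_id", "contig_id", "orf_index",
                               "protein_id"), "annotation")
  k <- assert_count(k, "k", min = 1L)
  row <- annotation[annotation$protein_id == focal, ]
  if (nrow(row) != 1L) {
    stop_gmrsd(sprintf("focal protein '%s' %s in the annotation", focal,
                       if (nrow(row)) "is not unique" else "was not found"))
  }
  contig <- annotation[annotation$genome_id == row$genome_id &
                         annotation$contig_id == row$contig_id, ]
  d <- contig$orf_index - row$orf_index
  nb <- contig[abs(d) >= 1L & abs(d) <= k, ]
  nb$distance <- nb$orf_index - row$orf_index
  truncated <- (row$orf_index - k < min(contig$orf_index)) ||
    (row$orf_index + k > max(contig$orf_index))
  nb$focal_protein_id <- focal
  nb$truncated <- truncated
  ## the flag also travels as an attribute so it survives an empty window
  attr(nb, "truncated") <- truncated
  nb
}

#' @rdname extract_neighborhood
#' @param focal_ids Character vector of focal protein ids.
#' @details `extract_neighborhoods()` is the vectorized form: one bound
#'   tibble over all focal genes.
#' @export
extract_neighborhoods <- function(annotation, focal_ids, k = 10) {
  assert_columns(annotation, c("genome_id", "contig_id", "orf_index",
                               "protein_id"), "annotation")
  k <- assert_count(k, "k", min = 1L)
  missing <- setdiff(focal_ids, annotation$protein_id)
  if (length(missing)) {
    stop_gmrsd(sprintf("focal protein(s) not found: %s",
                       paste(utils::head(missing, 5), collapse = ", ")))
  }
  focal_rows <- annotation |>
    dplyr::filter(.data$protein_id %in% focal_ids) |>
    dplyr::select("genome_id", "contig_id",
                  focal_index = "orf_index", focal_protein_id = "protein_id")
  contig_extent <- annotation |>
    dplyr::group_by(.data$genome_id, .data$contig_id) |>
    dplyr::summarise(.min_idx = min(.data$orf_index),
                     .max_idx = max(.data$orf_index), .groups = "drop")
  annotation |>
    dplyr::inner_join(focal_rows, by = c("genome_id", "contig_id"),
                      relationship = "many-to-many") |>
    dplyr::filter(abs(.data$orf_index - .data$focal_index) >= 1L,
                  abs(.data$orf_index - .data$focal_index) <= k) |>
    dplyr::inner_join(contig_extent, by = c("genome_id", "contig_id")) |>
    dplyr::mutate(
      distance = .data$orf_index - .data$focal_index,
      truncated = .data$focal_index - k < .data$.min_idx |
        .data$focal_index + k > .data$.max_idx
    ) |>
    dplyr::select(-"focal_index", -".min_idx", -".max_idx")
}

#' Select top-scoring non-overlapping domain hits
#'
#' Applies the "only top-scoring and non-overlapping matches" rule used for
#' neighborhood domain annotation: hits passing the E-value threshold are
#' sorted by ascending E-value and accepted greedily, a hit being accepted
#' iff its envelope overlaps no previously accepted hit of the same
#' protein. Every rejected hit therefore overlaps an accepted hit with an
#' E-value at most its own.
#'
#' @param hits Domain-hit tibble (`protein_id`, `domain_id`, `env_start`,
#'   `env_end`, `evalue`). Hits from several proteins are handled per
#'   protein.
#' @param evalue_max E-value threshold (strict; default `1e-3`).
#' @return The accepted subset, sorted by protein then envelope start.
#' @export
select_top_nonoverlapping <- function(hits, evalue_max = 1e-3) {
  assert_columns(hits, c("protein_id", "domain_id", "env_start", "env_end",
                         "evalue"), "hits")
  assert_number(evalue_max, "evalue_max", min = 0, strict_min = TRUE)
  hits <- dplyr::filter(hits, .data$evalue < evalue_max)
  if (!nrow(hits)) return(hits)

  counts <- table(hits$protein_id)
  single <- names(counts)[counts == 1L]
  multi <- names(counts)[counts > 1L]
  kept <- hits[hits$protein_id %in% single, ]

  if (length(multi)) {
    multi_hits <- hits[hits$protein_id %in% multi, ]
    picked <- multi_hits |>
      dplyr::group_by(.data$protein_id) |>
      dplyr::group_modify(function(h, key) greedy_nonoverlap(h)) |>
      dplyr::ungroup()
    kept <- dplyr::bind_rows(kept, picked)
  }
  dplyr::arrange(kept, .data$protein_id, .data$env_start, .data$evalue)
}

## greedy core for one protein's hits; deterministic tie-break on equal
## E-values by envelope start then domain id
greedy_nonoverlap <- function(h) {
  ord <- order(h$evalue, h$env_start, h$domain_id)
  h <- h[ord, ]
  acc_start <- integer(0)
  acc_end <- integer(0)
  keep <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    s <- h$env_start[i]
    e <- h$env_end[i]
    if (!any(s <= acc_end & e >= acc_start)) {
      keep[i] <- TRUE
      acc_start <- c(acc_start, s)
      acc_end <- c(acc_end, e)
    }
  }
  h[keep, ]
}

#' Count accepted domain instances over a protein set
#'
#' Applies [select_top_nonoverlapping()] to the hits of the given proteins
#' and tallies accepted hits per domain. Proteins appearing several times
#' (e.g. shared by overlapping windows) are counted once.
#'
#' @param protein_ids Character vector of protein ids (duplicates are
#'   de-duplicated).
#' @param hits Domain-hit tibble.
#' @param evalue_max E-value threshold passed to
#'   [select_top_nonoverlapping()].
#' @return A tibble (`domain_id`, `n`) with `sum(n)` equal to the number of
#'   accepted hit instances.
#' @export
count_domains <- function(protein_ids, hits, evalue_max = 1e-3) {
  protein_ids <- unique(protein_ids)
  sel <- select_top_nonoverlapping(
    hits[hits$protein_id %in% protein_ids, , drop = FALSE],
    evalue_max = evalue_max
  )
  dplyr::count(sel, domain_id = .data$domain_id, name = "n")
}

#' Neighborhood-versus-background domain count table
#'
#' Builds the two-sample count table behind the enrichment test: for each
#' domain, `x1` accepted instances among the neighborhood proteins and `x2`
#' among the background proteins, with denominators `n1` and `n2` the total
#' accepted instances in each set (proportions are per domain instance,
#' not per protein).
#'
#' @param neighborhood_proteins,background_proteins Character vectors of
#'   protein ids (each de-duplicated).
#' @param hits Domain-hit tibble.
#' @param evalue_max E-value threshold for hit selection.
#' @return A tibble (`domain_id`, `x1`, `x2`, `n1`, `n2`); domains absent
#'   from one side get a zero count.
#' @export
build_count_table <- function(neighborhood_proteins, background_proteins,
                              hits, evalue_max = 1e-3) {
  nb <- count_domains(neighborhood_proteins, hits, evalue_max)
  bg <- count_domains(background_proteins, hits, evalue_max)
  tab <- dplyr::full_join(
    dplyr::rename(nb, x1 = "n"),
    dplyr::rename(bg, x2 = "n"),
    by = "domain_id"
  ) |>
    dplyr::mutate(
      x1 = tidyr::replace_na(.data$x1, 0L),
      x2 = tidyr::replace_na(.data$x2, 0L)
    ) |>
    dplyr::arrange(.data$domain_id)
  tab$n1 <- sum(tab$x1)
  tab$n2 <- sum(tab$x2)
  tab
}

#' Read an ordered-ORF table from TSV
#'
#' Reads the tab-separated genome annotation format written by the
#' simulator and pipeline: columns `genome_id`, `contig_id`, `orf_index`,
#' `start`, `end`, `strand`, `protein_id`.
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_orf_table <- function(path) {
  out <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  assert_columns(out, c("genome_id", "contig_id", "orf_index", "protein_id"),
                 "ORF table")
  tibble::as_tibble(out)
}

#' Read a domain-hit table from TSV
#'
#' Columns `protein_id`, `domain_id`, `env_start`, `env_end`, `evalue`,
#' `model_coverage` (hmmscan-domtblout-like).
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_domain_table <- function(path) {
  out <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  assert_columns(out, c("protein_id", "domain_id", "env_start", "env_end",
                        "evalue", "model_coverage"), "domain table")
  tibble::as_tibble(out)
}
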