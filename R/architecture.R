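## Domain ids defining the two halves of the GmrSD system
GMRS_DOMAIN <- "DUF262"
GMRD_DOMAIN <- "DUF1524"

#' Filter domain hits by E-value and model coverage
#'
#' Keeps exactly the hits with E-value strictly below `evalue_max` and
#' model coverage strictly above `coverage_min` (boundary values are
#' rejected), preserving input order. These are the acceptance thresholds
#' used when confirming a tentative domain assignment.
#'
#' @param hits Tibble with at least `evalue` and `model_coverage` columns.
#' @param evalue_max Strict upper bound on the E-value (default 0.001).
#' @param coverage_min Strict lower bound on the fraction of the domain
#'   model covered (default 0.8).
#' @return The filtered tibble, same columns, order preserved.
#' @examples
#' hits <- tibble::tibble(
#'   protein_id = "p1", domain_id = "DUF262", env_start = 1, env_end = 200,
#'   evalue = c(1e-5, 1e-5), model_coverage = c(0.9, 0.7)
#' )
#' accept_domain_hits(hits)  # keeps only the first row
#' @export
accept_domain_hits <- function(hits, evalue_max = 0.001, coverage_min = 0.8) {
  assert_columns(hits, c("evalue", "model_coverage"), "hits")
  assert_number(evalue_max, "evalue_max", min = 0, strict_min = TRUE)
  assert_number(coverage_min, "coverage_min", min = 0, max = 1)
  dplyr::filter(hits, .data$evalue < evalue_max,
                .data$model_coverage > coverage_min)
}

#' Classify protein domain architectures
#'
#' Assigns each protein one of four architecture classes from its accepted
#' domain hits: `GMRS_ONLY` (DUF262 present, DUF1524 absent), `GMRD_ONLY`
#' (the converse), `DOUBLE` (both; the canonical GmrSD fusion carries
#' DUF262 N-terminally and DUF1524 C-terminally), or `OTHER` (neither).
#' Remaining domain ids are reported as extra domains. When a protein has
#' several hits of the same family domain, the region is their union span.
#' If the DUF262 and DUF1524 regions overlap, the protein is flagged and
#' classified by the better-scoring (lower E-value) of the two.
#'
#' @param hits Tibble of accepted domain hits (`protein_id`, `domain_id`,
#'   `env_start`, `env_end`, `evalue`); typically the output of
#'   [accept_domain_hits()].
#' @param s_domain,d_domain Domain ids defining the S and D halves
#'   (defaults `"DUF262"` and `"DUF1524"`).
#' @return A tibble with one row per protein: `protein_id`, `klass`,
#'   `extra_domains` (list-column), `s_start`, `s_end`, `d_start`, `d_end`
#'   (NA when the region is absent) and `overlap_flag`.
#' @export
classify_architectures <- function(hits, s_domain = GMRS_DOMAIN,
                                   d_domain = GMRD_DOMAIN) {
  assert_columns(hits, c("protein_id", "domain_id", "env_start", "env_end",
                         "evalue"), "hits")
  if (!nrow(hits)) {
    return(tibble::tibble(
      protein_id = character(0), klass = character(0),
      extra_domains = list(), s_start = integer(0), s_end = integer(0),
      d_start = integer(0), d_end = integer(0), overlap_flag = logical(0)
    ))
  }
  hits |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::group_modify(function(h, key) {
      classify_one(h, s_domain, d_domain)
    }) |>
    dplyr::ungroup()
}

classify_one <- function(h, s_domain, d_domain) {
  s_hits <- h[h$domain_id == s_domain, ]
  d_hits <- h[h$domain_id == d_domain, ]
  extra <- sort(unique(h$domain_id[!h$domain_id %in% c(s_domain, d_domain)]))
  span <- function(hh) {
    if (!nrow(hh)) c(NA_integer_, NA_integer_)
    else c(min(hh$env_start), max(hh$env_end))
  }
  s_reg <- span(s_hits)
  d_reg <- span(d_hits)
  has_s <- nrow(s_hits) > 0
  has_d <- nrow(d_hits) > 0
  overlap <- FALSE
  if (has_s && has_d && s_reg[1] <= d_reg[2] && d_reg[1] <= s_reg[2]) {
    ## overlapping family regions cannot be a genuine fusion: keep the
    ## better-scoring domain, flag the protein for audit
    overlap <- TRUE
    if (min(s_hits$evalue) <= min(d_hits$evalue)) {
      has_d <- FALSE
      d_reg <- c(NA_integer_, NA_integer_)
    } else {
      has_s <- FALSE
      s_reg <- c(NA_integer_, NA_integer_)
    }
  }
  klass <- if (has_s && has_d) "DOUBLE"
  else if (has_s) "GMRS_ONLY"
  else if (has_d) "GMRD_ONLY"
  else "OTHER"
  tibble::tibble(
    klass = klass, extra_domains = list(extra),
    s_start = as.integer(s_reg[1]), s_end = as.integer(s_reg[2]),
    d_start = as.integer(d_reg[1]), d_end = as.integer(d_reg[2]),
    overlap_flag = overlap
  )
}

#' @rdname classify_architectures
#' @details `classify_architecture()` is the single-protein form: all hits
#'   must belong to one protein.
#' @export
classify_architecture <- function(hits, s_domain = GMRS_DOMAIN,
                                  d_domain = GMRD_DOMAIN) {
  assert_columns(hits, c("protein_id", "domain_id", "env_start", "env_end",
                         "evalue"), "hits")
  if (nrow(hits) && dplyr::n_distinct(hits$protein_id) > 1L) {
    stop_gmrsd("classify_architecture() expects hits of a single protein; use classify_architectures() for many")
  }
  classify_architectures(hits, s_domain, d_domain)
}

#' Build per-genome inventories of GmrSD family architectures
#'
#' Counts, per genome, the double-domain, GmrS-only, GmrD-only and other
#' proteins. The counts partition the classified proteins of each genome.
#'
#' @param architectures Output of [classify_architectures()]; must carry a
#'   `genome_id` column or one is joined from `genomes`.
#' @param genomes Optional protein-to-genome map, a tibble with
#'   `protein_id` and `genome_id` (e.g. the annotation table of
#'   [simulate_genomes()]). Genomes present in the map but without
#'   classified proteins get all-zero rows; a protein mapped to two genomes
#'   is an error.
#' @return A tibble (`genome_id`, `n_double`, `n_s_only`, `n_d_only`,
#'   `n_other`).
#' @export
build_inventory <- function(architectures, genomes = NULL) {
  assert_columns(architectures, c("protein_id", "klass"), "architectures")
  if (!is.null(genomes)) {
    assert_columns(genomes, c("protein_id", "genome_id"), "genomes")
    map <- dplyr::distinct(genomes, .data$protein_id, .data$genome_id)
    dup <- map$protein_id[duplicated(map$protein_id)]
    if (length(dup)) {
      stop_gmrsd(sprintf("protein(s) mapped to more than one genome: %s",
                         paste(unique(dup), collapse = ", ")))
    }
    architectures <- dplyr::inner_join(
      dplyr::select(architectures, -dplyr::any_of("genome_id")),
      map, by = "protein_id"
    )
    all_genomes <- unique(genomes$genome_id)
  } else {
    assert_columns(architectures, "genome_id", "architectures")
    all_genomes <- unique(architectures$genome_id)
  }
  counts <- architectures |>
    dplyr::count(.data$genome_id, .data$klass) |>
    tidyr::pivot_wider(names_from = "klass", values_from = "n",
                       values_fill = 0L)
  for (col in c("DOUBLE", "GMRS_ONLY", "GMRD_ONLY", "OTHER")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  tibble::tibble(genome_id = all_genomes) |>
    dplyr::left_join(counts, by = "genome_id") |>
    dplyr::transmute(
      genome_id = .data$genome_id,
      n_double = tidyr::replace_na(.data$DOUBLE, 0L),
      n_s_only = tidyr::replace_na(.data$GMRS_ONLY, 0L),
      n_d_only = tidyr::replace_na(.data$GMRD_ONLY, 0L),
      n_other = tidyr::replace_na(.data$OTHER, 0L)
    ) |>
    dplyr::arrange(.data$genome_id)
}

#' Pair single-domain proteins into double-domain-like merged sequences
#'
#' For every genome with exactly one GmrS-only and exactly one GmrD-only
#' protein, emits their concatenation (S residues followed by D residues) as
#' a double-domain-like sequence — the candidate heterodimeric GmrSD system
#' of that organism. Genomes with any other single-domain count contribute
#' nothing. Pairing proceeds even when the genome also carries double-domain
#' proteins; such pairs are flagged via `double_present`.
#'
#' @param architectures Output of [classify_architectures()] with a
#'   `genome_id` column (or provide `genomes` as in [build_inventory()]).
#' @param sequences Protein sequences: a named character vector or a tibble
#'   with `protein_id` (or `seq_id`) and `sequence`.
#' @param genomes Optional protein-to-genome map (see [build_inventory()]).
#' @return A tibble (`genome_id`, `s_protein_id`, `d_protein_id`,
#'   `merged_id`, `merged_sequence`, `double_present`); `merged_id` has the
#'   form `<genome>|<S_id>+<D_id>|merged`.
#' @export
pair_single_domains <- function(architectures, sequences, genomes = NULL) {
  if (is.data.frame(sequences)) {
    if ("seq_id" %in% names(sequences) && !"protein_id" %in% names(sequences)) {
      sequences <- dplyr::rename(sequences, protein_id = "seq_id")
    }
    assert_columns(sequences, c("protein_id", "sequence"), "sequences")
    sequences <- setNames(sequences$sequence, sequences$protein_id)
  }
  if (!is.null(genomes)) {
    assert_columns(genomes, c("protein_id", "genome_id"), "genomes")
    architectures <- dplyr::inner_join(
      dplyr::select(architectures, -dplyr::any_of("genome_id")),
      dplyr::distinct(genomes, .data$protein_id, .data$genome_id),
      by = "protein_id"
    )
  }
  assert_columns(architectures, c("protein_id", "klass", "genome_id"),
                 "architectures")
  inv <- build_inventory(architectures)
  eligible <- inv$genome_id[inv$n_s_only == 1L & inv$n_d_only == 1L]
  if (!length(eligible)) {
    return(tibble::tibble(
      genome_id = character(0), s_protein_id = character(0),
      d_protein_id = character(0), merged_id = character(0),
      merged_sequence = character(0), double_present = logical(0)
    ))
  }
  purrr::map_dfr(eligible, function(g) {
    arch_g <- architectures[architectures$genome_id == g, ]
    s_id <- arch_g$protein_id[arch_g$klass == "GMRS_ONLY"]
    d_id <- arch_g$protein_id[arch_g$klass == "GMRD_ONLY"]
    missing <- setdiff(c(s_id, d_id), names(sequences))
    if (length(missing)) {
      stop_gmrsd(sprintf("no sequence provided for protein(s): %s",
                         paste(missing, collapse = ", ")))
    }
    tibble::tibble(
      genome_id = g, s_protein_id = s_id, d_protein_id = d_id,
      merged_id = sprintf("%s|%s+%s|merged", g, s_id, d_id),
      merged_sequence = paste0(sequences[[s_id]], sequences[[d_id]]),
      double_present = any(arch_g$klass == "DOUBLE")
    )
  })
}
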