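#' Specification for the annotated-genome simulator
#'
#' Describes a set of synthetic prokaryotic genomes: ordered ORFs on one or
#' more contigs, a vocabulary of protein domains drawn at background
#' frequencies, and a number of focal (GmrSD-like) genes per genome around
#' which a chosen subset of domains is enriched. The simulator is the ground
#' truth surface for the genomic-neighborhood (defense-island) enrichment
#' statistics: a domain with multiplier m has its odds of being drawn
#' multiplied by m for proteins encoded within `window_k` ORFs of a focal
#' gene, and is left at background frequency everywhere else.
#'
#' @param n_genomes Number of genomes to simulate.
#' @param contigs_per_genome Contigs per genome.
#' @param orfs_per_contig ORFs per contig.
#' @param domain_vocab_size Number of distinct background domains (M).
#' @param background_weights Probability vector of length
#'   `domain_vocab_size` summing to 1 (default uniform). These are the
#'   proteome-wide domain frequencies.
#' @param focal_per_genome Focal genes planted per genome. Focal genes are
#'   placed uniformly at random with a minimum separation of
#'   `2 * window_k + 1` ORFs so that neighborhoods never overlap.
#' @param enriched_domains Named numeric vector: names are domain ids
#'   (e.g. `"DOM001"`), values are odds multipliers `>= 1` applied inside
#'   neighborhood windows. An empty vector simulates the null.
#' @param window_k Neighborhood half-width in ORFs (default 10, the
#'   conventional defense-island window).
#' @param hits_per_protein `"one"` (default; every protein carries exactly
#'   one domain hit, keeping count denominators interpretable) or
#'   `"zero_to_three"` (0-3 hits per protein, uniform).
#' @param seed Integer seed; identical seeds give byte-identical output.
#'
#' @return An object of class `genome_sim_spec`.
#' @seealso [simulate_genomes()]
#' @export
genome_sim_spec <- function(n_genomes = 100,
                            contigs_per_genome = 1,
                            orfs_per_contig = 200,
                            domain_vocab_size = 50,
                            background_weights = NULL,
                            focal_per_genome = 1,
                            enriched_domains = numeric(0),
                            window_k = 10,
                            hits_per_protein = c("one", "zero_to_three"),
                            seed = 1) {
  n_genomes <- assert_count(n_genomes, "n_genomes", min = 1L)
  contigs_per_genome <- assert_count(contigs_per_genome, "contigs_per_genome", 1L)
  orfs_per_contig <- assert_count(orfs_per_contig, "orfs_per_contig", 1L)
  domain_vocab_size <- assert_count(domain_vocab_size, "domain_vocab_size", 1L)
  focal_per_genome <- assert_count(focal_per_genome, "focal_per_genome", 0L)
  window_k <- assert_count(window_k, "window_k", 1L)
  seed <- assert_count(seed, "seed", 0L)
  hits_per_protein <- match.arg(hits_per_protein)

  vocab <- sprintf("DOM%03d", seq_len(domain_vocab_size))
  if (is.null(background_weights)) {
    background_weights <- rep(1 / domain_vocab_size, domain_vocab_size)
  }
  if (length(background_weights) != domain_vocab_size ||
      any(background_weights < 0)) {
    stop_gmrsd("`background_weights` must be non-negative and have one entry per vocabulary domain")
  }
  if (abs(sum(background_weights) - 1) > 1e-12) {
    stop_gmrsd(sprintf(
      "`background_weights` must sum to 1 (+/- 1e-12); got %.15f",
      sum(background_weights)
    ))
  }
  if (length(enriched_domains)) {
    if (is.null(names(enriched_domains)) || any(!nzchar(names(enriched_domains)))) {
      stop_gmrsd("`enriched_domains` must be a named numeric vector of odds multipliers")
    }
    unknown <- setdiff(names(enriched_domains), vocab)
    if (length(unknown)) {
      stop_gmrsd(sprintf(
        "`enriched_domains` names not in the vocabulary: %s",
        paste(unknown, collapse = ", ")
      ))
    }
    if (any(enriched_domains < 1)) {
      stop_gmrsd("enrichment multipliers must be >= 1")
    }
  }
  ## windows must fit so min-separation placement is feasible
  n_slots <- orfs_per_contig %/% (2L * window_k + 1L) * contigs_per_genome
  if (focal_per_genome > max(n_slots, 1L)) {
    stop_gmrsd(sprintf(
      "cannot place %d focal genes with min separation %d in %d x %d ORFs",
      focal_per_genome, 2L * window_k + 1L, contigs_per_genome, orfs_per_contig
    ))
  }

  structure(
    list(
      n_genomes = n_genomes,
      contigs_per_genome = contigs_per_genome,
      orfs_per_contig = orfs_per_contig,
      domain_vocab = vocab,
      background_weights = as.numeric(background_weights),
      focal_per_genome = focal_per_genome,
      enriched_domains = enriched_domains,
      window_k = window_k,
      hits_per_protein = hits_per_protein,
      seed = seed
    ),
    class = "genome_sim_spec"
  )
}

#' @export
print.genome_sim_spec <- function(x, ...) {
  cat(sprintf(
    "<genome_sim_spec> %d genomes x %d contig(s) x %d ORFs, M = %d domains\n",
    x$n_genomes, x$contigs_per_genome, x$orfs_per_contig, length(x$domain_vocab)
  ))
  cat(sprintf(
    "  focal/genome = %d, window k = %d, enriched: %s\n",
    x$focal_per_genome, x$window_k,
    if (length(x$enriched_domains)) {
      paste(sprintf("%s x%g", names(x$enriched_domains), x$enriched_domains),
            collapse = ", ")
    } else "none (null)"
  ))
  invisible(x)
}

## focal positions on one contig: uniform over placements respecting the
## minimum separation 2k+1 (windows of distinct focal genes never overlap)
place_focal <- function(n_orfs, n_focal, min_sep) {
  if (n_focal == 0L) return(integer(0))
  pos <- integer(0)
  candidates <- seq_len(n_orfs) - 1L
  for (i in seq_len(n_focal)) {
    ok <- candidates[!candidates %in% unlist(lapply(pos, function(p) {
      seq(p - min_sep + 1L, p + min_sep - 1L)
    }))]
    if (!length(ok)) {
      stop_gmrsd("could not place focal genes with the required separation")
    }
    pos <- c(pos, sample(ok, 1L))
  }
  sort(pos)
}

#' Simulate annotated genomes with planted neighborhood enrichment
#'
#' Generates ordered-ORF genome annotations, a per-protein domain-hit table
#' (hmmscan-style: envelope coordinates, E-value, model coverage), and the
#' planted truth. Every focal protein carries a DUF262 and a DUF1524 hit
#' (a double-domain GmrSD-like gene); every other protein draws its domain(s)
#' from the background weights, except proteins within `window_k` ORFs of a
#' focal gene, for which the odds of each enriched domain are multiplied by
#' its multiplier.
#'
#' @param spec A [genome_sim_spec()].
#' @return A list of class `gmrsd_genome_sim` with elements
#'   * `annotation`: tibble of ORFs (`genome_id`, `contig_id`, `orf_index`,
#'     `start`, `end`, `strand`, `protein_id`),
#'   * `hits`: tibble of domain hits (`protein_id`, `domain_id`,
#'     `env_start`, `env_end`, `evalue`, `model_coverage`),
#'   * `truth`: list with `enriched_domains` (exactly the planted ids with
#'     multiplier > 1), `focal` (tibble `genome_id`, `protein_id`) and
#'     `window_proteins` (ids of proteins inside any window).
#' @examples
#' sim <- simulate_genomes(genome_sim_spec(n_genomes = 3, seed = 42))
#' head(sim$annotation)
#' @export
simulate_genomes <- function(spec) {
  if (!inherits(spec, "genome_sim_spec")) {
    stop_gmrsd("`spec` must be created with genome_sim_spec()")
  }
  set.seed(spec$seed)

  g_ids <- sprintf("g%04d", seq_len(spec$n_genomes))
  c_ids <- sprintf("c%02d", seq_len(spec$contigs_per_genome))
  n_per_contig <- spec$orfs_per_contig
  n_total <- spec$n_genomes * spec$contigs_per_genome * n_per_contig

  annotation <- tidyr::expand_grid(
    genome_id = g_ids, contig_id = c_ids, orf_index = seq_len(n_per_contig) - 1L
  )
  ## ORF geometry: lengths in nt (multiples of 3), small intergenic gaps
  orf_len <- sample(seq(300L, 2400L, by = 3L), n_total, replace = TRUE)
  gap <- sample(5L:150L, n_total, replace = TRUE)
  annotation <- annotation |>
    dplyr::group_by(.data$genome_id, .data$contig_id) |>
    dplyr::mutate(
      .len = orf_len[dplyr::cur_group_rows()],
      .gap = gap[dplyr::cur_group_rows()],
      start = cumsum(dplyr::lag(.data$.len + .data$.gap, default = 1L)),
      end = .data$start + .data$.len - 1L
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      strand = sample(c("+", "-"), n_total, replace = TRUE),
      protein_id = sprintf("%s_%s_p%04d", .data$genome_id, .data$contig_id,
                           .data$orf_index),
      aa_length = .data$.len %/% 3L
    ) |>
    dplyr::select(-".len", -".gap")

  ## focal placement, per genome/contig, min separation 2k+1
  min_sep <- 2L * spec$window_k + 1L
  focal <- purrr::map_dfr(g_ids, function(g) {
    ## distribute focal genes over contigs round-robin, place within contig
    contig_of <- rep(c_ids, length.out = spec$focal_per_genome)
    purrr::map_dfr(unique(contig_of), function(cc) {
      k <- sum(contig_of == cc)
      tibble::tibble(
        genome_id = g, contig_id = cc,
        orf_index = place_focal(n_per_contig, k, min_sep)
      )
    })
  })
  focal <- dplyr::inner_join(
    focal, annotation,
    by = c("genome_id", "contig_id", "orf_index")
  )

  ## window membership (focal itself excluded)
  in_window <- dplyr::inner_join(
    annotation,
    dplyr::select(focal, "genome_id", "contig_id", focal_index = "orf_index"),
    by = c("genome_id", "contig_id"),
    relationship = "many-to-many"
  ) |>
    dplyr::filter(
      abs(.data$orf_index - .data$focal_index) >= 1L,
      abs(.data$orf_index - .data$focal_index) <= spec$window_k
    ) |>
    dplyr::distinct(.data$protein_id)

  is_focal <- annotation$protein_id %in% focal$protein_id
  is_window <- annotation$protein_id %in% in_window$protein_id

  ## domain draws: background weights, odds multiplied inside windows
  w_bg <- spec$background_weights
  w_win <- w_bg
  if (length(spec$enriched_domains)) {
    idx <- match(names(spec$enriched_domains), spec$domain_vocab)
    w_win[idx] <- w_win[idx] * spec$enriched_domains
  }
  w_win <- w_win / sum(w_win)

  n_hits <- rep(1L, n_total)
  if (spec$hits_per_protein == "zero_to_three") {
    n_hits <- sample(0:3, n_total, replace = TRUE)
  }
  n_hits[is_focal] <- 0L  # focal proteins get their fixed DUF262+DUF1524 hits

  draw_pool <- rep.int(seq_len(n_total), n_hits)
  pool_window <- is_window[draw_pool]
  domain <- character(length(draw_pool))
  if (any(!pool_window)) {
    domain[!pool_window] <- sample(spec$domain_vocab, sum(!pool_window),
                                   replace = TRUE, prob = w_bg)
  }
  if (any(pool_window)) {
    domain[pool_window] <- sample(spec$domain_vocab, sum(pool_window),
                                  replace = TRUE, prob = w_win)
  }

  aa_len <- annotation$aa_length[draw_pool]
  env_start <- pmax(1L, as.integer(runif(length(draw_pool), 1, pmax(1, aa_len * 0.2))))
  env_end <- pmin(aa_len, env_start + as.integer(runif(length(draw_pool), 50, 250)))
  hits <- tibble::tibble(
    protein_id = annotation$protein_id[draw_pool],
    domain_id = domain,
    env_start = env_start,
    env_end = pmax(env_end, env_start),
    evalue = 10^runif(length(draw_pool), -30, -5),
    model_coverage = runif(length(draw_pool), 0.85, 1)
  )

  ## focal (GmrSD-like) proteins: DUF262 N-terminal, DUF1524 C-terminal
  if (nrow(focal)) {
    fl <- focal$aa_length
    focal_hits <- tibble::tibble(
      protein_id = rep(focal$protein_id, each = 2L),
      domain_id = rep(c("DUF262", "DUF1524"), times = nrow(focal)),
      env_start = as.vector(rbind(rep(5L, nrow(focal)), pmax(6L, fl %/% 2L))),
      env_end = as.vector(rbind(pmax(5L, fl %/% 2L - 10L), pmax(7L, fl - 4L))),
      evalue = 10^runif(2L * nrow(focal), -40, -15),
      model_coverage = runif(2L * nrow(focal), 0.85, 1)
    )
    hits <- dplyr::bind_rows(focal_hits, hits)
  }
  hits <- dplyr::arrange(hits, .data$protein_id, .data$env_start, .data$domain_id)

  structure(
    list(
      annotation = dplyr::select(annotation, -"aa_length"),
      hits = hits,
      truth = list(
        enriched_domains = names(spec$enriched_domains)[spec$enriched_domains > 1],
        focal = dplyr::select(focal, "genome_id", "protein_id"),
        window_proteins = in_window$protein_id
      ),
      spec = spec
    ),
    class = "gmrsd_genome_sim"
  )
}

#' @export
print.gmrsd_genome_sim <- function(x, ...) {
  cat(sprintf(
    "<gmrsd_genome_sim> %d ORFs, %d domain hits, %d focal genes, planted: %s\n",
    nrow(x$annotation), nrow(x$hits), nrow(x$truth$focal),
    if (length(x$truth$enriched_domains)) {
      paste(x$truth$enriched_domains, collapse = ", ")
    } else "none"
  ))
  invisible(x)
}
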