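#' Specification for the protein-family simulator
#'
#' Describes a synthetic GmrSD-like protein family: double-domain (S+D)
#' fusion proteins, genomes contributing one GmrS-only plus one GmrD-only
#' partner each (candidate heterodimeric systems), and unpaired single-domain
#' orphans. Degenerate signature motifs are planted at homologous positions:
#' region lengths and motif offsets are drawn once per family, so members
#' sharing an architecture class are length-identical and the planted
#' coordinates double as alignment columns.
#'
#' At each motif column a family consensus residue (satisfying the motif
#' element) is kept with probability `conservation_level`; otherwise the
#' residue is redrawn uniformly from the 20 standard amino acids. All
#' non-motif positions are i.i.d. uniform residues.
#'
#' @param n_double Number of double-domain (S+D fusion) sequences.
#' @param n_pairs Number of genomes contributing one GmrS-only and one
#'   GmrD-only sequence each.
#' @param n_orphans Number of unpaired single-domain sequences (alternating
#'   S-only / D-only, one genome each).
#' @param motif_specs Tibble with columns `name`, `region` (`"S"` or
#'   `"D"`), and `motif` (list of [compile_motif()] patterns) or `text`;
#'   defaults to the family motifs from [gmrsd_motifs()].
#' @param seq_length_range Length-2 integer vector; the S-region and
#'   D-region lengths are each drawn once (per family) uniformly from this
#'   range, in residues.
#' @param conservation_level Probability that a planted-motif column keeps
#'   its consensus residue in a given sequence, in `[0, 1]`.
#' @param seed Integer seed.
#' @return An object of class `family_sim_spec`.
#' @seealso [simulate_family()]
#' @export
family_sim_spec <- function(n_double = 40,
                            n_pairs = 10,
                            n_orphans = 10,
                            motif_specs = gmrsd_motifs(),
                            seq_length_range = c(220, 320),
                            conservation_level = 1,
                            seed = 1) {
  n_double <- assert_count(n_double, "n_double", 0L)
  n_pairs <- assert_count(n_pairs, "n_pairs", 0L)
  n_orphans <- assert_count(n_orphans, "n_orphans", 0L)
  assert_number(conservation_level, "conservation_level", 0, 1)
  seed <- assert_count(seed, "seed", 0L)
  if (length(seq_length_range) != 2L || any(seq_length_range < 1) ||
      seq_length_range[1] > seq_length_range[2]) {
    stop_gmrsd("`seq_length_range` must be c(min, max) with 1 <= min <= max")
  }
  if (is.data.frame(motif_specs)) {
    if (!"motif" %in% names(motif_specs)) {
      assert_columns(motif_specs, c("name", "region", "text"), "motif_specs")
      motif_specs$motif <- purrr::map2(motif_specs$text, motif_specs$name,
                                       compile_motif)
    }
    assert_columns(motif_specs, c("name", "region", "motif"), "motif_specs")
  } else {
    stop_gmrsd("`motif_specs` must be a data frame (see gmrsd_motifs())")
  }
  if (!all(motif_specs$region %in% c("S", "D"))) {
    stop_gmrsd("motif regions must be \"S\" or \"D\"")
  }
  for (reg in c("S", "D")) {
    tot <- sum(vapply(motif_specs$motif[motif_specs$region == reg],
                      length, integer(1)))
    if (tot > seq_length_range[1]) {
      stop_gmrsd(sprintf(
        "planted motifs for region %s (total %d residues) do not fit inside the minimum sequence length %d",
        reg, tot, seq_length_range[1]
      ))
    }
  }
  structure(
    list(
      n_double = n_double, n_pairs = n_pairs, n_orphans = n_orphans,
      motif_specs = motif_specs,
      seq_length_range = as.integer(seq_length_range),
      conservation_level = conservation_level,
      seed = seed
    ),
    class = "family_sim_spec"
  )
}

## motif offsets within a region: keep given order, random non-overlapping
## placement drawn once per family
layout_region <- function(region_len, motifs) {
  lens <- vapply(motifs, length, integer(1))
  free <- region_len - sum(lens)
  n <- length(lens)
  if (n == 0L) return(integer(0))
  ## random composition of `free` into n+1 gaps
  cuts <- sort(sample(0:free, n, replace = TRUE))
  gaps <- diff(c(0L, cuts))
  starts <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    pos <- pos + gaps[i]
    starts[i] <- pos + 1L
    pos <- pos + lens[i]
  }
  starts
}

#' Simulate a GmrSD-like protein family with planted motifs
#'
#' Generates ungapped protein sequences with architecture labels
#' (`DOUBLE`, `GMRS_ONLY`, `GMRD_ONLY`), genome assignments, a noise-free
#' domain-hit table consistent with the architectures (a DUF262 hit over the
#' S region, a DUF1524 hit over the D region), and the exact planted motif
#' coordinates.
#'
#' @param spec A [family_sim_spec()].
#' @return A list of class `gmrsd_family_sim` with elements
#'   * `sequences`: tibble (`seq_id`, `genome_id`, `klass`, `sequence`),
#'   * `hits`: tibble in the [simulate_genomes()] domain-hit format,
#'   * `truth`: tibble (`seq_id`, `pattern`, `region`, `start`, `end`) of
#'     planted motif coordinates in each ungapped sequence,
#'   * `layout`: list with the family's `s_length`, `d_length` and the
#'     per-motif offsets and consensus residues.
#' @examples
#' fam <- simulate_family(family_sim_spec(n_double = 5, seed = 7))
#' fam$truth
#' @export
simulate_family <- function(spec) {
  if (!inherits(spec, "family_sim_spec")) {
    stop_gmrsd("`spec` must be created with family_sim_spec()")
  }
  set.seed(spec$seed)
  aa <- aa_alphabet()

  s_len <- sample(seq(spec$seq_length_range[1], spec$seq_length_range[2]), 1L)
  d_len <- sample(seq(spec$seq_length_range[1], spec$seq_length_range[2]), 1L)

  ms <- spec$motif_specs
  s_motifs <- ms[ms$region == "S", ]
  d_motifs <- ms[ms$region == "D", ]
  s_starts <- layout_region(s_len, s_motifs$motif)
  d_starts <- layout_region(d_len, d_motifs$motif)

  ## family consensus residue per motif column (one residue satisfying each
  ## element, drawn once)
  consensus_for <- function(motifs) {
    lapply(motifs, function(p) {
      vapply(p$elements, function(e) {
        if (length(e) == 1L) e else sample(e, 1L)
      }, character(1))
    })
  }
  s_cons <- consensus_for(s_motifs$motif)
  d_cons <- consensus_for(d_motifs$motif)

  ## sequence roster
  roster <- list()
  if (spec$n_double) {
    roster$double <- tibble::tibble(
      seq_id = sprintf("dbl%04d", seq_len(spec$n_double)),
      genome_id = sprintf("gD%04d", seq_len(spec$n_double)),
      klass = "DOUBLE"
    )
  }
  if (spec$n_pairs) {
    roster$pairs <- tibble::tibble(
      seq_id = c(sprintf("pairS%04d", seq_len(spec$n_pairs)),
                 sprintf("pairD%04d", seq_len(spec$n_pairs))),
      genome_id = rep(sprintf("gP%04d", seq_len(spec$n_pairs)), 2L),
      klass = rep(c("GMRS_ONLY", "GMRD_ONLY"), each = spec$n_pairs)
    )
  }
  if (spec$n_orphans) {
    roster$orphans <- tibble::tibble(
      seq_id = sprintf("orp%04d", seq_len(spec$n_orphans)),
      genome_id = sprintf("gO%04d", seq_len(spec$n_orphans)),
      klass = rep_len(c("GMRS_ONLY", "GMRD_ONLY"), spec$n_orphans)
    )
  }
  roster <- dplyr::bind_rows(roster)
  if (!nrow(roster)) {
    return(structure(
      list(
        sequences = tibble::tibble(seq_id = character(0),
                                   genome_id = character(0),
                                   klass = character(0),
                                   sequence = character(0)),
        hits = empty_hits(),
        truth = tibble::tibble(seq_id = character(0), pattern = character(0),
                               region = character(0), start = integer(0),
                               end = integer(0)),
        layout = list(s_length = s_len, d_length = d_len),
        spec = spec
      ),
      class = "gmrsd_family_sim"
    ))
  }

  ## build one region's residues for one sequence
  make_region <- function(len, motifs, starts, cons) {
    res <- sample(aa, len, replace = TRUE)
    if (length(starts)) {
      for (i in seq_along(starts)) {
        cols <- seq.int(starts[i], starts[i] + length(cons[[i]]) - 1L)
        keep <- runif(length(cols)) < spec$conservation_level
        res[cols] <- ifelse(keep, cons[[i]],
                            sample(aa, length(cols), replace = TRUE))
      }
    }
    res
  }

  truth <- list()
  seqs <- character(nrow(roster))
  for (r in seq_len(nrow(roster))) {
    kl <- roster$klass[r]
    s_part <- if (kl %in% c("DOUBLE", "GMRS_ONLY")) {
      make_region(s_len, s_motifs$motif, s_starts, s_cons)
    } else character(0)
    d_part <- if (kl %in% c("DOUBLE", "GMRD_ONLY")) {
      make_region(d_len, d_motifs$motif, d_starts, d_cons)
    } else character(0)
    seqs[r] <- paste(c(s_part, d_part), collapse = "")

    d_offset <- if (kl == "DOUBLE") s_len else 0L
    tr <- list()
    if (length(s_part) && nrow(s_motifs)) {
      tr$s <- tibble::tibble(
        pattern = s_motifs$name, region = "S", start = s_starts,
        end = s_starts + vapply(s_motifs$motif, length, integer(1)) - 1L
      )
    }
    if (length(d_part) && nrow(d_motifs)) {
      tr$d <- tibble::tibble(
        pattern = d_motifs$name, region = "D",
        start = d_starts + d_offset,
        end = d_starts + d_offset + vapply(d_motifs$motif, length, integer(1)) - 1L
      )
    }
    tr <- dplyr::bind_rows(tr)
    if (nrow(tr)) truth[[roster$seq_id[r]]] <- tr
  }
  truth <- dplyr::bind_rows(truth, .id = "seq_id")

  ## noise-free domain hits matching the architectures
  hit_rows <- list()
  has_s <- roster$klass %in% c("DOUBLE", "GMRS_ONLY")
  has_d <- roster$klass %in% c("DOUBLE", "GMRD_ONLY")
  if (any(has_s)) {
    hit_rows$s <- tibble::tibble(
      protein_id = roster$seq_id[has_s], domain_id = "DUF262",
      env_start = 1L, env_end = s_len,
      evalue = 1e-20, model_coverage = 0.95
    )
  }
  if (any(has_d)) {
    d_start <- ifelse(roster$klass[has_d] == "DOUBLE", s_len + 1L, 1L)
    hit_rows$d <- tibble::tibble(
      protein_id = roster$seq_id[has_d], domain_id = "DUF1524",
      env_start = as.integer(d_start),
      env_end = as.integer(d_start + d_len - 1L),
      evalue = 1e-20, model_coverage = 0.95
    )
  }
  hits <- dplyr::arrange(dplyr::bind_rows(hit_rows), .data$protein_id,
                         .data$env_start)

  structure(
    list(
      sequences = dplyr::mutate(roster, sequence = seqs),
      hits = hits,
      truth = truth,
      layout = list(
        s_length = s_len, d_length = d_len,
        s_motif_starts = setNames(s_starts, s_motifs$name),
        d_motif_starts = setNames(d_starts, d_motifs$name),
        s_consensus = setNames(lapply(s_cons, paste, collapse = ""),
                               s_motifs$name),
        d_consensus = setNames(lapply(d_cons, paste, collapse = ""),
                               d_motifs$name)
      ),
      spec = spec
    ),
    class = "gmrsd_family_sim"
  )
}

empty_hits <- function() {
  tibble::tibble(protein_id = character(0), domain_id = character(0),
                 env_start = integer(0), env_end = integer(0),
                 evalue = numeric(0), model_coverage = numeric(0))
}

#' @export
print.gmrsd_family_sim <- function(x, ...) {
  tab <- table(x$sequences$klass)
  cat(sprintf(
    "<gmrsd_family_sim> %d sequences (%s), %d planted motif sites\n",
    nrow(x$sequences),
    paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
    nrow(x$truth)
  ))
  invisible(x)
}

#' Lay a simulated family out as a (trivially aligned) MSA
#'
#' Because family members of one architecture class are length-identical
#' and coordinates are homologous by construction, the family aligns
#' without inference: S-only sequences are padded with trailing gaps over
#' the D region and D-only sequences with leading gaps over the S region.
#'
#' @param fam A [simulate_family()] result.
#' @return An [msa()] of width `s_length + d_length`.
#' @export
family_msa <- function(fam) {
  if (!inherits(fam, "gmrsd_family_sim")) {
    stop_gmrsd("`fam` must come from simulate_family()")
  }
  s_len <- fam$layout$s_length
  d_len <- fam$layout$d_length
  pad <- function(seq, klass) {
    switch(klass,
      DOUBLE = seq,
      GMRS_ONLY = paste0(seq, strrep("-", d_len)),
      GMRD_ONLY = paste0(strrep("-", s_len), seq)
    )
  }
  aligned <- mapply(pad, fam$sequences$sequence, fam$sequences$klass,
                    USE.NAMES = FALSE)
  msa(setNames(aligned, fam$sequences$seq_id))
}
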