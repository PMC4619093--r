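#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end synthetic analysis in
#' one validated, YAML-round-trippable list: the neighborhood window
#' half-width (10 ORFs), the domain acceptance thresholds (E-value below
#' 0.001, model coverage above 0.8), the neighborhood annotation E-value
#' cut (1e-3), the familywise error rate (0.05), the conservation marking
#' threshold (0.95), the split support threshold (0.8), and the simulator
#' specifications.
#'
#' @param window_k Neighborhood half-width in ORFs.
#' @param evalue_domain_accept,coverage_min Family-domain acceptance
#'   thresholds (strict).
#' @param evalue_neighborhood E-value cut for neighborhood domain counting.
#' @param alpha Familywise error rate for the enrichment analysis.
#' @param conservation_threshold Strict threshold for the `+` conservation
#'   mark.
#' @param support_threshold Strict SH-like support threshold for split
#'   collapsing.
#' @param rank_direction `"descending"` or `"ascending"` enrichment
#'   ranking.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param genome_sim,family_sim,tree_sim Named lists of overrides passed to
#'   [genome_sim_spec()], [family_sim_spec()] and [tree_sim_spec()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_k = 10,
                            evalue_domain_accept = 0.001,
                            coverage_min = 0.8,
                            evalue_neighborhood = 1e-3,
                            alpha = 0.05,
                            conservation_threshold = 0.95,
                            support_threshold = 0.8,
                            rank_direction = "descending",
                            seed = 1,
                            genome_sim = list(),
                            family_sim = list(),
                            tree_sim = list()) {
  cfg <- list(
    window_k = assert_count(window_k, "window_k", 1L),
    evalue_domain_accept = assert_number(evalue_domain_accept,
                                         "evalue_domain_accept", 0,
                                         strict_min = TRUE),
    coverage_min = assert_number(coverage_min, "coverage_min", 0, 1),
    evalue_neighborhood = assert_number(evalue_neighborhood,
                                        "evalue_neighborhood", 0,
                                        strict_min = TRUE),
    alpha = assert_number(alpha, "alpha", 0, 1, strict_min = TRUE,
                          strict_max = TRUE),
    conservation_threshold = assert_number(conservation_threshold,
                                           "conservation_threshold", 0, 1),
    support_threshold = assert_number(support_threshold,
                                      "support_threshold", 0, 1),
    rank_direction = match.arg(rank_direction, c("descending", "ascending")),
    seed = assert_count(seed, "seed", 0L),
    genome_sim = genome_sim,
    family_sim = family_sim,
    tree_sim = tree_sim
  )
  ## YAML deserializes named vectors as lists; normalize so a config
  ## round-trips to an identical object
  if (!is.null(cfg$genome_sim$enriched_domains)) {
    cfg$genome_sim$enriched_domains <-
      unlist(cfg$genome_sim$enriched_domains)
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  if (!inherits(config, "pipeline_config")) {
    stop_gmrsd("`config` must come from pipeline_config()")
  }
  raw <- unclass(config)
  ## serialize the named multiplier vector as a YAML map so names survive
  if (!is.null(raw$genome_sim$enriched_domains)) {
    raw$genome_sim$enriched_domains <-
      as.list(raw$genome_sim$enriched_domains)
  }
  yaml::write_yaml(raw, path)
  invisible(path)
}

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (is.list(df[[col]])) {
      df[[col]] <- vapply(df[[col]], paste, character(1), collapse = ",")
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_fasta_plain <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(c(paste0(">", id), seqs[[id]]), con)
  }
  invisible(path)
}

#' Run the end-to-end synthetic analysis
#'
#' Executes every stage on simulated inputs with planted truth: genome and
#' family and tree-pair simulation, domain-hit acceptance and architecture
#' classification, per-genome inventories, single-domain pairing, alignment
#' merging and conservation profiling, consensus motif scanning,
#' neighborhood enrichment, and the coevolution pipeline. All stage outputs
#' are written as plain-text files (TSV / FASTA / Newick / JSON) into
#' `out_dir` together with a manifest recording the configuration hash, the
#' seed, and a content hash of every output, so a rerun with an identical
#' configuration reproduces identical hashes.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "pipeline_config")) {
    stop_gmrsd("`config` must come from pipeline_config()")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files <<- c(files, name)
    path
  }

  ## stage 1: simulation
  gspec <- do.call(genome_sim_spec,
                   utils::modifyList(list(seed = derive_seed(config$seed, 1),
                                          window_k = config$window_k),
                                     config$genome_sim))
  gsim <- simulate_genomes(gspec)
  fspec <- do.call(family_sim_spec,
                   utils::modifyList(list(seed = derive_seed(config$seed, 2)),
                                     config$family_sim))
  fsim <- simulate_family(fspec)
  tspec <- do.call(tree_sim_spec,
                   utils::modifyList(list(seed = derive_seed(config$seed, 3)),
                                     config$tree_sim))
  tsim <- simulate_tree_pair(tspec)
  emit("orfs.tsv", function(p) write_tsv_plain(gsim$annotation, p))
  emit("domain_hits.tsv", function(p) write_tsv_plain(gsim$hits, p))
  emit("truth.json", function(p) {
    jsonlite::write_json(gsim$truth, p, auto_unbox = TRUE, pretty = TRUE)
  })
  emit("family.fasta", function(p) {
    write_fasta_plain(setNames(fsim$sequences$sequence,
                               fsim$sequences$seq_id), p)
  })

  ## stage 2: architecture classification (family hits are noise-free but
  ## still pass through the acceptance filter)
  accepted <- accept_domain_hits(fsim$hits,
                                 evalue_max = config$evalue_domain_accept,
                                 coverage_min = config$coverage_min)
  arch <- classify_architectures(accepted)
  arch <- dplyr::left_join(
    arch,
    dplyr::select(fsim$sequences, protein_id = "seq_id", "genome_id"),
    by = "protein_id"
  )
  emit("architectures.tsv", function(p) write_tsv_plain(arch, p))

  ## stage 3: inventory + pairing
  inventory <- build_inventory(arch)
  pairs <- pair_single_domains(
    arch, setNames(fsim$sequences$sequence, fsim$sequences$seq_id)
  )
  emit("inventory.tsv", function(p) write_tsv_plain(inventory, p))
  emit("merged_pairs.fasta", function(p) {
    write_fasta_plain(setNames(pairs$merged_sequence, pairs$merged_id), p)
  })

  ## stage 4: alignment merge + conservation + motifs
  fam_msa <- family_msa(fsim)
  backbone <- fsim$sequences$seq_id[fsim$sequences$klass == "DOUBLE"]
  merged_msa <- fam_msa
  if (length(backbone)) {
    keep_a <- fsim$sequences$klass %in% c("DOUBLE", "GMRS_ONLY")
    keep_b <- fsim$sequences$klass %in% c("DOUBLE", "GMRD_ONLY")
    aln_a <- msa_drop_gap_columns(
      msa_restrict(fam_msa, fsim$sequences$seq_id[keep_a]))
    aln_b <- msa_drop_gap_columns(
      msa_restrict(fam_msa, fsim$sequences$seq_id[keep_b]))
    merged_msa <- merge_alignments(aln_a, aln_b, backbone)
  }
  profile <- conservation_profile(merged_msa,
                                  threshold = config$conservation_threshold)
  matches <- scan_motifs(
    setNames(fsim$sequences$sequence, fsim$sequences$seq_id),
    fsim$spec$motif_specs
  )
  consensus_windows <- scan_alignment_consensus(merged_msa,
                                                fsim$spec$motif_specs,
                                                min_column_freq = 0.5)
  emit("family_alignment.fasta", function(p) write_fasta_msa(merged_msa, p))
  emit("conservation.tsv", function(p) write_tsv_plain(profile, p))
  emit("motif_matches.tsv", function(p) write_tsv_plain(matches, p))
  emit("motif_consensus_windows.tsv",
       function(p) write_tsv_plain(consensus_windows, p))

  ## stage 5: neighborhood enrichment on the simulated genomes
  enrich <- neighborhood_enrichment(
    gsim$annotation, gsim$hits, gsim$truth$focal$protein_id,
    k = config$window_k, evalue_max = config$evalue_neighborhood,
    alpha = config$alpha, rank_direction = config$rank_direction
  )
  emit("enrichment.tsv", function(p) write_tsv_plain(tidy(enrich), p))

  ## stage 6: coevolution
  congr <- coevolve(tsim$tree_s, tsim$tree_d, tsim$association,
                    support_threshold = config$support_threshold)
  emit("tanglegram.json", function(p) {
    tanglegram_export(tsim$tree_s, tsim$tree_d, tsim$association, p)
  })
  emit("congruence.json", function(p) {
    jsonlite::write_json(as.list(congr), p, auto_unbox = TRUE, digits = NA)
  })

  ## stage 7: report + manifest
  results <- list(genome_sim = gsim, family_sim = fsim, tree_sim = tsim,
                  architectures = arch, inventory = inventory, pairs = pairs,
                  msa = merged_msa, conservation = profile,
                  motif_matches = matches, enrichment = enrich,
                  congruence = congr)
  emit("report.md", function(p) {
    writeLines(render_report(results, config), p)
  })
  manifest <- list(
    package = "gmrsdkit",
    version = as.character(utils::packageVersion("gmrsdkit")),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    files = lapply(setNames(files, files), function(f) {
      rlang::hash(readLines(file.path(out_dir, f), warn = FALSE))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(c(results, list(manifest = manifest)))
}

render_report <- function(results, config) {
  inv <- results$inventory
  enr <- tidy(results$enrichment)
  top <- utils::head(enr, 12)
  lines <- c(
    "# GmrSD synthetic-analysis report", "",
    "## Genome inventory (counts of architecture sets)", "",
    sprintf("genomes: %d; double-domain: %d; GmrS-only: %d; GmrD-only: %d; other: %d",
            nrow(inv), sum(inv$n_double), sum(inv$n_s_only),
            sum(inv$n_d_only), sum(inv$n_other)),
    sprintf("merged single-domain pairs: %d", nrow(results$pairs)), "",
    "## Most enriched neighborhood domains", "",
    "domain\tdiff\tci_lower\tci_upper\tenriched\trank",
    sprintf("%s\t%.5f\t%.5f\t%.5f\t%s\t%d",
            top$domain_id, top$diff, top$ci_lower, top$ci_upper,
            top$enriched, top$rank), "",
    sprintf("enriched domains: %d of %d (individual CI level %.6g)",
            sum(enr$enriched), nrow(enr),
            if (nrow(enr)) enr$level[1] else NA), "",
    "## Motif matches", "",
    sprintf("motif match rows: %d over %d sequences",
            nrow(results$motif_matches),
            dplyr::n_distinct(results$motif_matches$seq_id)), "",
    "## Coevolution", "",
    sprintf("shared leaf pairs: %d; RF distance: %d (normalized %.3f)",
            results$congruence$n_shared_pairs, results$congruence$rf,
            results$congruence$rf_normalized)
  )
  lines
}

#' Summarize a completed pipeline run directory
#'
#' Reads the stage outputs written by [run_pipeline()] and prints a
#' human-readable summary: the per-genome inventory roll-up, the
#' top-enriched-domain table, the motif match tally and the congruence
#' report. Missing sections are marked rather than failing the whole
#' summary; an empty or absent directory is an error.
#'
#' @param out_dir A directory produced by [run_pipeline()].
#' @return The report lines, invisibly; the report is also printed.
#' @export
summarize_run <- function(out_dir) {
  if (!dir.exists(out_dir) || !length(list.files(out_dir))) {
    stop_gmrsd(sprintf("'%s' is not a completed run directory", out_dir))
  }
  lines <- character(0)
  section <- function(file, fn) {
    path <- file.path(out_dir, file)
    if (file.exists(path)) fn(path) else sprintf("[missing section: %s]", file)
  }
  lines <- c(
    lines,
    section("inventory.tsv", function(p) {
      inv <- utils::read.delim(p)
      sprintf("genomes: %d; double: %d; S-only: %d; D-only: %d; other: %d",
              nrow(inv), sum(inv$n_double), sum(inv$n_s_only),
              sum(inv$n_d_only), sum(inv$n_other))
    }),
    section("enrichment.tsv", function(p) {
      enr <- utils::read.delim(p)
      c(sprintf("enriched domains: %d of %d", sum(enr$enriched), nrow(enr)),
        utils::capture.output(print(utils::head(
          enr[order(enr$rank), c("domain_id", "diff", "ci_lower", "enriched")],
          10
        ))))
    }),
    section("motif_matches.tsv", function(p) {
      mm <- utils::read.delim(p)
      sprintf("motif matches: %d rows, %d patterns", nrow(mm),
              length(unique(mm$pattern)))
    }),
    section("congruence.json", function(p) {
      cg <- jsonlite::read_json(p, simplifyVector = TRUE)
      sprintf("coevolution: %d shared pairs, RF = %d (normalized %.3f)",
              cg$n_shared_pairs, cg$rf, cg$rf_normalized)
    })
  )
  writeLines(lines)
  invisible(lines)
}
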