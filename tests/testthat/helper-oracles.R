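# Independent oracles and random-case builders shared across test files.
# These deliberately use naive algorithms (full enumeration, double loops)
# so they stay independent of the implementation they check.

# all match positions of a motif by brute-force double loop
brute_force_scan <- function(sequence, pattern) {
  if (is.character(pattern)) pattern <- compile_motif(pattern)
  chars <- strsplit(toupper(sequence), "")[[1]]
  m <- length(pattern$elements)
  starts <- integer(0)
  if (length(chars) >= m) {
    for (i in seq_len(length(chars) - m + 1L)) {
      ok <- TRUE
      for (j in seq_len(m)) {
        if (!chars[i + j - 1L] %in% pattern$elements[[j]]) {
          ok <- FALSE
          break
        }
      }
      if (ok) starts <- c(starts, i)
    }
  }
  starts
}

# verify the greedy top-scoring non-overlap contract on one protein's hits:
# accepted hits pairwise non-overlapping, and every rejected (passing) hit
# overlaps an accepted hit with evalue <= its own
check_nonoverlap_contract <- function(hits, accepted, evalue_max = 1e-3) {
  overlaps <- function(a_s, a_e, b_s, b_e) a_s <= b_e && b_s <= a_e
  if (nrow(accepted) > 1L) {
    for (i in seq_len(nrow(accepted) - 1L)) {
      for (j in seq.int(i + 1L, nrow(accepted))) {
        if (overlaps(accepted$env_start[i], accepted$env_end[i],
                     accepted$env_start[j], accepted$env_end[j])) {
          return(FALSE)
        }
      }
    }
  }
  passing <- hits[hits$evalue < evalue_max, ]
  key <- function(h) paste(h$domain_id, h$env_start, h$env_end, h$evalue)
  rejected <- passing[!key(passing) %in% key(accepted), ]
  if (nrow(rejected)) {
    for (i in seq_len(nrow(rejected))) {
      beaten <- FALSE
      for (j in seq_len(nrow(accepted))) {
        if (overlaps(rejected$env_start[i], rejected$env_end[i],
                     accepted$env_start[j], accepted$env_end[j]) &&
            accepted$evalue[j] <= rejected$evalue[i]) {
          beaten <- TRUE
          break
        }
      }
      if (!beaten) return(FALSE)
    }
  }
  TRUE
}

random_hitset <- function(n_hits = NULL, protein = "p1") {
  if (is.null(n_hits)) n_hits <- sample(1:12, 1)
  s <- sample(1:300, n_hits, replace = TRUE)
  tibble::tibble(
    protein_id = protein,
    domain_id = sprintf("D%02d", sample(1:20, n_hits, replace = TRUE)),
    env_start = s,
    env_end = s + sample(10:80, n_hits, replace = TRUE),
    evalue = 10^runif(n_hits, -12, 0),
    model_coverage = runif(n_hits, 0.5, 1)
  )
}

random_supported_tree <- function(n_leaves = 12) {
  tree <- ape::rtree(n_leaves)
  tree$node.label <- sprintf("%.2f", runif(tree$Nnode))
  tree
}

# random merge scenario: a shared backbone alignment plus per-alignment
# added rows and insertion columns; returns list(aln_a, aln_b, backbone)
random_merge_case <- function(n_backbone = 4, n_add = 3, n_anchor = 10) {
  aa <- aa_alphabet()
  rand_block <- function(nr, nc, p_gap = 0.25) {
    m <- matrix(sample(aa, nr * nc, replace = TRUE), nr, nc)
    m[matrix(runif(nr * nc) < p_gap, nr, nc)] <- "-"
    m
  }
  repeat {  # backbone anchor columns: no all-gap column, no all-gap row
    backbone <- rand_block(n_backbone, n_anchor)
    if (all(colSums(backbone != "-") > 0) && all(rowSums(backbone != "-") > 0)) break
  }
  rownames(backbone) <- sprintf("bb%02d", seq_len(n_backbone))
  extend <- function(prefix) {
    added <- rand_block(n_add, n_anchor, p_gap = 0.35)
    rownames(added) <- sprintf("%s%02d", prefix, seq_len(n_add))
    m <- rbind(backbone, added)
    # sprinkle insertion columns: gap in backbone rows, residues in >=1 added row
    n_ins <- sample(0:3, 1)
    for (i in seq_len(n_ins)) {
      col <- c(rep("-", n_backbone), sample(aa, n_add, replace = TRUE))
      col[n_backbone + sample(n_add, sample(0:(n_add - 1), 1))] <- "-"
      pos <- sample(0:ncol(m), 1)
      m <- cbind(m[, seq_len(pos), drop = FALSE], col,
                 m[, seq.int(pos + 1, length.out = ncol(m) - pos), drop = FALSE])
    }
    colnames(m) <- NULL
    msa(setNames(apply(m, 1, paste, collapse = ""), rownames(m)))
  }
  list(aln_a = extend("as"), aln_b = extend("bd"),
       backbone = rownames(backbone))
}

# family simulation joined to a genome map, classified end to end
classify_family <- function(fam) {
  arch <- classify_architectures(accept_domain_hits(fam$hits))
  dplyr::left_join(
    arch,
    dplyr::select(fam$sequences, protein_id = "seq_id", "genome_id", truth_klass = "klass"),
    by = "protein_id"
  )
}
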