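#' Read split supports from a tree's internal-node labels
#'
#' Parses `node.label` as numeric support values. If any value exceeds 1
#' the whole tree is taken to use the percentage dialect and every support
#' is rescaled by 1/100. Unparseable or absent labels give `NA`.
#'
#' @param tree An `ape::phylo` object.
#' @return Numeric vector of length `tree$Nnode` (node `i` of the vector is
#'   internal node `Ntip + i`).
#' @export
tree_supports <- function(tree) {
  if (!inherits(tree, "phylo")) stop_gmrsd("`tree` must be an ape phylo object")
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  sup <- suppressWarnings(as.numeric(tree$node.label))
  if (any(sup > 1, na.rm = TRUE)) sup <- sup / 100
  sup
}

#' Collapse poorly supported splits into polytomies
#'
#' Contracts every internal split whose support value is strictly below
#' the threshold (the conventional cut for SH-like local supports is 0.8:
#' a split at 0.79 is collapsed, one at 0.80 retained). The leaf set is
#' unchanged; remaining internal splits all have support at or above the
#' threshold, so the operation is idempotent. Splits with missing support
#' are collapsed (conservative) and a message is emitted. The root is never
#' contracted. Branch lengths of collapsed edges are added to their child
#' edges, preserving root-to-tip distances.
#'
#' @param tree An `ape::phylo` with supports in `node.label` (see
#'   [tree_supports()]).
#' @param threshold Strict support threshold (default 0.8).
#' @return The collapsed `phylo`, supports of retained splits kept in
#'   `node.label`.
#' @export
collapse_low_support <- function(tree, threshold = 0.8) {
  if (!inherits(tree, "phylo")) stop_gmrsd("`tree` must be an ape phylo object")
  assert_number(threshold, "threshold", min = 0, max = 1)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  sup <- tree_supports(tree)
  node_ids <- ntip + seq_len(nnode)
  low <- is.na(sup) | sup < threshold
  marked <- node_ids[low & node_ids != root]
  if (any(is.na(sup[node_ids != root][low[node_ids != root]]))) {
    rlang::inform("splits with missing support values were collapsed")
  }
  if (!length(marked)) return(tree)

  nvert <- ntip + nnode
  parent <- integer(nvert)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen <- NULL
  if (!is.null(tree$edge.length)) {
    elen <- numeric(nvert)
    elen[tree$edge[, 2]] <- tree$edge.length
  }
  is_marked <- logical(nvert)
  is_marked[marked] <- TRUE

  keep_internal <- setdiff(node_ids, marked)
  keep_vert <- c(seq_len(ntip), keep_internal)
  ## chase each kept vertex up through contracted ancestors; collapsed edge
  ## lengths are accumulated onto the child edge
  new_parent <- integer(nvert)
  new_len <- if (is.null(elen)) NULL else numeric(nvert)
  for (v in setdiff(keep_vert, root)) {
    p <- parent[v]
    acc <- if (is.null(elen)) 0 else elen[v]
    while (is_marked[p]) {
      if (!is.null(elen)) acc <- acc + elen[p]
      p <- parent[p]
    }
    new_parent[v] <- p
    if (!is.null(new_len)) new_len[v] <- acc
  }

  ## renumber: tips keep 1..ntip; kept internal nodes get ntip+1.. in
  ## ascending original order (root, the smallest internal id, stays first)
  new_id <- integer(nvert)
  new_id[seq_len(ntip)] <- seq_len(ntip)
  new_id[sort(keep_internal)] <- ntip + seq_along(keep_internal)
  children <- setdiff(keep_vert, root)
  edge <- cbind(new_id[new_parent[children]], new_id[children])
  out <- list(
    edge = edge,
    tip.label = tree$tip.label,
    Nnode = length(keep_internal),
    node.label = tree$node.label[sort(keep_internal) - ntip]
  )
  if (!is.null(new_len)) out$edge.length <- new_len[children]
  class(out) <- "phylo"
  attr(out, "order") <- NULL
  ape::reorder.phylo(out, "cladewise")
}

#' Prune unpaired counterpart leaves from a tree pair
#'
#' Removes from the GmrS tree every leaf without an associated GmrD
#' counterpart and vice versa, so that the two trees are left on leaf sets
#' in bijection via the association. Degree-2 nodes created by pruning are
#' suppressed.
#'
#' @param tree_s,tree_d `ape::phylo` trees.
#' @param assoc Association tibble with columns `s_leaf`, `d_leaf` (each
#'   leaf at most once); rows must reference existing leaves.
#' @return A list with elements `tree_s`, `tree_d` (pruned trees, or `NULL`
#'   with a warning if the association is empty) and `n_pruned_s`,
#'   `n_pruned_d`.
#' @export
prune_unpaired <- function(tree_s, tree_d, assoc) {
  assert_columns(assoc, c("s_leaf", "d_leaf"), "assoc")
  if (anyDuplicated(assoc$s_leaf) || anyDuplicated(assoc$d_leaf)) {
    stop_gmrsd("each leaf may appear at most once in the association")
  }
  if (!nrow(assoc)) {
    rlang::warn("empty association: both pruned trees are empty")
    return(list(tree_s = NULL, tree_d = NULL,
                n_pruned_s = length(tree_s$tip.label),
                n_pruned_d = length(tree_d$tip.label)))
  }
  missing_s <- setdiff(assoc$s_leaf, tree_s$tip.label)
  missing_d <- setdiff(assoc$d_leaf, tree_d$tip.label)
  if (length(missing_s) || length(missing_d)) {
    stop_gmrsd(sprintf("association references absent leaves: %s",
                       paste(c(missing_s, missing_d), collapse = ", ")))
  }
  list(
    tree_s = ape::keep.tip(tree_s, assoc$s_leaf),
    tree_d = ape::keep.tip(tree_d, assoc$d_leaf),
    n_pruned_s = length(tree_s$tip.label) - nrow(assoc),
    n_pruned_d = length(tree_d$tip.label) - nrow(assoc)
  )
}

## canonical keys of the non-trivial splits (bipartitions) of an unrooted
## tree, polytomies taken as-is; computed from the edge matrix directly
tree_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 4L) return(character(0))
  tips <- sort(tree$tip.label)
  root <- ntip + 1L
  nvert <- ntip + tree$Nnode
  ## postorder accumulation of tip descendants per internal node
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  clade <- vector("list", nvert)
  for (i in seq_len(ntip)) clade[[i]] <- tree$tip.label[i]
  ## fixed-point sweep (node ids need not be topologically ordered)
  pending <- seq.int(root, nvert)
  repeat {
    done <- TRUE
    for (v in pending) {
      if (is.null(clade[[v]])) {
        ch <- kids[[as.character(v)]]
        if (all(!vapply(clade[ch], is.null, logical(1)))) {
          clade[[v]] <- sort(unlist(clade[ch]))
        } else {
          done <- FALSE
        }
      }
    }
    if (done) break
  }
  keys <- character(0)
  for (v in setdiff(seq.int(root, nvert), root)) {
    side <- clade[[v]]
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    ## canonical side: the one containing the alphabetically first tip
    if (!tips[1] %in% side) side <- setdiff(tips, side)
    keys <- c(keys, paste(side, collapse = "|"))
  }
  unique(keys)
}

#' Topological congruence of two associated trees
#'
#' Relabels the GmrD tree's leaves by their associated GmrS leaf and
#' compares the two trees' non-trivial split sets (trees treated as
#' unrooted; polytomies compared as-is, without resolution). The
#' Robinson-Foulds distance is the number of splits present in exactly one
#' tree; the normalized distance divides by the total number of non-trivial
#' splits in both trees (0 when neither tree has any).
#'
#' @param tree_s,tree_d `ape::phylo` trees already pruned to the associated
#'   leaves (see [prune_unpaired()]).
#' @param assoc Association tibble (`s_leaf`, `d_leaf`).
#' @return A one-row tibble of class `gmrsd_congruence`: `rf`,
#'   `rf_normalized`, `n_shared_pairs`, `n_splits_s`, `n_splits_d`.
#' @export
congruence <- function(tree_s, tree_d, assoc) {
  assert_columns(assoc, c("s_leaf", "d_leaf"), "assoc")
  t_d <- tree_d
  idx <- match(t_d$tip.label, assoc$d_leaf)
  if (anyNA(idx)) {
    stop_gmrsd("every leaf of `tree_d` must appear in the association")
  }
  t_d$tip.label <- assoc$s_leaf[idx]
  if (!setequal(tree_s$tip.label, t_d$tip.label)) {
    stop_gmrsd("leaf sets do not match after relabeling through the association")
  }
  s_splits <- tree_splits(tree_s)
  d_splits <- tree_splits(t_d)
  rf <- length(setdiff(s_splits, d_splits)) +
    length(setdiff(d_splits, s_splits))
  denom <- length(s_splits) + length(d_splits)
  out <- tibble::tibble(
    rf = rf,
    rf_normalized = if (denom > 0) rf / denom else 0,
    n_shared_pairs = length(tree_s$tip.label),
    n_splits_s = length(s_splits),
    n_splits_d = length(d_splits)
  )
  class(out) <- c("gmrsd_congruence", class(out))
  out
}

#' Run the full coevolution (tanglegram) pipeline on a tree pair
#'
#' Collapses poorly supported splits in both trees, prunes leaves without a
#' counterpart, and scores topological congruence.
#'
#' @inheritParams prune_unpaired
#' @param support_threshold Strict support threshold for
#'   [collapse_low_support()] (default 0.8).
#' @return A one-row tibble: the [congruence()] report plus `n_pruned_s`
#'   and `n_pruned_d`.
#' @export
coevolve <- function(tree_s, tree_d, assoc, support_threshold = 0.8) {
  ts <- collapse_low_support(tree_s, support_threshold)
  td <- collapse_low_support(tree_d, support_threshold)
  assoc_present <- assoc[assoc$s_leaf %in% ts$tip.label &
                           assoc$d_leaf %in% td$tip.label, ]
  pruned <- prune_unpaired(ts, td, assoc_present)
  rep <- congruence(pruned$tree_s, pruned$tree_d, assoc_present)
  rep$n_pruned_s <- pruned$n_pruned_s
  rep$n_pruned_d <- pruned$n_pruned_d
  rep
}

#' Export / import a tanglegram as a single data file
#'
#' Writes both trees (Newick, supports in internal-node labels) and the
#' leaf association to one JSON file that external tanglegram viewers (or
#' this package itself) can consume, and reads it back without loss.
#'
#' @param tree_s,tree_d `ape::phylo` trees.
#' @param assoc Association tibble (`s_leaf`, `d_leaf`, optionally
#'   `source`).
#' @param path Output file path.
#' @return `tanglegram_export()` returns `path` invisibly;
#'   `tanglegram_import()` returns a list with `tree_s`, `tree_d`,
#'   `association`.
#' @export
tanglegram_export <- function(tree_s, tree_d, assoc, path) {
  assert_columns(assoc, c("s_leaf", "d_leaf"), "assoc")
  payload <- list(
    format = "gmrsdkit_tanglegram",
    tree_s = ape::write.tree(tree_s),
    tree_d = ape::write.tree(tree_d),
    links = as.data.frame(assoc)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname tanglegram_export
#' @export
tanglegram_import <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "gmrsdkit_tanglegram")) {
    stop_gmrsd("not a gmrsdkit tanglegram file")
  }
  links <- tibble::as_tibble(payload$links)
  if (!nrow(links)) {
    links <- tibble::tibble(s_leaf = character(0), d_leaf = character(0),
                            source = character(0))
  }
  list(
    tree_s = ape::read.tree(text = payload$tree_s),
    tree_d = ape::read.tree(text = payload$tree_d),
    association = links
  )
}
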