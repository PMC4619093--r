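#' Specification for the coevolving tree-pair simulator
#'
#' Describes a pair of leaf-associated phylogenies with controlled
#' topological discordance: the second tree is derived from the first by a
#' given number of random subtree-prune-regraft (SPR) moves, and internal
#' splits of both trees carry support values drawn from a user sampler.
#' This emulates the GmrS / GmrD domain-tree pairs used to assess
#' coevolution of the two halves of the GmrSD system.
#'
#' @param n_leaves Number of leaves (>= 4, so internal splits exist).
#' @param n_spr Number of random SPR moves applied to derive the second
#'   tree (0 gives identical topologies).
#' @param support_distribution A function `f(n)` returning `n` support
#'   values in `[0, 1]`; default `stats::runif`.
#' @param seed Integer seed.
#' @return An object of class `tree_sim_spec`.
#' @seealso [simulate_tree_pair()]
#' @export
tree_sim_spec <- function(n_leaves = 30, n_spr = 0,
                          support_distribution = stats::runif,
                          seed = 1) {
  n_leaves <- assert_count(n_leaves, "n_leaves", min = 4L)
  n_spr <- assert_count(n_spr, "n_spr", min = 0L)
  seed <- assert_count(seed, "seed", 0L)
  if (!is.function(support_distribution)) {
    stop_gmrsd("`support_distribution` must be a function of n")
  }
  structure(
    list(n_leaves = n_leaves, n_spr = n_spr,
         support_distribution = support_distribution, seed = seed),
    class = "tree_sim_spec"
  )
}

#' Simulate a pair of leaf-associated trees with planted discordance
#'
#' Draws a random topology for the GmrS tree, applies `n_spr` random SPR
#' moves (each uniform over valid prune-edge / regraft-edge pairs) to obtain
#' the GmrD topology, labels the
#' leaves `pairNNN_S` / `pairNNN_D`, and assigns per-split support values
#' from the spec's sampler (stored in the Newick internal-node labels).
#' With `n_spr = 0` the two trees have Robinson-Foulds distance 0.
#'
#' @param spec A [tree_sim_spec()].
#' @return A list of class `gmrsd_tree_sim` with `tree_s`, `tree_d`
#'   (`ape::phylo` with supports in `node.label`) and `association`, a
#'   tibble (`s_leaf`, `d_leaf`, `source`).
#' @examples
#' sim <- simulate_tree_pair(tree_sim_spec(n_leaves = 8, n_spr = 1, seed = 3))
#' sim$association
#' @export
simulate_tree_pair <- function(spec) {
  if (!inherits(spec, "tree_sim_spec")) {
    stop_gmrsd("`spec` must be created with tree_sim_spec()")
  }
  set.seed(spec$seed)
  n <- spec$n_leaves
  pair_ids <- sprintf("pair%03d", seq_len(n))

  tree_s <- ape::rtree(n, tip.label = paste0(pair_ids, "_S"))
  tree_d <- spr_moves(tree_s, spec$n_spr)
  tree_d$tip.label <- sub("_S$", "_D", tree_d$tip.label)

  attach_supports <- function(tree) {
    sup <- spec$support_distribution(tree$Nnode)
    if (any(sup < 0 | sup > 1)) {
      stop_gmrsd("`support_distribution` returned values outside [0, 1]")
    }
    tree$node.label <- sprintf("%.3f", sup)
    tree
  }
  tree_s <- attach_supports(tree_s)
  tree_d <- attach_supports(tree_d)

  structure(
    list(
      tree_s = tree_s,
      tree_d = tree_d,
      association = tibble::tibble(
        s_leaf = paste0(pair_ids, "_S"),
        d_leaf = paste0(pair_ids, "_D"),
        source = "double"
      )
    ),
    class = "gmrsd_tree_sim"
  )
}

## n random SPR moves applied one at a time
spr_moves <- function(tree, n_moves) {
  for (i in seq_len(n_moves)) tree <- random_spr(tree)
  tree
}

## one subtree-prune-regraft move on a rooted binary tree, drawn uniformly
## over the valid (prune-edge, regraft-edge) pairs: the subtree below the
## prune edge is detached, the degree-2 node left behind is suppressed, and
## the subtree is reattached onto any edge of the remaining tree (the
## attachment point subdivides that edge at a random position).
random_spr <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 3L) stop_gmrsd("SPR needs at least 3 leaves")
  root <- ntip + 1L
  edge <- tree$edge
  elen <- tree$edge.length %||% rep(1, nrow(edge))
  nvert <- ntip + tree$Nnode
  parent <- integer(nvert)
  parent[edge[, 2]] <- edge[, 1]

  ## vertex sets of every subtree, via postorder accumulation
  post <- ape::reorder.phylo(tree, "postorder")$edge
  vdesc <- as.list(seq_len(nvert))
  for (k in seq_len(nrow(post))) {
    vdesc[[post[k, 1]]] <- c(vdesc[[post[k, 1]]], vdesc[[post[k, 2]]])
  }
  n_sub_tips <- vapply(vdesc, function(s) sum(s <= ntip), integer(1))

  ## remaining-tree edge list after pruning edge k and suppressing its top
  remaining_after <- function(k) {
    p <- edge[k, 1]
    v <- edge[k, 2]
    sub <- vdesc[[v]]
    drop <- rep(FALSE, nrow(edge))
    drop[k] <- TRUE
    drop[edge[, 2] %in% sub] <- TRUE
    if (p == root) {
      sib_edge <- which(edge[, 1] == root & !drop & edge[, 2] != v)
      new_root <- edge[sib_edge, 2]
      drop[sib_edge] <- TRUE
      rem <- cbind(edge[!drop, , drop = FALSE], elen[!drop])
      list(rem = rem, root = new_root)
    } else {
      pp <- parent[p]
      sib_edge <- which(edge[, 1] == p & edge[, 2] != v)
      up_edge <- which(edge[, 2] == p)
      drop[c(sib_edge, up_edge)] <- TRUE
      rem <- cbind(edge[!drop, , drop = FALSE], elen[!drop])
      merged <- c(pp, edge[sib_edge, 2], elen[sib_edge] + elen[up_edge])
      list(rem = rbind(rem, merged), root = root)
    }
  }

  ## a prune edge is valid when the remaining tree keeps >= 2 tips (so it
  ## still has an edge to regraft onto)
  valid <- which(ntip - n_sub_tips[edge[, 2]] >= 2L)
  n_regraft <- vapply(valid, function(k) nrow(remaining_after(k)$rem),
                      integer(1))
  ## uniform over pairs: prune edge weighted by its regraft count
  k <- valid[sample.int(length(valid), 1L, prob = n_regraft)]
  ra <- remaining_after(k)
  j <- sample.int(nrow(ra$rem), 1L)

  v <- edge[k, 2]
  sub <- vdesc[[v]]
  sub_edges <- which(edge[, 2] %in% sub & seq_len(nrow(edge)) != k)
  w <- nvert + 1L
  u <- runif(1, 0.2, 0.8)
  x <- ra$rem[j, 1]; y <- ra$rem[j, 2]; len <- ra$rem[j, 3]
  new_edges <- rbind(
    ra$rem[-j, , drop = FALSE],
    c(x, w, len * u),
    c(w, y, len * (1 - u)),
    c(w, v, elen[k]),
    cbind(edge[sub_edges, , drop = FALSE], elen[sub_edges])
  )

  ## renumber to phylo convention: tips keep 1..ntip, new root = ntip+1
  internals <- sort(unique(new_edges[, 1]))
  internals <- c(ra$root, setdiff(internals, ra$root))
  map <- integer(max(c(new_edges[, 1], new_edges[, 2])))
  map[seq_len(ntip)] <- seq_len(ntip)
  map[internals] <- ntip + seq_along(internals)
  out <- list(
    edge = cbind(map[new_edges[, 1]], map[new_edges[, 2]]),
    edge.length = unname(new_edges[, 3]),
    tip.label = tree$tip.label,
    Nnode = length(internals)
  )
  class(out) <- "phylo"
  attr(out, "order") <- NULL
  ape::reorder.phylo(out, "cladewise")
}

#' @export
print.gmrsd_tree_sim <- function(x, ...) {
  cat(sprintf("<gmrsd_tree_sim> %d leaf pairs\n", nrow(x$association)))
  invisible(x)
}
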