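test_that("support collapsing is strict at the threshold", {
  tree <- ape::read.tree(text = "((a:1,b:1)0.79:1,(c:1,d:1)0.80:1,e:1);")
  collapsed <- collapse_low_support(tree, 0.8)
  # the 0.79 split is gone, the 0.80 split survives
  labs <- collapsed$node.label[nzchar(collapsed$node.label)]
  expect_false("0.79" %in% labs)
  expect_true("0.80" %in% labs)
  expect_setequal(collapsed$tip.label, tree$tip.label)
  expect_identical(collapsed$Nnode, tree$Nnode - 1L)
})

test_that("fully supported trees pass through unchanged and collapse is idempotent", {
  set.seed(21)
  for (i in 1:20) {
    tree <- random_supported_tree(sample(6:16, 1))
    once <- collapse_low_support(tree, 0.8)
    twice <- collapse_low_support(once, 0.8)
    expect_setequal(once$tip.label, tree$tip.label)
    expect_identical(ape::write.tree(twice), ape::write.tree(once))
  }
  solid <- random_supported_tree(8)
  solid$node.label <- rep("1.00", solid$Nnode)
  expect_identical(ape::write.tree(collapse_low_support(solid, 0.8)),
                   ape::write.tree(solid))
})

test_that("percentage supports are rescaled and missing supports collapse with a message", {
  pct <- ape::read.tree(text = "((a:1,b:1)79:1,(c:1,d:1)95:1,e:1);")
  expect_identical(sort(tree_supports(pct)[-1]), c(0.79, 0.95))
  collapsed <- collapse_low_support(pct, 0.8)
  expect_identical(collapsed$Nnode, pct$Nnode - 1L)

  blank <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1)0.9:1,e:1);")
  expect_message(out <- collapse_low_support(blank, 0.8), "missing support")
  expect_identical(out$Nnode, blank$Nnode - 1L)
})

test_that("collapse preserves root-to-tip distances", {
  tree <- ape::read.tree(text = "(((a:1,b:1)0.5:2,c:1)0.9:1,(d:1,e:1)0.9:1);")
  before <- ape::node.depth.edgelength(tree)[1:5]
  after_tree <- collapse_low_support(tree, 0.8)
  after <- ape::node.depth.edgelength(after_tree)[1:5]
  expect_equal(after[match(tree$tip.label, after_tree$tip.label)], before)
})

test_that("pruning leaves the associated bijection and suppresses unary nodes", {
  sim <- simulate_tree_pair(tree_sim_spec(n_leaves = 10, seed = 6))
  full <- prune_unpaired(sim$tree_s, sim$tree_d, sim$association)
  expect_identical(ape::Ntip(full$tree_s), 10L)
  expect_identical(full$n_pruned_s, 0L)

  part <- sim$association[1:4, ]
  pruned <- prune_unpaired(sim$tree_s, sim$tree_d, part)
  expect_setequal(pruned$tree_s$tip.label, part$s_leaf)
  expect_setequal(pruned$tree_d$tip.label, part$d_leaf)
  expect_identical(pruned$n_pruned_s, 6L)
  # binary tree on 4 leaves: no unary nodes left
  expect_lte(pruned$tree_s$Nnode, 3L)

  expect_warning(res <- prune_unpaired(sim$tree_s, sim$tree_d,
                                       sim$association[0, ]),
                 "empty association")
  expect_null(res$tree_s)
  expect_error(prune_unpaired(sim$tree_s, sim$tree_d,
                              tibble::tibble(s_leaf = "zz", d_leaf = "yy")),
               "absent")
})

test_that("congruence is zero on identical and on star trees", {
  sim <- simulate_tree_pair(tree_sim_spec(n_leaves = 12, n_spr = 0, seed = 9))
  rep0 <- congruence(sim$tree_s, sim$tree_d, sim$association)
  expect_identical(rep0$rf, 0L)
  expect_identical(rep0$rf_normalized, 0)

  # supports are drawn from runif, so a threshold of 1 collapses every split
  star_s <- collapse_low_support(sim$tree_s, 1)
  star_d <- collapse_low_support(sim$tree_d, 1)
  rep_star <- congruence(star_s, star_d, sim$association)
  expect_identical(rep_star$rf, 0L)
  expect_identical(rep_star$n_splits_s, 0L)
})

test_that("the split-set distance agrees with an independent RF implementation", {
  set.seed(31)
  for (i in 1:15) {
    n <- sample(6:20, 1)
    sim <- simulate_tree_pair(tree_sim_spec(n_leaves = n,
                                            n_spr = sample(0:3, 1),
                                            seed = i))
    mine <- congruence(sim$tree_s, sim$tree_d, sim$association)$rf
    td <- sim$tree_d
    td$tip.label <- sub("_D$", "_S", td$tip.label)
    ref <- phangorn::RF.dist(ape::unroot(sim$tree_s), ape::unroot(td),
                             check.labels = TRUE)
    expect_identical(mine, as.integer(ref))
  }
  # also on multifurcating trees after collapsing
  sim <- simulate_tree_pair(tree_sim_spec(n_leaves = 14, n_spr = 2, seed = 77))
  ts <- collapse_low_support(sim$tree_s, 0.6)
  td <- collapse_low_support(sim$tree_d, 0.6)
  mine <- congruence(ts, td, sim$association)$rf
  td$tip.label <- sub("_D$", "_S", td$tip.label)
  ref <- phangorn::RF.dist(ape::unroot(ts), ape::unroot(td),
                           check.labels = TRUE)
  expect_identical(mine, as.integer(ref))
})

test_that("tree-pair simulation honours its discordance and determinism contracts", {
  expect_error(tree_sim_spec(n_leaves = 3), "n_leaves")

  same <- simulate_tree_pair(tree_sim_spec(n_leaves = 9, n_spr = 0, seed = 4))
  expect_identical(congruence(same$tree_s, same$tree_d, same$association)$rf,
                   0L)

  a <- simulate_tree_pair(tree_sim_spec(n_leaves = 9, n_spr = 2, seed = 4))
  b <- simulate_tree_pair(tree_sim_spec(n_leaves = 9, n_spr = 2, seed = 4))
  expect_identical(ape::write.tree(a$tree_s), ape::write.tree(b$tree_s))
  expect_identical(ape::write.tree(a$tree_d), ape::write.tree(b$tree_d))
})

test_that("the full coevolution pipeline and tanglegram export round-trip", {
  sim <- simulate_tree_pair(tree_sim_spec(n_leaves = 12, n_spr = 1, seed = 15))
  rep <- coevolve(sim$tree_s, sim$tree_d, sim$association,
                  support_threshold = 0)
  expect_gte(rep$rf, 0L)
  expect_true(rep$rf_normalized >= 0 && rep$rf_normalized <= 1)
  expect_identical(rep$n_shared_pairs, 12L)

  path <- withr::local_tempfile(fileext = ".json")
  tanglegram_export(sim$tree_s, sim$tree_d, sim$association, path)
  back <- tanglegram_import(path)
  expect_identical(ape::write.tree(back$tree_s), ape::write.tree(sim$tree_s))
  expect_identical(ape::write.tree(back$tree_d), ape::write.tree(sim$tree_d))
  expect_identical(back$association$s_leaf, sim$association$s_leaf)
  expect_identical(nrow(back$association), 12L)
})
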