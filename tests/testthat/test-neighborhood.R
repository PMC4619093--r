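toy_annotation <- function(n_orfs = 30, genome = "g1", contig = "c01") {
  tibble::tibble(
    genome_id = genome, contig_id = contig,
    orf_index = seq_len(n_orfs) - 1L,
    start = (seq_len(n_orfs) - 1L) * 1000L + 1L,
    end = (seq_len(n_orfs) - 1L) * 1000L + 900L,
    strand = "+",
    protein_id = sprintf("%s_p%03d", genome, seq_len(n_orfs) - 1L)
  )
}

test_that("window extraction returns the k ORFs on each side of the focal gene", {
  ann <- toy_annotation(30)
  nb <- extract_neighborhood(ann, "g1_p015", k = 10)
  expect_identical(nrow(nb), 20L)
  expect_setequal(nb$orf_index, c(5:14, 16:25))
  expect_false(attr(nb, "truncated"))
  expect_false(any(nb$protein_id == "g1_p015"))

  edge <- extract_neighborhood(ann, "g1_p003", k = 10)
  expect_identical(nrow(edge), 13L)
  expect_true(attr(edge, "truncated"))

  lone <- extract_neighborhood(toy_annotation(1), "g1_p000", k = 10)
  expect_identical(nrow(lone), 0L)
  expect_true(attr(lone, "truncated"))

  expect_error(extract_neighborhood(ann, "nope"), "not found")
})

test_that("windows never cross contigs and the vectorized form agrees", {
  ann <- dplyr::bind_rows(toy_annotation(15, contig = "c01"),
                          toy_annotation(15, contig = "c02") |>
                            dplyr::mutate(protein_id = sub("_p", "_q", protein_id)))
  nb <- extract_neighborhood(ann, "g1_p014", k = 10)
  expect_true(all(nb$contig_id == "c01"))
  many <- extract_neighborhoods(ann, c("g1_p014", "g1_q000"), k = 10)
  solo <- extract_neighborhood(ann, "g1_q000", k = 10)
  expect_identical(
    sort(many$protein_id[many$focal_protein_id == "g1_q000"]),
    sort(solo$protein_id)
  )
  expect_lte(max(table(many$focal_protein_id)), 20L)
})

test_that("greedy selection keeps top-scoring non-overlapping hits", {
  h <- tibble::tibble(
    protein_id = "p1",
    domain_id = c("A", "B", "C"),
    env_start = c(1L, 50L, 160L),
    env_end = c(100L, 150L, 200L),
    evalue = c(1e-10, 1e-5, 1e-4),
    model_coverage = 0.9
  )
  kept <- select_top_nonoverlapping(h)
  expect_setequal(kept$domain_id, c("A", "C"))

  above <- tibble::tibble(protein_id = "p1", domain_id = "A",
                          env_start = 1L, env_end = 10L, evalue = 0.5,
                          model_coverage = 0.9)
  expect_identical(nrow(select_top_nonoverlapping(above)), 0L)
})

test_that("greedy selection satisfies the brute-force contract on random hit sets", {
  set.seed(99)
  for (i in 1:60) {
    h <- random_hitset()
    h$evalue <- 10^runif(nrow(h), -8, -4)  # all pass the threshold
    kept <- select_top_nonoverlapping(h)
    expect_true(check_nonoverlap_contract(h, kept))
  }
})

test_that("domain counting de-duplicates proteins shared by windows", {
  hits <- tibble::tibble(
    protein_id = c("a", "b"), domain_id = c("D1", "D2"),
    env_start = 1L, env_end = 50L, evalue = 1e-6, model_coverage = 0.9
  )
  counts <- count_domains(c("a", "b", "a"), hits)
  expect_identical(counts$n[counts$domain_id == "D1"], 1L)
  tab <- build_count_table(c("a", "b", "a"), c("a", "b"), hits)
  expect_identical(sum(tab$x1), tab$n1[1])
  expect_identical(sum(tab$x2), tab$n2[1])
})

test_that("the two-proportion interval matches its reference implementation", {
  # frozen from the continuity-corrected equal-proportions test:
  # x = (30, 10), n = (100, 200), 95%
  ci <- two_proportion_ci(30, 100, 10, 200, 0.95)
  expect_identical(ci$diff, 0.25)
  expect_lt(abs(ci$ci_lower - 0.14774025119613), 1e-9)
  expect_lt(abs(ci$ci_upper - 0.35225974880387), 1e-9)

  # live oracle over a random grid
  set.seed(4)
  for (i in 1:40) {
    n1 <- sample(5:400, 1); n2 <- sample(5:400, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    lv <- runif(1, 0.8, 0.999)
    mine <- two_proportion_ci(x1, n1, x2, n2, lv)
    ref <- suppressWarnings(
      stats::prop.test(c(x1, x2), c(n1, n2), conf.level = lv)$conf.int
    )
    expect_lt(max(abs(c(mine$ci_lower, mine$ci_upper) - ref)), 1e-9)
  }
})

test_that("interval symmetry, nesting and input validation hold", {
  sym <- two_proportion_ci(10, 100, 20, 200)
  expect_identical(sym$diff, 0)
  expect_lt(abs(sym$ci_lower + sym$ci_upper), 1e-12)
  expect_true(sym$ci_lower <= 0 && sym$ci_upper >= 0)

  narrow <- two_proportion_ci(30, 100, 10, 200, 0.95)
  wide <- two_proportion_ci(30, 100, 10, 200, 0.99)
  expect_lt(wide$ci_lower, narrow$ci_lower)
  expect_gt(wide$ci_upper, narrow$ci_upper)

  expect_error(two_proportion_ci(1, 0, 1, 10), "positive")
  expect_error(two_proportion_ci(5, 4, 1, 10), "counts")
  expect_error(two_proportion_ci(1, 10, 1, 10, 1), "between 0 and 1")
})

test_that("enrichment applies the Bonferroni-adjusted level and the above-zero rule", {
  one <- enrichment_analysis(tibble::tibble(domain_id = "A", x1 = 30, x2 = 10,
                                            n1 = 100, n2 = 200))
  expect_identical(one$level, 0.95)

  flat <- enrichment_analysis(tibble::tibble(
    domain_id = c("A", "B"), x1 = c(10, 90), x2 = c(20, 180)
  ))
  expect_identical(sum(flat$enriched), 0L)
  expect_true(all(flat$ci_lower <= flat$diff & flat$diff <= flat$ci_upper))

  empty <- enrichment_analysis(tibble::tibble(domain_id = character(0),
                                              x1 = integer(0),
                                              x2 = integer(0)))
  expect_identical(nrow(empty), 0L)
  expect_error(enrichment_analysis(flat[, c("domain_id", "x1", "x2")],
                                   alpha = 0), "alpha")
})

test_that("ranking directions are consistent inverses", {
  tab <- tibble::tibble(domain_id = sprintf("D%d", 1:6),
                        x1 = c(40, 5, 1, 20, 9, 2),
                        x2 = c(10, 50, 30, 20, 9, 40))
  down <- enrichment_analysis(tab, rank_direction = "descending")
  up <- enrichment_analysis(tab, rank_direction = "ascending")
  expect_identical(down$domain_id, rev(up$domain_id))
  expect_true(!is.unsorted(rev(down$ci_lower)))
  # enriched first under the default
  if (any(down$enriched)) {
    expect_identical(which(down$enriched), seq_len(sum(down$enriched)))
  }
})

test_that("the full neighborhood pipeline recovers a strongly planted domain", {
  spec <- genome_sim_spec(n_genomes = 40, orfs_per_contig = 150,
                          domain_vocab_size = 30,
                          enriched_domains = c(DOM004 = 8), seed = 55)
  sim <- simulate_genomes(spec)
  res <- neighborhood_enrichment(sim$annotation, sim$hits,
                                 sim$truth$focal$protein_id)
  expect_true(res$enriched[res$domain_id == "DOM004"])
  expect_identical(res$domain_id[1], "DOM004")
  expect_identical(glance(res)$n_domains, attr(res, "n_domains"))
})
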