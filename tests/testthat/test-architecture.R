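mk_hits <- function(...) {
  rows <- list(...)
  tibble::tibble(
    protein_id = vapply(rows, `[[`, "", "p"),
    domain_id = vapply(rows, `[[`, "", "d"),
    env_start = vapply(rows, function(r) as.integer(r$s), integer(1)),
    env_end = vapply(rows, function(r) as.integer(r$e), integer(1)),
    evalue = vapply(rows, function(r) r$ev %||% 1e-10, numeric(1)),
    model_coverage = vapply(rows, function(r) r$cov %||% 0.95, numeric(1))
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("hit acceptance applies strict E-value and coverage bounds", {
  h <- mk_hits(
    list(p = "p1", d = "DUF262", s = 1, e = 200, ev = 1e-5, cov = 0.9),
    list(p = "p1", d = "DUF262", s = 1, e = 200, ev = 1e-5, cov = 0.7),
    list(p = "p1", d = "DUF262", s = 1, e = 200, ev = 0.001, cov = 0.9),
    list(p = "p1", d = "DUF262", s = 1, e = 200, ev = 1e-5, cov = 0.8)
  )
  kept <- accept_domain_hits(h)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$model_coverage, 0.9)
  expect_identical(nrow(accept_domain_hits(h[0, ])), 0L)
})

test_that("hit acceptance is idempotent and commutes with concatenation", {
  set.seed(42)
  for (i in 1:10) {
    h1 <- random_hitset(8)
    h2 <- random_hitset(8, protein = "p2")
    once <- accept_domain_hits(h1)
    expect_identical(accept_domain_hits(once), once)
    expect_identical(
      accept_domain_hits(dplyr::bind_rows(h1, h2)),
      dplyr::bind_rows(accept_domain_hits(h1), accept_domain_hits(h2))
    )
  }
})

test_that("architecture classes follow the domain content", {
  s_only <- classify_architecture(mk_hits(
    list(p = "p1", d = "DUF262", s = 1, e = 250)
  ))
  expect_identical(s_only$klass, "GMRS_ONLY")
  expect_true(is.na(s_only$d_start))

  dbl <- classify_architecture(mk_hits(
    list(p = "p2", d = "DUF262", s = 1, e = 250),
    list(p = "p2", d = "DUF1524", s = 300, e = 520)
  ))
  expect_identical(dbl$klass, "DOUBLE")
  expect_lt(dbl$s_end, dbl$d_start)

  d_extra <- classify_architecture(mk_hits(
    list(p = "p3", d = "DUF1524", s = 10, e = 200),
    list(p = "p3", d = "PF01035", s = 220, e = 300)
  ))
  expect_identical(d_extra$klass, "GMRD_ONLY")
  expect_identical(d_extra$extra_domains[[1]], "PF01035")

  other <- classify_architecture(mk_hits(
    list(p = "p4", d = "PF00001", s = 1, e = 90)
  ))
  expect_identical(other$klass, "OTHER")
})

test_that("classification is invariant to hit order and flags S/D overlap", {
  h <- mk_hits(
    list(p = "p1", d = "DUF262", s = 1, e = 250, ev = 1e-20),
    list(p = "p1", d = "DUF1524", s = 300, e = 520, ev = 1e-8),
    list(p = "p1", d = "PF01035", s = 530, e = 600, ev = 1e-4)
  )
  set.seed(1)
  for (i in 1:5) {
    perm <- h[sample(nrow(h)), ]
    expect_identical(classify_architecture(perm), classify_architecture(h))
  }
  # overlapping DUF262/DUF1524 regions: better E-value wins, flagged
  ov <- classify_architecture(mk_hits(
    list(p = "p9", d = "DUF262", s = 1, e = 300, ev = 1e-20),
    list(p = "p9", d = "DUF1524", s = 200, e = 480, ev = 1e-6)
  ))
  expect_identical(ov$klass, "GMRS_ONLY")
  expect_true(ov$overlap_flag)
})

test_that("multiple same-domain hits collapse to one union-span region", {
  arch <- classify_architecture(mk_hits(
    list(p = "p1", d = "DUF262", s = 10, e = 80),
    list(p = "p1", d = "DUF262", s = 120, e = 200)
  ))
  expect_identical(arch$klass, "GMRS_ONLY")
  expect_identical(c(arch$s_start, arch$s_end), c(10L, 200L))
})

test_that("inventories count and partition the family members per genome", {
  arch <- tibble::tibble(
    protein_id = c("a", "b", "c", "d"),
    klass = c("DOUBLE", "DOUBLE", "GMRS_ONLY", "GMRD_ONLY"),
    genome_id = c("g1", "g1", "g2", "g2")
  )
  genomes <- tibble::tibble(protein_id = c("a", "b", "c", "d", "e"),
                            genome_id = c("g1", "g1", "g2", "g2", "g3"))
  inv <- build_inventory(dplyr::select(arch, -genome_id), genomes)
  expect_identical(inv$n_double, c(2L, 0L, 0L))
  expect_identical(inv$n_s_only, c(0L, 1L, 0L))
  expect_identical(inv$n_d_only, c(0L, 1L, 0L))
  # counts partition the classified proteins
  expect_identical(sum(inv$n_double + inv$n_s_only + inv$n_d_only + inv$n_other),
                   4L)
  # an empty genome reports all zeros
  expect_identical(unlist(inv[inv$genome_id == "g3", -1]),
                   c(n_double = 0L, n_s_only = 0L, n_d_only = 0L, n_other = 0L))
  # a protein in two genomes is an error
  bad <- tibble::tibble(protein_id = c("a", "a"), genome_id = c("g1", "g2"))
  expect_error(build_inventory(dplyr::select(arch, -genome_id), bad),
               "more than one genome")
})

test_that("pairing requires exactly one single-domain protein of each type", {
  seqs <- c(s1 = "MKKS", d1 = "WDDD", s2 = "MSSS", dbl = "MMMM")
  one_each <- tibble::tibble(
    protein_id = c("s1", "d1"), klass = c("GMRS_ONLY", "GMRD_ONLY"),
    genome_id = "g1"
  )
  mp <- pair_single_domains(one_each, seqs)
  expect_identical(nrow(mp), 1L)
  expect_identical(mp$merged_sequence, "MKKSWDDD")
  expect_identical(nchar(mp$merged_sequence),
                   nchar(seqs[["s1"]]) + nchar(seqs[["d1"]]))
  expect_identical(mp$merged_id, "g1|s1+d1|merged")
  expect_false(mp$double_present)

  two_s <- dplyr::bind_rows(one_each, tibble::tibble(
    protein_id = "s2", klass = "GMRS_ONLY", genome_id = "g1"
  ))
  expect_identical(nrow(pair_single_domains(two_s, seqs)), 0L)

  only_double <- tibble::tibble(protein_id = "dbl", klass = "DOUBLE",
                                genome_id = "g1")
  expect_identical(nrow(pair_single_domains(only_double, seqs)), 0L)

  # pairing proceeds alongside a DOUBLE protein but is flagged
  with_double <- dplyr::bind_rows(one_each, only_double)
  mp2 <- pair_single_domains(with_double, seqs)
  expect_identical(nrow(mp2), 1L)
  expect_true(mp2$double_present)
})

test_that("pair count is bounded by the scarcer single-domain class", {
  fam <- simulate_family(family_sim_spec(n_double = 5, n_pairs = 4,
                                         n_orphans = 7, seed = 13))
  arch <- classify_family(fam)
  mp <- pair_single_domains(arch, setNames(fam$sequences$sequence,
                                           fam$sequences$seq_id))
  expect_lte(nrow(mp), min(sum(arch$klass == "GMRS_ONLY"),
                           sum(arch$klass == "GMRD_ONLY")))
})
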