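test_that("msa construction validates its input", {
  expect_error(msa(c(a = "ACD", b = "AC")), "same length")
  expect_error(msa(setNames(c("ACD", "ACD"), c("a", "a"))), "unique")
  expect_error(msa(c("ACD")), "named")
  m <- msa(c(a = "acd", b = "a-d"))
  expect_identical(unclass(m)[["a"]], "ACD")
  expect_identical(msa_width(m), 3L)
  expect_identical(msa_ungap(m)[["b"]], "AD")
})

test_that("merging with a backbone-only second alignment is the identity", {
  aln_a <- msa(c(bb1 = "AC-DE", bb2 = "ACQDE", s1 = "AC-D-"))
  aln_b <- msa(c(bb1 = "AC-DE", bb2 = "ACQDE"))
  merged <- merge_alignments(aln_a, aln_b, c("bb1", "bb2"))
  expect_identical(unclass(msa_drop_gap_columns(merged)),
                   unclass(msa_drop_gap_columns(aln_a)))
})

test_that("single-domain overflow grows the merge by equal gap stretches", {
  # backbone: two double-domain sequences; A adds an S-only sequence with a
  # 2-residue insertion after the S region; B adds a D-only sequence
  aln_a <- msa(c(bb1 = "ACD--EFG", bb2 = "ACD--EFG", s1 = "ACDKL---"))
  aln_b <- msa(c(bb1 = "ACDEFG", bb2 = "ACDEFG", d1 = "---EFG"))
  merged <- merge_alignments(aln_a, aln_b, c("bb1", "bb2"))
  expect_identical(
    unclass(merged),
    c(bb1 = "ACD--EFG", bb2 = "ACD--EFG", s1 = "ACDKL---", d1 = "-----EFG")
  )
  # width grew by exactly the 2-residue overflow relative to aln_b
  expect_identical(msa_width(merged), msa_width(aln_b) + 2L)
})

test_that("disjoint added rows are all retained exactly once", {
  case <- random_merge_case(n_backbone = 3, n_add = 4)
  merged <- merge_alignments(case$aln_a, case$aln_b, case$backbone)
  expect_identical(
    length(merged),
    length(case$aln_a) + length(case$aln_b) - length(case$backbone)
  )
  expect_identical(anyDuplicated(names(merged)), 0L)
})

test_that("backbone sequence mismatches and inconsistent columns are errors", {
  aln_a <- msa(c(bb1 = "ACDE", s1 = "AC--"))
  aln_b <- msa(c(bb1 = "ACDF", d1 = "--DF"))
  expect_error(merge_alignments(aln_a, aln_b, "bb1"), "bb1")
  # same residues, but backbone aligned differently between A and B
  aln_c <- msa(c(bb1 = "AC-DE", bb2 = "A-CDE", x = "ACDDE"))
  aln_d <- msa(c(bb1 = "A-CDE", bb2 = "AC-DE", y = "ACDDE"))
  expect_error(merge_alignments(aln_c, aln_d, c("bb1", "bb2")),
               "column-for-column")
})

test_that("random merges preserve residues and the backbone round-trip", {
  set.seed(7)
  for (i in 1:25) {
    case <- random_merge_case()
    merged <- merge_alignments(case$aln_a, case$aln_b, case$backbone)
    # no residue created or lost, for every id
    for (aln in list(case$aln_a, case$aln_b)) {
      ug <- msa_ungap(aln)
      expect_identical(msa_ungap(merged)[names(ug)], ug)
    }
    # restricting to the backbone and deleting all-gap columns reproduces
    # the backbone portion of both inputs column-for-column
    back_of <- function(aln) {
      unclass(msa_drop_gap_columns(msa_restrict(aln, case$backbone)))
    }
    expect_identical(back_of(merged), back_of(case$aln_a))
    expect_identical(back_of(merged), back_of(case$aln_b))
  }
})

test_that("conservation marks strictly above-threshold columns only", {
  all_same <- conservation_profile(msa(c(a = "A", b = "A", c = "A")))
  expect_identical(all_same$frequency, 1)
  expect_true(all_same$plus_mark)

  # 19 of 20 agree: frequency exactly 0.95 is NOT marked (strict >)
  seqs <- setNames(c(rep("D", 19), "E"), sprintf("s%02d", 1:20))
  at_bound <- conservation_profile(msa(seqs))
  expect_identical(at_bound$frequency, 0.95)
  expect_false(at_bound$plus_mark)

  gaps <- conservation_profile(msa(c(a = "-", b = "-", c = "-")))
  expect_identical(gaps$frequency, 0)
  expect_true(is.na(gaps$residue))
  expect_false(gaps$plus_mark)
})

test_that("gapped rows count against conservation and X is never modal", {
  m <- msa(c(a = "K", b = "K", c = "-", d = "X"))
  prof <- conservation_profile(m)
  expect_identical(prof$frequency, 0.5)
  expect_identical(prof$residue, "K")
})

test_that("conservation frequencies are invariant to row order", {
  set.seed(3)
  seqs <- setNames(
    replicate(12, paste(sample(c(aa_alphabet(), "-"), 30, replace = TRUE),
                        collapse = "")),
    sprintf("s%02d", 1:12)
  )
  base <- conservation_profile(msa(seqs))
  perm <- conservation_profile(msa(seqs[sample(length(seqs))]))
  expect_identical(base$frequency, perm$frequency)
  expect_identical(base$residue, perm$residue)
})

test_that("FASTA round-trips through Biostrings", {
  skip_if_not_installed("Biostrings")
  m <- msa(c(a = "AC-DE", b = "ACQDE"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_msa(m, path)
  expect_identical(unclass(read_fasta_msa(path)), unclass(m))
})
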