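test_that("identical sequences align full length at identity 1", {
  set.seed(11)
  a <- random_seq(22)
  r <- local_align(a, a)
  expect_equal(r$identity, 1.0)
  expect_equal(r$aligned_length, 22L)
  expect_equal(r$score, 22)
})

test_that("sequences with no common signal fail the homolog filter", {
  r <- local_align(strrep("A", 22), strrep("C", 22))
  expect_true(r$empty || r$aligned_length <= 1)
  f <- match_filter(0.70, 18)
  expect_false(!r$empty && r$identity >= f$min_identity &&
                 r$aligned_length >= f$min_length)
})

test_that("22-mers with 4 scattered mismatches align full length at 18/22", {
  set.seed(12)
  repeat { # scattered positions, each mutation guaranteed to differ
    a <- random_seq(22)
    b <- mutate_at(a, c(3, 8, 15, 20))
    if (direct_identity(a, b) == 18 / 22) break
  }
  r <- local_align(a, b)
  expect_equal(r$aligned_length, 22L)
  expect_equal(r$identity, 18 / 22)
  f <- match_filter(0.70, 18)
  expect_true(r$identity >= f$min_identity && r$aligned_length >= f$min_length)
})

test_that("local scores agree with an independent aligner on random pairs", {
  set.seed(13)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  for (k in 1:40) {
    a <- random_seq(sample(8:30, 1))
    b <- random_seq(sample(8:30, 1))
    ours <- local_align(a, b)
    ref <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                         substitutionMatrix = mat,
                                         gapOpening = 2, gapExtension = 1)
    expect_equal(ours$score, Biostrings::score(ref),
                 info = paste(a, b))
  }
})

test_that("global alignment of a 3' extension yields one terminal gap", {
  a <- "TACGTACGTACGTACGTACGTA"
  b <- paste0(a, "G")
  r <- global_align(a, b)
  expect_equal(r$qaln, paste0(a, "-"))
  expect_equal(r$taln, b)
})

test_that("msa of identical or nearly identical sequences is gap-free", {
  set.seed(14)
  s <- random_seq(22)
  aln <- align_msa(c(a = s, b = s, c = s, d = s))
  expect_true(all(!grepl("-", aln)))
  s2 <- mutate_at(s, 10)
  aln2 <- align_msa(c(a = s, b = s, c = s2))
  expect_true(all(!grepl("-", aln2)))
  expect_equal(nchar(aln2[[1]]), 22L)
})

test_that("msa places a single terminal gap for a 3' extension", {
  set.seed(15)
  s <- random_seq(22)
  ext <- paste0(s, "G")
  aln <- align_msa(c(a = s, b = s, c = s, d = ext))
  expect_equal(unique(nchar(aln)), 23L)
  expect_equal(substr(aln[["a"]], 23, 23), "-")
  expect_equal(aln[["d"]], ext)
})

test_that("empty sequences are rejected", {
  expect_error(local_align("", "ACGT"), "non-empty")
  expect_error(global_align("ACGT", ""), "non-empty")
})
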