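# a 5-bp GC stem with a 4-nt loop; pairs (1,14)..(5,10)
stem5 <- "GGGGGAAAACCCCC"

test_that("identical rows reproduce the single-sequence fold with zero covariance", {
  set.seed(41)
  for (k in 1:5) {
    hp <- designed_hairpin(10, 4)
    aln <- setNames(rep(hp, 4), paste0("s", 1:4))
    cf <- consensus_fold(aln)
    f <- fold_mfe(hp)
    expect_equal(cf$structure, f$structure)
    expect_equal(cf$consensus_energy, f$energy)
    expect_equal(cf$covariance_contribution, 0)
  }
})

test_that("a compensatory pair earns covariance bonus -1", {
  row2 <- stem5
  substr(row2, 3, 3) <- "A"; substr(row2, 12, 12) <- "T" # GC -> AT, restored
  cf <- consensus_fold(c(a = stem5, b = row2))
  # pair (3,12): two pair types among rows -> cov = -(2-1) = -1
  expect_equal(cf$covariance_contribution, -1)
  expect_lt(cf$covariance_contribution, 0)
  # thermo at (3,12) averages GC and AT: (-3 + -2)/2; other four pairs -3
  expect_equal(cf$thermo_part, 4 * -3 + (-2.5))
  expect_equal(cf$consensus_energy, cf$thermo_part + cf$covariance_contribution)
})

test_that("a pair-breaking row is kept by majority with penalty +1", {
  rows <- c(a = stem5, b = stem5, c = stem5, d = stem5)
  substr(rows["d"], 3, 3) <- "A" # d cannot pair (3,12); 3/4 still can
  cf <- consensus_fold(rows)
  expect_equal(cf$covariance_contribution, 1)
  expect_equal(substr(cf$structure, 3, 3), "(")
})

test_that("a column pair fails the majority-pairable gate", {
  rows <- c(a = stem5, b = stem5)
  substr(rows["b"], 3, 3) <- "A" # 1/2 pairable: not > 50%
  cf <- consensus_fold(rows)
  expect_equal(substr(cf$structure, 3, 3), ".")
})

test_that("sci is exactly 1 for identical rows and undefined for unfoldable rows", {
  set.seed(42)
  hp <- designed_hairpin(12, 4)
  r <- sci(setNames(rep(hp, 3), paste0("s", 1:3)))
  expect_equal(r$sci, 1)
  expect_equal(r$covariance_contribution, 0)
  expect_equal(r$mean_pairwise_identity, 1)
  r2 <- sci(c(a = strrep("A", 20), b = strrep("A", 20)))
  expect_true(r2$degenerate)
  expect_true(is.na(r2$sci))
})

test_that("compensated substitutions conserve sci better than pair-breaking ones", {
  comp <- stem5
  substr(comp, 3, 3) <- "A"; substr(comp, 12, 12) <- "T"
  broken <- stem5
  substr(broken, 3, 3) <- "A"
  aln_comp <- c(a = stem5, b = stem5, c = stem5, d = comp)
  aln_broken <- c(a = stem5, b = stem5, c = stem5, d = broken)
  expect_gt(sci(aln_comp)$sci, sci(aln_broken)$sci)
})

test_that("mean pairwise identity follows its definition", {
  a <- "TACGTACGTACGTACGTACG" # 20-mer
  b <- mutate_at(a, c(5, 11))
  expect_equal(mean_pairwise_identity(c(a = a, b = b)), 0.90)
  # three rows with pairwise identities 1.0, 0.9, 0.9
  expect_equal(mean_pairwise_identity(c(a = a, b = a, c = b)),
               mean(c(1, 0.9, 0.9)))
  # gap-vs-base is mismatch, gap-vs-gap excluded
  expect_equal(mean_pairwise_identity(c(a = "AC-GT-", b = "ACCGT-")),
               4 / 5)
})

test_that("ragged alignments are rejected", {
  expect_error(consensus_fold(c(a = "ACGT", b = "ACG")), "ragged")
})
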