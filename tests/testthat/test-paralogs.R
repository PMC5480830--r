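# small synthetic locus: pre-miRNA with flanks, fast to scan
make_locus <- function(flank = 400, pre = 80) {
  window <- random_seq(2 * flank + pre)
  locus_query("locusA", window, flank, flank + pre)
}

test_that("an exact genomic copy is found and called present", {
  set.seed(81)
  q <- make_locus()
  genome <- c(chr1 = q$window)
  m <- scan_genome(q, genome)
  expect_equal(nrow(m), 1)
  expect_equal(m$identity, 1.0)
  expect_equal(m$q_start, 0)
  expect_equal(m$q_end, nchar(q$window))
  call <- call_presence(q, m, genome, species = "sp1")
  expect_equal(call$status, "present")
})

test_that("random targets produce no permissive-threshold matches", {
  set.seed(82)
  for (k in 1:20) {
    q <- locus_query("q", random_seq(1080), 500, 580)
    m <- scan_genome(q, c(chr1 = random_seq(10000)))
    expect_equal(nrow(m), 0)
  }
})

test_that("a diverged copy with ~20% substitutions is retained", {
  set.seed(83)
  q <- make_locus(flank = 200, pre = 80)
  n <- nchar(q$window)
  copy <- mutate_at(q$window, sample(n, round(0.15 * n)))
  genome <- c(chr1 = paste0(random_seq(500), copy, random_seq(500)))
  m <- scan_genome(q, genome)
  expect_gte(nrow(m), 1)
  expect_gte(m$identity[1], 0.70)
  expect_gte(m$aligned_length[1], 300)
  call <- call_presence(q, m, genome, species = "sp1")
  expect_equal(call$status, "present")
})

test_that("a deleted pre-miRNA with intact flanks is absent_flanks_conserved", {
  set.seed(84)
  q <- make_locus()
  target <- paste0(substr(q$window, 1, q$pre_start),
                   substr(q$window, q$pre_end + 1, nchar(q$window)))
  genome <- c(chr1 = target)
  m <- scan_genome(q, genome)
  expect_gte(nrow(m), 1)
  call <- call_presence(q, m, genome, species = "sp1")
  expect_equal(call$status, "absent_flanks_conserved")
})

test_that("no matches at all is not_found", {
  set.seed(85)
  q <- make_locus(flank = 200)
  genome <- c(chr1 = random_seq(3000))
  m <- scan_genome(q, genome)
  call <- call_presence(q, m, genome, species = "sp1")
  expect_equal(call$status, "not_found")
})

test_that("presence calls are invariant to match order", {
  set.seed(86)
  q <- make_locus()
  target <- paste0(substr(q$window, 1, q$pre_start),
                   substr(q$window, q$pre_end + 1, nchar(q$window)))
  genome <- c(chr1 = target)
  m <- scan_genome(q, genome)
  if (nrow(m) > 1) {
    perm <- m[rev(seq_len(nrow(m))), ]
    expect_equal(call_presence(q, m, genome)$status,
                 call_presence(q, perm, genome)$status)
  } else {
    succeed("single match; order trivially irrelevant")
  }
})

test_that("repetitive query regions are masked and their matches dropped", {
  set.seed(87)
  rep_el <- random_seq(320)
  uniq <- random_seq(400)
  window <- paste0(uniq, rep_el)
  q <- locus_query("q", window, 50, 130)
  genome <- c(chr1 = paste0(paste(rep(rep_el, 15), collapse = ""),
                            random_seq(300), uniq))
  m <- scan_genome(q, genome)
  expect_gte(nrow(m), 10) # the repeat hits many times, the unique flank once
  filt <- filter_repetitive(m, nchar(window), max_hits = 10)
  # repeat-driven matches dropped, unique-region match kept
  expect_lt(nrow(filt), nrow(m))
  expect_true(any(filt$q_start < 400)) # the unique-region match survives
  expect_true(all(filt$q_start < 400)) # every repeat-driven match is gone
  uniq_only <- m[m$q_start < 350, , drop = FALSE]
  expect_equal(nrow(filter_repetitive(uniq_only, nchar(window),
                                      max_hits = 10)),
               nrow(uniq_only)) # unique-hit queries pass through unchanged
})
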