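zero_rates <- c(seed = 0, central = 0, supplementary = 0, tail = 0,
                stem = 0, loop = 0, flank = 0)

test_that("ancestral hairpins have the advertised geometry and fold deeply", {
  set.seed(101)
  anc <- make_ancestral_hairpin(stem_len = 30, loop_len = 10,
                                mature_len = 22, flank_len = 0)
  expect_equal(nchar(anc$window), 70) # 2 * 30 + 10
  f <- fold_mfe(anc$window)
  expect_gte(nrow(f$pairs), 25)
  expect_lte(f$energy, -2 * 30) # every stem pair is GC or AT
  anc2 <- make_ancestral_hairpin(18, 4, mature_len = 20, flank_len = 0)
  expect_equal(nchar(anc2$window), 40)
  expect_true(anc2$mature_end <= nchar(anc2$window))
  expect_true(anc2$star_start >= 0 && anc2$star_end <= 40)
})

test_that("zero rates propagate the ancestor unchanged with empty variant truth", {
  p <- sim_params(n_families = 2, flank_len = 50, rates = zero_rates,
                  deletions = list(), seed = 102)
  sim <- simulate_study(p)
  for (fam in sim$families) {
    anc_mature <- substr(fam$ancestor$window, fam$ancestor$mature_start + 1,
                         fam$ancestor$mature_end)
    for (tp in fam$tips) {
      expect_equal(tp$window, fam$ancestor$window)
      expect_equal(tp$mature, anc_mature)
    }
  }
  expect_equal(nrow(sim$truth$variants), 0)
})

test_that("a deletion on the Strepsirrhini stem branch marks exactly those taxa", {
  p <- sim_params(n_families = 2, flank_len = 50, rates = zero_rates,
                  seed = 103) # default deletion event on family 1
  sim <- simulate_study(p)
  pres <- sim$truth$presence
  absent <- pres$species[pres$locus == "fam01" &
                           pres$status == "absent_flanks_conserved"]
  expect_setequal(absent, c("mouse_lemur", "aye_aye", "galago"))
  expect_true(all(pres$status[pres$locus == "fam02"] == "present"))
  # deleted windows keep flanks, lose the pre-miRNA
  fam1 <- sim$families[[1]]
  del_tip <- Filter(function(tp) tp$deleted, fam1$tips)[[1]]
  expect_equal(nchar(del_tip$window),
               nchar(fam1$ancestor$window) -
                 (fam1$ancestor$pre_end - fam1$ancestor$pre_start))
})

test_that("duplication events add an independently evolving locus to carriers", {
  apes <- c("human", "chimpanzee", "bonobo", "gorilla", "orangutan", "gibbon")
  p <- sim_params(n_families = 1, flank_len = 30, deletions = list(),
                  duplications = list(list(clade = apes, family = 1L)),
                  seed = 104)
  sim <- simulate_study(p)
  dup_ids <- sim$matures$id[sim$matures$locus == "fam01-dup"]
  expect_setequal(sim$matures$species[sim$matures$locus == "fam01-dup"], apes)
  expect_equal(sum(sim$matures$locus == "fam01"), 13)
})

test_that("shift events move the mature register in the designated clade only", {
  apes <- c("human", "chimpanzee", "bonobo", "gorilla", "orangutan", "gibbon")
  p <- sim_params(n_families = 1, flank_len = 30, deletions = list(),
                  shifts = list(list(clade = apes, family = 1L, offset = 1L)),
                  seed = 105)
  sim <- simulate_study(p)
  sh <- sim$truth$shifts
  expect_true(all(sh$shift[sh$species %in% apes] == 1L))
  expect_true(all(sh$shift[!sh$species %in% apes] == 0L))
})

test_that("identical parameters give byte-identical bundles", {
  p <- sim_params(n_families = 2, flank_len = 40, seed = 106)
  d1 <- tempfile(); d2 <- tempfile()
  m1 <- write_study_bundle(simulate_study(p), d1)
  m2 <- write_study_bundle(simulate_study(p), d2)
  keep <- m1$file != "manifest.tsv"
  expect_identical(m1$md5[keep], m2$md5[keep])
})

test_that("an empty study still writes a well-formed bundle", {
  p <- sim_params(n_families = 0, deletions = list(), seed = 107)
  sim <- simulate_study(p)
  d <- tempfile()
  manifest <- write_study_bundle(sim, d)
  expect_true(all(c("matures.fasta", "predictions.tsv", "tree.nwk") %in%
                    manifest$file))
  pred <- read.delim(file.path(d, "predictions.tsv"))
  expect_equal(nrow(pred), 0)
  expect_true(all(c("id", "species", "score", "depth", "mature", "star",
                    "hairpin") %in% names(pred)))
})

test_that("written bundles feed back into the parsers losslessly", {
  p <- sim_params(n_families = 2, flank_len = 50, seed = 108,
                  deletions = list())
  sim <- simulate_study(p)
  d <- tempfile()
  write_study_bundle(sim, d)
  matures <- read_fasta(file.path(d, "matures.fasta"))
  expect_equal(length(matures), nrow(sim$matures))
  preds <- parse_prediction_table(file.path(d, "predictions.tsv"))
  expect_equal(sort(preds$id), sort(sim$matures$id))
  # located spans agree with the simulator's bookkeeping
  fam <- sim$families[[1]]
  tp <- fam$tips[[1]]
  rec <- preds[preds$id == paste0(tp$locus, "|", tp$species), ]
  expect_equal(rec$mature_start, tp$mature_start_in_hairpin)
})
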