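test_that("identical sequences yield no variants", {
  set.seed(61)
  s <- random_seq(22)
  aln <- align_group_matures(setNames(rep(s, 5), paste0("sp", 1:5)))
  v <- call_variants(aln)
  expect_equal(nrow(v), 0)
})

test_that("a single-species substitution is called with position and region", {
  # one species carries C where the other six have T at mature position 11
  set.seed(62)
  s <- random_seq(22)
  substr(s, 11, 11) <- "T"
  sg <- s; substr(sg, 11, 11) <- "C"
  seqs <- c(setNames(rep(s, 6),
                     c("human", "chimpanzee", "bonobo", "gorilla",
                       "orangutan", "rhesus")),
            galago = sg)
  v <- call_variants(align_group_matures(seqs), "miR-26b-5p")
  expect_equal(nrow(v), 1)
  expect_equal(v$position, 11L)
  expect_equal(v$ref, "T")
  expect_equal(v$alt, "C")
  expect_equal(v$species, "galago")
  expect_equal(v$region, "central")
})

test_that("shared minority bases list every carrier species", {
  set.seed(63)
  s <- random_seq(22); substr(s, 10, 10) <- "C"
  sv <- s; substr(sv, 10, 10) <- "A"
  seqs <- c(sp1 = s, sp2 = s, sp3 = s, sp4 = sv, sp5 = sv)
  v <- call_variants(align_group_matures(seqs))
  expect_equal(nrow(v), 1)
  expect_equal(v$n_species, 2L)
  expect_equal(v$species, "sp4,sp5")
  # oracle: direct column tally
  expect_equal(v$position, 10L)
})

test_that("multi-state columns emit one variant per minority base", {
  set.seed(64)
  s <- random_seq(22); substr(s, 15, 15) <- "G"
  s2 <- s; substr(s2, 15, 15) <- "A"
  s3 <- s; substr(s3, 15, 15) <- "C"
  seqs <- c(a = s, b = s, c = s, d = s2, e = s3)
  expect_warning(v <- call_variants(align_group_matures(seqs)), "states")
  expect_equal(nrow(v), 2)
  expect_setequal(v$alt, c("A", "C"))
  expect_equal(unique(v$region), "supplementary")
})

test_that("indel columns are reported separately, not as substitutions", {
  set.seed(65)
  s <- random_seq(22)
  ext <- paste0(s, "G")
  seqs <- c(a = s, b = s, c = s, d = ext)
  v <- call_variants(align_msa(seqs))
  expect_equal(nrow(v), 0)
  ind <- attr(v, "indels")
  expect_equal(nrow(ind), 1)
  expect_equal(ind$species, "a,b,c")
})

test_that("variant counts are consistent across region and position summaries", {
  set.seed(66)
  p <- sim_params(n_families = 12, flank_len = 0, compensatory_prob = 0,
                  deletions = list(), seed = 66)
  sim <- simulate_study(p)
  vars <- list()
  for (fam in sim$families) {
    tps <- Filter(function(tp) !tp$deleted, fam$tips)
    seqs <- setNames(vapply(tps, `[[`, "", "mature"),
                     vapply(tps, `[[`, "", "species"))
    vars[[fam$family]] <- suppressWarnings(
      call_variants(align_group_matures(seqs), fam$family))
  }
  vars <- do.call(rbind, vars)
  s <- summarize_variants(vars, primate_clades())
  expect_equal(sum(s$by_region), nrow(vars))
  expect_equal(sum(s$by_position$n), nrow(vars))
  expect_equal(s$n_pairs, sum(vars$n_species))
})

test_that("zero seed-region rate yields no seed variants", {
  rates <- c(seed = 0, central = 0.08, supplementary = 0.02, tail = 0.08,
             stem = 0.05, loop = 0.1, flank = 0.1)
  p <- sim_params(n_families = 20, flank_len = 0, rates = rates,
                  compensatory_prob = 0, deletions = list(), seed = 67)
  sim <- simulate_study(p)
  for (fam in sim$families) {
    seqs <- setNames(vapply(fam$tips, `[[`, "", "mature"),
                     vapply(fam$tips, `[[`, "", "species"))
    v <- suppressWarnings(call_variants(align_group_matures(seqs), fam$family))
    if (nrow(v)) expect_true(all(v$position >= 9))
  }
})

test_that("per-region variant densities recover the simulated rate ordering", {
  rates <- c(seed = 0.005, central = 0.05, supplementary = 0.015, tail = 0.05,
             stem = 0.04, loop = 0.1, flank = 0.1)
  p <- sim_params(n_families = 200, flank_len = 0, rates = rates,
                  compensatory_prob = 0, deletions = list(),
                  enforce_separation = FALSE, seed = 68)
  sim <- simulate_study(p)
  v <- sim$truth$variants
  pairs_by_region <- tapply(v$n_species, factor(v$region,
                                                levels = names(table(v$region))),
                            sum)
  width <- c(seed = 8, central = 4, supplementary = 4, tail = 6)
  dens <- function(r) {
    n <- pairs_by_region[[r]]
    if (is.null(n) || is.na(n)) n <- 0
    n / width[[r]]
  }
  expect_lt(dens("seed"), dens("supplementary"))
  expect_lt(dens("supplementary"), dens("central"))
  # equal-rate regions have similar densities (ratio within Monte-Carlo noise)
  ratio <- dens("central") / dens("tail")
  expect_gt(ratio, 0.6)
  expect_lt(ratio, 1.67)
})

test_that("species absent from the clade map are reported by name", {
  v <- data.frame(mirna = "m", position = 10L, ref = "A", alt = "T",
                  species = "dodo", n_species = 1L, region = "central",
                  stringsAsFactors = FALSE)
  expect_error(summarize_variants(v, primate_clades()), "dodo")
})
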