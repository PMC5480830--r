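# two synthetic families: high identity within, unrelated across
make_two_families <- function() {
  set.seed(51)
  repeat {
    base1 <- random_seq(22)
    base2 <- random_seq(22)
    cross <- local_align(base1, base2)
    if (cross$empty || cross$identity <= 0.5 || cross$aligned_length < 12) break
  }
  fam1 <- c(base1, replicate(4, mutate_at(base1, sample(22, 2))))
  fam2 <- c(base2, replicate(4, mutate_at(base2, sample(22, 2))))
  mature_records(id = c(paste0("f1_", 1:5), paste0("f2_", 1:5)),
                 species = rep(paste0("sp", 1:5), 2),
                 sequence = c(fam1, fam2))
}

test_that("all_vs_all retains exactly the within-family pairs", {
  recs <- make_two_families()
  hits <- all_vs_all(recs)
  fam <- substr(recs$id, 1, 2)
  names(fam) <- recs$id
  expect_true(all(fam[hits$query] == fam[hits$subject]))
  # oracle: direct ungapped identity of the constructed 22-mers
  within <- t(combn(recs$id[fam == "f1"], 2))
  for (k in seq_len(nrow(within))) {
    a <- recs$sequence[recs$id == within[k, 1]]
    b <- recs$sequence[recs$id == within[k, 2]]
    if (direct_identity(a, b) >= 0.70) {
      found <- any((hits$query == within[k, 1] & hits$subject == within[k, 2]) |
                     (hits$query == within[k, 2] & hits$subject == within[k, 1]))
      expect_true(found, info = paste(within[k, ], collapse = "/"))
    }
  }
})

test_that("degenerate all_vs_all inputs behave", {
  recs <- mature_records(c("a", "b"), c("s1", "s2"),
                         rep("TACGTACGTACGTACGTACGTA", 2))
  hits <- all_vs_all(recs)
  expect_equal(nrow(hits), 1) # one undirected pair
  one <- mature_records("a", "s1", "TACGTACGTACGTACGTACGTA")
  expect_equal(nrow(all_vs_all(one)), 0)
})

test_that("clustering is single linkage: chains merge transitively", {
  matches <- data.frame(query = c("A", "B"), subject = c("B", "C"),
                        stringsAsFactors = FALSE)
  cl <- cluster_homologs(matches, c("A", "B", "C", "D"))
  expect_equal(length(cl$groups), 1)
  expect_equal(cl$groups[[1]], c("A", "B", "C"))
  expect_equal(cl$singletons, "D")
  empty <- cluster_homologs(all_vs_all(mature_records(
    "x", "s", "TACGTACGTACGTACGTACGTA")), c("a", "b", "c"))
  expect_equal(length(empty$groups), 0)
  expect_equal(empty$singletons, c("a", "b", "c"))
})

test_that("clustering equals an independent union-find oracle and ignores input order", {
  recs <- make_two_families()
  hits <- all_vs_all(recs)
  cl <- cluster_homologs(hits, recs$id)
  oracle <- uf_components(recs$id, hits$query, hits$subject)
  # same partition (labels differ)
  expect_equal(rand_index(cl$membership[recs$id], oracle[recs$id]), 1.0)
  expect_equal(length(cl$groups), 2)
  set.seed(52)
  perm <- sample(nrow(recs))
  hits2 <- all_vs_all(recs[perm, ])
  cl2 <- cluster_homologs(hits2, recs$id[perm])
  expect_identical(cl$groups, cl2$groups)
})

test_that("ortholog subdivision splits paralog sub-families and enforces >= 3 species", {
  set.seed(53)
  base <- random_seq(22)
  paralog <- mutate_at(base, sample(22, 6)) # ~73% cross identity
  subA <- vapply(1:4, function(i) mutate_at(base, sample(22, 1)), "")
  subB <- vapply(1:4, function(i) mutate_at(paralog, sample(22, 1)), "")
  members <- mature_records(
    id = c(paste0("A", 1:4), paste0("B", 1:4)),
    species = rep(paste0("sp", 1:4), 2),
    sequence = c(subA, subB))
  ogs <- subdivide_orthologs(members, "HG:test", high_identity = 0.85)
  expect_equal(length(ogs), 2)
  expect_setequal(unlist(lapply(ogs, function(o) o$members$id)),
                  members$id)

  five <- mature_records(paste0("m", 1:5), paste0("sp", 1:5),
                         rep(base, 5))
  ogs5 <- subdivide_orthologs(five, "HG:five")
  expect_equal(length(ogs5), 1)
  expect_equal(nrow(ogs5[[1]]$members), 5)

  two_sp <- mature_records(paste0("m", 1:3), c("sp1", "sp1", "sp2"),
                           rep(base, 3))
  expect_equal(length(subdivide_orthologs(two_sp, "HG:two")), 0)
})

test_that("duplicate sequences from one species keep the best representative", {
  set.seed(54)
  base <- random_seq(22)
  members <- mature_records(
    id = c("a1", "a2", "b1", "c1"),
    species = c("sp1", "sp1", "sp2", "sp3"),
    sequence = c(base, mutate_at(base, sample(22, 2)), base, base),
    read_depth = c(10L, 99L, 5L, 5L))
  ogs <- subdivide_orthologs(members, "HG:dup")
  expect_equal(length(ogs), 1)
  # a1 is identical to the others, a2 carries 2 mismatches: a1 wins
  expect_setequal(ogs[[1]]$members$id, c("a1", "b1", "c1"))
})

test_that("prediction confirmation requires a perfect 18 nt block and collapses paralogs", {
  set.seed(55)
  v <- random_seq(22)
  validated <- data.frame(id = c("v1", "v2"), species = c("gorilla", "rhesus"),
                          sequence = c(v, random_seq(22)),
                          stringsAsFactors = FALSE)
  block17 <- paste0(substr(v, 1, 17), random_seq(5)) # 17 nt exact block only
  pred <- data.frame(
    id = c("p_same", "p_17nt", "par1", "par2", "par3"),
    family = c("mirX", "mirY", "fam320", "fam320", "fam320"),
    score = c(10, 10, 20, 22, 19),
    sequence = c(v, block17, v, v, v), stringsAsFactors = FALSE)
  res <- confirm_predictions(validated, pred)
  p <- res$predictions
  expect_equal(p$n_species[p$id == "p_same"], 1)
  expect_equal(p$species[p$id == "p_same"], "gorilla")
  expect_equal(p$n_species[p$id == "p_17nt"], 0)
  fam <- res$families[res$families$family == "fam320", ]
  expect_equal(nrow(fam), 1)
  expect_equal(fam$score, 22) # highest-scoring paralog represents the family
})
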