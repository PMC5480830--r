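#' Default 13-taxon primate-like tree
#'
#' Six apes, two Old World monkeys, two New World monkeys and three
#' Strepsirrhines, in the topology of the primate phylogeny. Branch
#' lengths are in arbitrary time units (root-to-tip depth 0.65) and are
#' invented for simulation purposes; substitution rates are expressed per
#' site per unit of this branch length.
#'
#' @return Newick string.
#' @export
primate_tree <- function() {
  paste0(
    "(((((((human:0.06,(chimpanzee:0.03,bonobo:0.03):0.03):0.02,",
    "gorilla:0.08):0.04,orangutan:0.12):0.04,gibbon:0.16):0.09,",
    "(rhesus:0.12,baboon:0.12):0.13):0.15,",
    "(marmoset:0.2,squirrel_monkey:0.2):0.2):0.25,",
    "((mouse_lemur:0.3,aye_aye:0.3):0.1,galago:0.4):0.25);")
}

#' Simulation parameters
#'
#' Defines the study conditions the simulator emulates: ~22 nt matures on
#' the 5' arm of a perfect-stem hairpin (~80 nt pre-miRNA inside a window
#' with 1000 nt flanks), evolved along the default primate-like tree with
#' region-specific substitution rates ordered seed < supplementary <
#' central/tail (the mature conservation gradient), faster loop and flank
#' evolution, compensatory stem substitutions, and lineage-specific
#' deletion/duplication events. The default event list carries one
#' pre-miRNA deletion on the Strepsirrhini stem branch, reproducing the
#' insertion-event pattern in which flanking sequence is conserved while
#' the element itself is missing in the basal suborder.
#'
#' @param n_families Number of independent miRNA families (default 20).
#' @param stem_len,loop_len Hairpin stem/loop lengths (default 32/16:
#'   80 nt pre-miRNA).
#' @param mature_len Mature length (default 22).
#' @param flank_len Flank length on each side of the pre-miRNA
#'   (default 1000).
#' @param rates Substitutions per site per unit branch length for regions
#'   `seed`, `central`, `supplementary`, `tail`, `stem`, `loop`, `flank`.
#' @param compensatory_prob Probability that a stem substitution is
#'   accompanied by the pairing-restoring partner substitution.
#' @param deletions,duplications,shifts Lists of events; each event is
#'   `list(clade = <tip labels>, family = <index>)` (shifts also carry
#'   `offset`). The event applies on the branch subtending the clade's
#'   MRCA.
#' @param ancestor_max_score Rejection-sampling cap on the local alignment
#'   score between any two ancestral matures (default 7, just below the
#'   minimum score of an ungapped alignment passing the 70%/18 nt homolog
#'   filter). A cheap prescreen; `Inf` disables it.
#' @param enforce_separation When TRUE (default), a freshly evolved family
#'   is re-drawn if any of its descendant matures passes the homolog
#'   clustering filter (70% identity over >= 18 columns) against a
#'   previously generated family, so distinct families are separated below
#'   the clustering threshold by construction. Disable for large
#'   simulations where family separability is not under study.
#' @param tree Newick string.
#' @param seed RNG seed.
#' @export
sim_params <- function(n_families = 20L, stem_len = 32L, loop_len = 16L,
                       mature_len = 22L, flank_len = 1000L,
                       rates = c(seed = 0.002, central = 0.04,
                                 supplementary = 0.01, tail = 0.04,
                                 stem = 0.04, loop = 0.10, flank = 0.15),
                       compensatory_prob = 0.3,
                       deletions = list(list(
                         clade = c("mouse_lemur", "aye_aye", "galago"),
                         family = 1L)),
                       duplications = list(), shifts = list(),
                       ancestor_max_score = 7, enforce_separation = TRUE,
                       tree = primate_tree(), seed = 1L) {
  need <- c("seed", "central", "supplementary", "tail", "stem", "loop",
            "flank")
  stopifnot(all(need %in% names(rates)), all(rates >= 0),
            compensatory_prob >= 0, compensatory_prob <= 1,
            stem_len >= 18, loop_len >= 4, mature_len >= 18,
            mature_len <= stem_len + loop_len, flank_len >= 0)
  structure(list(n_families = as.integer(n_families),
                 stem_len = as.integer(stem_len),
                 loop_len = as.integer(loop_len),
                 mature_len = as.integer(mature_len),
                 flank_len = as.integer(flank_len),
                 rates = rates[need],
                 compensatory_prob = compensatory_prob,
                 deletions = deletions, duplications = duplications,
                 shifts = shifts, ancestor_max_score = ancestor_max_score,
                 enforce_separation = isTRUE(enforce_separation),
                 tree = tree, seed = as.integer(seed)),
            class = "sim_params")
}

.BASES <- c("A", "C", "G", "T")
.COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Build a random ancestral hairpin locus
#'
#' Perfect-complement stem (so every stem pair is canonical GC/AT), random
#' loop, mature on the 5' arm starting at the first stem position, random
#' flanks. Uses the current RNG state.
#'
#' @param stem_len,loop_len,mature_len,flank_len See [sim_params()].
#' @return List: `window` (string), 0-based half-open coordinates
#'   (`pre_start`, `pre_end`, `mature_start`, `mature_end`, `star_start`,
#'   `star_end`), and `pairing` (1-based partner index per window
#'   position, NA off the stem).
#' @export
make_ancestral_hairpin <- function(stem_len = 32L, loop_len = 16L,
                                   mature_len = 22L, flank_len = 1000L) {
  stopifnot(stem_len >= 18, loop_len >= 4, mature_len <= stem_len + loop_len)
  arm1 <- sample(.BASES, stem_len, replace = TRUE)
  loop <- sample(.BASES, loop_len, replace = TRUE)
  arm2 <- rev(unname(.COMP[arm1]))
  up <- sample(.BASES, flank_len, replace = TRUE)
  dn <- sample(.BASES, flank_len, replace = TRUE)
  window <- c(up, arm1, loop, arm2, dn)
  pre_start <- flank_len
  pre_len <- 2L * stem_len + loop_len
  n <- length(window)
  pairing <- rep(NA_integer_, n)
  for (i in seq_len(stem_len)) {
    a <- pre_start + i                      # 1-based index of arm1 pos i
    b <- pre_start + pre_len - i + 1L       # matching arm2 position
    pairing[a] <- b
    pairing[b] <- a
  }
  mstart <- pre_start                        # mature starts at the stem 5' end
  sstart <- pre_start + pre_len - min(mature_len, stem_len)
  list(window = paste(window, collapse = ""),
       pre_start = pre_start, pre_end = pre_start + pre_len,
       mature_start = mstart, mature_end = mstart + mature_len,
       star_start = sstart, star_end = pre_start + pre_len,
       pairing = pairing,
       stem_len = stem_len, loop_len = loop_len, mature_len = mature_len,
       flank_len = flank_len)
}

# per-position rate category, given the (possibly shifted) mature start
.region_map <- function(anc, mature_start) {
  n <- nchar(anc$window)
  reg <- rep("flank", n)
  pre <- seq(anc$pre_start + 1L, anc$pre_end)
  arm1 <- seq(anc$pre_start + 1L, anc$pre_start + anc$stem_len)
  loop <- seq(anc$pre_start + anc$stem_len + 1L,
              anc$pre_start + anc$stem_len + anc$loop_len)
  reg[pre] <- "stem"
  reg[loop] <- "loop"
  mpos <- seq(mature_start + 1L, mature_start + anc$mature_len)
  mrel <- seq_len(anc$mature_len)
  reg[mpos] <- assign_region(mrel)
  reg
}

# mutate a window character vector along one branch
.mutate <- function(win, reg, pairing, rates, comp_prob, bl) {
  p <- 1 - exp(-rates[reg] * bl)
  hit <- which(runif(length(win)) < p)
  for (i in hit) {
    win[i] <- sample(setdiff(.BASES, win[i]), 1L)
    if (!is.na(pairing[i]) && runif(1) < comp_prob) {
      win[pairing[i]] <- unname(.COMP[win[i]])
    }
  }
  win
}

.find_event_edge <- function(tree, clade) {
  stopifnot(all(clade %in% tree$tip.label))
  node <- if (length(clade) == 1) {
    match(clade, tree$tip.label)
  } else {
    ape::getMRCA(tree, clade)
  }
  which(tree$edge[, 2] == node)
}

#' Evolve one hairpin family along a tree
#'
#' Substitutions are drawn per site with probability
#' `1 - exp(-rate * branch length)` (uniform base exchange); a stem
#' substitution is accompanied by the complement-restoring partner change
#' with probability `compensatory_prob` (instantaneous compensation).
#' Deletion events excise the pre-miRNA but keep the flanks; duplication
#' events copy the locus, which then evolves independently; shift events
#' move the mature start by `offset` in all descendants. Uses the current
#' RNG state.
#'
#' @param anc Output of [make_ancestral_hairpin()].
#' @param params A [sim_params()].
#' @param family Family index (events are matched against it).
#' @param family_id Label used in locus/record ids.
#' @return List of per-tip locus records (see source) plus the event log.
#' @export
evolve_along_tree <- function(anc, params, family = 1L,
                              family_id = sprintf("fam%02d", family)) {
  tree <- ape::read.tree(text = params$tree)
  tree <- ape::reorder.phylo(tree, "cladewise")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  ev_for <- function(events) {
    keep <- Filter(function(e) e$family == family, events)
    vapply(keep, function(e) .find_event_edge(tree, e$clade), integer(1))
  }
  del_edges <- ev_for(params$deletions)
  dup_edges <- ev_for(params$duplications)
  shift_ev <- Filter(function(e) e$family == family, params$shifts)
  shift_edges <- vapply(shift_ev, function(e) .find_event_edge(tree, e$clade),
                        integer(1))
  shift_offsets <- vapply(shift_ev, function(e) as.integer(e$offset),
                          integer(1))

  root_locus <- list(id = family_id, window = strsplit(anc$window, "")[[1]],
                     deleted = FALSE, mature_start = anc$mature_start)
  states <- vector("list", ntip + tree$Nnode)
  states[[root]] <- list(root_locus)
  log <- list()

  for (e in seq_len(nrow(tree$edge))) {
    parent <- tree$edge[e, 1]
    child <- tree$edge[e, 2]
    bl <- tree$edge.length[e]
    loci <- states[[parent]]
    out <- list()
    for (lc in loci) {
      reg <- .region_map(anc, lc$mature_start)
      win <- .mutate(lc$window, reg, anc$pairing, params$rates,
                     params$compensatory_prob, bl)
      lc$window <- win
      out[[length(out) + 1L]] <- lc
    }
    if (e %in% dup_edges) {
      dup <- out[[1]]
      dup$id <- paste0(family_id, "-dup")
      out[[length(out) + 1L]] <- dup
      log[[length(log) + 1L]] <- list(event = "duplication", edge = e)
    }
    if (e %in% del_edges) {
      out[[1]]$deleted <- TRUE
      log[[length(log) + 1L]] <- list(event = "deletion", edge = e)
    }
    for (k in which(shift_edges == e)) {
      for (li in seq_along(out)) {
        out[[li]]$mature_start <- out[[li]]$mature_start + shift_offsets[k]
      }
      log[[length(log) + 1L]] <- list(event = "shift", edge = e,
                                      offset = shift_offsets[k])
    }
    states[[child]] <- out
  }

  ex_fl <- min(20L, anc$flank_len)
  tips <- list()
  for (t in seq_len(ntip)) {
    sp <- tree$tip.label[t]
    for (lc in states[[t]]) {
      win <- lc$window
      if (lc$deleted) {
        seqs <- paste(win[-seq(anc$pre_start + 1L, anc$pre_end)],
                      collapse = "")
        tips[[length(tips) + 1L]] <- list(
          locus = lc$id, species = sp, deleted = TRUE, window = seqs)
        next
      }
      hstart <- anc$pre_start - ex_fl
      hend <- anc$pre_end + ex_fl
      hp <- paste(win[seq(hstart + 1L, hend)], collapse = "")
      ms <- lc$mature_start
      tips[[length(tips) + 1L]] <- list(
        locus = lc$id, species = sp, deleted = FALSE,
        window = paste(win, collapse = ""),
        hairpin = hp,
        hairpin_start = hstart,
        mature = paste(win[seq(ms + 1L, ms + anc$mature_len)],
                       collapse = ""),
        star = paste(win[seq(anc$star_start + 1L, anc$star_end)],
                     collapse = ""),
        mature_start_in_hairpin = ms - hstart,
        shift = ms - anc$mature_start)
    }
  }
  list(family = family_id, ancestor = anc, tips = tips, events = log)
}

#' Simulate a full study bundle with known ground truth
#'
#' Generates `n_families` independent hairpin loci and evolves each along
#' the tree. Family ancestors are rejection-sampled so that no two
#' ancestral matures share a local alignment score of 6 or more
#' (cross-family identity stays far below the homolog-clustering filter
#' by construction, while within-family identity stays high), giving
#' unambiguous family ground truth.
#'
#' @param params A [sim_params()].
#' @return `mir_sim` object: `params`, `species`, `families` (per-family
#'   output of [evolve_along_tree()]), `matures` (record table with
#'   simulated scores/read depths), `truth` (family membership, variant,
#'   presence and shift tables).
#' @export
simulate_study <- function(params = sim_params()) {
  set.seed(params$seed)
  tree <- ape::read.tree(text = params$tree)
  species <- tree$tip.label
  scoring <- align_scoring()

  max_sc <- params$ancestor_max_score %||% 7
  filt <- match_filter(0.70, 18L)
  # direction-free: traceback tie-breaks can give the two orders different
  # optimal alignments, so a pair clashes if either direction passes
  passes_filter <- function(a, b) {
    one <- function(x, y) {
      r <- local_align(x, y, scoring)
      !r$empty && r$identity >= filt$min_identity &&
        r$aligned_length >= filt$min_length
    }
    one(a, b) || one(b, a)
  }
  anc_matures <- character(0)
  accepted_matures <- character(0)
  families <- vector("list", params$n_families)
  for (f in seq_len(params$n_families)) {
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > 2000L) {
        stop("could not draw a sufficiently separated family ", f,
             "; relax ancestor_max_score/enforce_separation or lower ",
             "n_families")
      }
      anc <- make_ancestral_hairpin(params$stem_len, params$loop_len,
                                    params$mature_len, params$flank_len)
      mat <- substr(anc$window, anc$mature_start + 1, anc$mature_end)
      ok <- !length(anc_matures) || !is.finite(max_sc) ||
        all(vapply(anc_matures, function(x) {
          local_align(x, mat, scoring)$score <= max_sc
        }, logical(1)))
      if (!ok) next
      fam <- evolve_along_tree(anc, params, family = f)
      if (params$enforce_separation && length(accepted_matures)) {
        # separation is a property of the emitted data: no descendant mature
        # may pass the clustering filter against an earlier family
        mats <- vapply(Filter(function(tp) !tp$deleted, fam$tips),
                       `[[`, "", "mature")
        clash <- any(vapply(mats, function(a) {
          any(vapply(accepted_matures, function(b) passes_filter(a, b),
                     logical(1)))
        }, logical(1)))
        if (clash) next
      }
      break
    }
    anc_matures <- c(anc_matures, mat)
    if (params$enforce_separation) {
      accepted_matures <- c(
        accepted_matures,
        vapply(Filter(function(tp) !tp$deleted, fam$tips), `[[`, "",
               "mature"))
    }
    families[[f]] <- fam
  }

  matures <- list()
  truth_fam <- list()
  for (fam in families) {
    for (tp in fam$tips) {
      if (tp$deleted) next
      id <- paste0(tp$locus, "|", tp$species)
      matures[[length(matures) + 1L]] <- data.frame(
        id = id, species = tp$species, sequence = tp$mature,
        read_depth = 3L + rpois(1, 47),
        score = round(runif(1, 0, 10), 2),
        family = fam$family, locus = tp$locus, stringsAsFactors = FALSE)
      truth_fam[[length(truth_fam) + 1L]] <- data.frame(
        id = id, family = fam$family, locus = tp$locus,
        species = tp$species, stringsAsFactors = FALSE)
    }
  }
  matures <- do.call(rbind, matures)
  truth_fam <- do.call(rbind, truth_fam)

  truth_variants <- .truth_variants(families)
  truth_presence <- .truth_presence(families, species)
  truth_shifts <- .truth_shifts(families)

  structure(list(params = params, species = species, families = families,
                 matures = matures,
                 truth = list(families = truth_fam,
                              variants = truth_variants,
                              presence = truth_presence,
                              shifts = truth_shifts)),
            class = "mir_sim")
}

# majority-base tally over the true (unaligned) matures of each locus:
# the direct-count ground truth the alignment-based caller must recover
.truth_variants <- function(families) {
  rows <- list()
  for (fam in families) {
    by_locus <- split(fam$tips, vapply(fam$tips, `[[`, "", "locus"))
    for (locus in names(by_locus)) {
      tps <- Filter(function(tp) !tp$deleted, by_locus[[locus]])
      if (length(tps) < 2) next
      mats <- vapply(tps, `[[`, "", "mature")
      names(mats) <- vapply(tps, `[[`, "", "species")
      m <- do.call(rbind, strsplit(mats, ""))
      rownames(m) <- names(mats)
      for (pos in seq_len(ncol(m))) {
        tab <- sort(table(m[, pos]), decreasing = TRUE)
        if (length(tab) == 1) next
        top <- names(tab)[tab == max(tab)]
        ref <- sort(top)[1]
        for (alt in sort(setdiff(names(tab), ref))) {
          sp <- sort(rownames(m)[m[, pos] == alt])
          rows[[length(rows) + 1L]] <- data.frame(
            mirna = locus, position = pos, ref = ref, alt = alt,
            species = paste(sp, collapse = ","), n_species = length(sp),
            region = assign_region(pos), stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(mirna = character(), position = integer(),
                      ref = character(), alt = character(),
                      species = character(), n_species = integer(),
                      region = character(), stringsAsFactors = FALSE)
  }
  out
}

.truth_presence <- function(families, species) {
  rows <- list()
  for (fam in families) {
    for (tp in fam$tips) {
      rows[[length(rows) + 1L]] <- data.frame(
        locus = tp$locus, species = tp$species,
        status = if (tp$deleted) "absent_flanks_conserved" else "present",
        stringsAsFactors = FALSE)
    }
    # species entirely lacking a duplicated locus carry no row: at zero
    # divergence a fresh duplicate is indistinguishable from its parent
  }
  do.call(rbind, rows)
}

.truth_shifts <- function(families) {
  rows <- list()
  for (fam in families) {
    for (tp in fam$tips) {
      if (tp$deleted) next
      rows[[length(rows) + 1L]] <- data.frame(
        locus = tp$locus, species = tp$species, shift = tp$shift,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a simulated study bundle to disk
#'
#' Emits the exact formats the pipeline consumes: a mature FASTA, a
#' prediction TSV (id, species, score, depth, mature, star, hairpin),
#' one multi-contig genome FASTA per species (one contig per locus;
#' deleted loci keep their flanks), the species tree, and the ground
#' truth tables. Returns a manifest of files with MD5 checksums.
#'
#' @param sim A `mir_sim` from [simulate_study()].
#' @param out_dir Output directory (created if needed).
#' @return data.frame manifest (invisibly): `file`, `md5`.
#' @export
write_study_bundle <- function(sim, out_dir) {
  stopifnot(inherits(sim, "mir_sim"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  wf <- function(name) file.path(out_dir, name)

  mat <- sim$matures
  if (is.null(mat)) {
    mat <- data.frame(id = character(), species = character(),
                      sequence = character(), read_depth = integer(),
                      score = numeric(), family = character(),
                      locus = character(), stringsAsFactors = FALSE)
  }
  if (nrow(mat)) {
    write_fasta(setNames(mat$sequence, mat$id), wf("matures.fasta"))
  } else {
    writeLines(character(0), wf("matures.fasta"))
  }

  pred <- list()
  for (fam in sim$families) {
    for (tp in fam$tips) {
      if (tp$deleted) next
      pred[[length(pred) + 1L]] <- data.frame(
        id = paste0(tp$locus, "|", tp$species), species = tp$species,
        score = mat$score[match(paste0(tp$locus, "|", tp$species), mat$id)],
        depth = mat$read_depth[match(paste0(tp$locus, "|", tp$species),
                                     mat$id)],
        mature = tp$mature, star = tp$star, hairpin = tp$hairpin,
        stringsAsFactors = FALSE)
    }
  }
  pred <- if (length(pred)) do.call(rbind, pred) else
    data.frame(id = character(), species = character(), score = numeric(),
               depth = integer(), mature = character(), star = character(),
               hairpin = character(), stringsAsFactors = FALSE)
  write.table(pred, wf("predictions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  for (sp in sim$species) {
    contigs <- character(0)
    for (fam in sim$families) {
      for (tp in fam$tips) {
        if (tp$species == sp) contigs[tp$locus] <- tp$window
      }
    }
    fn <- wf(paste0("genome_", sp, ".fasta"))
    if (length(contigs)) write_fasta(contigs, fn) else
      writeLines(character(0), fn)
  }

  writeLines(sim$params$tree, wf("tree.nwk"))
  tw <- function(d, name) {
    write.table(d, wf(name), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tw(sim$truth$families %||% data.frame(), "truth_families.tsv")
  tw(sim$truth$variants, "truth_variants.tsv")
  tw(sim$truth$presence %||% data.frame(), "truth_presence.tsv")
  tw(sim$truth$shifts %||% data.frame(), "truth_shifts.tsv")

  files <- sort(list.files(out_dir, full.names = FALSE))
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE)
  tw(manifest, "manifest.tsv")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
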