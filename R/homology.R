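#' Identity/length filter for homology matches
#'
#' The operative thresholds for homolog detection between ~22 nt mature
#' sequences: at least `min_identity` over at least `min_length` aligned
#' columns. Defaults 0.70 / 18 for homolog clustering; 1.0 / 18 is the
#' conservative setting used when confirming predicted miRNAs.
#'
#' @export
match_filter <- function(min_identity = 0.70, min_length = 18L) {
  stopifnot(min_identity > 0, min_identity <= 1, min_length >= 1)
  structure(list(min_identity = min_identity,
                 min_length = as.integer(min_length)),
            class = "match_filter")
}

#' Construct a table of mature miRNA records
#'
#' @param id,species,sequence,read_depth Parallel vectors.
#' @export
mature_records <- function(id, species, sequence, read_depth = 0L) {
  sequence <- gsub("U", "T", toupper(sequence), fixed = TRUE)
  stopifnot(length(id) == length(species), length(id) == length(sequence),
            all(nzchar(sequence)), all(read_depth >= 0),
            !any(grepl("[^ACGTN]", sequence)))
  if (anyDuplicated(id)) stop("mature record ids must be unique")
  data.frame(id = as.character(id), species = as.character(species),
             sequence = sequence,
             read_depth = as.integer(rep_len(read_depth, length(id))),
             stringsAsFactors = FALSE)
}

#' All-versus-all matching of mature sequences
#'
#' Every unordered pair is locally aligned; pairs passing the
#' identity/length filter are retained. Self-hits are excluded and each
#' retained pair appears exactly once (the relation is symmetric because
#' the optimal local alignment score and identity are direction-free).
#'
#' @param matures A [mature_records()] data.frame.
#' @param filter A [match_filter()].
#' @param scoring An [align_scoring()].
#' @return data.frame of undirected retained matches.
#' @export
all_vs_all <- function(matures, filter = match_filter(),
                       scoring = align_scoring()) {
  n <- nrow(matures)
  out <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        r <- local_align(matures$sequence[i], matures$sequence[j], scoring)
        if (!r$empty && r$identity >= filter$min_identity &&
            r$aligned_length >= filter$min_length) {
          out[[length(out) + 1L]] <- data.frame(
            query = matures$id[i], subject = matures$id[j],
            identity = r$identity, aligned_length = r$aligned_length,
            score = r$score,
            q_start = r$query_span[1], q_end = r$query_span[2],
            t_start = r$subject_span[1], t_end = r$subject_span[2],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(query = character(), subject = character(),
                      identity = numeric(), aligned_length = integer(),
                      score = numeric(), q_start = integer(),
                      q_end = integer(), t_start = integer(),
                      t_end = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Single-linkage clustering of matches into homology groups
#'
#' Groups are the connected components of the undirected match graph: a
#' sequence joins a group if it matches at least one member. Sequences
#' with no retained match are reported as singletons (no known homologs
#' within the dataset). Group ids are assigned deterministically from the
#' lexicographically smallest member id.
#'
#' @param matches Output of [all_vs_all()].
#' @param ids All sequence ids under consideration (members + singletons).
#' @return List with `groups` (named list of member-id vectors),
#'   `singletons`, and `membership` (named vector id -> group id).
#' @export
cluster_homologs <- function(matches, ids) {
  stopifnot(!anyDuplicated(ids))
  ids <- as.character(ids)
  if (nrow(matches) == 0) {
    return(list(groups = setNames(list(), character(0)),
                singletons = sort(ids),
                membership = setNames(rep(NA_character_, length(ids)), ids)))
  }
  g <- igraph::graph_from_data_frame(
    matches[, c("query", "subject")], directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  membership <- setNames(rep(NA_character_, length(ids)), ids)
  groups <- list()
  for (k in seq_len(comp$no)) {
    members <- sort(names(comp$membership)[comp$membership == k])
    if (length(members) == 1) next
    gid <- paste0("HG:", members[1])
    groups[[gid]] <- members
    membership[members] <- gid
  }
  groups <- groups[order(names(groups))]
  list(groups = groups,
       singletons = sort(ids[is.na(membership)]),
       membership = membership)
}

#' Subdivide a homology group into ortholog groups
#'
#' Within a homology group (which may mix paralogs), connected components
#' at a higher identity threshold separate individual miRNAs. If a species
#' contributes more than one sequence to a component, the one with the
#' highest mean identity to the rest of the component is kept (ties broken
#' by higher read depth, then lexicographic id). Components with fewer
#' than three species are dropped. Kept members are aligned with
#' [align_msa()].
#'
#' The default threshold 0.85 replaces manual inspection of alignments
#' and trees with a reproducible criterion; it is deliberately exposed.
#'
#' @param members [mature_records()] rows belonging to one homology group.
#' @param group_id Id of the parent homology group.
#' @param high_identity Identity threshold for subdivision (default 0.85).
#' @param scoring An [align_scoring()].
#' @return List of ortholog groups: each has `id`, `members` (records),
#'   `alignment` (gapped, named by species).
#' @export
subdivide_orthologs <- function(members, group_id = "HG",
                                high_identity = 0.85,
                                scoring = align_scoring()) {
  n <- nrow(members)
  if (n < 3) return(list())
  # full-length (global) identity: local end-trimming would inflate the
  # identity of diverged paralog pairs and defeat the subdivision threshold
  idm <- matrix(1, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      r <- global_align(members$sequence[i], members$sequence[j], scoring)
      idm[i, j] <- idm[j, i] <- r$identity
    }
  }
  adj <- idm >= high_identity
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  out <- list()
  for (k in sort(unique(comp))) {
    idx <- which(comp == k)
    sp <- members$species[idx]
    if (length(unique(sp)) < 3) next
    keep <- integer(0)
    for (s in unique(sp)) {
      cand <- idx[sp == s]
      if (length(cand) == 1) { keep <- c(keep, cand); next }
      mean_id <- vapply(cand, function(i) {
        others <- setdiff(idx, i)
        mean(idm[i, others])
      }, numeric(1))
      ord <- order(-mean_id, -members$read_depth[cand], members$id[cand])
      keep <- c(keep, cand[ord[1]])
    }
    keep <- sort(keep)
    recs <- members[keep, , drop = FALSE]
    seqs <- setNames(recs$sequence, recs$species)
    aln <- align_msa(seqs, scoring)
    og <- list(id = NA_character_, parent = group_id, members = recs,
               alignment = aln)
    out[[length(out) + 1L]] <- og
  }
  # deterministic ids ordered by smallest member id
  if (length(out)) {
    first <- vapply(out, function(o) min(o$members$id), character(1))
    out <- out[order(first)]
    for (k in seq_along(out)) {
      out[[k]]$id <- paste0(group_id, ".", k)
      class(out[[k]]) <- "ortholog_group"
    }
  }
  out
}

#' Confirm homology-predicted miRNAs against validated matures
#'
#' A predicted miRNA is confirmed in a species when some validated mature
#' sequence from that species shares a perfect match of at least
#' `min_length` nt (100% identity, i.e. an exact common substring).
#' Paralogs with (near-)identical matures cannot be told apart, so each
#' family keeps a single best-scoring representative in the per-family
#' output; the per-prediction species count is also returned.
#'
#' @param validated data.frame with `id`, `species`, `sequence`.
#' @param predicted data.frame with `id`, `family`, `score`, `sequence`.
#' @param min_length Minimum exact-match length (default 18).
#' @return List with `predictions` (one row per predicted miRNA, species
#'   count and confirming species) and `families` (best-scoring confirmed
#'   representative per family).
#' @export
confirm_predictions <- function(validated, predicted, min_length = 18L) {
  norm <- function(x) gsub("U", "T", toupper(x), fixed = TRUE)
  validated$sequence <- norm(validated$sequence)
  predicted$sequence <- norm(predicted$sequence)
  kmers <- function(s, k) {
    if (nchar(s) < k) return(character(0))
    substring(s, seq_len(nchar(s) - k + 1), seq(k, nchar(s)))
  }
  by_species <- split(validated$sequence, validated$species)
  vk <- lapply(by_species, function(ss) {
    unique(unlist(lapply(ss, kmers, k = min_length), use.names = FALSE))
  })
  conf_species <- lapply(predicted$sequence, function(p) {
    pk <- kmers(p, min_length)
    if (!length(pk)) return(character(0))
    names(vk)[vapply(vk, function(set) any(pk %in% set), logical(1))]
  })
  preds <- data.frame(
    id = predicted$id, family = predicted$family, score = predicted$score,
    n_species = lengths(conf_species),
    species = vapply(conf_species, function(s) paste(sort(s), collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE)
  confirmed <- preds[preds$n_species > 0, , drop = FALSE]
  fam <- lapply(split(confirmed, confirmed$family), function(d) {
    d[order(-d$score, d$id)[1], , drop = FALSE]
  })
  families <- do.call(rbind, fam)
  if (is.null(families)) families <- preds[0, ]
  rownames(families) <- NULL
  list(predictions = preds, families = families)
}
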