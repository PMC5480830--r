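#' Paralog locus query
#'
#' A pre-miRNA plus up to 1000 nt of flanking sequence on each side,
#' used to anchor presence/absence calls: conserved flanks identify the
#' locus even when the element itself has been lost.
#'
#' @param id Paralog id.
#' @param window Window sequence (single string).
#' @param pre_start,pre_end 0-based half-open span of the pre-miRNA
#'   within the window.
#' @export
locus_query <- function(id, window, pre_start, pre_end) {
  .check_seq(window, "window")
  window <- gsub("U", "T", toupper(window), fixed = TRUE)
  stopifnot(pre_start >= 0, pre_end <= nchar(window), pre_start < pre_end)
  if (nchar(window) > (pre_end - pre_start) + 2000) {
    stop("window exceeds pre-miRNA plus 1000 nt flanks")
  }
  structure(list(id = id, window = window,
                 pre_start = as.integer(pre_start),
                 pre_end = as.integer(pre_end)),
            class = "locus_query")
}

.empty_matches <- function() {
  data.frame(contig = character(), q_start = integer(), q_end = integer(),
             t_start = integer(), t_end = integer(), score = numeric(),
             identity = numeric(), aligned_length = integer(),
             qaln = character(), taln = character(), stringsAsFactors = FALSE)
}

#' Scan a genome for matches to a locus query
#'
#' Blast-like multi-hit search: per contig, the best local alignment is
#' taken repeatedly with previously matched subject intervals masked, so
#' separate conserved segments (for example the two flanks around a
#' deleted pre-miRNA) surface as separate matches. Matches are then
#' filtered permissively at `min_identity` over `min_length` columns and
#' sorted by score.
#'
#' @param query A [locus_query()].
#' @param genome Named character vector of contig sequences.
#' @param min_identity,min_length Match filter (defaults 0.70 / 300).
#' @param scoring An [align_scoring()].
#' @param min_score Raw-score floor that stops the iterative search.
#' @param max_matches Per-contig cap on collected matches.
#' @param seed_k Word size of the seeding prefilter: contigs sharing no
#'   exact `seed_k`-mer with the query are skipped without alignment (a
#'   300 nt match at 70% identity shares a conserved 12-mer except with
#'   negligible probability). Set `seed_k = 0` to disable.
#' @return data.frame of matches (0-based half-open spans; `q_*` on the
#'   query window, `t_*` on the contig) with aligned strings.
#' @export
scan_genome <- function(query, genome, min_identity = 0.70,
                        min_length = 300L, scoring = align_scoring(),
                        min_score = 25, max_matches = 50L, seed_k = 12L) {
  stopifnot(inherits(query, "locus_query"), is.character(genome),
            !is.null(names(genome)))
  kmers <- function(s, k) {
    if (nchar(s) < k) return(character(0))
    unique(substring(s, seq_len(nchar(s) - k + 1), seq(k, nchar(s))))
  }
  qk <- if (seed_k > 0) kmers(query$window, seed_k) else character(0)
  rows <- list()
  for (ct in names(genome)) {
    target <- gsub("U", "T", toupper(genome[[ct]]), fixed = TRUE)
    if (seed_k > 0 && nchar(target) >= seed_k &&
        !any(kmers(target, seed_k) %in% qk)) next
    hits <- cpp_scan(query$window, target, scoring$match, scoring$mismatch,
                     -scoring$gap_open, -scoring$gap_extend,
                     min_score, as.integer(max_matches))
    for (h in hits) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = ct, q_start = h$q_start, q_end = h$q_end,
        t_start = h$t_start, t_end = h$t_end, score = h$score,
        identity = .aln_identity(h$qaln, h$taln),
        aligned_length = nchar(h$qaln),
        qaln = h$qaln, taln = h$taln, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.empty_matches())
  m <- do.call(rbind, rows)
  m <- m[m$identity >= min_identity & m$aligned_length >= min_length, ,
         drop = FALSE]
  m <- m[order(-m$score, m$contig, m$t_start), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Drop matches driven by repetitive query regions
#'
#' Query positions covered by more than `max_hits` matches are treated as
#' repetitive elements; matches with more than half of their query span
#' inside masked positions are removed.
#'
#' @param matches Output of [scan_genome()] (possibly pooled over
#'   genomes).
#' @param query_len Length of the query window.
#' @param max_hits Coverage threshold (default 100).
#' @return Filtered matches, with the masked positions as attribute
#'   `masked`.
#' @export
filter_repetitive <- function(matches, query_len, max_hits = 100L) {
  if (nrow(matches) == 0) return(matches)
  cov <- integer(query_len)
  for (k in seq_len(nrow(matches))) {
    span <- (matches$q_start[k] + 1L):matches$q_end[k]
    cov[span] <- cov[span] + 1L
  }
  masked <- cov > max_hits
  drop <- vapply(seq_len(nrow(matches)), function(k) {
    span <- (matches$q_start[k] + 1L):matches$q_end[k]
    mean(masked[span]) > 0.5
  }, logical(1))
  out <- matches[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "masked") <- which(masked)
  out
}

# identity of the alignment restricted to query positions in [from, to),
# plus the fraction of those positions covered by the alignment
.pre_region_identity <- function(h, from, to) {
  q <- strsplit(h$qaln, "")[[1]]
  t <- strsplit(h$taln, "")[[1]]
  qpos <- h$q_start # 0-based position of the NEXT query char
  inside <- logical(length(q))
  for (col in seq_along(q)) {
    if (q[col] != "-") {
      inside[col] <- qpos >= from && qpos < to
      qpos <- qpos + 1L
    }
  }
  n_inside <- sum(inside)
  if (n_inside == 0) return(list(identity = 0, coverage = 0))
  list(identity = sum(q[inside] == t[inside]) / n_inside,
       coverage = n_inside / (to - from))
}

#' Classify a paralog locus as present, absent with conserved flanks, or
#' not found
#'
#' The highest-scoring match whose alignment actually covers the
#' pre-miRNA span of the query (identity over the pre-miRNA columns at
#' least `rescue_identity` across at least `rescue_coverage` of the
#' pre-miRNA) is called `present`. Otherwise, if flank matches exist, the
#' hypothetical location of the pre-miRNA (100 nt upstream to 200 nt
#' downstream of its expected start) is extracted from the target and
#' aligned to the pre-miRNA: a passing alignment rescues a `present`
#' call, a failing one yields `absent_flanks_conserved`. No matches at
#' all is `not_found`.
#'
#' A long-gap local alignment can bridge a deleted pre-miRNA on flank
#' similarity alone, which is why span overlap by itself is not treated
#' as presence.
#'
#' @param query A [locus_query()].
#' @param matches Matches from [scan_genome()] (after
#'   [filter_repetitive()]), all against one target genome.
#' @param genome The target genome (named contigs); needed for the
#'   hypothetical-location extraction.
#' @param species Label for the target genome.
#' @param hyp_window Upstream/downstream extent of the hypothetical
#'   location (default 100 / 200).
#' @param rescue_identity Identity threshold (default 0.70).
#' @param rescue_coverage Minimum fraction of the pre-miRNA that must be
#'   aligned (default 0.60).
#' @param scoring An [align_scoring()].
#' @return One-row data.frame: `species`, `paralog`, `status`, best-match
#'   coordinates and identity, `note`.
#' @export
call_presence <- function(query, matches, genome, species = NA_character_,
                          hyp_window = c(100L, 200L),
                          rescue_identity = 0.70, rescue_coverage = 0.60,
                          scoring = align_scoring()) {
  stopifnot(inherits(query, "locus_query"))
  res <- function(status, contig = NA_character_, t_start = NA_integer_,
                  t_end = NA_integer_, identity = NA_real_,
                  aligned_length = NA_integer_, note = "") {
    data.frame(species = species, paralog = query$id, status = status,
               contig = contig, t_start = t_start, t_end = t_end,
               identity = identity, aligned_length = aligned_length,
               note = note, stringsAsFactors = FALSE)
  }
  if (nrow(matches) == 0) return(res("not_found", note = "no matches"))
  matches <- matches[order(-matches$score, matches$contig, matches$t_start), ,
                     drop = FALSE]
  overlapping <- matches$q_start < query$pre_end &
    matches$q_end > query$pre_start
  pre_len <- query$pre_end - query$pre_start
  if (any(overlapping)) {
    h <- matches[which(overlapping)[1], ]
    pri <- .pre_region_identity(h, query$pre_start, query$pre_end)
    if (pri$identity >= rescue_identity && pri$coverage >= rescue_coverage) {
      return(res("present", h$contig, h$t_start, h$t_end, h$identity,
                 h$aligned_length, "pre-miRNA covered by best match"))
    }
  }
  # flank evidence only: extract the hypothetical location and look for
  # the pre-miRNA there
  h <- matches[1, ]
  est_start <- h$t_start + (query$pre_start - h$q_start)
  contig_seq <- gsub("U", "T", toupper(genome[[h$contig]]), fixed = TRUE)
  lo <- max(0L, est_start - hyp_window[1])
  hi <- min(nchar(contig_seq), est_start + hyp_window[2])
  if (hi <= lo) {
    return(res("absent_flanks_conserved", h$contig, h$t_start, h$t_end,
               h$identity, h$aligned_length,
               "hypothetical location outside contig"))
  }
  hyp <- substr(contig_seq, lo + 1, hi)
  pre <- substr(query$window, query$pre_start + 1, query$pre_end)
  r <- local_align(pre, hyp, scoring)
  if (!r$empty && r$identity >= rescue_identity &&
      r$aligned_length >= rescue_coverage * pre_len) {
    return(res("present", h$contig, lo + r$subject_span[1],
               lo + r$subject_span[2], r$identity, r$aligned_length,
               "rescued at hypothetical location"))
  }
  res("absent_flanks_conserved", h$contig, h$t_start, h$t_end, h$identity,
      h$aligned_length, "flank match without pre-miRNA")
}
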