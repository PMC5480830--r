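#' Alignment scoring scheme
#'
#' Defaults: match +1, mismatch -1, gap open -2, gap extend -1. A gap of
#' length L costs `gap_open + L * gap_extend`.
#'
#' @export
align_scoring <- function(match = 1, mismatch = -1, gap_open = -2,
                          gap_extend = -1) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "align_scoring")
}

.check_seq <- function(x, arg = "sequence") {
  if (!is.character(x) || length(x) != 1 || !nzchar(x)) {
    stop(arg, " must be a single non-empty string")
  }
  x
}

# identity over aligned columns: gap columns count as mismatch
.aln_identity <- function(qaln, taln) {
  if (!nzchar(qaln)) return(0)
  q <- strsplit(qaln, "")[[1]]
  t <- strsplit(taln, "")[[1]]
  sum(q == t & q != "-") / length(q)
}

.wrap_match <- function(r, query, subject) {
  len <- nchar(r$qaln)
  structure(list(
    query = query, subject = subject, score = r$score,
    identity = .aln_identity(r$qaln, r$taln), aligned_length = len,
    query_span = c(r$q_start, r$q_end), subject_span = c(r$t_start, r$t_end),
    qaln = r$qaln, taln = r$taln, empty = isTRUE(r$empty)),
    class = "match_result")
}

#' Optimal local (Smith-Waterman) alignment
#'
#' Affine-gap local alignment with deterministic traceback (at ties,
#' diagonal over up over left; the longer of two equal-scoring paths, i.e.
#' the smaller start coordinate, is preferred). Identity is computed as
#' matched columns divided by all aligned columns, gap columns counting as
#' mismatches -- the stricter of the common conventions.
#'
#' @param a,b Sequences (single strings over A/C/G/T/N).
#' @param scoring An [align_scoring()].
#' @return A `match_result`: score, identity, aligned_length, 0-based
#'   half-open `query_span` / `subject_span`, and the aligned strings.
#' @export
local_align <- function(a, b, scoring = align_scoring()) {
  .check_seq(a, "a"); .check_seq(b, "b")
  r <- cpp_align(a, b, "local", scoring$match, scoring$mismatch,
                 -scoring$gap_open, -scoring$gap_extend)
  .wrap_match(r, a, b)
}

#' Global (Needleman-Wunsch) alignment with affine gaps
#'
#' End gaps are penalized; used for the near-identical sequences of an
#' ortholog group where terminal extensions should surface as terminal
#' gap columns.
#'
#' @inheritParams local_align
#' @export
global_align <- function(a, b, scoring = align_scoring()) {
  .check_seq(a, "a"); .check_seq(b, "b")
  r <- cpp_align(a, b, "global", scoring$match, scoring$mismatch,
                 -scoring$gap_open, -scoring$gap_extend)
  .wrap_match(r, a, b)
}

#' Anchored multiple alignment of near-identical sequences
#'
#' Center-star progressive alignment: the sequence with the highest mean
#' pairwise identity is the anchor; every other sequence is globally
#' aligned to it and the pairwise alignments are merged column-wise
#' ("once a gap, always a gap" relative to the anchor). For the
#' near-identical inputs typical of mature miRNAs and pre-miRNA hairpins
#' this reproduces the exhaustive global alignment; columns without gaps
#' map 1:1 to anchor positions. Deterministic: ties in anchor choice go to
#' the lexicographically smallest name, insertions are right-aligned
#' against the following anchor column.
#'
#' @param seqs Named character vector (>= 1 sequences).
#' @param scoring An [align_scoring()].
#' @return Named character vector of gapped rows, all the same width.
#' @export
align_msa <- function(seqs, scoring = align_scoring()) {
  stopifnot(is.character(seqs), length(seqs) >= 1, !is.null(names(seqs)))
  if (anyDuplicated(names(seqs))) stop("sequence names must be unique")
  n <- length(seqs)
  if (n == 1) return(seqs)
  if (n == 2) {
    r <- global_align(seqs[[1]], seqs[[2]], scoring)
    out <- c(r$qaln, r$taln)
    names(out) <- names(seqs)
    return(out)
  }
  idm <- matrix(1, n, n, dimnames = list(names(seqs), names(seqs)))
  alns <- vector("list", n * n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      r <- global_align(seqs[[i]], seqs[[j]], scoring)
      idm[i, j] <- idm[j, i] <- r$identity
      alns[[(i - 1) * n + j]] <- r
    }
  }
  mean_id <- rowMeans(idm) - 1 / n # exclude the self term
  center <- order(-mean_id, names(seqs))[1]

  L <- nchar(seqs[[center]])
  # decompose each center-vs-other alignment into per-anchor-slot insertions
  decomp <- vector("list", n)
  for (j in seq_len(n)) {
    if (j == center) next
    i1 <- min(center, j); i2 <- max(center, j)
    r <- alns[[(i1 - 1) * n + i2]]
    caln <- if (center < j) r$qaln else r$taln
    saln <- if (center < j) r$taln else r$qaln
    cc <- strsplit(caln, "")[[1]]
    sc <- strsplit(saln, "")[[1]]
    ins <- vector("list", L + 1)   # insertions before anchor pos k (k = 1..L+1)
    main <- character(L)           # subject char aligned to anchor pos k
    k <- 0L
    buf <- character(0)
    for (col in seq_along(cc)) {
      if (cc[col] != "-") {
        k <- k + 1L
        ins[[k]] <- buf
        buf <- character(0)
        main[k] <- sc[col]
      } else {
        buf <- c(buf, sc[col])
      }
    }
    ins[[L + 1]] <- buf
    decomp[[j]] <- list(ins = ins, main = main)
  }
  ins_len <- integer(L + 1)
  for (j in seq_len(n)) {
    if (j == center) next
    ins_len <- pmax(ins_len, lengths(decomp[[j]]$ins))
  }
  cen_chars <- strsplit(seqs[[center]], "")[[1]]
  build_row <- function(main, ins) {
    parts <- character(0)
    for (k in seq_len(L)) {
      pad <- ins_len[k] - length(ins[[k]])
      parts <- c(parts, rep("-", pad), ins[[k]], main[k])
    }
    pad <- ins_len[L + 1] - length(ins[[L + 1]])
    parts <- c(parts, ins[[L + 1]], rep("-", pad))
    paste(parts, collapse = "")
  }
  out <- character(n)
  for (j in seq_len(n)) {
    if (j == center) {
      out[j] <- build_row(cen_chars, rep(list(character(0)), L + 1))
    } else {
      out[j] <- build_row(decomp[[j]]$main, decomp[[j]]$ins)
    }
  }
  names(out) <- names(seqs)
  out
}

# character matrix view of an alignment (rows = sequences)
.aln_matrix <- function(alignment) {
  stopifnot(is.character(alignment), length(alignment) >= 1)
  w <- unique(nchar(alignment))
  if (length(w) != 1) stop("ragged alignment: rows differ in width")
  m <- do.call(rbind, strsplit(alignment, ""))
  rownames(m) <- names(alignment)
  m
}
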