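#' Excise candidate hairpin windows around a read stack
#'
#' Mirrors the two-window excision used when screening read stacks for
#' pre-miRNAs: one window with 20 nt upstream and 70 nt downstream
#' flanking sequence, and one with 70 nt upstream and 20 nt downstream,
#' so that a genuine pre-miRNA is captured whichever hairpin arm carries
#' the mature reads. Windows are truncated (and flagged) at contig edges.
#'
#' @param genome_seq Contig sequence (single string).
#' @param stack_start,stack_end 0-based half-open span of the read stack.
#' @param flank_short,flank_long Flank sizes (defaults 20 and 70).
#' @return List of two windows, each with `start`, `end` (0-based
#'   half-open), `sequence`, `truncated`.
#' @export
excise_hairpin_window <- function(genome_seq, stack_start, stack_end,
                                  flank_short = 20L, flank_long = 70L) {
  .check_seq(genome_seq, "genome_seq")
  n <- nchar(genome_seq)
  stopifnot(stack_start >= 0, stack_end <= n, stack_start < stack_end)
  mk <- function(up, down) {
    s <- stack_start - up
    e <- stack_end + down
    truncated <- s < 0 || e > n
    s <- max(0L, s); e <- min(n, e)
    list(start = s, end = e,
         sequence = substr(genome_seq, s + 1, e),
         truncated = truncated)
  }
  list(mature_5p = mk(flank_short, flank_long),
       mature_3p = mk(flank_long, flank_short))
}

#' Detect mature-sequence register shifts within an ortholog group
#'
#' Structural changes in a hairpin can move the processing sites, shifting
#' the excised mature sequence -- and with it the seed -- by one or more
#' nucleotides in part of the clade. The hairpins are multiply aligned and
#' each species' mature start is mapped to an alignment column; the
#' per-species shift is the signed column offset from the modal start
#' column. Shifts are measured in column space, so upstream indels that do
#' not move the mature's aligned placement yield shift 0.
#'
#' @param hairpins data.frame with `species`, `sequence` (hairpin),
#'   `mature_start`, `mature_end` (0-based half-open within the hairpin).
#' @param scoring An [align_scoring()].
#' @return data.frame `species`, `start_col`, `shift`, with the modal
#'   column as attribute `modal_col`.
#' @export
detect_seed_shift <- function(hairpins, scoring = align_scoring()) {
  stopifnot(nrow(hairpins) >= 3)
  bad <- hairpins$mature_start < 0 |
    hairpins$mature_end > nchar(hairpins$sequence) |
    hairpins$mature_start >= hairpins$mature_end
  if (any(bad)) {
    stop("mature span outside hairpin for species: ",
         paste(hairpins$species[bad], collapse = ", "))
  }
  seqs <- setNames(hairpins$sequence, hairpins$species)
  aln <- align_msa(seqs, scoring)
  start_col <- integer(nrow(hairpins))
  for (k in seq_len(nrow(hairpins))) {
    row <- strsplit(aln[[hairpins$species[k]]], "")[[1]]
    nongap <- which(row != "-")
    start_col[k] <- nongap[hairpins$mature_start[k] + 1L]
  }
  tab <- table(start_col)
  modal <- as.integer(names(tab)[order(-tab, as.integer(names(tab)))[1]])
  out <- data.frame(species = hairpins$species, start_col = start_col,
                    shift = start_col - modal, stringsAsFactors = FALSE)
  attr(out, "modal_col") <- modal
  out
}
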