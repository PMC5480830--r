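#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and, with the default DNA alphabet, `U` is
#' converted to `T`. The internal alphabet of the whole package is DNA;
#' conversion happens only at I/O boundaries. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"DNA"` (default; U -> T), `"RNA"` (T -> U) or `"none"`
#'   (uppercase only).
#' @return Named character vector of sequences (names are full headers).
#' @export
read_fasta <- function(path, alphabet = c("DNA", "RNA", "none")) {
  alphabet <- match.arg(alphabet)
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  if (length(seqs) && any(!nzchar(seqs))) {
    bad <- names(seqs)[!nzchar(seqs)][1]
    stop("empty sequence for record '", bad, "' in ", path)
  }
  if (alphabet == "DNA") seqs <- gsub("U", "T", seqs, fixed = TRUE)
  if (alphabet == "RNA") seqs <- gsub("T", "U", seqs, fixed = TRUE)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line width (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Prediction-table filter
#'
#' Score and read-depth thresholds applied when ingesting a hairpin
#' prediction table. The defaults (score cut-off 0, minimum read depth 3)
#' are the relaxed inclusion criteria appropriate for species with little
#' or no prior miRNA annotation, where prediction scores run systematically
#' low; downstream clustering and alignment remove residual false positives.
#'
#' @param min_score Minimum prediction score (default 0).
#' @param min_depth Minimum read depth (default 3).
#' @export
prediction_filter <- function(min_score = 0, min_depth = 3L) {
  stopifnot(min_depth >= 0)
  structure(list(min_score = min_score, min_depth = as.integer(min_depth)),
            class = "prediction_filter")
}

#' Parse a hairpin prediction table
#'
#' Reads a TSV with columns `id`, `species`, `score`, `depth`, `mature`,
#' `star`, `hairpin` (a miRDeep2-style excision product: the pre-miRNA
#' hairpin plus ~20 nt of flanking sequence). Rows failing the filter are
#' dropped; mature and star segments are located within the hairpin by
#' exact substring search, taking the leftmost occurrence (with a warning
#' if a segment occurs more than once). Rows whose mature or star is not a
#' substring of the hairpin are skipped with a warning naming the record.
#'
#' All spans are 0-based half-open coordinates into the hairpin sequence.
#'
#' @param path Path to the TSV (header row required).
#' @param filter A [prediction_filter()].
#' @return data.frame of hairpin records with located spans.
#' @export
parse_prediction_table <- function(path, filter = prediction_filter()) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "species", "score", "depth", "mature", "star", "hairpin")
  if (!all(need %in% names(tab))) {
    stop("prediction table must have columns: ", paste(need, collapse = ", "))
  }
  empty <- data.frame(id = character(), species = character(),
                      score = numeric(), read_depth = integer(),
                      sequence = character(), mature = character(),
                      star = character(),
                      mature_start = integer(), mature_end = integer(),
                      star_start = integer(), star_end = integer(),
                      loop_start = integer(), loop_end = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(tab) == 0) return(empty)
  tab <- tab[tab$score >= filter$min_score & tab$depth >= filter$min_depth, ,
             drop = FALSE]
  norm <- function(x) gsub("U", "T", toupper(x), fixed = TRUE)
  tab$mature <- norm(tab$mature)
  tab$star <- norm(tab$star)
  tab$hairpin <- norm(tab$hairpin)

  locate <- function(needle, hay, id, what) {
    hits <- gregexpr(needle, hay, fixed = TRUE)[[1]]
    if (hits[1] == -1) return(NULL)
    if (length(hits) > 1) {
      warning(what, " of record '", id,
              "' occurs ", length(hits),
              " times in hairpin; using leftmost occurrence")
    }
    c(start = hits[1] - 1L, end = hits[1] - 1L + nchar(needle))
  }

  out <- vector("list", nrow(tab))
  for (k in seq_len(nrow(tab))) {
    row <- tab[k, ]
    m <- locate(row$mature, row$hairpin, row$id, "mature")
    s <- locate(row$star, row$hairpin, row$id, "star")
    if (is.null(m) || is.null(s)) {
      warning("record '", row$id, "': ",
              if (is.null(m)) "mature" else "star",
              " not found in hairpin; row skipped")
      next
    }
    lo <- c(start = min(m["end"], s["end"]), end = max(m["start"], s["start"]))
    out[[k]] <- data.frame(
      id = row$id, species = row$species, score = row$score,
      read_depth = as.integer(row$depth), sequence = row$hairpin,
      mature = row$mature, star = row$star,
      mature_start = unname(m["start"]), mature_end = unname(m["end"]),
      star_start = unname(s["start"]), star_end = unname(s["end"]),
      loop_start = unname(lo["start"]), loop_end = unname(lo["end"]),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) return(empty)
  rownames(res) <- NULL
  res
}

#' Functional regions of a mature miRNA
#'
#' Positions are 1-based on the mature sequence: seed 1-8 (the primary
#' determinant of target recognition), central 9-12, 3' supplementary
#' 13-16 (secondary pairing region), tail 17 to the end.
#'
#' @param position Integer vector of 1-based mature positions.
#' @return Character vector of region labels.
#' @export
assign_region <- function(position) {
  stopifnot(all(position >= 1))
  cut(position, breaks = c(0, 8, 12, 16, Inf),
      labels = c("seed", "central", "supplementary", "tail")) |>
    as.character()
}

#' Region scheme boundaries
#' @return Named list of 1-based inclusive position ranges.
#' @export
region_scheme <- function() {
  list(seed = c(1L, 8L), central = c(9L, 12L),
       supplementary = c(13L, 16L), tail = c(17L, NA_integer_))
}

#' Primate clade map used by the simulator and pipeline
#'
#' Thirteen-taxon study design: six apes, two Old World monkeys, two New
#' World monkeys, three Strepsirrhines.
#'
#' @return Named character vector mapping species to lineage.
#' @export
primate_clades <- function() {
  c(human = "ape", chimpanzee = "ape", bonobo = "ape", gorilla = "ape",
    orangutan = "ape", gibbon = "ape",
    rhesus = "old_world_monkey", baboon = "old_world_monkey",
    marmoset = "new_world_monkey", squirrel_monkey = "new_world_monkey",
    mouse_lemur = "strepsirrhine", aye_aye = "strepsirrhine",
    galago = "strepsirrhine")
}

# clade map keyed by the free-text species names used in published variant
# tables ("mouse lemur", "aye-aye", ...)
.report_clades <- function() {
  c("human" = "ape", "chimpanzee" = "ape", "bonobo" = "ape",
    "gorilla" = "ape", "orangutan" = "ape", "gibbon" = "ape",
    "rhesus macaque" = "old_world_monkey", "baboon" = "old_world_monkey",
    "marmoset" = "new_world_monkey", "squirrel monkey" = "new_world_monkey",
    "mouse lemur" = "strepsirrhine", "aye-aye" = "strepsirrhine",
    "galago" = "strepsirrhine")
}
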