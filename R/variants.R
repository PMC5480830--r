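#' Align the mature sequences of an ortholog group
#'
#' Anchored global multiple alignment of >= 3 mature sequences (18-26 nt).
#' For the near-identical inputs typical of mature miRNAs the result is
#' gap-free and columns map 1:1 to mature positions.
#'
#' @param seqs Named character vector (names = species), >= 3 sequences.
#' @param scoring An [align_scoring()].
#' @return Named character vector of gapped rows.
#' @export
align_group_matures <- function(seqs, scoring = align_scoring()) {
  stopifnot(length(seqs) >= 3)
  if (any(nchar(seqs) < 18 | nchar(seqs) > 26)) {
    warning("mature sequence length outside the typical 18-26 nt range")
  }
  align_msa(seqs, scoring)
}

#' Call substitution variants in a mature alignment
#'
#' Per alignment column the reference base is the majority base among
#' non-gap rows (ties broken by the designated reference species' base if
#' present, else alphabetically); every minority base yields one variant
#' listing all species that carry it. Positions are 1-based on the
#' consensus mature sequence: columns where more than half the rows are
#' gaps are insertion columns and are excluded from position numbering.
#' Columns involving gaps are reported separately as indels, never as
#' substitutions. A column with more than two states emits multiple
#' variants (with a warning).
#'
#' @param alignment Named character vector of gapped rows (>= 3,
#'   names = species).
#' @param group_id Label for the miRNA ortholog group.
#' @param reference_species Optional species whose base breaks majority
#'   ties.
#' @return data.frame of variants (`mirna`, `position`, `ref`, `alt`,
#'   `species` comma-joined, `n_species`, `region`) with an `indels`
#'   data.frame attribute.
#' @export
call_variants <- function(alignment, group_id = "group",
                          reference_species = NULL) {
  m <- .aln_matrix(alignment)
  nr <- nrow(m)
  vars <- list()
  indels <- list()
  pos <- 0L
  for (col in seq_len(ncol(m))) {
    x <- m[, col]
    gap <- x == "-"
    if (any(gap)) {
      indels[[length(indels) + 1L]] <- data.frame(
        mirna = group_id, column = col,
        species = paste(sort(rownames(m)[gap]), collapse = ","),
        stringsAsFactors = FALSE)
    }
    if (sum(gap) > nr / 2) next # insertion column: not a mature position
    pos <- pos + 1L
    bases <- x[!gap]
    tab <- sort(table(bases), decreasing = TRUE)
    if (length(tab) == 1) next
    top <- names(tab)[tab == max(tab)]
    ref <- if (length(top) == 1) {
      top[1]
    } else if (!is.null(reference_species) &&
               reference_species %in% rownames(m) &&
               m[reference_species, col] %in% top) {
      m[reference_species, col]
    } else {
      sort(top)[1]
    }
    alts <- setdiff(names(tab), ref)
    if (length(alts) > 1) {
      warning("column ", col, " of ", group_id, " has ", length(alts) + 1,
              " states; emitting one variant per minority base")
    }
    for (alt in sort(alts)) {
      sp <- sort(names(bases)[bases == alt])
      vars[[length(vars) + 1L]] <- data.frame(
        mirna = group_id, position = pos, ref = ref, alt = alt,
        species = paste(sp, collapse = ","), n_species = length(sp),
        region = assign_region(pos), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, vars)
  if (is.null(out)) {
    out <- data.frame(mirna = character(), position = integer(),
                      ref = character(), alt = character(),
                      species = character(), n_species = integer(),
                      region = character(), stringsAsFactors = FALSE)
  }
  ind <- do.call(rbind, indels)
  if (is.null(ind)) {
    ind <- data.frame(mirna = character(), column = integer(),
                      species = character(), stringsAsFactors = FALSE)
  }
  attr(out, "indels") <- ind
  out
}

#' Summarise variants by region, position and lineage
#'
#' Counts variants per functional region and per mature position, the
#' number of distinct miRNAs carrying variation, and variant-species
#' pairs per lineage (a variant carried by three species contributes
#' three pairs -- the unit in which lineage-level variation is reported).
#'
#' @param variants data.frame from [call_variants()] (or rows of the same
#'   shape); `species` is comma-joined.
#' @param clade_map Named character vector species -> lineage.
#' @return `variant_summary` list: `n_variants`, `n_pairs`, `n_mirna`,
#'   `by_region`, `by_position`, `by_lineage`.
#' @export
summarize_variants <- function(variants, clade_map) {
  regions <- c("seed", "central", "supplementary", "tail")
  species <- unlist(strsplit(variants$species, ",\\s*"))
  missing <- setdiff(unique(species), names(clade_map))
  if (length(missing)) {
    stop("species missing from clade_map: ", paste(missing, collapse = ", "))
  }
  pairs_lineage <- table(factor(clade_map[species],
                                levels = sort(unique(unname(clade_map)))))
  by_region <- table(factor(variants$region, levels = regions))
  by_position <- as.data.frame(table(position = variants$position),
                               stringsAsFactors = FALSE)
  if (nrow(by_position)) {
    by_position$position <- as.integer(by_position$position)
    names(by_position)[2] <- "n"
  } else {
    by_position <- data.frame(position = integer(), n = integer())
  }
  structure(list(
    n_variants = nrow(variants),
    n_pairs = length(species),
    n_mirna = length(unique(variants$mirna)),
    by_region = c(by_region),
    by_position = by_position,
    by_lineage = c(pairs_lineage)), class = "variant_summary")
}

#' @export
print.variant_summary <- function(x, ...) {
  cat("variants:", x$n_variants, " variant-species pairs:", x$n_pairs,
      " miRNAs with variation:", x$n_mirna, "\n")
  cat("by region: ",
      paste(names(x$by_region), x$by_region, sep = "=", collapse = "  "),
      "\n")
  cat("by lineage:",
      paste(names(x$by_lineage), x$by_lineage, sep = "=", collapse = "  "),
      "\n")
  invisible(x)
}
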