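#' Pairing-score folding parameters
#'
#' The folding engine minimises a sum of pairing scores over nested
#' canonical structures (a weighted Nussinov model): GC pairs score -3,
#' AU -2, GU wobble -1, and hairpin loops must span at least `min_loop`
#' unpaired bases. The scores order pair stabilities the same way the
#' nearest-neighbour model does while keeping the optimum brute-force
#' verifiable; all downstream statistics (z-score, SCI) are defined
#' relative to this model.
#'
#' @param gc,au,gu Pair scores (negative reals).
#' @param min_loop Minimum hairpin loop size (default 3).
#' @export
fold_params <- function(gc = -3, au = -2, gu = -1, min_loop = 3L) {
  stopifnot(gc < 0, au < 0, gu < 0, min_loop >= 0)
  structure(list(gc = gc, au = au, gu = gu, min_loop = as.integer(min_loop)),
            class = "fold_params")
}

.check_fold_seq <- function(seq) {
  seq <- gsub("U", "T", toupper(.check_seq(seq)), fixed = TRUE)
  if (grepl("[^ACGT]", seq)) {
    stop("sequence contains characters outside A/C/G/T/U")
  }
  seq
}

#' Minimum-energy secondary structure
#'
#' Dynamic-programming minimisation of the pairing-score model over all
#' nested canonical structures. Traceback is deterministic: leaving a base
#' unpaired is preferred at ties, otherwise the smallest admissible
#' partner is chosen.
#'
#' @param seq Sequence over A/C/G/T/U.
#' @param params [fold_params()].
#' @return `fold_result`: `structure` (dot-bracket), `energy`, and `pairs`
#'   (two-column matrix of 1-based paired positions).
#' @export
fold_mfe <- function(seq, params = fold_params()) {
  seq <- .check_fold_seq(seq)
  r <- cpp_fold(seq, params$gc, params$au, params$gu, params$min_loop)
  structure(list(sequence = seq, structure = r$structure, energy = r$energy,
                 pairs = r$pairs), class = "fold_result")
}

#' Exhaustive folding oracle
#'
#' Enumerates every valid nested canonical structure of a short sequence
#' (length <= 14, enforced) without memoisation and returns the minimum
#' energy. Exists to verify [fold_mfe()]; never used in the pipeline.
#'
#' @inheritParams fold_mfe
#' @return List with `energy` and `n_structures` enumerated.
#' @export
brute_force_fold <- function(seq, params = fold_params()) {
  seq <- .check_fold_seq(seq)
  n <- nchar(seq)
  if (n > 14) stop("brute_force_fold is restricted to sequences of length <= 14")
  x <- strsplit(seq, "")[[1]]
  score <- function(a, b) {
    p <- paste0(a, b)
    switch(p, GC = , CG = params$gc, AT = , TA = params$au,
           GT = , TG = params$gu, NA_real_)
  }
  ml <- params$min_loop
  enum <- function(i, j) {
    if (i >= j) return(list(numeric(0)))
    res <- enum(i + 1, j) # i unpaired
    ks <- if (i + ml + 1 <= j) seq(i + ml + 1, j) else integer(0)
    for (k in ks) {
      s <- score(x[i], x[k])
      if (is.na(s)) next
      left <- enum(i + 1, k - 1)
      right <- enum(k + 1, j)
      for (l in left) for (r in right) {
        res[[length(res) + 1L]] <- c(s, l, r)
      }
    }
    res
  }
  structs <- if (n < 2) list(numeric(0)) else enum(1, n)
  energies <- vapply(structs, sum, numeric(1))
  list(energy = min(energies), n_structures = length(structs))
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, "\n", sep = "")
  cat("energy:", x$energy, "(", nrow(x$pairs), "pairs )\n")
  invisible(x)
}
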