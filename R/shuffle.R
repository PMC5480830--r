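#' Dinucleotide-preserving shuffle (Altschul-Erickson)
#'
#' Returns a random sequence with exactly the same dinucleotide count
#' multiset (and hence mononucleotide composition) as the input, by
#' sampling a random Eulerian walk over the dinucleotide multigraph. The
#' first and last residues are preserved. Uses the current RNG state;
#' seed with `set.seed()` for reproducibility.
#'
#' @param seq Sequence (single string).
#' @return Shuffled sequence.
#' @export
dinucleotide_shuffle <- function(seq) {
  seq <- .check_seq(seq)
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  if (n <= 3 || length(unique(x)) == 1) return(seq)
  verts <- unique(x)
  from <- x[-n]
  to <- x[-1]
  out_edges <- split(to, factor(from, levels = verts))
  last_v <- x[n]

  ok <- FALSE
  tries <- 0L
  last_edge <- NULL
  while (!ok) {
    tries <- tries + 1L
    if (tries > 10000L) stop("dinucleotide shuffle failed to converge")
    last_edge <- vapply(verts, function(v) {
      if (v == last_v || length(out_edges[[v]]) == 0) return(NA_character_)
      e <- out_edges[[v]]
      e[sample.int(length(e), 1L)]
    }, character(1))
    names(last_edge) <- verts
    # the chosen last edges must form a tree directed toward last_v
    ok <- TRUE
    for (v in verts) {
      if (is.na(last_edge[[v]])) next
      seen <- character(0)
      cur <- v
      while (cur != last_v) {
        if (cur %in% seen || is.na(last_edge[[cur]])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
  }

  ordered <- list()
  for (v in verts) {
    e <- out_edges[[v]]
    if (!is.na(last_edge[[v]])) {
      drop <- match(last_edge[[v]], e)
      e <- e[-drop]
    }
    if (length(e) > 1) e <- e[sample.int(length(e))]
    if (!is.na(last_edge[[v]])) e <- c(e, last_edge[[v]])
    ordered[[v]] <- e
  }
  ptr <- setNames(rep(1L, length(verts)), verts)
  res <- character(n)
  res[1] <- x[1]
  cur <- x[1]
  for (i in seq(2, n)) {
    nxt <- ordered[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  paste(res, collapse = "")
}

#' Thermodynamic-stability z-score against a shuffle null
#'
#' Standardised difference between a sequence's minimum folding energy
#' and the energy distribution of composition-preserving shuffles:
#' `z = (E_obs - mean(E_shuffled)) / sd(E_shuffled)`. Lower z means
#' greater stability; values below -3 indicate structures very unlikely
#' to arise by composition alone. The Monte-Carlo null preserves
#' dinucleotide counts by default (the stricter, standard choice);
#' `method = "mononucleotide"` permutes residues freely.
#'
#' If the shuffle energies are (numerically) constant the z-score is
#' defined as 0 and flagged degenerate.
#'
#' @param seq Sequence.
#' @param n_shuffles Number of shuffles (>= 2).
#' @param seed Optional integer seed (local to this call).
#' @param params [fold_params()].
#' @param method `"dinucleotide"` or `"mononucleotide"`.
#' @return `stability_result`: `z`, `energy`, `shuffle_mean`,
#'   `shuffle_sd`, `n_shuffles`, `degenerate`, `method`, `seed`.
#' @export
z_score <- function(seq, n_shuffles = 100L, seed = NULL,
                    params = fold_params(),
                    method = c("dinucleotide", "mononucleotide")) {
  method <- match.arg(method)
  stopifnot(n_shuffles >= 2)
  seq <- .check_fold_seq(seq)
  e_obs <- fold_mfe(seq, params)$energy
  energies <- .with_seed(seed, function() {
    vapply(seq_len(n_shuffles), function(k) {
      s <- if (method == "dinucleotide") {
        dinucleotide_shuffle(seq)
      } else {
        paste(sample(strsplit(seq, "")[[1]]), collapse = "")
      }
      fold_mfe(s, params)$energy
    }, numeric(1))
  })
  m <- mean(energies)
  s <- sd(energies)
  degenerate <- !is.finite(s) || s < 1e-9
  z <- if (degenerate) 0 else (e_obs - m) / s
  structure(list(z = z, energy = e_obs, shuffle_mean = m, shuffle_sd = s,
                 n_shuffles = as.integer(n_shuffles), degenerate = degenerate,
                 method = method, seed = seed),
            class = "stability_result")
}

#' Count the 16 dinucleotides of a sequence
#'
#' @param seq Sequence.
#' @return Named integer vector over the 16 DNA dinucleotides.
#' @export
dinucleotide_counts <- function(seq) {
  seq <- .check_seq(seq)
  x <- strsplit(seq, "")[[1]]
  lv <- c(t(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)))
  if (length(x) < 2) return(setNames(rep(0L, 16), lv))
  d <- paste0(x[-length(x)], x[-1])
  table(factor(d, levels = lv)) |> c()
}
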