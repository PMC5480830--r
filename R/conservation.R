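#' Covariance-scoring parameters for consensus folding
#'
#' A consensus column pair earns a covariance bonus when different rows
#' realise it with different canonical pair types (compensatory or
#' consistent substitutions) and a penalty for rows that cannot pair there
#' (inconsistent substitutions): `cov(i, j) = -b * (t - 1) + q * m`, with
#' `t` the number of distinct canonical pair types among pairable rows and
#' `m` the number of non-pairable rows. A column pair is admissible only
#' when more than `min_pairable` of the rows can form a canonical pair.
#'
#' @param b Compensation bonus weight (default 1).
#' @param q Inconsistency penalty weight (default 1).
#' @param min_pairable Fraction of rows that must be pairable (default 0.5,
#'   strict).
#' @export
cov_params <- function(b = 1, q = 1, min_pairable = 0.5) {
  stopifnot(b >= 0, q >= 0, min_pairable >= 0, min_pairable < 1)
  structure(list(b = b, q = q, min_pairable = min_pairable),
            class = "cov_params")
}

.pair_score_chr <- function(a, b, params) {
  p <- paste0(a, b)
  ifelse(p %in% c("GC", "CG"), params$gc,
         ifelse(p %in% c("AT", "TA"), params$au,
                ifelse(p %in% c("GT", "TG"), params$gu, NA_real_)))
}

# column-pair score matrices for an alignment: thermodynamic mean, covariance
# term, and the admissibility gate
.consensus_scores <- function(m, params, cparams) {
  n <- ncol(m)
  nr <- nrow(m)
  thermo <- matrix(NA_real_, n, n)
  covm <- matrix(NA_real_, n, n)
  total <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) {
    ai <- m[, i]
    for (j in seq(i + 1, n)) {
      bj <- m[, j]
      sc <- .pair_score_chr(ai, bj, params)
      pairable <- !is.na(sc)
      if (sum(pairable) <= cparams$min_pairable * nr) next
      t_types <- length(unique(paste0(ai, bj)[pairable]))
      mm <- sum(!pairable)
      th <- sum(sc[pairable]) / nr
      cv <- -cparams$b * (t_types - 1) + cparams$q * mm
      thermo[i, j] <- th
      covm[i, j] <- cv
      total[i, j] <- th + cv
    }
  }
  list(thermo = thermo, cov = covm, total = total)
}

#' Consensus structure of an alignment with covariance weighting
#'
#' Folds the alignment's columns with the same nested-structure dynamic
#' program as [fold_mfe()], scoring a column pair by the mean pairing
#' score over rows (non-pairable rows contribute 0) plus the covariance
#' term of [cov_params()]. The consensus energy decomposes exactly into a
#' thermodynamic part and a covariance contribution; a negative covariance
#' contribution indicates compensatory/consistent substitutions
#' supporting the consensus structure.
#'
#' @param alignment Named character vector of gapped rows (equal width,
#'   >= 2 rows).
#' @param params [fold_params()].
#' @param cparams [cov_params()].
#' @return List: `structure` (dot-bracket over columns),
#'   `consensus_energy`, `thermo_part`, `covariance_contribution`,
#'   `pairs`.
#' @export
consensus_fold <- function(alignment, params = fold_params(),
                           cparams = cov_params()) {
  stopifnot(length(alignment) >= 2)
  m <- .aln_matrix(toupper(gsub("U", "T", alignment, fixed = TRUE)))
  sc <- .consensus_scores(m, params, cparams)
  r <- cpp_fold_matrix(sc$total, params$min_loop)
  pairs <- r$pairs
  thermo_part <- 0
  cov_contrib <- 0
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      thermo_part <- thermo_part + sc$thermo[pairs[k, 1], pairs[k, 2]]
      cov_contrib <- cov_contrib + sc$cov[pairs[k, 1], pairs[k, 2]]
    }
  }
  list(structure = r$structure,
       consensus_energy = thermo_part + cov_contrib,
       thermo_part = thermo_part,
       covariance_contribution = cov_contrib,
       pairs = pairs)
}

#' Mean pairwise identity of an alignment
#'
#' For each row pair: identical non-gap columns divided by columns where
#' at least one row has a base (gap-vs-base counts as mismatch,
#' gap-vs-gap is excluded). Returns the mean over all pairs.
#'
#' @param alignment Named character vector of gapped rows (>= 2).
#' @export
mean_pairwise_identity <- function(alignment) {
  stopifnot(length(alignment) >= 2)
  m <- .aln_matrix(alignment)
  n <- nrow(m)
  ids <- c()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      a <- m[i, ]; b <- m[j, ]
      comp <- a != "-" | b != "-"
      if (!any(comp)) { ids <- c(ids, NA_real_); next }
      ids <- c(ids, sum(a == b & a != "-" & comp) / sum(comp))
    }
  }
  mean(ids)
}

#' Structure Conservation Index of a pre-miRNA alignment
#'
#' `SCI = consensus energy / mean(individual folding energies)`. Values
#' near 1 indicate structural conservation; compensatory substitutions
#' can push the consensus energy below the individual mean (SCI > 1 is
#' possible). With an (absolute) mean individual energy below `eps` the
#' index is undefined and flagged.
#'
#' @param alignment Named character vector of gapped rows (>= 2).
#' @param params [fold_params()].
#' @param cparams [cov_params()].
#' @param eps Degeneracy tolerance for the denominator.
#' @return `conservation_result`: `sci`, `consensus_energy`,
#'   `thermo_part`, `covariance_contribution`, `mean_pairwise_identity`,
#'   `individual_energies`, `degenerate`.
#' @export
sci <- function(alignment, params = fold_params(), cparams = cov_params(),
                eps = 1e-9) {
  stopifnot(length(alignment) >= 2)
  rows <- gsub("-", "", alignment, fixed = TRUE)
  if (any(!nzchar(rows))) stop("alignment contains an all-gap row")
  e_ind <- vapply(rows, function(s) fold_mfe(s, params)$energy, numeric(1))
  cf <- consensus_fold(alignment, params, cparams)
  denom <- mean(e_ind)
  degenerate <- abs(denom) < eps
  structure(list(
    sci = if (degenerate) NA_real_ else cf$consensus_energy / denom,
    consensus_energy = cf$consensus_energy,
    thermo_part = cf$thermo_part,
    covariance_contribution = cf$covariance_contribution,
    mean_pairwise_identity = mean_pairwise_identity(alignment),
    individual_energies = e_ind,
    consensus_structure = cf$structure,
    degenerate = degenerate), class = "conservation_result")
}
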