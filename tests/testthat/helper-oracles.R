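# independent oracles and small constructors shared across tests

BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# perfect hairpin: stem_len complementary pairs around an A-loop
designed_hairpin <- function(stem_len = 15, loop_len = 4) {
  arm <- random_seq(stem_len)
  paste0(arm, strrep("A", loop_len), revcomp(arm))
}

# mutate a sequence at given 1-based positions (to a different base)
mutate_at <- function(s, positions) {
  x <- strsplit(s, "")[[1]]
  for (p in positions) x[p] <- sample(setdiff(BASES, x[p]), 1)
  paste(x, collapse = "")
}

# plain union-find over an edge list: independent connected-components oracle
uf_components <- function(ids, from, to) {
  parent <- setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (k in seq_along(from)) {
    ra <- find(from[k]); rb <- find(to[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(ids, find, character(1))
  # canonical label: smallest member id of each component
  comp <- split(ids, roots)
  lab <- setNames(character(length(ids)), ids)
  for (members in comp) lab[members] <- min(members)
  lab
}

# ungapped percent-identity of two equal-length sequences
direct_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  stopifnot(length(x) == length(y))
  mean(x == y)
}

# write a prediction table TSV and return its path
write_pred_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
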