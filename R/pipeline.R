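#' Pipeline configuration
#'
#' Aggregates the stage parameters: the homolog-clustering filter (70%
#' identity over >= 18 nt), the ortholog subdivision threshold, the
#' prediction-table inclusion thresholds (score >= 0, depth >= 3), folding
#' and z-score settings, and the paralog-scan filter (70% identity over
#' >= 300 nt).
#'
#' @param ... Overrides for any default listed in the source.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_identity = 0.70, min_length = 18L,
    subdivision_identity = 0.85,
    min_score = 0, min_depth = 3L,
    min_species_variants = 3L, min_species_structure = 5L,
    fold = fold_params(), cov = cov_params(),
    n_shuffles = 50L, seed = 1L,
    paralog_min_identity = 0.70, paralog_min_length = 300L,
    rescue_identity = 0.70, rescue_coverage = 0.60,
    max_hits = 100L,
    reference_species = "human",
    clade_map = primate_clades(),
    scoring = align_scoring(),
    run_structure = TRUE, run_paralogs = TRUE, run_trees = TRUE)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config keys: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

.log_stage <- function(stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
}

#' Run the full comparative pipeline on a study bundle
#'
#' Stages: parse the prediction table and mature FASTA; all-versus-all
#' matching and single-linkage clustering into homology groups; ortholog
#' subdivision; variant calling and summary per ortholog group (>= 3
#' species); structural conservation (mean pairwise identity, per-species
#' z-scores, SCI, covariance contribution) for groups with >= 5 species;
#' flank-anchored paralog presence/absence against every species' genome;
#' neighbor-joining trees. Each stage writes a TSV under `out_dir`.
#'
#' @param bundle_dir Directory holding `matures.fasta`, `predictions.tsv`,
#'   `genome_<species>.fasta` and `tree.nwk` (as written by
#'   [write_study_bundle()], or assembled by hand in the same formats).
#' @param out_dir Output directory.
#' @param config A [pipeline_config()].
#' @return `mirevol_report`: per-stage counts plus the main result tables.
#' @export
run_pipeline <- function(bundle_dir, out_dir,
                         config = pipeline_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scoring <- config$scoring
  tsv <- function(d, name) {
    write.table(d, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  pred_path <- file.path(bundle_dir, "predictions.tsv")
  preds <- parse_prediction_table(
    pred_path, prediction_filter(config$min_score, config$min_depth))
  .log_stage("parse", sprintf("%d hairpin records retained", nrow(preds)))

  matures <- mature_records(preds$id, preds$species, preds$mature,
                            preds$read_depth)
  report <- list(n_matures = nrow(matures))

  if (nrow(matures) == 0) {
    .log_stage("cluster", "no matures; writing empty outputs")
    empty <- data.frame()
    tsv(data.frame(group = character(), id = character(),
                   species = character()), "groups.tsv")
    tsv(data.frame(), "variants.tsv")
    report <- c(report, list(n_homology_groups = 0L, n_singletons = 0L,
                             n_ortholog_groups = 0L,
                             n_groups_structure = 0L, n_variants = 0L))
    class(report) <- "mirevol_report"
    return(report)
  }

  filt <- match_filter(config$min_identity, config$min_length)
  hits <- all_vs_all(matures, filt, scoring)
  cl <- cluster_homologs(hits, matures$id)
  .log_stage("cluster", sprintf("%d homology groups, %d singletons",
                                length(cl$groups), length(cl$singletons)))
  groups_df <- do.call(rbind, c(list(
    data.frame(group = character(), id = character(), species = character(),
               stringsAsFactors = FALSE)),
    lapply(names(cl$groups), function(g) {
      ids <- cl$groups[[g]]
      data.frame(group = g, id = ids,
                 species = matures$species[match(ids, matures$id)],
                 stringsAsFactors = FALSE)
    })))
  tsv(groups_df, "groups.tsv")

  ogs <- list()
  for (g in names(cl$groups)) {
    members <- matures[matures$id %in% cl$groups[[g]], , drop = FALSE]
    ogs <- c(ogs, subdivide_orthologs(members, g,
                                      config$subdivision_identity, scoring))
  }
  .log_stage("subdivide", sprintf("%d ortholog groups with >= 3 species",
                                  length(ogs)))

  all_vars <- list()
  for (og in ogs) {
    v <- call_variants(og$alignment, og$id,
                       reference_species = config$reference_species)
    if (nrow(v)) all_vars[[length(all_vars) + 1L]] <- v
  }
  variants <- if (length(all_vars)) do.call(rbind, all_vars) else
    call_variants(c(a = "ACGTACGTACGTACGTACGT",
                    b = "ACGTACGTACGTACGTACGT",
                    c = "ACGTACGTACGTACGTACGT"))[0, ]
  tsv(variants, "variants.tsv")
  known <- unique(unlist(strsplit(variants$species, ",\\s*")))
  clade_map <- config$clade_map
  extra <- setdiff(known, names(clade_map))
  if (length(extra)) clade_map <- c(clade_map, setNames(rep("other",
                                                            length(extra)),
                                                        extra))
  vsum <- summarize_variants(variants, clade_map)
  tsv(data.frame(region = names(vsum$by_region), n = c(vsum$by_region)),
      "variant_regions.tsv")
  tsv(vsum$by_position, "variant_positions.tsv")
  .log_stage("variants", sprintf("%d variants in %d ortholog groups",
                                 vsum$n_variants, vsum$n_mirna))

  struct <- data.frame()
  if (isTRUE(config$run_structure)) {
    rows <- list()
    k <- 0L
    for (og in ogs) {
      if (nrow(og$members) < config$min_species_structure) next
      k <- k + 1L
      pre <- .pre_sequences(preds, og$members$id)
      if (length(pre) < config$min_species_structure) next
      aln <- align_msa(pre, scoring)
      cons <- sci(aln, config$fold, config$cov)
      zs <- vapply(seq_along(pre), function(i) {
        z_score(pre[[i]], config$n_shuffles,
                seed = config$seed + 7919L * k + i,
                params = config$fold)$z
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        group = og$id, n_species = length(pre),
        mean_pairwise_identity = cons$mean_pairwise_identity,
        mean_z = mean(zs), min_z = min(zs),
        sci = cons$sci,
        covariance_contribution = cons$covariance_contribution,
        stringsAsFactors = FALSE)
    }
    struct <- if (length(rows)) do.call(rbind, rows) else
      data.frame(group = character(), n_species = integer(),
                 mean_pairwise_identity = numeric(), mean_z = numeric(),
                 min_z = numeric(), sci = numeric(),
                 covariance_contribution = numeric())
    tsv(struct, "structure.tsv")
    .log_stage("structure", sprintf("%d groups with >= %d species",
                                    nrow(struct),
                                    config$min_species_structure))
  }

  presence <- data.frame()
  if (isTRUE(config$run_paralogs)) {
    presence <- .presence_stage(bundle_dir, preds, config, scoring)
    tsv(presence, "presence.tsv")
    .log_stage("paralogs", sprintf("%d presence calls", nrow(presence)))
  }

  trees <- character(0)
  if (isTRUE(config$run_trees)) {
    for (og in ogs) {
      dm <- p_distance_matrix(og$alignment)
      if (nrow(dm) >= 3 && any(dm > 0)) {
        nwk <- tryCatch(as.character(nj_tree(dm)), error = function(e) NA)
        if (!is.na(nwk)) trees[og$id] <- nwk
      }
    }
    writeLines(paste0(names(trees), "\t", trees),
               file.path(out_dir, "trees.tsv"))
    .log_stage("trees", sprintf("%d trees", length(trees)))
  }

  report <- c(report, list(
    n_homology_groups = length(cl$groups),
    n_singletons = length(cl$singletons),
    n_ortholog_groups = length(ogs),
    n_groups_structure = nrow(struct),
    n_variants = vsum$n_variants,
    n_invariant_groups = length(ogs) - vsum$n_mirna,
    variant_summary = vsum,
    groups = groups_df, ortholog_groups = ogs, variants = variants,
    structure = struct, presence = presence, trees = trees,
    config = config))
  rep_counts <- report[vapply(report, function(x)
    is.numeric(x) && length(x) == 1, logical(1))]
  tsv(data.frame(key = names(rep_counts), value = unlist(rep_counts)),
      "report.tsv")
  class(report) <- "mirevol_report"
  report
}

# pre-miRNA sequences (hairpin trimmed to the mature..star extent) for the
# members of an ortholog group, named by species
.pre_sequences <- function(preds, ids) {
  idx <- match(ids, preds$id)
  idx <- idx[!is.na(idx)]
  out <- character(0)
  for (i in idx) {
    s <- min(preds$mature_start[i], preds$star_start[i])
    e <- max(preds$mature_end[i], preds$star_end[i])
    out[preds$species[i]] <- substr(preds$sequence[i], s + 1, e)
  }
  out
}

.presence_stage <- function(bundle_dir, preds, config, scoring) {
  genomes <- list.files(bundle_dir, pattern = "^genome_.*\\.fasta$",
                        full.names = TRUE)
  if (!length(genomes)) return(data.frame())
  species <- sub("^genome_(.*)\\.fasta$", "\\1", basename(genomes))
  ref <- config$reference_species
  if (!(ref %in% species)) return(data.frame())
  all_genomes <- lapply(genomes, read_fasta)
  names(all_genomes) <- species
  ref_genome <- all_genomes[[ref]]

  calls <- list()
  for (locus in names(ref_genome)) {
    window <- ref_genome[[locus]]
    rec <- preds[preds$species == ref &
                   startsWith(preds$id, paste0(locus, "|")), , drop = FALSE]
    if (nrow(rec) == 0) next
    hp_at <- regexpr(rec$sequence[1], window, fixed = TRUE)
    if (hp_at < 0) next
    # pre-miRNA extent inside the excised hairpin = mature..star span
    pre_start <- (hp_at - 1L) + min(rec$mature_start[1], rec$star_start[1])
    pre_end <- (hp_at - 1L) + max(rec$mature_end[1], rec$star_end[1])
    query <- locus_query(locus, window, pre_start, pre_end)
    for (k in seq_along(genomes)) {
      sp <- species[k]
      genome <- all_genomes[[sp]]
      m <- scan_genome(query, genome, config$paralog_min_identity,
                       config$paralog_min_length, scoring)
      m <- filter_repetitive(m, nchar(window), config$max_hits)
      calls[[length(calls) + 1L]] <- call_presence(
        query, m, genome, species = sp,
        rescue_identity = config$rescue_identity,
        rescue_coverage = config$rescue_coverage, scoring = scoring)
    }
  }
  if (!length(calls)) return(data.frame())
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' @export
print.mirevol_report <- function(x, ...) {
  cat("mirevol pipeline report\n")
  cat("  matures:            ", x$n_matures, "\n")
  cat("  homology groups:    ", x$n_homology_groups,
      "(singletons:", x$n_singletons, ")\n")
  cat("  ortholog groups:    ", x$n_ortholog_groups, "\n")
  cat("  structural groups:  ", x$n_groups_structure, "\n")
  cat("  mature variants:    ", x$n_variants, "\n")
  invisible(x)
}

#' Recompute the published mature-variant summary from the packaged table
#'
#' The packaged fixture transcribes the published summary of all variants
#' found within the mature region of a miRNA ortholog group across the 13
#' sequenced primates (17 rows: miRNA, substitution, 1-based mature
#' position, carrier species). This function re-derives the headline
#' statistics from it: distinct miRNAs with variation, variant-species
#' pairs per lineage, and per-region counts.
#'
#' @param path Path to the fixture TSV; defaults to the packaged copy.
#' @return List: `n_mirna`, `n_pairs`, `by_lineage`, `by_region`,
#'   `by_position`, and the parsed `variants` table.
#' @export
table1_check <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_variants.tsv", package = "mirevol")
  }
  if (!file.exists(path)) stop("variant fixture not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("microRNA", "variant", "position", "species") %in%
                  names(tab)))
  parts <- strsplit(tab$variant, "\\s*>\\s*")
  variants <- data.frame(
    mirna = tab$microRNA,
    position = as.integer(tab$position),
    ref = vapply(parts, `[`, "", 1),
    alt = vapply(parts, `[`, "", 2),
    species = tab$species,
    n_species = lengths(strsplit(tab$species, ",\\s*")),
    region = assign_region(as.integer(tab$position)),
    stringsAsFactors = FALSE)
  s <- summarize_variants(variants, .report_clades())
  list(n_mirna = s$n_mirna, n_pairs = s$n_pairs,
       by_lineage = s$by_lineage, by_region = s$by_region,
       by_position = s$by_position, variants = variants)
}

#' Rand index between two partitions
#'
#' Agreement between two clusterings of the same items: the fraction of
#' item pairs on which the partitions agree (together in both, or apart
#' in both). 1 means identical partitions.
#'
#' @param a,b Label vectors of equal length (same item order).
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) {
    sa <- a[i] == a[seq(i + 1, n)]
    sb <- b[i] == b[seq(i + 1, n)]
    agree <- agree + sum(sa == sb)
  }
  agree / (n * (n - 1) / 2)
}
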