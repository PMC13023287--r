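tier_levels <- c("high_confidence", "partial", "rejected")

#' Hierarchically evaluate gene-lncRNA pairs
#'
#' The hierarchical filtering stage. Four conditions are checked, in order,
#' for every pair:
#'
#' * **specificity (A)** - the primary, gating criterion: the target TFO1
#'   count exceeds both permutation nulls (shuffled lncRNA and shuffled
#'   target) and the enrichment over the biological control is at least
#'   `params$enrichment_min_fold`;
#' * **accessibility (B)**: at least `params$min_accessible_hits` TFO1 hits
#'   fall in structurally accessible transcript regions;
#' * **CpG context (C)**: at least `params$min_cpg_hits` TFO1 hits overlap
#'   CpG islands;
#' * **density (D)**: the target TFO1 count itself reaches
#'   `params$min_target_hits` overlapping triplexes.
#'
#' Pairs failing specificity are `rejected`; pairs passing all four are
#' `high_confidence`; everything else is `partial`. SNP co-localization is
#' annotated but never affects the tier (it is interpretive, not filtering,
#' evidence). Tier assignment is a pure function of each row, so it is
#' idempotent and order-independent across pairs.
#'
#' @param pairs Tibble with one row per pair: counts `target`,
#'   `shuffled_lncrna`, `shuffled_target`, `control`, plus `cpg_overlap`,
#'   `accessible_overlap` and optional `snp_inside` and identifier columns,
#'   all computed under identical [screen_params()].
#' @param params [screen_params()].
#' @return The input with added columns `enrichment`,
#'   `criterion_specificity`, `criterion_accessibility`, `criterion_cpg`,
#'   `criterion_density`, `tier` (factor `high_confidence` > `partial` >
#'   `rejected`) and `failed_criteria` (`;`-separated, empty iff
#'   high confidence).
#' @examples
#' x <- tibble::tibble(target = 22, shuffled_lncrna = 1, shuffled_target = 2,
#'                     control = 5, cpg_overlap = 15, accessible_overlap = 22)
#' evaluate_pairs(x)$tier
#' @export
evaluate_pairs <- function(pairs, params = screen_params()) {
  x <- pairs
  if (!"snp_inside" %in% names(x)) x$snp_inside <- FALSE
  x$enrichment <- enrichment_ratio(x$target, x$control)
  x$criterion_specificity <- x$target > x$shuffled_lncrna &
    x$target > x$shuffled_target &
    x$enrichment >= params$enrichment_min_fold
  x$criterion_accessibility <- x$accessible_overlap >= params$min_accessible_hits
  x$criterion_cpg <- x$cpg_overlap >= params$min_cpg_hits
  x$criterion_density <- x$target >= params$min_target_hits
  x$tier <- factor(ifelse(!x$criterion_specificity, "rejected",
                          ifelse(x$criterion_accessibility & x$criterion_cpg &
                                   x$criterion_density,
                                 "high_confidence", "partial")),
                   levels = tier_levels)
  x$failed_criteria <- vapply(seq_len(nrow(x)), function(k) {
    paste(c("specificity", "accessibility", "cpg_island", "density")[
      !c(x$criterion_specificity[k], x$criterion_accessibility[k],
         x$criterion_cpg[k], x$criterion_density[k])], collapse = ";")
  }, character(1))
  x
}

#' Evaluate a single gene-lncRNA pair
#'
#' Scalar convenience wrapper around [evaluate_pairs()].
#'
#' @param counts Numeric vector or list with `target`, `shuffled_lncrna`,
#'   `shuffled_target`, `control`.
#' @param cpg_overlap,accessible_overlap Hit-overlap tallies for the pair.
#' @param snp_inside Does a significant SNP fall inside the lncRNA locus?
#' @param params [screen_params()].
#' @return A one-row evaluation tibble (see [evaluate_pairs()]).
#' @examples
#' evaluate_pair(c(target = 22, shuffled_lncrna = 1, shuffled_target = 2,
#'                 control = 5), cpg_overlap = 15, accessible_overlap = 22)
#' @export
evaluate_pair <- function(counts, cpg_overlap, accessible_overlap,
                          snp_inside = FALSE, params = screen_params()) {
  counts <- as.list(counts)
  evaluate_pairs(tibble(
    target = counts$target,
    shuffled_lncrna = counts$shuffled_lncrna,
    shuffled_target = counts$shuffled_target,
    control = counts$control,
    cpg_overlap = cpg_overlap,
    accessible_overlap = accessible_overlap,
    snp_inside = snp_inside
  ), params)
}

#' Rank evaluated pairs
#'
#' Deterministic total order: tier (high confidence first), then target TFO1
#' count descending, then enrichment descending, then lexicographic pair
#' identifiers.
#'
#' @param evaluations [evaluate_pairs()] output.
#' @return The same tibble, ranked, with a `rank` column prepended.
#' @export
rank_pairs <- function(evaluations) {
  x <- evaluations
  gid <- if ("gene_id" %in% names(x)) x$gene_id else ""
  tid <- if ("transcript_id" %in% names(x)) x$transcript_id
         else if ("label" %in% names(x)) x$label else ""
  ord <- order(as.integer(x$tier), -x$target, -x$enrichment, gid, tid)
  out <- x[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  select(out, "rank", dplyr::everything())
}

#' Write the screen's report tables
#'
#' Emits the four per-stage report tables (cis pairs with distances, TFO1
#' counts with controls and enrichment, CpG-island overlaps,
#' accessible-region overlaps), the master evaluation table, the SNP
#' co-localization table and a JSON run-metadata file recording parameters,
#' seed and package version. Outputs are deterministic for a given input
#' (byte-identical across reruns with the same seed).
#'
#' @param evaluations Ranked or unranked [evaluate_pairs()] output.
#' @param pairs [find_cis_lncrnas()] output.
#' @param colocalizations [snp_colocalize()] output.
#' @param outdir Output directory (created if missing).
#' @param params [screen_params()].
#' @return Invisibly, the vector of files written.
#' @export
render_reports <- function(evaluations, pairs, colocalizations, outdir,
                           params = screen_params()) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) {
      abort(sprintf("cannot create output directory '%s'", outdir))
    }
  }
  ev <- evaluations
  for (col in c("gene_id", "lncrna_gene_id", "transcript_id", "label")) {
    if (!col %in% names(ev)) ev[[col]] <- ""
  }
  files <- c(
    table1_cis_pairs = "table1_cis_pairs.tsv",
    table2_tfo1_counts = "table2_tfo1_counts.tsv",
    table3_cpg_overlap = "table3_cpg_overlap.tsv",
    table4_accessibility_overlap = "table4_accessibility_overlap.tsv",
    evaluations = "evaluations.tsv",
    snp_colocalization = "snp_colocalization.tsv",
    run_metadata = "run_metadata.json"
  )
  paths <- file.path(outdir, files)
  names(paths) <- names(files)

  readr::write_tsv(
    select(pairs, "gene_id", "chrom", "lncrna_gene_id", "transcript_id",
           "label", "distance"),
    paths[["table1_cis_pairs"]])
  readr::write_tsv(
    select(ev, "gene_id", "label", "target", "shuffled_lncrna",
           "shuffled_target", "control", "enrichment"),
    paths[["table2_tfo1_counts"]])
  readr::write_tsv(
    tibble(pair = paste(ev$gene_id, ev$label, sep = "-"),
           hits_overlapping_cpg_islands = ev$cpg_overlap),
    paths[["table3_cpg_overlap"]])
  readr::write_tsv(
    tibble(lncrna = ev$label,
           hits_overlapping_accessible_regions = ev$accessible_overlap),
    paths[["table4_accessibility_overlap"]])
  readr::write_tsv(ev, paths[["evaluations"]])
  readr::write_tsv(colocalizations, paths[["snp_colocalization"]])

  meta <- list(
    package = "triplexscreen",
    version = as.character(utils::packageVersion("triplexscreen")),
    parameters = unclass(params),
    n_pairs = nrow(ev),
    tiers = as.list(table(ev$tier))
  )
  jsonlite::write_json(meta, paths[["run_metadata"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}
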