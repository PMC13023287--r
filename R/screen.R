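#' Run the complete triplex screen on a locus set
#'
#' The end-to-end pipeline: (1) pair genes with lncRNA loci in their cis
#' windows and intersect SNPs with lncRNA loci; (2) scan each pair's
#' transcript against its promoter with permutation and biological-control
#' runs; (3) detect (or ingest) CpG islands and count TFO1 hits overlapping
#' them; (4) compute each transcript's accessibility profile and count TFO1
#' hits whose TFO lies in accessible RNA; (5) evaluate and rank all pairs
#' with the hierarchical filter. Identical inputs, parameters and seed give
#' byte-identical reports.
#'
#' @param locus A locus set as returned by [simulate_locus_set()] /
#'   [read_locus_set()]: list with `genes`, `lncrnas` (with `seq`), `snps`,
#'   `genome` (named character vector), optional `islands`, and `control`
#'   (list `seq`, `chrom`, `origin`).
#' @param params [screen_params()].
#' @param table Triad table.
#' @param model [energy_model()] for the accessibility stage.
#' @param outdir Optional report directory; when given, [render_reports()]
#'   is called.
#' @return An object of class `triplex_screen`: list with `pairs`,
#'   `colocalizations`, `evaluations` (ranked), `tfo1` (named list of
#'   clusters), `profiles` (named list of accessibility profiles),
#'   `islands`, `params`.
#' @examples
#' \donttest{
#' locus <- simulate_locus_set(sim_config(n_genes = 1, tts_length = 80))
#' res <- run_screen(locus)
#' tidy(res)
#' }
#' @export
run_screen <- function(locus, params = screen_params(),
                       table = default_triad_table(),
                       model = energy_model(), outdir = NULL) {
  pairs <- find_cis_lncrnas(locus$genes, locus$lncrnas, params)
  coloc <- snp_colocalize(locus$snps, locus$lncrnas)
  promoters <- promoter_region(locus$genes, params)

  profiles <- list()
  tfo1 <- list()
  rows <- list()

  for (k in seq_len(nrow(pairs))) {
    gid <- pairs$gene_id[k]
    tid <- pairs$transcript_id[k]
    gsel <- locus$genes[locus$genes$gene_id == gid, ]
    prom <- promoters[promoters$gene_id == gid, ]
    prom_seq <- subseq_1based(locus$genome[[prom$chrom]], prom$start, prom$end)
    tx_seq <- locus$lncrnas$seq[locus$lncrnas$transcript_id == tid][1]

    ctl <- run_screen_with_controls(
      gid, tid, prom_seq, tx_seq, locus$control$seq, params, table,
      promoter_origin = prom$start, promoter_chrom = prom$chrom)
    tfo1[[paste(gid, tid, sep = "-")]] <- ctl$target_tfo1

    islands <- if (!is.null(locus$islands)) {
      locus$islands
    } else {
      detect_cpg_islands(prom_seq, origin = prom$start, chrom = prom$chrom)
    }
    cpg <- overlap_hits_islands(ctl$target_tfo1$members, islands)

    if (is.null(profiles[[tid]])) {
      profiles[[tid]] <- unpaired_profile(tx_seq, params, model)
    }
    regions <- accessible_regions(profiles[[tid]], params$punp_threshold)
    acc <- overlap_hits_accessible(ctl$target_tfo1$members, regions)

    lnc_gene <- pairs$lncrna_gene_id[k]
    rows[[k]] <- mutate(
      ctl$counts,
      lncrna_gene_id = lnc_gene,
      label = pairs$label[k],
      cpg_overlap = cpg$count,
      accessible_overlap = acc$count,
      snp_inside = lnc_gene %in% coloc$lncrna_gene_id
    )
  }

  ev <- if (length(rows) > 0) {
    rank_pairs(evaluate_pairs(bind_rows(rows), params))
  } else {
    rank_pairs(evaluate_pairs(tibble(
      gene_id = character(), transcript_id = character(),
      lncrna_gene_id = character(), label = character(),
      target = integer(), shuffled_lncrna = integer(),
      shuffled_target = integer(), control = integer(),
      cpg_overlap = integer(), accessible_overlap = integer(),
      snp_inside = logical()), params))
  }

  res <- structure(list(
    pairs = pairs, colocalizations = coloc, evaluations = ev,
    tfo1 = tfo1, profiles = profiles,
    islands = if (!is.null(locus$islands)) locus$islands else NULL,
    params = params
  ), class = "triplex_screen")

  if (!is.null(outdir)) {
    render_reports(ev, pairs, coloc, outdir, params)
  }
  res
}

#' @export
print.triplex_screen <- function(x, ...) {
  cat("<triplex_screen> ", nrow(x$evaluations), " gene-lncRNA pair(s)\n",
      sep = "")
  tb <- table(x$evaluations$tier)
  cat("  tiers: ", paste(names(tb), tb, sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Tidy the pair evaluations of a screen
#'
#' @param x A `triplex_screen` object.
#' @param ... Unused.
#' @return The ranked evaluation tibble (one row per gene-lncRNA pair).
#' @method tidy triplex_screen
#' @export
tidy.triplex_screen <- function(x, ...) {
  as_tibble(x$evaluations)
}

#' One-row summary of a screen
#'
#' @param x A `triplex_screen` object.
#' @param ... Unused.
#' @return Tibble with pair and tier counts and the seed used.
#' @method glance triplex_screen
#' @export
glance.triplex_screen <- function(x, ...) {
  ev <- x$evaluations
  tibble(
    n_pairs = nrow(ev),
    n_high_confidence = sum(ev$tier == "high_confidence"),
    n_partial = sum(ev$tier == "partial"),
    n_rejected = sum(ev$tier == "rejected"),
    n_snp_colocalized = nrow(x$colocalizations),
    seed = x$params$seed
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
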