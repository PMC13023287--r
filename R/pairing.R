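#' Pair target genes with lncRNA loci in their cis windows
#'
#' Stage 1 of the screen. Each gene's cis window ([cis_window()]) is
#' intersected with lncRNA loci; any overlap (not full containment) makes a
#' candidate pair. One transcript is paired per lncRNA gene: the canonical
#' transcript when a logical `canonical` column marks it, otherwise the
#' longest transcript (ties broken by transcript id).
#'
#' @param genes Tibble of target genes: `gene_id`, `chrom`, `tss`, `strand`
#'   (plus optional `symbol`, `start`, `end`).
#' @param lncrnas Tibble of lncRNA transcripts: `gene_id`, `transcript_id`,
#'   `label`, `chrom`, `start`, `end` (locus), `seq` (transcript sequence,
#'   RNA alphabet) and optional `canonical`.
#' @param params [screen_params()].
#' @return A tibble of pairs sorted by gene then ascending distance, with
#'   columns `gene_id`, `lncrna_gene_id`, `transcript_id`, `label`, `chrom`,
#'   `distance` (TSS to nearest locus edge, 0 if the TSS falls inside),
#'   `locus_start`, `locus_end`, `window_start`, `window_end`.
#' @export
find_cis_lncrnas <- function(genes, lncrnas, params = screen_params()) {
  empty <- tibble(
    gene_id = character(), lncrna_gene_id = character(),
    transcript_id = character(), label = character(), chrom = character(),
    distance = numeric(), locus_start = numeric(), locus_end = numeric(),
    window_start = numeric(), window_end = numeric()
  )
  if (nrow(genes) == 0 || nrow(lncrnas) == 0) {
    inform("find_cis_lncrnas: empty annotation set; returning no pairs")
    return(empty)
  }
  lnc <- canonical_transcripts(lncrnas)
  win <- cis_window(genes, params)

  wgr <- GenomicRanges::GRanges(win$chrom, IRanges::IRanges(win$start, win$end))
  lgr <- GenomicRanges::GRanges(lnc$chrom, IRanges::IRanges(lnc$start, lnc$end))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(wgr, lgr, ignore.strand = TRUE))

  gidx <- S4Vectors::queryHits(ov)
  lidx <- S4Vectors::subjectHits(ov)
  if (length(gidx) == 0) return(empty)

  out <- tibble(
    gene_id = genes$gene_id[gidx],
    lncrna_gene_id = lnc$gene_id[lidx],
    transcript_id = lnc$transcript_id[lidx],
    label = lnc$label[lidx],
    chrom = lnc$chrom[lidx],
    distance = interval_distance(genes$tss[gidx],
                                 lnc[lidx, c("chrom", "start", "end")]),
    locus_start = lnc$start[lidx],
    locus_end = lnc$end[lidx],
    window_start = win$start[gidx],
    window_end = win$end[gidx]
  )
  arrange(out, .data$gene_id, .data$distance, .data$transcript_id)
}

# canonical transcript per lncRNA gene: flagged canonical if present,
# else longest transcript sequence, ties by transcript_id
canonical_transcripts <- function(lncrnas) {
  x <- lncrnas
  if (!"label" %in% names(x)) x$label <- x$transcript_id
  x$.len <- nchar(x$seq)
  x$.canon <- if ("canonical" %in% names(x)) x$canonical else FALSE
  x <- arrange(x, .data$gene_id, desc(.data$.canon), desc(.data$.len),
               .data$transcript_id)
  x <- x[!duplicated(x$gene_id), , drop = FALSE]
  select(x, -dplyr::any_of(c(".len", ".canon")))
}

#' Co-localize SNPs with lncRNA loci
#'
#' Point-in-interval, strand-agnostic intersection of significant SNP
#' positions with lncRNA locus intervals. One record is emitted per
#' (SNP, lncRNA gene) combination where the SNP position falls within the
#' locus (inclusive of both boundaries).
#'
#' @param snps Tibble with `snp_id`, `chrom`, `pos`.
#' @param lncrnas Tibble of lncRNA loci (`gene_id`, `chrom`, `start`, `end`);
#'   transcript-level rows are collapsed to one locus per gene.
#' @return Tibble `snp_id`, `lncrna_gene_id`, `pos`, `inside` (all `TRUE`).
#' @export
snp_colocalize <- function(snps, lncrnas) {
  empty <- tibble(snp_id = character(), lncrna_gene_id = character(),
                  pos = numeric(), inside = logical())
  if (nrow(snps) == 0 || nrow(lncrnas) == 0) return(empty)
  loci <- distinct(lncrnas, .data$gene_id, .data$chrom, .data$start, .data$end)
  sgr <- GenomicRanges::GRanges(snps$chrom, IRanges::IRanges(snps$pos, snps$pos))
  lgr <- GenomicRanges::GRanges(loci$chrom, IRanges::IRanges(loci$start, loci$end))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(sgr, lgr, ignore.strand = TRUE))
  si <- S4Vectors::queryHits(ov)
  li <- S4Vectors::subjectHits(ov)
  if (length(si) == 0) return(empty)
  arrange(tibble(
    snp_id = snps$snp_id[si],
    lncrna_gene_id = loci$gene_id[li],
    pos = snps$pos[si],
    inside = TRUE
  ), .data$snp_id, .data$lncrna_gene_id)
}
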