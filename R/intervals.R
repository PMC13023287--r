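#' Construct a genomic interval table
#'
#' Genomic intervals are plain tibbles with columns `chrom`, `start`, `end`
#' and `strand`, using the 1-based inclusive coordinate convention of
#' Ensembl/GFF3 throughout the package (`length = end - start + 1`). BED input
#' is converted on read.
#'
#' @param chrom Chromosome labels.
#' @param start,end 1-based inclusive positions, `start >= 1`, `end >= start`.
#' @param strand `"+"`, `"-"` or `"*"` (unstranded); recycled.
#' @return A tibble with one row per interval.
#' @examples
#' gi("chr1", 10, 20)
#' @export
gi <- function(chrom, start, end, strand = "*") {
  x <- tibble(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = rep_len(as.character(strand), length(chrom))
  )
  bad <- x$start < 1 | x$end < x$start | !x$strand %in% c("+", "-", "*")
  if (any(bad)) {
    abort(sprintf("invalid genomic interval at row %d (start=%s, end=%s, strand=%s)",
                  which(bad)[1], x$start[which(bad)[1]], x$end[which(bad)[1]],
                  x$strand[which(bad)[1]]))
  }
  x
}

#' Do two genomic intervals overlap?
#'
#' Strand-agnostic overlap under 1-based inclusive coordinates: intervals on
#' the same chromosome overlap iff `max(starts) <= min(ends)`; a shared
#' boundary base counts. Intervals on different chromosomes never overlap.
#'
#' @param a,b Interval tibbles (see [gi()]); rows are matched elementwise and
#'   recycled to the longer length.
#' @return A logical vector.
#' @examples
#' interval_overlap(gi("c", 10, 20), gi("c", 20, 30))  # TRUE: shared base
#' interval_overlap(gi("c", 10, 20), gi("c", 21, 30))  # FALSE: adjacent
#' @export
interval_overlap <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  a$chrom[ai] == b$chrom[bi] &
    pmax(a$start[ai], b$start[bi]) <= pmin(a$end[ai], b$end[bi])
}

#' Distance from a point to a genomic interval
#'
#' Absolute genomic distance from a point (typically a TSS) to the nearest
#' edge of an interval (typically a lncRNA locus): 0 when the point falls
#' inside the interval, otherwise `min(|point - start|, |point - end|)`.
#'
#' @param point 1-based positions (numeric vector).
#' @param iv Interval tibble, recycled against `point`.
#' @param point_chrom Optional chromosome labels of the points; when supplied,
#'   a chromosome mismatch with `iv` is an error (loci on different
#'   chromosomes have no finite cis distance).
#' @return Numeric vector of distances in bp.
#' @examples
#' interval_distance(41174024, gi("ECA13", 41160959, 41163821))  # 10203
#' @export
interval_distance <- function(point, iv, point_chrom = NULL) {
  n <- max(length(point), nrow(iv))
  pi_ <- rep_len(seq_along(point), n)
  ii <- rep_len(seq_len(nrow(iv)), n)
  if (!is.null(point_chrom)) {
    pc <- rep_len(as.character(point_chrom), n)
    if (any(pc != iv$chrom[ii])) {
      abort(sprintf("point on '%s' and interval on '%s' are on different chromosomes and not comparable",
                    pc[pc != iv$chrom[ii]][1], iv$chrom[ii][pc != iv$chrom[ii]][1]))
    }
  }
  p <- point[pi_]
  s <- iv$start[ii]
  e <- iv$end[ii]
  ifelse(p >= s & p <= e, 0, pmin(abs(p - s), abs(p - e)))
}

# strand with fail-soft default: unknown strand becomes "+" with a warning
resolve_strand <- function(strand, ids = NULL) {
  unknown <- is.na(strand) | !strand %in% c("+", "-")
  if (any(unknown)) {
    warn(sprintf("gene strand unknown for %s; defaulting to '+'",
                 paste(if (is.null(ids)) which(unknown) else ids[unknown], collapse = ", ")))
    strand[unknown] <- "+"
  }
  strand
}

#' Promoter region of target genes
#'
#' Strand-aware promoter window around each TSS: on the plus strand
#' `[tss - upstream, tss + downstream]`, on the minus strand
#' `[tss - downstream, tss + upstream]`, clipped at chromosome position 1.
#' Genes with unknown strand are treated as plus-strand with a warning.
#'
#' @param genes Tibble with columns `gene_id`, `chrom`, `tss` and `strand`.
#' @param params A [screen_params()] object supplying the upstream/downstream
#'   extents (defaults 3500/1500 bp).
#' @return A tibble `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @examples
#' g <- tibble::tibble(gene_id = "PRSS21", chrom = "ECA13",
#'                     tss = 41174024, strand = "+")
#' promoter_region(g)  # [41170524, 41175524]
#' @export
promoter_region <- function(genes, params = screen_params()) {
  strand <- resolve_strand(genes$strand, genes$gene_id)
  up <- ifelse(strand == "+", params$promoter_upstream, params$promoter_downstream)
  dn <- ifelse(strand == "+", params$promoter_downstream, params$promoter_upstream)
  tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = pmax(1, genes$tss - up),
    end = genes$tss + dn,
    strand = strand
  )
}

#' Cis window around target gene TSSs
#'
#' The fixed, strand-agnostic window `[tss - flank, tss + flank]` (clipped at
#' position 1) inside which lncRNA loci are considered candidate cis
#' regulators.
#'
#' @inheritParams promoter_region
#' @return A tibble `gene_id`, `chrom`, `start`, `end`.
#' @examples
#' g <- tibble::tibble(gene_id = "g", chrom = "c", tss = 1e5, strand = "+")
#' cis_window(g)  # [50000, 150000]
#' @export
cis_window <- function(genes, params = screen_params()) {
  tibble(
    gene_id = genes$gene_id,
    chrom = genes$chrom,
    start = pmax(1, genes$tss - params$window_flank),
    end = genes$tss + params$window_flank
  )
}
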