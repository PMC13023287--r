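#' Detect CpG islands with the Gardiner-Garden-Frommer rule
#'
#' Sliding evaluation of 200-bp windows at step 1: a window qualifies iff its
#' GC content is at least `gc_min` percent and its observed/expected CpG
#' ratio, `(N_CG * L) / (N_C * N_G)`, is at least `oe_min`. Overlapping
#' qualifying windows are merged; each merged island is re-scored over its
#' full extent and reported in genome coordinates. The defaults (200 bp, 50%,
#' 0.6) emulate a predicted-CpG-island annotation track; the stricter
#' Takai-Jones thresholds (500, 55, 0.65) can be requested through the
#' arguments.
#'
#' @param seq DNA sequence to scan.
#' @param origin Genomic coordinate of `seq` position 1.
#' @param chrom Chromosome label.
#' @param window_size Window length in bp (and minimum island length).
#' @param gc_min Minimum window GC percent.
#' @param oe_min Minimum observed/expected CpG ratio.
#' @return Tibble of islands: `chrom`, `start`, `end`, `length`,
#'   `gc_percent`, `obs_exp_cpg`, `source = "detector"`; empty (with a
#'   message) when `seq` is shorter than `window_size`. Islands are disjoint
#'   and sorted.
#' @examples
#' detect_cpg_islands(strrep("CG", 150))  # one island, obs/exp 2.0
#' detect_cpg_islands(strrep("AT", 150))  # none
#' @export
detect_cpg_islands <- function(seq, origin = 1, chrom = "chr",
                               window_size = 200L, gc_min = 50,
                               oe_min = 0.6) {
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  length = integer(), gc_percent = numeric(),
                  obs_exp_cpg = numeric(), source = character())
  seq <- normalize_dna(seq)
  n <- nchar(seq)
  if (n < window_size) {
    inform(sprintf("sequence of %d bp is shorter than the %d bp island window; no islands",
                   n, window_size))
    return(empty)
  }
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  is_c <- as.integer(v == "C")
  is_g <- as.integer(v == "G")
  is_cg <- as.integer(v[-n] == "C" & v[-1] == "G")  # CG dinucleotide starts

  cum <- function(x) c(0, cumsum(x))
  cc <- cum(is_c); cg_ <- cum(is_g); ccg <- cum(is_cg)
  L <- as.integer(window_size)
  starts <- seq_len(n - L + 1)
  nC <- cc[starts + L] - cc[starts]
  nG <- cg_[starts + L] - cg_[starts]
  # dinucleotides fully inside the window: starts in [s, s+L-2]
  nCG <- ccg[pmin(starts + L - 1, n)] - ccg[starts]

  gc <- 100 * (nC + nG) / L
  oe <- ifelse(nC * nG > 0, (nCG * L) / (nC * nG), 0)
  ok <- gc >= gc_min & oe >= oe_min
  if (!any(ok)) return(empty)

  merged <- IRanges::reduce(IRanges::IRanges(starts[ok], starts[ok] + L - 1))
  s <- IRanges::start(merged); e <- IRanges::end(merged)
  len <- e - s + 1
  mC <- cc[e + 1] - cc[s]
  mG <- cg_[e + 1] - cg_[s]
  mCG <- ccg[pmin(e, n - 1) + 1] - ccg[s]
  tibble(
    chrom = chrom,
    start = origin + s - 1,
    end = origin + e - 1,
    length = as.integer(len),
    gc_percent = 100 * (mC + mG) / len,
    obs_exp_cpg = ifelse(mC * mG > 0, (mCG * len) / (mC * mG), 0),
    source = "detector"
  )
}

#' Count triplex hits overlapping CpG islands
#'
#' A hit overlaps an island when its TTS interval shares at least one base
#' with the island (same chromosome); no minimum-fraction rule is applied.
#'
#' @param hits Hit tibble ([scan_triplexes()] or TFO1 members).
#' @param islands Island tibble ([detect_cpg_islands()] or ingested BED).
#' @return A list with `count` (number of hits overlapping at least one
#'   island) and `hits` (the input annotated with `cpg_overlap` and the
#'   overlapping `island_ids`, `;`-separated `chrom:start-end` labels).
#' @export
overlap_hits_islands <- function(hits, islands) {
  if (nrow(hits) == 0) {
    return(list(count = 0L,
                hits = mutate(hits, cpg_overlap = logical(0),
                              island_ids = character(0))))
  }
  if (is.null(islands) || nrow(islands) == 0) {
    return(list(count = 0L,
                hits = mutate(hits, cpg_overlap = FALSE, island_ids = "")))
  }
  hgr <- GenomicRanges::GRanges(hits$chrom,
                                IRanges::IRanges(hits$tts_start, hits$tts_end))
  igr <- GenomicRanges::GRanges(islands$chrom,
                                IRanges::IRanges(islands$start, islands$end))
  ov <- suppressWarnings(GenomicRanges::findOverlaps(hgr, igr, ignore.strand = TRUE))
  ids <- sprintf("%s:%d-%d", islands$chrom, as.integer(islands$start),
                 as.integer(islands$end))
  lab <- vapply(seq_len(nrow(hits)), function(k) {
    j <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == k]
    paste(ids[j], collapse = ";")
  }, character(1))
  out <- mutate(hits, cpg_overlap = lab != "", island_ids = lab)
  list(count = sum(out$cpg_overlap), hits = out)
}
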