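# ---- sequence utilities ----------------------------------------------------

normalize_rna <- function(seq) chartr("Tt", "Uu", toupper(seq))
normalize_dna <- function(seq) chartr("Uu", "Tt", toupper(seq))

rna_codes <- function(seq) {
  v <- strsplit(normalize_rna(seq), "", fixed = TRUE)[[1]]
  x <- unname(c(A = 0L, C = 1L, G = 2L, U = 3L)[v])
  x[is.na(x)] <- -1L
  x
}

dna_codes <- function(seq) {
  v <- strsplit(normalize_dna(seq), "", fixed = TRUE)[[1]]
  x <- unname(c(A = 0L, C = 1L, G = 2L, T = 3L)[v])
  x[is.na(x)] <- -1L
  x
}

revcomp_dna <- function(seq) {
  x <- chartr("ACGTacgt", "TGCAtgca", normalize_dna(seq))
  paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
}

reverse_seq <- function(seq) {
  paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = "")
}

empty_hits <- function() {
  tibble(
    tfo_start = integer(), tfo_end = integer(),
    chrom = character(), tts_start = numeric(), tts_end = numeric(),
    orientation = character(), dna_strand = character(),
    length = integer(), identity = numeric(), stability = numeric()
  )
}

# ---- triplex scan ----------------------------------------------------------

#' Scan a lncRNA transcript against a promoter duplex for triplex hits
#'
#' The algorithmic core of the screen: an ungapped diagonal scan of the RNA
#' third strand against both strands of the target duplex, in both parallel
#' and antiparallel orientation, under Hoogsteen/reverse-Hoogsteen triad
#' weights. On each diagonal every window of length at least
#' `params$min_triplex_len` is evaluated; a window qualifies when its identity
#' (percent of positions forming any admissible triad) is at least
#' `params$min_identity` and its mean triad weight at least
#' `params$min_stability`. Overlapping qualifying windows on one diagonal are
#' collapsed to a single non-redundant hit: the stability-maximal qualifying
#' window of the overlap group (ties: longest, then leftmost), so nested and
#' shifted windows of the same alignment are not double-counted. Distinct
#' diagonals report distinct hits; their overlap on the target is the density
#' signal that [select_tfo1()] measures.
#'
#' @param rna Transcript sequence (RNA alphabet; `T` is read as `U`).
#' @param dna Target duplex given as its forward genomic strand (DNA
#'   alphabet). Both strands are scanned as the potential purine-rich strand.
#' @param params [screen_params()] supplying `min_triplex_len`,
#'   `min_identity`, `min_stability`.
#' @param table Triad table, see [default_triad_table()].
#' @param origin Genomic coordinate of `dna` position 1 (1-based).
#' @param chrom Chromosome label for reported target coordinates.
#' @param orientations,strands Subsets of orientations / duplex strands to
#'   scan (defaults: all four combinations).
#' @return A tibble of hits with TFO coordinates on the transcript
#'   (`tfo_start`, `tfo_end`, 1-based), TTS coordinates mapped to the forward
#'   genomic strand (`chrom`, `tts_start`, `tts_end`), `orientation`,
#'   `dna_strand`, `length`, `identity` (percent) and `stability` (mean triad
#'   weight), deterministically ordered by target then transcript position.
#' @examples
#' p <- screen_params()
#' hits <- scan_triplexes(strrep("U", 60), strrep("A", 60), p,
#'                        orientations = "parallel")
#' hits$identity  # 100
#' @export
scan_triplexes <- function(rna, dna, params = screen_params(),
                           table = default_triad_table(),
                           origin = 1, chrom = "chr",
                           orientations = c("parallel", "antiparallel"),
                           strands = c("+", "-")) {
  rna <- normalize_rna(rna)
  dna <- normalize_dna(dna)
  m <- nchar(rna)
  n <- nchar(dna)
  lg <- params$min_triplex_len
  if (m < lg || n < lg) {
    abort(sprintf("sequences must be at least min_triplex_len = %d nt (rna %d, dna %d)",
                  lg, m, n))
  }
  rc <- rna_codes(rna)
  for (nm in c("rna", "dna")) {
    codes <- if (nm == "rna") rc else dna_codes(dna)
    frac <- mean(codes < 0)
    if (frac > 0.10) {
      warn(sprintf("%s sequence contains %.0f%% ambiguous bases; they score weight 0",
                   nm, 100 * frac))
    }
  }
  mats <- triad_matrices(table)

  res <- list()
  for (sigma in strands) {
    pseq <- if (sigma == "+") dna else revcomp_dna(dna)
    pc <- dna_codes(pseq)
    for (ori in orientations) {
      aseq <- if (ori == "parallel") rna else reverse_seq(rna)
      ac <- if (ori == "parallel") rc else rev(rc)
      raw <- scan_pair_cpp(ac, pc, mats[[ori]], lg,
                           params$min_identity, params$min_stability)
      if (nrow(raw) == 0) next
      len <- raw$a2 - raw$a1 + 1L
      if (ori == "parallel") {
        tfo1 <- raw$a1; tfo2 <- raw$a2
      } else {
        tfo1 <- m - raw$a2 + 1L; tfo2 <- m - raw$a1 + 1L
      }
      if (sigma == "+") {
        tts1 <- origin + raw$p1 - 1; tts2 <- origin + raw$p2 - 1
      } else {
        tts1 <- origin + n - raw$p2; tts2 <- origin + n - raw$p1
      }
      res[[length(res) + 1]] <- tibble(
        tfo_start = as.integer(tfo1), tfo_end = as.integer(tfo2),
        chrom = chrom, tts_start = tts1, tts_end = tts2,
        orientation = ori, dna_strand = sigma,
        length = as.integer(len),
        identity = 100 * raw$nz / len,
        stability = raw$sw / len
      )
    }
  }
  if (length(res) == 0) return(empty_hits())
  out <- bind_rows(res)
  ord <- order(out$tts_start, out$tts_end, out$tfo_start, out$tfo_end,
               match(out$orientation, c("parallel", "antiparallel")),
               match(out$dna_strand, c("+", "-")))
  out[ord, , drop = FALSE]
}

# ---- TFO1 selection --------------------------------------------------------

#' Select the densest cluster of triplex hits (TFO1)
#'
#' Sweep-line maximum-overlap count over the target (TTS) intervals of a hit
#' set. The peak is the region of maximal coverage depth; the TFO1 cluster is
#' the set of hits covering that peak, and its `hit_count` (the depth) is the
#' overlapping-triplex count used throughout the screen as the density and
#' strength indicator. Ties between equally deep peaks are broken by higher
#' mean member stability, then by leftmost genomic position.
#'
#' @param hits Hit tibble from [scan_triplexes()].
#' @return An object of class `tfo1_cluster`: a list with `chrom`,
#'   `peak_start`, `peak_end`, `hit_count` and `members` (hit tibble). An
#'   empty hit set gives `hit_count` 0 and an empty member table.
#' @examples
#' h <- scan_triplexes(strrep("U", 60), strrep("A", 60), screen_params())
#' select_tfo1(h)$hit_count
#' @export
select_tfo1 <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) {
    return(structure(list(chrom = NA_character_, peak_start = NA_real_,
                          peak_end = NA_real_, hit_count = 0L,
                          members = empty_hits()),
                     class = "tfo1_cluster"))
  }
  best <- NULL
  for (ch in sort(unique(hits$chrom))) {
    h <- hits[hits$chrom == ch, , drop = FALSE]
    bounds <- sort(unique(c(h$tts_start, h$tts_end + 1)))
    segs <- tibble(start = bounds[-length(bounds)], end = bounds[-1] - 1)
    cover <- lapply(seq_len(nrow(segs)), function(k) {
      which(h$tts_start <= segs$start[k] & h$tts_end >= segs$start[k])
    })
    depth <- lengths(cover)
    mx <- max(depth)
    cand <- which(depth == mx)
    mstab <- vapply(cand, function(k) mean(h$stability[cover[[k]]]), numeric(1))
    # higher mean member stability, then leftmost
    pick <- cand[order(-mstab, segs$start[cand])][1]
    cl <- list(chrom = ch, peak_start = segs$start[pick],
               peak_end = segs$end[pick], hit_count = as.integer(mx),
               members = h[cover[[pick]], , drop = FALSE],
               .mstab = mean(h$stability[cover[[pick]]]))
    if (is.null(best) || cl$hit_count > best$hit_count ||
        (cl$hit_count == best$hit_count && cl$.mstab > best$.mstab)) {
      best <- cl
    }
  }
  best$.mstab <- NULL
  structure(best, class = "tfo1_cluster")
}

#' @export
print.tfo1_cluster <- function(x, ...) {
  cat("<tfo1_cluster> ", x$hit_count, " overlapping hit(s)", sep = "")
  if (x$hit_count > 0) {
    cat(" at ", x$chrom, ":", x$peak_start, "-", x$peak_end, sep = "")
  }
  cat("\n")
  invisible(x)
}
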