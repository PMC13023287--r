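#' Screen-wide parameters
#'
#' Bundles every tunable threshold of the screen in one validated object.
#' Defaults follow the study conditions the screen was designed around:
#' +/-50 kb cis windows, promoters from 3500 bp upstream to 1500 bp downstream
#' of the TSS, triplex calls of at least 50 nt with identity >= 60% and mean
#' triad stability >= 1.0, local folding with window and span of 70 nt, an
#' unpaired-probability cutoff of 0.5, and a 2-fold enrichment floor over the
#' biological negative control.
#'
#' @param window_flank Cis-window half-width around the TSS, in bp.
#' @param promoter_upstream,promoter_downstream Promoter extent upstream /
#'   downstream of the TSS, in bp (strand-aware).
#' @param min_triplex_len Minimum triplex length (nt) for a reported hit.
#' @param min_identity Minimum identity (percent of positions forming any
#'   admissible triad) for a reported hit.
#' @param min_stability Minimum mean triad stability weight for a reported hit.
#' @param punp_threshold Per-base unpaired-probability cutoff defining
#'   structurally accessible regions.
#' @param fold_window Sliding window length (nt) for local folding.
#' @param fold_span Maximum base-pair span (nt) inside a folding window;
#'   must not exceed `fold_window`.
#' @param enrichment_min_fold Minimum target/control TFO1 enrichment ratio for
#'   the specificity criterion.
#' @param min_target_hits Minimum TFO1 overlapping-triplex count (density) a
#'   pair must reach to be called high confidence.
#' @param min_cpg_hits Minimum number of TFO1 hits overlapping CpG islands.
#' @param min_accessible_hits Minimum number of TFO1 hits whose TFO overlaps
#'   an accessible region of the transcript.
#' @param shuffle_mode `"mononucleotide"` (base-composition preserving) or
#'   `"dinucleotide"` (Altschul-Erickson, dinucleotide preserving).
#' @param n_shuffle Number of shuffle replicates per null; counts are the
#'   median over replicates when `n_shuffle > 1`.
#' @param seed Integer seed from which all randomized steps are derived.
#'
#' @return An object of class `screen_params` (a named list).
#' @examples
#' p <- screen_params()
#' p$window_flank
#' @export
screen_params <- function(window_flank = 50000L,
                          promoter_upstream = 3500L,
                          promoter_downstream = 1500L,
                          min_triplex_len = 50L,
                          min_identity = 60,
                          min_stability = 1.0,
                          punp_threshold = 0.5,
                          fold_window = 70L,
                          fold_span = 70L,
                          enrichment_min_fold = 2.0,
                          min_target_hits = 20L,
                          min_cpg_hits = 1L,
                          min_accessible_hits = 1L,
                          shuffle_mode = c("mononucleotide", "dinucleotide"),
                          n_shuffle = 1L,
                          seed = 1L) {
  shuffle_mode <- match.arg(shuffle_mode)
  p <- list(
    window_flank = as.integer(window_flank),
    promoter_upstream = as.integer(promoter_upstream),
    promoter_downstream = as.integer(promoter_downstream),
    min_triplex_len = as.integer(min_triplex_len),
    min_identity = as.numeric(min_identity),
    min_stability = as.numeric(min_stability),
    punp_threshold = as.numeric(punp_threshold),
    fold_window = as.integer(fold_window),
    fold_span = as.integer(fold_span),
    enrichment_min_fold = as.numeric(enrichment_min_fold),
    min_target_hits = as.integer(min_target_hits),
    min_cpg_hits = as.integer(min_cpg_hits),
    min_accessible_hits = as.integer(min_accessible_hits),
    shuffle_mode = shuffle_mode,
    n_shuffle = as.integer(n_shuffle),
    seed = as.integer(seed)
  )
  stopifnot(
    p$window_flank > 0, p$promoter_upstream >= 0, p$promoter_downstream >= 0,
    p$min_triplex_len > 0, p$min_identity > 0, p$min_identity <= 100,
    p$min_stability >= 0, p$punp_threshold >= 0, p$punp_threshold <= 1,
    p$fold_window > 0, p$fold_span > 0, p$fold_span <= p$fold_window,
    p$enrichment_min_fold >= 0, p$min_target_hits >= 0, p$n_shuffle >= 1
  )
  structure(p, class = "screen_params")
}

#' @export
print.screen_params <- function(x, ...) {
  cat("<screen_params>\n")
  for (nm in names(x)) cat("  ", nm, ": ", format(x[[nm]]), "\n", sep = "")
  invisible(x)
}

# deterministic small sub-seed derived from the master seed and string ids;
# kept below 2^31 so it is always a valid R integer seed
derive_seed <- function(seed, ...) {
  ids <- paste(c(...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(ids)) h <- (h * 131 + v) %% 2147480009
  as.integer((as.numeric(seed) * 7919 + h + 1) %% 2147480009)
}
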