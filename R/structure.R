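# ---- energy model ----------------------------------------------------------

#' Simple additive base-pair energy model for local RNA folding
#'
#' A structure's free energy is the sum of its base-pair energies; the
#' Boltzmann ensemble weights structures by `exp(-E/kT)`. Allowed pairs are
#' GC/CG, AU/UA and the GU/UG wobble. This deliberately minimal model (no
#' nearest-neighbour stacking, lone pairs allowed, dangles ignored) is used
#' for the accessibility filter, whose downstream use is a binary 0.5 cut on
#' unpaired probabilities; it is fully verifiable against brute-force
#' ensemble enumeration.
#'
#' @param pair_energies Named numeric vector of pair energies (negative =
#'   stabilizing) for `GC`, `AU`, `GU`; symmetric pairs are implied.
#' @param min_hairpin Minimum number of unpaired bases in a hairpin loop.
#' @param kT Thermal energy in the same units as `pair_energies`.
#' @return An object of class `energy_model`.
#' @examples
#' energy_model()
#' @export
energy_model <- function(pair_energies = c(GC = -3, AU = -2, GU = -1),
                         min_hairpin = 3L, kT = 0.616) {
  stopifnot(min_hairpin >= 0, kT > 0,
            all(c("GC", "AU", "GU") %in% names(pair_energies)))
  q <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                       c("A", "C", "G", "U")))
  set_pair <- function(b1, b2, e) {
    q[b1, b2] <<- exp(-e / kT)
    q[b2, b1] <<- exp(-e / kT)
  }
  set_pair("G", "C", pair_energies[["GC"]])
  set_pair("A", "U", pair_energies[["AU"]])
  set_pair("G", "U", pair_energies[["GU"]])
  structure(list(pair_energies = pair_energies,
                 min_hairpin = as.integer(min_hairpin),
                 kT = kT, q = q),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model> pair energies:",
      paste(names(x$pair_energies), x$pair_energies, sep = "=", collapse = ", "),
      "| min hairpin", x$min_hairpin, "| kT", x$kT, "\n")
  invisible(x)
}

# ---- partition function ----------------------------------------------------

#' Base-pairing probability matrix of a sequence window
#'
#' McCaskill-style inside-outside dynamic programme over pseudoknot-free
#' structures with hairpin loops of at least `model$min_hairpin` unpaired
#' bases and base-pair span at most `max_span`, Boltzmann-weighted by summed
#' pair energies. Intended for windows up to a few hundred nt.
#'
#' @param seq RNA sequence (`T` read as `U`; ambiguous bases never pair).
#' @param model [energy_model()].
#' @param max_span Maximum base-pair span `j - i` (default: no constraint
#'   beyond the window length).
#' @return A symmetric matrix `P` with `P[i, j]` the probability that bases
#'   `i` and `j` are paired in the ensemble; row sums are at most 1.
#' @examples
#' p <- pair_probabilities("GGGAAACCC")
#' p[1, 9] > 0
#' @export
pair_probabilities <- function(seq, model = energy_model(), max_span = NULL) {
  codes <- rna_codes(seq)
  n <- length(codes)
  if (is.null(max_span)) max_span <- n
  res <- mccaskill_window_cpp(codes, model$q, model$min_hairpin,
                              as.integer(max_span))
  res$p
}

#' Windowed unpaired-probability profile of a transcript
#'
#' The RNAplfold-style accessibility profile: windows of length
#' `min(params$fold_window, length)` slide along the transcript with step 1;
#' in each window per-base unpaired probabilities `1 - sum_j P(i, j)` are
#' computed from the window's Boltzmann ensemble (pair span capped at
#' `params$fold_span`), and the profile value at a position is the arithmetic
#' mean over all windows containing it. A value of 1 denotes a fully exposed
#' base, 0 a base always engaged in Watson-Crick pairing.
#'
#' @param seq Transcript sequence (RNA alphabet).
#' @param params [screen_params()] supplying `fold_window` / `fold_span`.
#' @param model [energy_model()].
#' @return A tibble of class `accessibility_profile` with columns `pos`,
#'   `base`, `p_unp`, and attributes `window` and `span`.
#' @examples
#' prof <- unpaired_profile(strrep("A", 30))
#' all(prof$p_unp == 1)
#' @export
unpaired_profile <- function(seq, params = screen_params(),
                             model = energy_model()) {
  seq <- normalize_rna(seq)
  codes <- rna_codes(seq)
  prof <- punp_profile_cpp(codes, model$q, model$min_hairpin,
                           params$fold_span, params$fold_window)
  out <- tibble(
    pos = seq_along(codes),
    base = strsplit(seq, "", fixed = TRUE)[[1]],
    p_unp = as.numeric(prof)
  )
  structure(out, class = c("accessibility_profile", class(out)),
            window = params$fold_window, span = params$fold_span)
}

#' Extract accessible regions from an unpaired-probability profile
#'
#' Maximal runs of consecutive positions whose unpaired probability is at
#' least `threshold`. Regions are disjoint, sorted and not extendable.
#'
#' @param profile [unpaired_profile()] output (any tibble with `pos`,
#'   `p_unp`).
#' @param threshold Per-base unpaired-probability cutoff (default 0.5).
#' @return Tibble `start`, `end`, `length`, `mean_punp` in transcript
#'   coordinates.
#' @export
accessible_regions <- function(profile, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  ok <- profile$p_unp >= threshold
  if (!any(ok)) {
    return(tibble(start = integer(), end = integer(), length = integer(),
                  mean_punp = numeric()))
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble(
    start = profile$pos[starts[keep]],
    end = profile$pos[ends[keep]],
    length = as.integer(ends[keep] - starts[keep] + 1),
    mean_punp = vapply(which(keep), function(k) {
      mean(profile$p_unp[starts[k]:ends[k]])
    }, numeric(1))
  )
}

#' Count triplex hits whose TFO lies in accessible RNA
#'
#' A hit is accessibility-supported when its TFO interval on the transcript
#' shares at least one base with an accessible region.
#'
#' @param hits Hit tibble with `tfo_start` / `tfo_end` transcript
#'   coordinates.
#' @param regions [accessible_regions()] output for the same transcript.
#' @return A list with `count` and the annotated `hits` (columns
#'   `accessible`, `region_ids`).
#' @export
overlap_hits_accessible <- function(hits, regions) {
  if (nrow(hits) == 0) {
    return(list(count = 0L, hits = mutate(hits, accessible = logical(0),
                                          region_ids = character(0))))
  }
  if (is.null(regions) || nrow(regions) == 0) {
    return(list(count = 0L, hits = mutate(hits, accessible = FALSE,
                                          region_ids = "")))
  }
  lab <- vapply(seq_len(nrow(hits)), function(k) {
    j <- which(pmax(hits$tfo_start[k], regions$start) <=
                 pmin(hits$tfo_end[k], regions$end))
    paste(sprintf("%d-%d", regions$start[j], regions$end[j]), collapse = ";")
  }, character(1))
  out <- mutate(hits, accessible = lab != "", region_ids = lab)
  list(count = sum(out$accessible), hits = out)
}
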