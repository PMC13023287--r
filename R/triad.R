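#' Hoogsteen triad stability table
#'
#' A triad table assigns a stability weight in `{0, 1, 2}` to every
#' combination of third-strand RNA base, duplex base (given as the base on the
#' scanned, purine-rich strand of the target duplex) and third-strand
#' orientation. Weight 2 marks canonical triads, weight 1 documented weak
#' triads, 0 everything else.
#'
#' The default table encodes the canonical parallel (pyrimidine-motif) triads
#' U·A:T and C·G:C with weight 2 and the weak parallel triads G·G:C and G·T:A
#' with weight 1; antiparallel (purine-motif) triads A·A:T, G·G:C and U·A:T
#' carry weight 2 and C·A:T weight 1. The same table ships as an editable
#' key-value file at `system.file("extdata", "triad_table.tsv", package =
#' "triplexscreen")` and can be modified and re-read with
#' [read_triad_table()].
#'
#' @return A tibble with columns `orientation` (`"parallel"`/`"antiparallel"`),
#'   `rna` (A/C/G/U), `dna` (purine-strand base A/C/G/T) and `weight`,
#'   containing all 2 x 4 x 4 keys.
#' @examples
#' tt <- default_triad_table()
#' sum(tt$weight)  # 13: 6 parallel + 7 antiparallel
#' @export
default_triad_table <- function() {
  full <- tidyr::expand_grid(
    orientation = c("parallel", "antiparallel"),
    rna = c("A", "C", "G", "U"),
    dna = c("A", "C", "G", "T")
  )
  nz <- tibble(
    orientation = c("parallel", "parallel", "parallel", "parallel",
                    "antiparallel", "antiparallel", "antiparallel", "antiparallel"),
    rna = c("U", "C", "G", "G", "A", "G", "U", "C"),
    dna = c("A", "G", "G", "T", "A", "G", "A", "A"),
    weight = c(2, 2, 1, 1, 2, 2, 2, 1)
  )
  out <- left_join(full, nz, by = c("orientation", "rna", "dna"))
  out$weight[is.na(out$weight)] <- 0
  out
}

#' Read a triad table from a key-value config file
#'
#' The file is tab-separated with columns `orientation`, `rna`, `dna`,
#' `weight`; omitted keys default to weight 0. Weights must lie in `[0, 2]`.
#'
#' @param path Path to the TSV file.
#' @return A full triad-table tibble (see [default_triad_table()]).
#' @export
read_triad_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  stopifnot(all(c("orientation", "rna", "dna", "weight") %in% names(x)))
  if (any(x$weight < 0 | x$weight > 2)) {
    abort("triad weights must lie in [0, 2]")
  }
  base <- default_triad_table()
  base$weight <- NULL
  out <- left_join(base, x[, c("orientation", "rna", "dna", "weight")],
                   by = c("orientation", "rna", "dna"))
  out$weight[is.na(out$weight)] <- 0
  out
}

# internal: triad table as a pair of 4x4 numeric matrices
# rows = RNA base ACGU, cols = scanned duplex strand base ACGT
triad_matrices <- function(table = default_triad_table()) {
  mk <- function(ori) {
    m <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                         c("A", "C", "G", "T")))
    sub <- table[table$orientation == ori, ]
    m[cbind(match(sub$rna, rownames(m)), match(sub$dna, colnames(m)))] <- sub$weight
    m
  }
  list(parallel = mk("parallel"), antiparallel = mk("antiparallel"))
}

#' Stability weight of a single Hoogsteen triad
#'
#' @param rna_base Third-strand RNA base (`A`, `C`, `G` or `U`; `T` is
#'   accepted and read as `U`).
#' @param duplex_pair Watson-Crick duplex pair written with the scanned-strand
#'   base first (e.g. `"A:T"`, `"G:C"`), or just the scanned-strand base.
#' @param orientation `"parallel"` or `"antiparallel"`.
#' @param table A triad table, see [default_triad_table()].
#' @return Numeric weight in `[0, 2]`; vectorized over the base arguments.
#' @examples
#' triad_weight("U", "A:T", "parallel")      # 2, canonical T.A-T triad
#' triad_weight("A", "G:C", "parallel")      # 0
#' @export
triad_weight <- function(rna_base, duplex_pair, orientation,
                         table = default_triad_table()) {
  orientation <- match.arg(orientation, c("parallel", "antiparallel"))
  rna <- toupper(as.character(rna_base))
  rna[rna == "T"] <- "U"
  dna <- toupper(substr(gsub(":", "", as.character(duplex_pair)), 1, 1))
  bad_r <- !rna %in% c("A", "C", "G", "U")
  bad_d <- !dna %in% c("A", "C", "G", "T")
  if (any(bad_r | bad_d)) {
    abort(sprintf("non-nucleotide symbol at position %d: rna='%s', duplex='%s'",
                  which(bad_r | bad_d)[1], rna[which(bad_r | bad_d)[1]],
                  dna[which(bad_r | bad_d)[1]]))
  }
  m <- triad_matrices(table)[[orientation]]
  m[cbind(match(rna, rownames(m)), match(dna, colnames(m)))]
}
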