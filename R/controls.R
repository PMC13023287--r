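# ---- sequence shuffles -----------------------------------------------------

#' Shuffle a sequence preserving base or dinucleotide composition
#'
#' The permutation-null generator. `mononucleotide` draws a seeded uniform
#' permutation of the letters (base histogram preserved exactly);
#' `dinucleotide` performs an Altschul-Erickson shuffle: a random Eulerian
#' walk on the dinucleotide transition multigraph, preserving the dinucleotide
#' multiset (and hence base composition and first/last letters) exactly.
#' Identical `seed` and input always reproduce the same output.
#'
#' @param seq Character sequence (any alphabet).
#' @param seed Integer seed.
#' @param mode `"mononucleotide"` or `"dinucleotide"`.
#' @return The shuffled sequence (single string).
#' @examples
#' shuffle_sequence("AACCGGTT", seed = 1)
#' @export
shuffle_sequence <- function(seq, seed,
                             mode = c("mononucleotide", "dinucleotide")) {
  mode <- match.arg(mode)
  if (nchar(seq) == 0) abort("cannot shuffle an empty sequence")
  if (nchar(seq) == 1) return(seq)
  withr::with_seed(as.integer(seed), {
    v <- strsplit(seq, "", fixed = TRUE)[[1]]
    if (mode == "mononucleotide") {
      paste(v[sample.int(length(v))], collapse = "")
    } else {
      paste(altschul_erickson(v), collapse = "")
    }
  })
}

# Altschul-Erickson dinucleotide shuffle: permute, for each vertex, the order
# of its outgoing edges, and accept the ordering iff the walk from the first
# letter consumes every edge (a valid Eulerian path). Rejection sampling over
# edge orderings yields a uniform-ish random Eulerian path; expected retries
# are small for nucleotide alphabets.
altschul_erickson <- function(v) {
  n <- length(v)
  from <- v[-n]
  to <- v[-1]
  verts <- unique(v)
  out_edges <- split(to, factor(from, levels = verts))
  repeat {
    shuffled <- lapply(out_edges, function(e) e[sample.int(length(e))])
    ptr <- stats::setNames(rep(1L, length(verts)), verts)
    walk <- character(n)
    walk[1] <- v[1]
    cur <- v[1]
    ok <- TRUE
    for (i in 2:n) {
      es <- shuffled[[cur]]
      p <- ptr[[cur]]
      if (is.null(es) || p > length(es)) { ok <- FALSE; break }
      ptr[[cur]] <- p + 1L
      cur <- es[p]
      walk[i] <- cur
    }
    if (ok) return(walk)
  }
}

# ---- enrichment ------------------------------------------------------------

#' Fold enrichment of the target TFO1 count over the negative control
#'
#' `observed / control`, with the conventions: both zero gives 1.0 (no signal
#' anywhere), a positive count over a zero control gives `Inf` (signal with a
#' silent control).
#'
#' @param observed,control Non-negative TFO1 overlapping-triplex counts.
#' @return Numeric ratio (reported to one decimal in text output).
#' @examples
#' enrichment_ratio(22, 5)  # 4.4
#' @export
enrichment_ratio <- function(observed, control) {
  if (any(observed < 0) || any(control < 0)) {
    abort("triplex counts cannot be negative")
  }
  out <- ifelse(control == 0,
                ifelse(observed > 0, Inf, 1.0),
                observed / control)
  as.numeric(out)
}

# ---- permutation / negative controls --------------------------------------

#' Run the triplex scan on a pair together with its permutation and
#' biological controls
#'
#' Four scan + TFO1 runs under identical parameters: the real transcript
#' against the real target promoter, a shuffled transcript against the real
#' target, the real transcript against a shuffled target, and the real
#' transcript against an unrelated control promoter (ideally from a different
#' chromosome). The four TFO1 overlapping-triplex counts are the
#' specificity evidence for the pair. Shuffle seeds are derived
#' deterministically from `params$seed` and the pair identifiers; with
#' `params$n_shuffle > 1` each null count is the median over replicates.
#'
#' @param gene_id,transcript_id Pair identifiers (used for seed derivation
#'   and reporting).
#' @param promoter_seq Target promoter sequence (forward strand DNA).
#' @param transcript_seq lncRNA transcript sequence (RNA alphabet).
#' @param control_promoter_seq Control promoter sequence; required.
#' @param params [screen_params()].
#' @param table Triad table.
#' @param promoter_origin,promoter_chrom Genomic origin and chromosome of the
#'   target promoter (for hit coordinates).
#' @return A list with `counts` (one-row tibble: `gene_id`, `transcript_id`,
#'   `target`, `shuffled_lncrna`, `shuffled_target`, `control`,
#'   `enrichment`), `target_tfo1` (the [select_tfo1()] cluster of the real
#'   run) and `target_hits` (full hit tibble of the real run).
#' @export
run_screen_with_controls <- function(gene_id, transcript_id,
                                     promoter_seq, transcript_seq,
                                     control_promoter_seq,
                                     params = screen_params(),
                                     table = default_triad_table(),
                                     promoter_origin = 1,
                                     promoter_chrom = "chr") {
  if (is.null(control_promoter_seq) || is.na(control_promoter_seq) ||
      nchar(control_promoter_seq) == 0) {
    abort(paste("a control promoter sequence is required: supply the promoter",
                "of an unrelated gene (preferably on another chromosome)"))
  }
  count_of <- function(rna, dna, origin = 1, chrom = "ctrl") {
    select_tfo1(scan_triplexes(rna, dna, params, table, origin, chrom))$hit_count
  }
  null_count <- function(which, fn) {
    reps <- vapply(seq_len(params$n_shuffle), function(r) {
      fn(derive_seed(params$seed, gene_id, transcript_id, which, r))
    }, numeric(1))
    as.integer(round(stats::median(reps)))
  }

  target_hits <- scan_triplexes(transcript_seq, promoter_seq, params, table,
                                promoter_origin, promoter_chrom)
  tfo1 <- select_tfo1(target_hits)

  shuf_rna <- null_count("lncrna", function(s) {
    count_of(shuffle_sequence(transcript_seq, s, params$shuffle_mode),
             promoter_seq)
  })
  shuf_dna <- null_count("target", function(s) {
    count_of(transcript_seq,
             shuffle_sequence(promoter_seq, s, params$shuffle_mode))
  })
  ctrl <- count_of(transcript_seq, control_promoter_seq)

  counts <- tibble(
    gene_id = gene_id, transcript_id = transcript_id,
    target = tfo1$hit_count,
    shuffled_lncrna = shuf_rna,
    shuffled_target = shuf_dna,
    control = as.integer(ctrl),
    enrichment = enrichment_ratio(tfo1$hit_count, ctrl)
  )
  list(counts = counts, target_tfo1 = tfo1, target_hits = target_hits)
}
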