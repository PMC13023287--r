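# Synthetic locus-set generator: ground-truth inputs with the statistical
# structure the screen assumes, replacing genome-database downloads in every
# test. One chromosome per target gene; lncRNA loci upstream within the cis
# window; planted homopurine TTS tracts in promoters with triad-matched TFOs
# embedded in the transcripts, either in unstructured (exposed) or
# self-pairing (buried) context; CpG-enriched island plants overlapping the
# TTS; SNPs placed inside or outside lncRNA loci.

#' Configuration for the synthetic locus-set generator
#'
#' Defaults describe the screen's reference conditions: a handful of
#' single-gene chromosomes, mammalian-like background GC (0.42), planted
#' target sites of 50-150 bp (the size range of observed triplex interaction
#' sites), transcripts of 500 nt (above the 200 nt lncRNA floor), and one
#' lncRNA per gene. Per-gene vectors (`planted`, `accessibility_class`,
#' `island_plant`, `snp_plant`) are recycled to `n_genes`.
#'
#' @param n_genes Number of target genes (one chromosome each).
#' @param n_lncrnas_per_gene lncRNA loci per gene.
#' @param chrom_length Chromosome length in bp.
#' @param background_gc Background GC fraction for genomic sequence.
#' @param transcript_length Transcript length (nt), > 200.
#' @param tts_length_range Planted TTS length range (nt), drawn uniformly.
#' @param tts_length Optional fixed TTS length overriding the range.
#' @param planted_identity Percent identity of exposed planted TFOs
#'   (mismatches are placed at seeded, non-adjacent positions).
#' @param planted Logical per gene: is a TFO/TTS planted?
#' @param accessibility_class `"exposed"` or `"buried"` per gene.
#' @param island_plant Logical per gene: plant a CpG island over the TTS?
#' @param snp_plant `"inside"`, `"outside"` or `"none"` per gene.
#' @param seed Integer seed; identical configurations and seeds produce
#'   byte-identical outputs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 4L,
                       n_lncrnas_per_gene = 1L,
                       chrom_length = 120001L,
                       background_gc = 0.42,
                       transcript_length = 500L,
                       tts_length_range = c(50L, 150L),
                       tts_length = NULL,
                       planted_identity = 100,
                       planted = c(TRUE, TRUE, TRUE, FALSE),
                       accessibility_class = c("exposed", "buried",
                                               "exposed", "exposed"),
                       island_plant = c(TRUE, TRUE, FALSE, FALSE),
                       snp_plant = c("inside", "outside", "none", "none"),
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_lncrnas_per_gene = as.integer(n_lncrnas_per_gene),
    chrom_length = as.integer(chrom_length),
    background_gc = background_gc,
    transcript_length = as.integer(transcript_length),
    tts_length_range = as.integer(tts_length_range),
    tts_length = if (is.null(tts_length)) NULL else as.integer(tts_length),
    planted_identity = planted_identity,
    planted = rep_len(planted, n_genes),
    accessibility_class = rep_len(accessibility_class, n_genes),
    island_plant = rep_len(island_plant, n_genes),
    snp_plant = rep_len(snp_plant, n_genes),
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$n_genes >= 1, cfg$background_gc > 0, cfg$background_gc < 1,
    cfg$transcript_length > 200,
    all(cfg$accessibility_class %in% c("exposed", "buried")),
    all(cfg$snp_plant %in% c("inside", "outside", "none")),
    cfg$tts_length_range[1] >= 50, cfg$tts_length_range[2] >= cfg$tts_length_range[1],
    cfg$tts_length_range[2] <= 500
  )
  structure(cfg, class = "sim_config")
}

random_dna <- function(n, gc = 0.42) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# does any 50-bp window carry an A- or T-density high enough to act as a
# chance triplex target site (>= 56%)?
has_at_patch <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(v) < 50) return(FALSE)
  cum <- function(x) c(0, cumsum(x))
  ca <- cum(v == "A"); ct <- cum(v == "T")
  idx <- seq_len(length(v) - 49)
  max(ca[idx + 50] - ca[idx]) >= 28 || max(ct[idx + 50] - ct[idx]) >= 28
}

# background scanned by the screen (promoters, control) must not contain
# chance A/T tracts dense enough to be real U.A:T / A.A:T triplex targets:
# a competing true site in the background would make the planted ground
# truth ill-defined. Rejection-resampled i.i.d. background.
clean_dna <- function(n, gc = 0.42) {
  repeat {
    seq <- random_dna(n, gc)
    if (!has_at_patch(seq)) return(seq)
  }
}

# A-rich transcript background: scarce G keeps incidental Watson-Crick
# structure away from exposed plants, and modest C keeps the base composition
# of planted transcripts low enough in pyrimidines that shuffled copies do
# not rematch the homopurine target tract by composition alone
random_rna_background <- function(n) {
  paste(sample(c("A", "C", "U", "G"), n, replace = TRUE,
               prob = c(0.63, 0.10, 0.22, 0.05)), collapse = "")
}

replace_substr <- function(seq, start, replacement) {
  paste0(substr(seq, 1, start - 1), replacement,
         substr(seq, start + nchar(replacement), nchar(seq)))
}

#' Plant a triplex target site into a duplex sequence
#'
#' Writes a homopurine (poly-G) tract of the requested length into the given
#' position of a promoter sequence and returns the triad-matched RNA stretch
#' (the TFO) that binds it at exactly the configured identity: matched
#' positions carry the canonical weight-2 triad for the chosen orientation
#' (C·G:C parallel, G·G:C antiparallel), mismatches are placed at seeded
#' random non-adjacent positions and use a base with triad weight 0.
#'
#' @param promoter_seq Target sequence (DNA alphabet).
#' @param position 1-based start of the planted tract.
#' @param length Tract length (nt).
#' @param identity Planted identity in percent; values below the screen's
#'   `min_identity` make the plant undetectable by design (a warning is
#'   emitted).
#' @param orientation `"parallel"` or `"antiparallel"`.
#' @param table Triad table (used to pick match/mismatch bases).
#' @param seed Seed for mismatch placement.
#' @param min_identity Screen identity threshold used for the warning.
#' @return List with `dna` (modified sequence), `tfo` (RNA, 5'->3'),
#'   `tts_start`, `tts_end` (positions within `promoter_seq`).
#' @export
plant_tts <- function(promoter_seq, position, length, identity = 100,
                      orientation = c("parallel", "antiparallel"),
                      table = default_triad_table(), seed = 1L,
                      min_identity = 60) {
  orientation <- match.arg(orientation)
  if (position < 1 || position + length - 1 > nchar(promoter_seq)) {
    abort("planted tract does not fit inside the target sequence")
  }
  if (identity < min_identity) {
    warn(sprintf("planted identity %.0f%% is below the screen threshold %.0f%%; the plant will be undetectable by design",
                 identity, min_identity))
  }
  tract <- strrep("G", length)
  match_base <- if (orientation == "parallel") "C" else "G"
  mismatch_base <- if (orientation == "parallel") "A" else "C"
  n_mm <- round(length * (1 - identity / 100))
  tfo_fwd <- rep(match_base, length)
  if (n_mm > 0) {
    withr::with_seed(as.integer(seed), {
      pos <- sort(sample(seq(1, length, by = 2), n_mm))
    })
    tfo_fwd[pos] <- mismatch_base
  }
  # the TFO aligns 3'->5' along the purine strand in antiparallel orientation
  tfo <- if (orientation == "parallel") {
    paste(tfo_fwd, collapse = "")
  } else {
    paste(rev(tfo_fwd), collapse = "")
  }
  list(
    dna = replace_substr(promoter_seq, position, tract),
    tfo = normalize_rna(tfo),
    tts_start = position,
    tts_end = position + length - 1
  )
}

# Buried plants: the transcript carries a self-folding tract of C and G
# blocks bound to a poly-G TTS in parallel register (C reads G:C at weight
# 2, G reads G:C at weight 1; identity 100, mean stability ~1.5 at the
# plant register). Design rules learnt from the scan's window algebra:
# (i) a single central C8 block makes the window anchored on it
# ([C8 G7 C7 G7 C7 G7 C7], 29 C positions) the unique stability-maximal
# qualifying window wherever it is reachable, so full-register hits stack
# at the centre of the 134-bp target and the TFO1 density peak lies where
# boundary-register hits (confined to within 50 bp of a target edge)
# cannot reach; (ii) the tract is flanked by U21 blocks that score nothing
# against any DNA the scan can align them with, exceed the 20-position
# zero-padding budget that the 60% identity floor allows a window, and
# pair abundant background adenosines - so windows that must pad to reach
# the 50-nt minimum pad into folded RNA, never into the accessible poly-A
# guards; (iii) the C/G edge blocks have pairing partners on both sides
# (wobble to the U21, Watson-Crick inward), so no hairpin loop is pinned
# onto a position a hit can contain. Poly-C DNA spacers isolate the TTS
# (the C column scores no triad in either orientation).
buried_margin <- 21L  # fold extent beyond the TTS image on each side

buried_tfo <- function() {
  wing <- strrep(paste0(strrep("G", 7), strrep("C", 7)), 4)
  paste0(strrep("U", 21),
         wing, strrep("G", 7), strrep("C", 8), strrep("G", 7),
         chartr("CG", "GC", wing),
         strrep("U", 21))
}

# Buried targets use a fixed 134-bp site at the top of the observed
# 51-150 bp size range: burying a triplex target takes extensive secondary
# structure, and a long target keeps boundary-register hits (whose windows
# may pad toward the transcript guards) away from the central density peak
# that defines the TFO1 cluster.
buried_length <- function(length) {
  134L
}

island_flank <- 300L
tts_gap <- 20L    # poly-C DNA spacer between the TTS and its island flanks
tfo_guard <- 15L  # transcript guard length on each side of a planted TFO

#' Simulate a ground-truth locus set
#'
#' Generates a complete input set for the screen: genome (one chromosome per
#' gene plus a control chromosome), GFF3 annotation with genes and lncRNA
#' loci inside the cis windows, transcript sequences, SNPs, an unrelated
#' control promoter, optionally planted CpG islands, and a ground-truth
#' table. For planted pairs a poly-G TTS is written into the promoter
#' (between 3500 bp upstream and 1500 bp downstream of the TSS) and the
#' triad-complementary TFO is embedded in the transcript inside 15-nt
#' poly-A guards (triad weight 0 at a poly-G target in every orientation,
#' so detected hits coincide with the tract): a pure pyrimidine tract in
#' unstructured A-rich context for `exposed` plants, or, for `buried`
#' plants, the central 134-bp core of a self-folding C/G block tract whose
#' U21 flanks keep every reportable window inside folded RNA (see the
#' methods vignette for the construct's design rules). The TTS is isolated
#' by 20-bp poly-C spacers; islands are planted as CpG-repeat flanks beyond
#' them (total span about 700-800 bp). All output is deterministic under
#' `config$seed`.
#'
#' @param config [sim_config()].
#' @param dir Optional output directory; when given, writes `genome.fa`,
#'   `annotation.gff3`, `transcripts.fa`, `snps.vcf`,
#'   `control_promoter.fa`, `islands.bed` (if any island planted),
#'   `truth.tsv` and `sim_config.json` (readable with [read_locus_set()]).
#' @return The locus set as a list (`genes`, `lncrnas`, `snps`, `genome`,
#'   `islands`, `control`, `truth`), invisibly when `dir` is given.
#' @export
simulate_locus_set <- function(config = sim_config(), dir = NULL) {
  params <- screen_params()
  prom_up <- params$promoter_upstream
  prom_dn <- params$promoter_downstream

  tts_len_of <- function() {
    if (!is.null(config$tts_length)) config$tts_length
    else sample(seq(config$tts_length_range[1], config$tts_length_range[2]), 1)
  }

  # feasibility: island flanks, spacers and maximal tract must fit in the
  # promoter, and the fold plus guards in the transcript
  max_len <- if (!is.null(config$tts_length)) config$tts_length
             else config$tts_length_range[2]
  if (max_len + 2 * island_flank + 2 > prom_up + prom_dn + 1) {
    abort("planted TTS plus island flanks would not fit inside the promoter region")
  }
  if (config$transcript_length <
        max_len + 2 * (buried_margin + tfo_guard) + 60) {
    abort("transcript_length too short to host the planted TFO and its guards")
  }

  out <- withr::with_seed(config$seed, {
    tss <- (config$chrom_length + 1L) %/% 2L
    genes <- list(); lncrnas <- list(); snps <- list()
    genome <- character(0); islands <- list(); truth <- list()

    for (i in seq_len(config$n_genes)) {
      chrom <- sprintf("chr%d", i)
      gene_id <- sprintf("GENE%02d", i)
      chromseq <- random_dna(config$chrom_length, config$background_gc)
      gene_end <- min(tss + 1999L, config$chrom_length)
      prom_start <- tss - prom_up
      prom_end <- tss + prom_dn
      chromseq <- replace_substr(chromseq, prom_start,
                                 clean_dna(prom_end - prom_start + 1L,
                                           config$background_gc))

      planted <- config$planted[i]
      class_i <- config$accessibility_class[i]
      island_i <- config$island_plant[i] && planted
      tts_start <- NA_real_; tts_end <- NA_real_
      isl_start <- NA_real_; isl_end <- NA_real_
      tfo_seq <- NULL; tts_len <- NA_integer_

      if (planted) {
        tts_len <- tts_len_of()
        if (class_i == "buried") tts_len <- buried_length(tts_len)
        margin <- island_flank + tts_gap
        lo <- prom_start + margin
        hi <- prom_end - tts_len + 1L - margin
        tts_start <- lo + sample.int(hi - lo + 1L, 1) - 1L
        tts_end <- tts_start + tts_len - 1L
        if (class_i == "exposed") {
          pl <- plant_tts(chromseq, tts_start, tts_len,
                          identity = config$planted_identity,
                          orientation = "parallel",
                          seed = derive_seed(config$seed, gene_id, "mm"),
                          min_identity = params$min_identity)
          chromseq <- pl$dna
          tfo_seq <- pl$tfo
        } else {
          chromseq <- replace_substr(chromseq, tts_start, strrep("G", tts_len))
          tfo_seq <- buried_tfo()
        }
        # the C column scores no triad in either orientation, so the
        # spacers stop boundary-register windows from recruiting island
        # bases across the transcript guards
        chromseq <- replace_substr(chromseq, tts_start - tts_gap,
                                   strrep("C", tts_gap))
        chromseq <- replace_substr(chromseq, tts_end + 1L,
                                   strrep("C", tts_gap))
        if (island_i) {
          chromseq <- replace_substr(chromseq, tts_start - margin,
                                     strrep("CG", island_flank / 2))
          chromseq <- replace_substr(chromseq, tts_end + tts_gap + 1L,
                                     strrep("CG", island_flank / 2))
          isl_start <- tts_start - margin
          isl_end <- tts_end + margin
          islands[[length(islands) + 1]] <- tibble(
            chrom = chrom, start = isl_start, end = isl_end,
            name = sprintf("island_%s", gene_id), source = "planted")
        }
      }
      genome[chrom] <- chromseq
      genes[[i]] <- tibble(gene_id = gene_id, symbol = gene_id, chrom = chrom,
                           start = tss, end = gene_end, strand = "+", tss = tss)

      for (j in seq_len(config$n_lncrnas_per_gene)) {
        lnc_gene <- sprintf("LNCG%02d_%d", i, j)
        lnc_tx <- sprintf("LNCT%02d_%d", i, j)
        label <- sprintf("lnc%02d_%d", i, j)
        d_edge <- round(runif(1, 1500, 45000))
        locus_end <- tss - d_edge
        locus_start <- locus_end - config$transcript_length + 1L

        tx <- random_rna_background(config$transcript_length)
        tfo_start <- NA_real_; tfo_end <- NA_real_
        if (planted && j == 1) {
          insert <- paste0(strrep("A", tfo_guard), tfo_seq,
                           strrep("A", tfo_guard))
          lo_t <- 25L
          hi_t <- config$transcript_length - nchar(insert) - 25L
          pre <- lo_t + sample.int(hi_t - lo_t + 1L, 1) - 1L
          tx <- replace_substr(tx, pre + 1L, insert)
          off <- if (class_i == "buried") buried_margin else 0L
          tfo_start <- pre + tfo_guard + off + 1L
          tfo_end <- tfo_start + tts_len - 1L
        }
        lncrnas[[length(lncrnas) + 1]] <- tibble(
          gene_id = lnc_gene, transcript_id = lnc_tx, label = label,
          chrom = chrom, start = locus_start, end = locus_end,
          strand = "+", seq = tx)

        if (j == 1 && config$snp_plant[i] != "none") {
          pos <- if (config$snp_plant[i] == "inside") {
            locus_start + config$transcript_length %/% 2L
          } else {
            tss + 30000L
          }
          snps[[length(snps) + 1]] <- tibble(
            snp_id = sprintf("SNP%02d", i), chrom = chrom, pos = pos)
        }

        if (j == 1) {
          # an exposed planted tract of >= 50 nt yields overlapping hits at
          # every register with >= min_identity percent of the window inside
          # the tract, i.e. about 2*(len - 30) + 1 >= 41 overlapping
          # triplexes, which clears the density criterion with a wide margin
          intended <- if (!planted) "rejected" else {
            passes <- class_i == "exposed" && island_i &&
              config$planted_identity >= params$min_identity
            if (passes) "high_confidence" else "partial"
          }
          truth[[length(truth) + 1]] <- tibble(
            pair_id = paste(gene_id, label, sep = "-"),
            gene_id = gene_id, transcript_id = lnc_tx, label = label,
            planted = planted,
            tts_start = tts_start, tts_end = tts_end,
            tfo_start = tfo_start, tfo_end = tfo_end,
            accessibility_class = if (planted) class_i else NA_character_,
            island_start = isl_start, island_end = isl_end,
            snp_pos = if (config$snp_plant[i] == "inside") {
              locus_start + config$transcript_length %/% 2L
            } else NA_real_,
            intended_tier = intended)
        }
      }
    }

    control_seq <- clean_dna(5001L, config$background_gc)
    list(
      genes = bind_rows(genes),
      lncrnas = bind_rows(lncrnas),
      snps = if (length(snps)) bind_rows(snps) else
        tibble(snp_id = character(), chrom = character(), pos = numeric()),
      genome = genome,
      islands = if (length(islands)) bind_rows(islands) else NULL,
      control = list(seq = control_seq, chrom = "chrC", origin = 1),
      truth = bind_rows(truth)
    )
  })

  if (!is.null(dir)) {
    write_locus_set(out, config, dir)
    return(invisible(out))
  }
  out
}

# write the generator's output in the formats the pipeline reads
write_locus_set <- function(locus, config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(stats::setNames(locus$genome, names(locus$genome)),
              file.path(dir, "genome.fa"))
  write_fasta(stats::setNames(locus$lncrnas$seq, locus$lncrnas$transcript_id),
              file.path(dir, "transcripts.fa"))
  write_fasta(stats::setNames(
    locus$control$seq,
    sprintf("CONTROL chrom=%s origin=%d", locus$control$chrom,
            as.integer(locus$control$origin))),
    file.path(dir, "control_promoter.fa"))

  g <- locus$genes
  l <- distinct(locus$lncrnas, .data$gene_id, .data$chrom, .data$start,
                .data$end, .data$strand)
  lt <- locus$lncrnas
  gr <- c(
    GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end), g$strand,
                           type = "gene", ID = g$gene_id, Name = g$symbol,
                           biotype = "protein_coding", Parent = NA_character_),
    GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$tss, g$end), g$strand,
                           type = "mRNA", ID = paste0(g$gene_id, ".t1"),
                           Name = g$symbol, biotype = NA_character_,
                           Parent = g$gene_id),
    GenomicRanges::GRanges(l$chrom, IRanges::IRanges(l$start, l$end), l$strand,
                           type = "gene", ID = l$gene_id, Name = l$gene_id,
                           biotype = "lncRNA", Parent = NA_character_),
    GenomicRanges::GRanges(lt$chrom, IRanges::IRanges(lt$start, lt$end),
                           lt$strand, type = "lnc_RNA", ID = lt$transcript_id,
                           Name = lt$label, biotype = NA_character_,
                           Parent = lt$gene_id)
  )
  rtracklayer::export(gr, file.path(dir, "annotation.gff3"), format = "gff3")

  write_snp_vcf(locus$snps, file.path(dir, "snps.vcf"),
                contigs = stats::setNames(nchar(locus$genome),
                                          names(locus$genome)))
  if (!is.null(locus$islands)) {
    write_bed_intervals(locus$islands, file.path(dir, "islands.bed"))
  }
  readr::write_tsv(locus$truth, file.path(dir, "truth.tsv"))
  jsonlite::write_json(unclass(config), file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
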