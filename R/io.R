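# Readers/writers for the standard formats the screen touches. All positional
# data are converted to the package's 1-based inclusive convention on read
# (BED is half-open 0-based on disk); sequences are case-folded to upper and
# U/T-normalized per molecule type (transcripts -> U, genomic -> T).

#' Read a FASTA file into a tibble
#'
#' @param path FASTA file (uncompressed).
#' @param molecule `"dna"` (U folded to T) or `"rna"` (T folded to U).
#' @return Tibble `name` (full header line), `seq`.
#' @export
read_fasta <- function(path, molecule = c("dna", "rna")) {
  molecule <- match.arg(molecule)
  set <- if (molecule == "dna") {
    Biostrings::readBStringSet(path)
  } else {
    Biostrings::readBStringSet(path)
  }
  seqs <- as.character(set)
  seqs <- if (molecule == "dna") normalize_dna(seqs) else normalize_rna(seqs)
  tibble(name = names(set), seq = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector, or tibble with `name` and `seq`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) {
    x <- stats::setNames(seqs$seq, seqs$name)
  } else {
    x <- seqs
  }
  set <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read target genes and lncRNA loci from a GFF3 annotation
#'
#' Target genes are `gene` features with `biotype=protein_coding`; their TSS
#' is the 5' end of the canonical (`mRNA`) transcript when one is annotated,
#' otherwise the gene's own 5' end, and can be overridden per gene through
#' `tss_table`. lncRNA loci are `gene` features with `biotype=lncRNA` whose
#' `lnc_RNA` children provide transcript ids and labels; the locus interval
#' is the gene feature's span.
#'
#' @param path GFF3 file.
#' @param tss_table Optional tibble (or TSV path) with columns `gene_id`,
#'   `tss` overriding derived TSS positions.
#' @return List of tibbles `genes` (`gene_id`, `symbol`, `chrom`, `start`,
#'   `end`, `strand`, `tss`) and `lncrnas` (`gene_id`, `transcript_id`,
#'   `label`, `chrom`, `start`, `end`, `strand`; transcript sequences come
#'   from a separate FASTA).
#' @export
read_gff3_annotation <- function(path, tss_table = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  if (!"biotype" %in% names(df)) {
    abort(sprintf("GFF3 '%s' lacks the biotype attribute used to separate target genes from lncRNA loci", path))
  }
  parent1 <- function(p) vapply(p, function(v) if (length(v)) v[[1]] else NA_character_, character(1))

  gdf <- df[df$type == "gene" & df$biotype == "protein_coding", , drop = FALSE]
  tdf <- df[df$type == "mRNA", , drop = FALSE]
  tss <- vapply(seq_len(nrow(gdf)), function(k) {
    tx <- tdf[parent1(tdf$Parent) == gdf$ID[k], , drop = FALSE]
    five_prime <- function(s, e, strand) if (strand == "-") e else s
    if (nrow(tx) == 0) {
      five_prime(gdf$start[k], gdf$end[k], gdf$strand[k])
    } else {
      tx <- tx[order(-(tx$end - tx$start), tx$ID), , drop = FALSE]
      five_prime(tx$start[1], tx$end[1], tx$strand[1])
    }
  }, numeric(1))
  genes <- tibble(
    gene_id = gdf$ID,
    symbol = if ("Name" %in% names(gdf)) gdf$Name else gdf$ID,
    chrom = gdf$seqnames, start = gdf$start, end = gdf$end,
    strand = gdf$strand, tss = tss
  )
  if (!is.null(tss_table)) {
    if (is.character(tss_table)) {
      tss_table <- readr::read_tsv(tss_table, show_col_types = FALSE)
    }
    i <- match(genes$gene_id, tss_table$gene_id)
    genes$tss[!is.na(i)] <- tss_table$tss[i[!is.na(i)]]
  }

  lgene <- df[df$type == "gene" & df$biotype == "lncRNA", , drop = FALSE]
  ltx <- df[df$type == "lnc_RNA", , drop = FALSE]
  if (nrow(ltx) > 0) {
    pid <- parent1(ltx$Parent)
    gi_ <- match(pid, lgene$ID)
    lncrnas <- tibble(
      gene_id = pid,
      transcript_id = ltx$ID,
      label = if ("Name" %in% names(ltx)) ltx$Name else ltx$ID,
      chrom = ifelse(is.na(gi_), ltx$seqnames, lgene$seqnames[gi_]),
      start = ifelse(is.na(gi_), ltx$start, lgene$start[gi_]),
      end = ifelse(is.na(gi_), ltx$end, lgene$end[gi_]),
      strand = ifelse(is.na(gi_), ltx$strand, lgene$strand[gi_])
    )
  } else {
    lncrnas <- tibble(gene_id = character(), transcript_id = character(),
                      label = character(), chrom = character(),
                      start = numeric(), end = numeric(), strand = character())
  }
  list(genes = genes, lncrnas = lncrnas)
}

#' Read BED intervals (0-based half-open on disk) as 1-based inclusive
#'
#' @param path BED file (3+ columns).
#' @return Tibble `chrom`, `start`, `end`, `name`, `source = "bed"` (BED
#'   islands bypass detector validation; the source flag records provenance).
#' @export
read_bed_intervals <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) as.character(gr$name) else "",
    source = "bed"
  )
}

#' Write intervals to BED (converting back to 0-based half-open)
#'
#' @param x Tibble with `chrom`, `start`, `end` and optional `name`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_bed_intervals <- function(x, path) {
  gr <- GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end))
  if ("name" %in% names(x)) gr$name <- x$name
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read SNP positions from a VCF or a 3-column TSV
#'
#' @param path `.vcf` file (positions only are used) or TSV with columns
#'   `snp_id`, `chrom`, `pos`.
#' @return Tibble `snp_id`, `chrom`, `pos`.
#' @export
read_vcf_positions <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fx <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    tibble(
      snp_id = ifelse(is.na(fx$ID) | fx$ID == ".",
                      paste0(fx$CHROM, ":", fx$POS), fx$ID),
      chrom = fx$CHROM,
      pos = as.numeric(fx$POS)
    )
  } else {
    x <- readr::read_tsv(path, show_col_types = FALSE)
    stopifnot(all(c("snp_id", "chrom", "pos") %in% names(x)))
    x[, c("snp_id", "chrom", "pos")]
  }
}

# minimal fixed-field VCF emission (plain text; vcfR's writer gzips, and the
# pipeline's outputs must stay plain text)
write_snp_vcf <- function(snps, path, contigs = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  if (!is.null(contigs)) {
    for (k in seq_along(contigs)) {
      writeLines(sprintf("##contig=<ID=%s,length=%d>",
                         names(contigs)[k], contigs[k]), con)
    }
  }
  writeLines("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", con)
  if (nrow(snps) > 0) {
    ref <- if ("ref" %in% names(snps)) snps$ref else "N"
    alt <- if ("alt" %in% names(snps)) snps$alt else "."
    writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                       snps$chrom, as.integer(snps$pos), snps$snp_id,
                       ref, alt), con)
  }
  invisible(path)
}

#' Read a simulated (or equivalently structured) locus set from a directory
#'
#' Expects the layout written by [simulate_locus_set()]: `genome.fa`,
#' `annotation.gff3`, `transcripts.fa`, `snps.vcf`, `control_promoter.fa`,
#' optional `islands.bed` and `truth.tsv`.
#'
#' @param dir Directory path.
#' @return A locus-set list: `genes`, `lncrnas` (with transcript `seq`),
#'   `snps`, `genome` (named character vector of chromosome sequences),
#'   `islands` (tibble or `NULL`), `control` (list `seq`, `chrom`, `origin`)
#'   and `truth` (tibble or `NULL`).
#' @export
read_locus_set <- function(dir) {
  need <- c("genome.fa", "annotation.gff3", "transcripts.fa", "snps.vcf",
            "control_promoter.fa")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0) {
    abort(sprintf("locus set at '%s' is missing: %s",
                  dir, paste(missing, collapse = ", ")))
  }
  genome_tbl <- read_fasta(file.path(dir, "genome.fa"), "dna")
  genome <- stats::setNames(genome_tbl$seq, sub(" .*", "", genome_tbl$name))
  ann <- read_gff3_annotation(file.path(dir, "annotation.gff3"))
  tx <- read_fasta(file.path(dir, "transcripts.fa"), "rna")
  tx$name <- sub(" .*", "", tx$name)
  lncrnas <- left_join(ann$lncrnas,
                       rename(tx, transcript_id = "name"),
                       by = "transcript_id")
  if (any(is.na(lncrnas$seq))) {
    abort(sprintf("transcript sequence missing for %s",
                  paste(lncrnas$transcript_id[is.na(lncrnas$seq)], collapse = ", ")))
  }
  snps <- read_vcf_positions(file.path(dir, "snps.vcf"))
  ctrl_tbl <- read_fasta(file.path(dir, "control_promoter.fa"), "dna")
  hdr <- ctrl_tbl$name[1]
  get_attr <- function(key, default) {
    m <- regmatches(hdr, regexec(paste0(key, "=([^ ]+)"), hdr))[[1]]
    if (length(m) == 2) m[2] else default
  }
  control <- list(seq = ctrl_tbl$seq[1],
                  chrom = get_attr("chrom", "control"),
                  origin = as.numeric(get_attr("origin", "1")))
  islands <- if (file.exists(file.path(dir, "islands.bed"))) {
    read_bed_intervals(file.path(dir, "islands.bed"))
  } else NULL
  truth <- if (file.exists(file.path(dir, "truth.tsv"))) {
    readr::read_tsv(file.path(dir, "truth.tsv"), show_col_types = FALSE)
  } else NULL
  list(genes = ann$genes, lncrnas = lncrnas, snps = snps, genome = genome,
       islands = islands, control = control, truth = truth)
}

# 1-based inclusive substring of a chromosome sequence
subseq_1based <- function(seq, start, end) {
  substr(seq, start, end)
}
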