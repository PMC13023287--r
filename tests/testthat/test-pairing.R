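make_random_annotation <- function(n_genes, n_lnc, span = 5e6) {
  genes <- tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chrom = sample(c("c1", "c2"), n_genes, replace = TRUE),
    tss = sample(span, n_genes), strand = "+"
  )
  lnc <- tibble::tibble(
    gene_id = sprintf("l%03d", seq_len(n_lnc)),
    transcript_id = sprintf("t%03d", seq_len(n_lnc)),
    label = sprintf("lnc%03d", seq_len(n_lnc)),
    chrom = sample(c("c1", "c2"), n_lnc, replace = TRUE),
    start = sample(span, n_lnc)
  )
  lnc$end <- lnc$start + sample(200:3000, n_lnc, replace = TRUE)
  lnc$strand <- "+"
  lnc$seq <- strrep("A", 300)
  list(genes = genes, lncrnas = lnc)
}

test_that("cis pairing equals brute-force all-pairs filtering", {
  set.seed(21)
  params <- screen_params()
  for (rep in 1:3) {
    ann <- make_random_annotation(40, 60)
    pairs <- find_cis_lncrnas(ann$genes, ann$lncrnas, params)
    # brute force: every (gene, lncRNA) with any window/locus overlap
    brute <- list()
    for (i in seq_len(nrow(ann$genes))) {
      for (j in seq_len(nrow(ann$lncrnas))) {
        g <- ann$genes[i, ]; l <- ann$lncrnas[j, ]
        ws <- max(1, g$tss - params$window_flank)
        we <- g$tss + params$window_flank
        if (g$chrom == l$chrom && max(ws, l$start) <= min(we, l$end)) {
          brute[[length(brute) + 1]] <- paste(g$gene_id, l$transcript_id)
        }
      }
    }
    expect_setequal(paste(pairs$gene_id, pairs$transcript_id),
                    unlist(brute))
    # every reported distance within the flank; sorted by gene then distance
    expect_true(all(pairs$distance <= params$window_flank))
    expect_identical(order(pairs$gene_id, pairs$distance, pairs$transcript_id),
                     seq_len(nrow(pairs)))
  }
})

test_that("pairing is translation invariant", {
  set.seed(8)
  ann <- make_random_annotation(15, 25)
  p1 <- find_cis_lncrnas(ann$genes, ann$lncrnas)
  shift <- 12345
  g2 <- dplyr::mutate(ann$genes, tss = tss + shift)
  l2 <- dplyr::mutate(ann$lncrnas, start = start + shift, end = end + shift)
  p2 <- find_cis_lncrnas(g2, l2)
  expect_equal(p1[, c("gene_id", "transcript_id", "distance")],
               p2[, c("gene_id", "transcript_id", "distance")])
})

test_that("window membership is overlap, not containment", {
  g <- tibble::tibble(gene_id = "g", chrom = "c", tss = 1e5, strand = "+")
  straddle <- tibble::tibble(gene_id = "l", transcript_id = "t", label = "lnc",
                             chrom = "c", start = 149000, end = 151000,
                             strand = "+", seq = strrep("A", 300))
  outside <- dplyr::mutate(straddle, start = 151000, end = 153000)
  expect_equal(nrow(find_cis_lncrnas(g, straddle)), 1)
  expect_equal(nrow(suppressMessages(find_cis_lncrnas(g, outside))), 0)
})

test_that("one canonical transcript is paired per lncRNA gene", {
  g <- tibble::tibble(gene_id = "g", chrom = "c", tss = 1e5, strand = "+")
  l <- tibble::tibble(
    gene_id = "l1", transcript_id = c("tA", "tB", "tC"),
    label = c("a", "b", "c"), chrom = "c", start = 90000, end = 92000,
    strand = "+", seq = c(strrep("A", 250), strrep("A", 400), strrep("A", 400)))
  # longest wins; equal lengths break by transcript id
  expect_equal(find_cis_lncrnas(g, l)$transcript_id, "tB")
  l$canonical <- c(TRUE, FALSE, FALSE)
  expect_equal(find_cis_lncrnas(g, l)$transcript_id, "tA")
})

test_that("empty annotations give an empty, typed result", {
  g <- tibble::tibble(gene_id = character(), chrom = character(),
                      tss = numeric(), strand = character())
  l <- tibble::tibble(gene_id = character(), transcript_id = character(),
                      label = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      strand = character(), seq = character())
  expect_message(p <- find_cis_lncrnas(g, l), "empty annotation")
  expect_equal(nrow(p), 0)
})

test_that("SNP co-localization is inclusive point-in-interval", {
  lnc <- tibble::tibble(gene_id = "l1", chrom = "c1",
                        start = 41160959, end = 41163821)
  snps <- tibble::tibble(
    snp_id = c("in_middle", "at_start", "at_end", "outside", "other_chrom"),
    chrom = c("c1", "c1", "c1", "c1", "c2"),
    pos = c(41162000, 41160959, 41163821, 41163822, 41162000))
  co <- snp_colocalize(snps, lnc)
  expect_setequal(co$snp_id, c("in_middle", "at_start", "at_end"))
  expect_true(all(co$inside))
})
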