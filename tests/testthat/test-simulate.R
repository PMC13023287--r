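test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 5, tts_length = 64)
  a <- simulate_locus_set(cfg)
  b <- simulate_locus_set(cfg)
  expect_identical(a, b)
  withr::with_tempdir({
    simulate_locus_set(cfg, "run1")
    simulate_locus_set(cfg, "run2")
    for (f in list.files("run1")) {
      expect_identical(readBin(file.path("run1", f), "raw", 1e7),
                       readBin(file.path("run2", f), "raw", 1e7),
                       label = f)
    }
  })
})

test_that("planted exposed sites are recovered by the scan at full identity", {
  cfg <- sim_config(n_genes = 1, planted = TRUE,
                    accessibility_class = "exposed", island_plant = TRUE,
                    snp_plant = "none", tts_length = 60, seed = 17)
  locus <- simulate_locus_set(cfg)
  tr <- locus$truth[1, ]
  p <- screen_params()
  prom <- promoter_region(locus$genes, p)
  prom_seq <- substr(locus$genome[[prom$chrom]], prom$start, prom$end)
  hits <- scan_triplexes(locus$lncrnas$seq[1], prom_seq, p,
                         origin = prom$start, chrom = prom$chrom)
  cl <- select_tfo1(hits)
  # at least one merged hit per fully-contained register; boundary registers
  # (windows padding below the plant's full length) add more
  expect_gte(cl$hit_count, 2 * (60 - p$min_triplex_len) + 1)
  best <- strongest_tts(cl)
  expect_equal(best, c(tr$tts_start, tr$tts_end))
  # the recovering hit covers the planted TFO exactly
  m <- cl$members[order(-cl$members$stability, -cl$members$length), ][1, ]
  expect_equal(c(m$tfo_start, m$tfo_end), c(tr$tfo_start, tr$tfo_end))
  expect_equal(m$identity, 100)
})

test_that("sub-threshold planted identity leaves no qualifying hit", {
  expect_warning(
    pl <- plant_tts(random_dna_seq(400), 100, 60, identity = 50),
    "undetectable")
  p <- screen_params()
  rna <- paste0(strrep("A", 100), pl$tfo, strrep("A", 100))
  hits <- scan_triplexes(rna, pl$dna, p)
  inplant <- hits[hits$tts_start <= pl$tts_end & hits$tts_end >= pl$tts_start &
                    hits$identity >= 60, ]
  expect_equal(nrow(inplant), 0)
})

test_that("parallel and antiparallel plants give different TFO sequences", {
  set.seed(3)
  dna <- random_dna_seq(300)
  a <- plant_tts(dna, 50, 60, orientation = "parallel")
  b <- plant_tts(dna, 50, 60, orientation = "antiparallel")
  expect_false(identical(a$tfo, b$tfo))
  expect_equal(a$tfo, strrep("C", 60))
  expect_equal(b$tfo, strrep("G", 60))
  expect_error(plant_tts(dna, 290, 60), "does not fit")
})

test_that("infeasible configurations fail before writing anything", {
  expect_error(sim_config(tts_length_range = c(40, 100)))
  cfg <- sim_config(transcript_length = 260L)
  expect_error(simulate_locus_set(cfg), "transcript_length")
  withr::with_tempdir(expect_equal(length(list.files(".")), 0))
})

test_that("generated files round-trip through the readers", {
  withr::with_tempdir({
    cfg <- sim_config(seed = 9, tts_length = 64)
    written <- simulate_locus_set(cfg, "locus")
    expect_true(all(file.exists(file.path(
      "locus", c("genome.fa", "annotation.gff3", "transcripts.fa",
                 "snps.vcf", "control_promoter.fa", "islands.bed",
                 "truth.tsv", "sim_config.json")))))
    back <- read_locus_set("locus")
    expect_equal(back$genes$gene_id, written$genes$gene_id)
    expect_equal(back$genes$tss, written$genes$tss)
    expect_equal(back$lncrnas$seq, written$lncrnas$seq)
    expect_equal(back$lncrnas[, c("start", "end")],
                 written$lncrnas[, c("start", "end")])
    expect_equal(back$snps$pos, written$snps$pos)
    expect_equal(back$genome, written$genome)
    expect_equal(back$control$seq, written$control$seq)
    expect_equal(as.numeric(back$islands$start),
                 as.numeric(written$islands$start))
    expect_equal(back$truth$intended_tier, written$truth$intended_tier)
  })
})

test_that("truth records are internally consistent", {
  cfg <- sim_config(seed = 23, tts_length = 78)
  locus <- simulate_locus_set(cfg)
  tr <- locus$truth
  p <- screen_params()
  prom <- promoter_region(locus$genes, p)
  for (k in which(tr$planted)) {
    # planted TTS lies inside the promoter region of its gene
    pk <- prom[prom$gene_id == tr$gene_id[k], ]
    expect_gte(tr$tts_start[k], pk$start)
    expect_lte(tr$tts_end[k], pk$end)
    # planted island overlaps the TTS
    if (!is.na(tr$island_start[k])) {
      expect_lte(tr$island_start[k], tr$tts_start[k])
      expect_gte(tr$island_end[k], tr$tts_end[k])
    }
  }
  expect_equal(tr$intended_tier,
               c("high_confidence", "partial", "partial", "rejected"))
  # planted SNPs marked inside really fall into the locus
  co <- snp_colocalize(locus$snps, locus$lncrnas)
  expect_true("SNP01" %in% co$snp_id)   # inside plant
  expect_false("SNP02" %in% co$snp_id)  # outside plant
})

test_that("background-only loci pass no specificity criterion", {
  # no plants: the screen should find essentially nothing
  ok <- 0
  for (sd in 1:10) {
    cfg <- sim_config(n_genes = 1, planted = FALSE, island_plant = FALSE,
                      snp_plant = "none", seed = 400 + sd)
    locus <- simulate_locus_set(cfg)
    p <- screen_params()
    prom <- promoter_region(locus$genes, p)
    prom_seq <- substr(locus$genome[[prom$chrom]], prom$start, prom$end)
    cts <- run_screen_with_controls(
      "GENE01", "LNCT01_1", prom_seq, locus$lncrnas$seq[1],
      locus$control$seq, p, promoter_origin = prom$start,
      promoter_chrom = prom$chrom)$counts
    ev <- evaluate_pairs(dplyr::mutate(cts, cpg_overlap = 0L,
                                       accessible_overlap = 0L))
    if (!ev$criterion_specificity) ok <- ok + 1
  }
  expect_gte(ok, 9)
})
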