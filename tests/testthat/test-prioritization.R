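test_that("the documented tier patterns evaluate as expected", {
  # a strong pair: dominates both nulls, 4.4-fold enriched, dense,
  # CpG-anchored and accessible
  hi <- evaluate_pair(c(target = 22, shuffled_lncrna = 1, shuffled_target = 2,
                        control = 5), cpg_overlap = 15, accessible_overlap = 22)
  expect_equal(as.character(hi$tier), "high_confidence")
  expect_equal(hi$failed_criteria, "")
  # randomized sequences out-scoring the target: rejected
  rej <- evaluate_pair(c(target = 3, shuffled_lncrna = 9, shuffled_target = 1,
                         control = 3), cpg_overlap = 0, accessible_overlap = 1)
  expect_equal(as.character(rej$tier), "rejected")
  expect_match(rej$failed_criteria, "specificity")
  # specific but without CpG context: partial
  par <- evaluate_pair(c(target = 9, shuffled_lncrna = 2, shuffled_target = 1,
                         control = 2), cpg_overlap = 0, accessible_overlap = 9)
  expect_equal(as.character(par$tier), "partial")
  expect_match(par$failed_criteria, "cpg_island")
})

test_that("failed criteria are empty exactly for high-confidence pairs", {
  set.seed(83)
  x <- tibble::tibble(
    target = sample(0:40, 200, TRUE),
    shuffled_lncrna = sample(0:15, 200, TRUE),
    shuffled_target = sample(0:15, 200, TRUE),
    control = sample(0:15, 200, TRUE),
    cpg_overlap = sample(0:20, 200, TRUE),
    accessible_overlap = sample(0:20, 200, TRUE))
  ev <- evaluate_pairs(x)
  expect_identical(ev$failed_criteria == "",
                   as.character(ev$tier) == "high_confidence")
  expect_identical(!ev$criterion_specificity,
                   as.character(ev$tier) == "rejected")
})

test_that("tier assignment is a pure, order-independent function", {
  set.seed(89)
  x <- tibble::tibble(
    target = sample(0:40, 50, TRUE), shuffled_lncrna = sample(0:15, 50, TRUE),
    shuffled_target = sample(0:15, 50, TRUE), control = sample(0:15, 50, TRUE),
    cpg_overlap = sample(0:20, 50, TRUE),
    accessible_overlap = sample(0:20, 50, TRUE))
  perm <- sample(nrow(x))
  a <- evaluate_pairs(x)[perm, ]
  b <- evaluate_pairs(x[perm, ])
  expect_equal(a$tier, b$tier)
  expect_equal(evaluate_pairs(x), evaluate_pairs(evaluate_pairs(x)[names(x)]))
})

test_that("raising the enrichment floor never promotes a pair", {
  set.seed(97)
  x <- tibble::tibble(
    target = sample(0:40, 100, TRUE), shuffled_lncrna = sample(0:15, 100, TRUE),
    shuffled_target = sample(0:15, 100, TRUE), control = sample(0:15, 100, TRUE),
    cpg_overlap = sample(0:20, 100, TRUE),
    accessible_overlap = sample(0:20, 100, TRUE))
  lo <- evaluate_pairs(x, screen_params(enrichment_min_fold = 2))
  hi <- evaluate_pairs(x, screen_params(enrichment_min_fold = 4))
  expect_true(all(as.integer(hi$tier) >= as.integer(lo$tier)))
})

test_that("ranking is a deterministic total order", {
  x <- tibble::tibble(
    gene_id = c("g2", "g1", "g3", "g1"),
    transcript_id = c("t2", "t1", "t3", "t0"),
    target = c(25, 25, 8, 3), shuffled_lncrna = c(1, 1, 2, 9),
    shuffled_target = c(1, 1, 1, 1), control = c(5, 10, 2, 2),
    cpg_overlap = c(4, 4, 0, 1), accessible_overlap = c(25, 25, 8, 1))
  r <- rank_pairs(evaluate_pairs(x))
  # both high-confidence pairs first; equal counts rank by enrichment
  expect_equal(r$gene_id[1:2], c("g2", "g1"))
  expect_equal(as.character(r$tier[1]), "high_confidence")
  expect_equal(as.character(r$tier[4]), "rejected")
  expect_equal(r$rank, 1:4)
})

test_that("reports mirror the published table layouts", {
  withr::with_tempdir({
    x <- tibble::tibble(
      gene_id = "g1", lncrna_gene_id = "l1", transcript_id = "t1",
      label = "lnc1", target = 22, shuffled_lncrna = 1, shuffled_target = 2,
      control = 5, cpg_overlap = 15, accessible_overlap = 22)
    ev <- rank_pairs(evaluate_pairs(x))
    pairs <- tibble::tibble(gene_id = "g1", chrom = "c1",
                            lncrna_gene_id = "l1", transcript_id = "t1",
                            label = "lnc1", distance = 10203,
                            locus_start = 1, locus_end = 300,
                            window_start = 1, window_end = 1e5)
    coloc <- tibble::tibble(snp_id = "s1", lncrna_gene_id = "l1",
                            pos = 100, inside = TRUE)
    paths <- render_reports(ev, pairs, coloc, "reports")
    expect_true(all(file.exists(paths)))
    t2 <- readr::read_tsv(paths[["table2_tfo1_counts"]], show_col_types = FALSE)
    expect_identical(names(t2), c("gene_id", "label", "target",
                                  "shuffled_lncrna", "shuffled_target",
                                  "control", "enrichment"))
    t1 <- readr::read_tsv(paths[["table1_cis_pairs"]], show_col_types = FALSE)
    expect_equal(t1$distance, 10203)
    master <- readr::read_tsv(paths[["evaluations"]], show_col_types = FALSE)
    expect_equal(nrow(master), nrow(ev))
    # empty evaluations still produce headers-only files
    empty_ev <- rank_pairs(evaluate_pairs(x[0, ]))
    paths2 <- render_reports(empty_ev, pairs[0, ], coloc[0, ], "reports2")
    e2 <- readr::read_tsv(paths2[["table2_tfo1_counts"]], show_col_types = FALSE)
    expect_equal(nrow(e2), 0)
    expect_identical(names(e2), names(t2))
  })
})

test_that("SNP co-localization never changes the tier", {
  base <- c(target = 22, shuffled_lncrna = 1, shuffled_target = 2, control = 5)
  a <- evaluate_pair(base, 15, 22, snp_inside = TRUE)
  b <- evaluate_pair(base, 15, 22, snp_inside = FALSE)
  expect_equal(a$tier, b$tier)
})
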