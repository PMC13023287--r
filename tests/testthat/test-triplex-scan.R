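test_that("the default triad table matches its documented weights", {
  tt <- default_triad_table()
  expect_equal(nrow(tt), 32)  # 2 orientations x 4 x 4
  expect_true(all(tt$weight >= 0 & tt$weight <= 2))
  expect_equal(sum(tt$weight[tt$orientation == "parallel"]), 6)
  expect_equal(sum(tt$weight[tt$orientation == "antiparallel"]), 7)
  expect_equal(triad_weight("U", "A:T", "parallel"), 2)
  expect_equal(triad_weight("A", "G:C", "parallel"), 0)
  expect_equal(triad_weight("G", "G:C", "antiparallel"), 2)
  expect_error(triad_weight("X", "A:T", "parallel"), "non-nucleotide")
  # the shipped config file reproduces the built-in table
  shipped <- read_triad_table(system.file("extdata", "triad_table.tsv",
                                          package = "triplexscreen"))
  expect_equal(dplyr::arrange(shipped, orientation, rna, dna),
               dplyr::arrange(default_triad_table(), orientation, rna, dna))
})

test_that("a perfect homopolymer duplex yields the canonical full-length hit", {
  p <- screen_params()
  h <- scan_triplexes(strrep("U", 60), strrep("A", 60), p,
                      orientations = "parallel")
  # the perfect-register diagonal gives the unique full-length hit ...
  full <- h[h$length == 60, ]
  expect_equal(nrow(full), 1)
  expect_equal(full$identity, 100)
  expect_equal(full$stability, 2.0)
  expect_equal(c(full$tts_start, full$tts_end), c(1, 60))
  # ... and shifted registers give one merged hit per qualifying offset,
  # the overlapping-triplex density the screen measures
  expect_equal(nrow(h), 2 * (60 - p$min_triplex_len) + 1)
  expect_equal(select_tfo1(h)$hit_count, nrow(h))
})

test_that("sequences below the length threshold are rejected, empty scans empty", {
  p <- screen_params()
  expect_error(scan_triplexes(strrep("U", 30), strrep("A", 100), p),
               "min_triplex_len")
  set.seed(3)
  h <- scan_triplexes(random_rna_seq(60), random_dna_seq(60), p)
  expect_equal(nrow(h), 0)  # random 60-mers cannot reach lg=50 thresholds
})

test_that("ambiguous bases warn above 10% and score weight zero", {
  p <- screen_params()
  rna <- paste0(strrep("N", 10), strrep("U", 50))
  expect_warning(h <- scan_triplexes(rna, strrep("A", 60), p,
                                     orientations = "parallel"),
                 "ambiguous")
  # the pure U-run is recovered in full; windows reaching into the N block
  # treat those positions as non-matching, never as triads
  expect_true(any(h$tfo_start == 11 & h$tfo_end == 60 & h$identity == 100))
  expect_true(all(h$identity[h$tfo_start < 11] < 100))
})

test_that("scan output equals the exhaustive enumeration oracle", {
  p <- screen_params()
  set.seed(77)
  for (rep in 1:10) {
    m <- sample(55:120, 1); n <- sample(55:120, 1)
    rna <- random_rna_seq(m); dna <- random_dna_seq(n)
    if (rep > 5) {
      L <- sample(50:55, 1)
      ps <- sample(n - L + 1, 1); ts <- sample(m - L + 1, 1)
      dna <- paste0(substr(dna, 1, ps - 1), strrep("G", L), substr(dna, ps + L, n))
      rna <- paste0(substr(rna, 1, ts - 1), strrep("C", L), substr(rna, ts + L, m))
    }
    a <- as.data.frame(scan_triplexes(rna, dna, p, origin = 500, chrom = "cc"))
    b <- oracle_scan(rna, dna, p, origin = 500, chrom = "cc")
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("every emitted hit satisfies its own thresholds", {
  p <- screen_params(min_triplex_len = 12L)  # small lg: plenty of hits
  set.seed(13)
  for (rep in 1:5) {
    h <- scan_triplexes(random_rna_seq(150), random_dna_seq(200), p)
    expect_gt(nrow(h), 0)
    expect_true(all(h$length >= p$min_triplex_len))
    expect_true(all(h$identity >= p$min_identity - 1e-9))
    expect_true(all(h$stability >= p$min_stability - 1e-9))
    expect_true(all(h$identity <= 100))
    expect_true(all(h$tts_end - h$tts_start + 1 == h$length))
    expect_true(all(h$tfo_end - h$tfo_start + 1 == h$length))
  }
})

test_that("the scan is reverse-complement covariant", {
  p <- screen_params(min_triplex_len = 12L)
  set.seed(19)
  rna <- random_rna_seq(100)
  dna <- random_dna_seq(120)
  h1 <- scan_triplexes(rna, dna, p, origin = 1)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", dna), "")[[1]]), collapse = "")
  h2 <- scan_triplexes(rna, rc, p, origin = 1)
  # reverse-complementing the DNA swaps strand labels and mirrors TTS coords
  n <- nchar(dna)
  key <- function(h, flip) {
    strand <- if (flip) ifelse(h$dna_strand == "+", "-", "+") else h$dna_strand
    ts <- if (flip) n - h$tts_end + 1 else h$tts_start
    te <- if (flip) n - h$tts_start + 1 else h$tts_end
    sort(paste(h$tfo_start, h$tfo_end, ts, te, h$orientation, strand))
  }
  expect_identical(key(h1, FALSE), key(h2, TRUE))
})

test_that("raising any threshold never increases the number of hits", {
  set.seed(23)
  rna <- random_rna_seq(150); dna <- random_dna_seq(200)
  base <- screen_params(min_triplex_len = 12L, min_identity = 55,
                        min_stability = 0.8)
  n0 <- nrow(scan_triplexes(rna, dna, base))
  expect_gt(n0, 0)
  for (tweak in list(list(min_triplex_len = 16L),
                     list(min_identity = 70),
                     list(min_stability = 1.1))) {
    args <- utils::modifyList(list(min_triplex_len = 12L, min_identity = 55,
                                   min_stability = 0.8), tweak)
    p2 <- do.call(screen_params, args)
    expect_lte(nrow(scan_triplexes(rna, dna, p2)), n0)
  }
})

test_that("TFO1 depth equals the per-base coverage maximum", {
  set.seed(31)
  for (rep in 1:10) {
    k <- sample(5:20, 1)
    starts <- sample(500, k, replace = TRUE)
    ends <- starts + sample(10:80, k, replace = TRUE)
    hits <- tibble::tibble(
      tfo_start = 1L, tfo_end = 10L, chrom = "c",
      tts_start = starts, tts_end = ends,
      orientation = "parallel", dna_strand = "+",
      length = ends - starts + 1L, identity = 100,
      stability = runif(k, 1, 2))
    cl <- select_tfo1(hits)
    expect_equal(cl$hit_count, oracle_max_coverage(starts, ends))
    expect_true(all(cl$members$tts_start <= cl$peak_start &
                      cl$members$tts_end >= cl$peak_start))
  }
})

test_that("TFO1 ties break by stability then leftmost, empty input is empty", {
  empty <- select_tfo1(scan_triplexes(strrep("A", 60), strrep("C", 60),
                                      screen_params()))
  expect_equal(empty$hit_count, 0)
  expect_equal(nrow(empty$members), 0)
  # two disjoint single hits: depth 1, higher-stability peak wins
  hits <- tibble::tibble(
    tfo_start = 1L, tfo_end = 50L, chrom = "c",
    tts_start = c(100, 300), tts_end = c(149, 349),
    orientation = "parallel", dna_strand = "+",
    length = 50L, identity = 100, stability = c(1.2, 1.8))
  cl <- select_tfo1(hits)
  expect_equal(cl$hit_count, 1)
  expect_equal(cl$peak_start, 300)
  # equal stability: leftmost peak
  hits$stability <- c(1.5, 1.5)
  expect_equal(select_tfo1(hits)$peak_start, 100)
})

test_that("scanning is deterministic", {
  set.seed(3)
  rna <- random_rna_seq(120); dna <- random_dna_seq(150)
  p <- screen_params(min_triplex_len = 15L)
  expect_identical(scan_triplexes(rna, dna, p), scan_triplexes(rna, dna, p))
})
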