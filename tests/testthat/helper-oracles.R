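# Independent brute-force oracles. These re-derive every result from first
# principles (exhaustive enumeration), sharing no code path with the package
# implementations they check.

oracle_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
}

oracle_rev <- function(seq) paste(rev(strsplit(seq, "")[[1]]), collapse = "")

# Exhaustive diagonal triplex scan: every (start, end) window on every
# diagonal, orientation and strand is scored; qualifying windows are grouped
# into overlap components and each component reports its stability-maximal
# window (ties: longest, then leftmost).
oracle_scan <- function(rna, dna, params = screen_params(),
                        table = default_triad_table(),
                        origin = 1, chrom = "chr") {
  rna <- chartr("Tt", "Uu", toupper(rna))
  dna <- chartr("Uu", "Tt", toupper(dna))
  m <- nchar(rna); n <- nchar(dna)
  lg <- params$min_triplex_len
  idmin <- params$min_identity
  smin <- params$min_stability

  wmat <- list()
  for (ori in c("parallel", "antiparallel")) {
    mm <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                          c("A", "C", "G", "T")))
    tt <- table[table$orientation == ori, ]
    mm[cbind(match(tt$rna, rownames(mm)), match(tt$dna, colnames(mm)))] <- tt$weight
    wmat[[ori]] <- mm
  }
  code_of <- function(seq, alpha) {
    v <- strsplit(seq, "")[[1]]
    i <- match(v, alpha)
    i[is.na(i)] <- 0L
    i
  }

  better <- function(sw1, l1, sw2, l2) {
    lhs <- sw1 * l2; rhs <- sw2 * l1
    if (lhs > rhs + 1e-9) return(TRUE)
    if (abs(lhs - rhs) <= 1e-9 && l1 > l2) return(TRUE)
    FALSE
  }

  rows <- list()
  for (sigma in c("+", "-")) {
    pseq <- if (sigma == "+") dna else oracle_revcomp(dna)
    pcode <- code_of(pseq, c("A", "C", "G", "T"))
    for (ori in c("parallel", "antiparallel")) {
      aseq <- if (ori == "parallel") rna else oracle_rev(rna)
      acode <- code_of(aseq, c("A", "C", "G", "U"))
      mm <- wmat[[ori]]
      for (d in (-(m - 1)):(n - 1)) {
        aidx <- max(1, 1 - d):min(m, n - d)
        if (length(aidx) < lg) next
        wv <- vapply(aidx, function(a) {
          if (acode[a] == 0 || pcode[a + d] == 0) 0 else mm[acode[a], pcode[a + d]]
        }, numeric(1))
        Lw <- length(wv)
        csum <- c(0, cumsum(wv))
        cnz <- c(0, cumsum(wv > 0))
        qual <- list()
        for (s in 1:(Lw - lg + 1)) {
          e <- (s + lg - 1):Lw
          len <- e - s + 1
          nz <- cnz[e + 1] - cnz[s]
          sw <- csum[e + 1] - csum[s]
          ok <- 100 * nz - idmin * len >= -1e-9 & sw - smin * len >= -1e-9
          if (any(ok)) {
            qual[[length(qual) + 1]] <-
              cbind(s, e[ok], nz[ok], sw[ok], deparse.level = 0)
          }
        }
        if (length(qual) == 0) next
        q <- do.call(rbind, qual)
        q <- q[order(q[, 1], q[, 2]), , drop = FALSE]
        # overlap components
        comp <- integer(nrow(q)); cid <- 1; cend <- q[1, 2]; comp[1] <- 1
        if (nrow(q) > 1) for (k in 2:nrow(q)) {
          if (q[k, 1] <= cend) { comp[k] <- cid; cend <- max(cend, q[k, 2]) }
          else { cid <- cid + 1; comp[k] <- cid; cend <- q[k, 2] }
        }
        for (cc in unique(comp)) {
          sub <- q[comp == cc, , drop = FALSE]
          best <- 1
          if (nrow(sub) > 1) for (k in 2:nrow(sub)) {
            if (better(sub[k, 4], sub[k, 2] - sub[k, 1] + 1,
                       sub[best, 4], sub[best, 2] - sub[best, 1] + 1)) best <- k
          }
          s <- sub[best, 1]; e <- sub[best, 2]
          a1 <- aidx[s]; a2 <- aidx[e]
          p1 <- a1 + d; p2 <- a2 + d
          len <- a2 - a1 + 1
          tfo <- if (ori == "parallel") c(a1, a2) else c(m - a2 + 1, m - a1 + 1)
          tts <- if (sigma == "+") c(origin + p1 - 1, origin + p2 - 1)
                 else c(origin + n - p2, origin + n - p1)
          rows[[length(rows) + 1]] <- data.frame(
            tfo_start = tfo[1], tfo_end = tfo[2], chrom = chrom,
            tts_start = tts[1], tts_end = tts[2], orientation = ori,
            dna_strand = sigma, length = len,
            identity = 100 * sub[best, 3] / len,
            stability = sub[best, 4] / len, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(tfo_start = integer(), tfo_end = integer(),
                      chrom = character(), tts_start = numeric(),
                      tts_end = numeric(), orientation = character(),
                      dna_strand = character(), length = integer(),
                      identity = numeric(), stability = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$tts_start, out$tts_end, out$tfo_start, out$tfo_end,
            match(out$orientation, c("parallel", "antiparallel")),
            match(out$dna_strand, c("+", "-"))), , drop = FALSE]
}

# per-base interval coverage maximum (oracle for select_tfo1 depth)
oracle_max_coverage <- function(starts, ends) {
  if (length(starts) == 0) return(0L)
  pos <- min(starts):max(ends)
  max(vapply(pos, function(p) sum(starts <= p & ends >= p), numeric(1)))
}

# Exhaustive enumeration of all pseudoknot-free secondary structures with
# hairpin loops >= min_hairpin, Boltzmann-weighted by summed pair energies.
# Returns the partition function, per-base unpaired probabilities and the
# base-pair probability matrix.
oracle_boltzmann <- function(seq, model = energy_model()) {
  seq <- chartr("Tt", "Uu", toupper(seq))
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  q <- model$q
  mh <- model$min_hairpin
  allowed <- function(i, j) {
    j - i > mh && v[i] %in% rownames(q) && v[j] %in% rownames(q) &&
      q[v[i], v[j]] > 0
  }
  memo <- new.env()
  structs <- function(i, j) {
    if (j <= i) return(list(matrix(numeric(0), nrow = 2)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- structs(i, j - 1)                      # j unpaired
    ks <- if (j - mh - 1 >= i) i:(j - mh - 1) else integer(0)
    for (k in ks) {
      if (!allowed(k, j)) next
      left <- structs(i, k - 1)
      right <- if (k + 1 <= j - 1) structs(k + 1, j - 1)
               else list(matrix(numeric(0), nrow = 2))
      for (L in left) for (R in right) {
        out[[length(out) + 1]] <- cbind(L, R, c(k, j))
      }
    }
    memo[[key]] <- out
    out
  }
  all_s <- structs(1, n)
  Z <- 0
  unp <- numeric(n)
  pmat <- matrix(0, n, n)
  for (st in all_s) {
    wgt <- if (ncol(st) == 0) 1 else prod(q[cbind(v[st[1, ]], v[st[2, ]])])
    Z <- Z + wgt
    paired <- st[, , drop = FALSE]
    flag <- rep(TRUE, n)
    if (ncol(paired) > 0) {
      flag[c(paired[1, ], paired[2, ])] <- FALSE
      pmat[cbind(paired[1, ], paired[2, ])] <-
        pmat[cbind(paired[1, ], paired[2, ])] + wgt
    }
    unp[flag] <- unp[flag] + wgt
  }
  pmat <- pmat / Z
  pmat <- pmat + t(pmat)
  list(Z = Z, punp = unp / Z, pmat = pmat, n_structures = length(all_s))
}

# Brute-force Gardiner-Garden-Frommer evaluation: explicit per-window loop
# and merge of qualifying windows.
oracle_cpg <- function(seq, window = 200L, gc_min = 50, oe_min = 0.6) {
  v <- strsplit(toupper(seq), "")[[1]]
  n <- length(v)
  if (n < window) return(data.frame(start = integer(), end = integer()))
  ok <- logical(n - window + 1)
  for (s in seq_len(n - window + 1)) {
    win <- v[s:(s + window - 1)]
    nc <- sum(win == "C"); ng <- sum(win == "G")
    ncg <- sum(win[-window] == "C" & win[-1] == "G")
    gc <- 100 * (nc + ng) / window
    oe <- if (nc * ng > 0) (ncg * window) / (nc * ng) else 0
    ok[s] <- gc >= gc_min && oe >= oe_min
  }
  if (!any(ok)) return(data.frame(start = integer(), end = integer()))
  s_ok <- which(ok)
  starts <- c(); ends <- c()
  cs <- s_ok[1]; ce <- s_ok[1] + window - 1
  for (s in s_ok[-1]) {
    if (s <= ce) ce <- s + window - 1
    else { starts <- c(starts, cs); ends <- c(ends, ce); cs <- s; ce <- s + window - 1 }
  }
  starts <- c(starts, cs); ends <- c(ends, ce)
  data.frame(start = starts, end = ends)
}

# interval jaccard and strongest-member TTS, shared by recovery tests
jaccard_iv <- function(a, b) {
  inter <- max(0, min(a[2], b[2]) - max(a[1], b[1]) + 1)
  inter / (max(a[2], b[2]) - min(a[1], b[1]) + 1)
}

strongest_tts <- function(cluster) {
  m <- cluster$members
  m <- m[order(-m$stability, -m$length, m$tts_start), ]
  c(m$tts_start[1], m$tts_end[1])
}

random_rna_seq <- function(n, probs = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE, prob = probs),
        collapse = "")
}

random_dna_seq <- function(n, probs = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}
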