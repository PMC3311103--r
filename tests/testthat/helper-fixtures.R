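# Shared fixtures and independent oracles, built in code at test time.

# A tiny hand-built dataset: two amplicons with known CpG layout, one cell
# type, fully deterministic levels.
make_tiny_dataset <- function(levels_a = c(0.9, 0.8, 0.1, 0.2, 0.9),
                              levels_b = c(0.1, 0.9, 0.8),
                              cell_type = "ct1") {
  #        123456789012345678901234567890
  seq_a <- "AACGTTCGAAACGTTTTCGAAACGTTTTTT"   # CpGs at 3, 7, 12, 18, 23
  seq_b <- "TTTCGAAACGGGGCGTTTTT"             # CpGs at 4, 9, 14
  amp <- Biostrings::DNAStringSet(c(a = seq_a, b = seq_b))
  starts <- c(0L, 1000L)
  S4Vectors::mcols(amp) <- S4Vectors::DataFrame(
    chrom = "chrT", start = starts,
    end = starts + Biostrings::width(amp),
    cpgOffsets = I(list(c(3L, 7L, 12L, 18L, 23L), c(4L, 9L, 14L))))
  rec <- rbind(
    data.frame(chrom = "chrT", pos = starts[1] + c(3, 7, 12, 18, 23) - 1,
               strand = "+", level = levels_a, coverage = 30L,
               cellType = cell_type),
    data.frame(chrom = "chrT", pos = starts[2] + c(4, 9, 14) - 1,
               strand = "+", level = levels_b, coverage = 30L,
               cellType = cell_type))
  assembleDataset(amp, rec)
}

# Fast strong-signal simulation for unit tests (smaller than the full
# 60-amplicon study conditions).
small_strong_sim <- function(nAmplicons = 12, seed = 101, ...) {
  simulateMethylationData(nAmplicons = nAmplicons, ampliconLength = 1200,
                          cpgDensity = 0.015, seed = seed, ...)
}

# Independent AUC oracle: all-pairs comparison with half-credit for ties.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Independent parenthesization oracle: structurally enumerate all binary
# parenthesizations of n leaves and count them (no recurrence arithmetic).
oracle_parenthesizations <- function(n) {
  enum <- function(n) {
    if (n == 1) return(list("L"))
    out <- list()
    for (i in seq_len(n - 1)) {
      for (l in enum(i)) for (r in enum(n - i)) {
        out[[length(out) + 1L]] <- list(l, r)
      }
    }
    out
  }
  length(enum(n))
}

# Exhaustive search oracle over all 2^m configurations of a tiny
# single-amplicon dataset: the minimum weighted squared error, fitting the
# model per configuration exactly as the objective defines. Works directly
# on boundary bitmasks with span counts precomputed for every contiguous
# site range, independent of the hill-climbing code path.
oracle_exhaustive <- function(dataset, cellType, kmers, ridge = 1e-6,
                              threshold = 0.5) {
  st <- siteTable(dataset)
  st <- st[st$cellType == cellType, ]
  st <- st[order(st$amplicon, st$offset), ]
  stopifnot(length(unique(st$amplicon)) == 1L)
  seq1 <- as.character(ampliconSeqs(dataset))[[unique(st$amplicon)]]
  off <- st$offset
  lab <- st$level > threshold
  n <- length(off)
  m <- n - 1L

  # counts for every contiguous site range [i, j], in one dictionary pass
  pairs <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  spans <- substring(seq1, off[pairs[, "row"]], off[pairs[, "col"]] + 1L)
  pd <- Biostrings::PDict(kmers)
  counts <- t(Biostrings::vcountPDict(pd, Biostrings::DNAStringSet(spans)))
  key <- pairs[, "row"] * 1000L + pairs[, "col"]

  best <- Inf
  for (mask in 0:(2^m - 1)) {
    bits <- as.logical(bitwAnd(bitwShiftR(mask, 0:(m - 1L)), 1L))
    cut <- which(c(bits, TRUE))
    first <- c(1L, utils::head(cut, -1L) + 1L)
    t01 <- vapply(seq_along(cut),
                  function(i) mean(lab[first[i]:cut[i]]) > 0.5, logical(1))
    if (all(t01) || !any(t01)) next
    X <- counts[match(first * 1000L + cut, key), , drop = FALSE]
    colnames(X) <- kmers
    mod <- fitKmerLogistic(X, t01, ridge = ridge)
    sizes <- cut - first + 1L
    E <- sum((mean(sizes) / sizes) *
               (decisionScores(mod, X) - as.numeric(t01))^2)
    if (E < best) best <- E
  }
  best
}

expect_valid <- function(object) {
  testthat::expect_true(isTRUE(methods::validObject(object, test = TRUE)))
}
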