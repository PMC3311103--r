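test_that("countKmers slides, masks N and handles short sequences", {
  expect_equal(countKmers("ACGACG", 3),
               c(ACG = 2L, CGA = 1L, GAC = 1L)[c("ACG", "CGA", "GAC")])
  expect_equal(sort(names(countKmers("AANCG", 2))), c("AA", "CG"))
  expect_equal(unname(countKmers("AANCG", 2)), c(1L, 1L))
  expect_equal(countKmers("ACG", 4), integer(0))
  expect_equal(countKmers("acgt", 2), c(AC = 1L, CG = 1L, GT = 1L))
})

test_that("k-mer counts sum to the number of N-free windows", {
  withr::with_seed(5, {
    for (i in 1:25) {
      s <- paste(sample(c("A", "C", "G", "T", "N"), 60, replace = TRUE,
                        prob = c(.24, .24, .24, .24, .04)), collapse = "")
      k <- sample(1:6, 1)
      windows <- substring(s, seq_len(60 - k + 1), seq_len(60 - k + 1) + k - 1)
      expect_equal(sum(countKmers(s, k)),
                   sum(!grepl("N", windows, fixed = TRUE)))
    }
  })
})

test_that("site flanks are centered on the CG and truncated at ends", {
  expect_equal(extractSiteFlank("AAACGTTT", 4, l = 4), "ACGT")
  # flank at the start is truncated on the left, never padded
  expect_equal(extractSiteFlank("CGTTTTTT", 1, l = 6), "CGTT")
  # l covering everything returns the whole amplicon
  expect_equal(extractSiteFlank("AACGTT", 3, l = 100), "AACGTT")
  expect_error(extractSiteFlank("AAACGTTT", 2, l = 4), "not a CpG")
  expect_error(extractSiteFlank("AAACGTTT", 4, l = 5))
})

test_that("balanceClasses down-samples the majority deterministically", {
  counts <- matrix(rpois(80, 1), 40, 2, dimnames = list(NULL, c("AC", "GT")))
  inst <- new("KmerInstances", counts = counts,
              labels = c(rep("+", 30), rep("-", 10)), k = 2L)
  b1 <- balanceClasses(inst, 9)
  expect_equal(sum(b1@labels == "+"), 10L)
  expect_equal(sum(b1@labels == "-"), 10L)
  expect_identical(balanceClasses(inst, 9)@counts, b1@counts)
  expect_false(identical(balanceClasses(inst, 10)@counts, b1@counts))

  balanced <- new("KmerInstances", counts = counts[1:20, ],
                  labels = rep(c("+", "-"), 10), k = 2L)
  b2 <- balanceClasses(balanced, 3)
  expect_equal(sort(rownames(b2@counts)), sort(rownames(balanced@counts)))
  expect_equal(dim(b2@counts), dim(balanced@counts))

  mono <- new("KmerInstances", counts = counts, labels = rep("+", 40), k = 2L)
  expect_error(balanceClasses(mono, 1), "one class")
})

test_that("Welch p-values match stats::t.test column by column", {
  withr::with_seed(13, {
    x <- matrix(rpois(200 * 12, 2), 200, 12,
                dimnames = list(NULL, sprintf("K%02d", 1:12)))
    x[, 1] <- x[, 1] + rep(c(2L, 0L), each = 100)   # one shifted column
    plus <- rep(c(TRUE, FALSE), each = 100)
    p_mine <- methylseg:::welch_p_values(x, plus)
    p_ref <- apply(x, 2, function(col) {
      stats::t.test(col[plus], col[!plus])$p.value
    })
    expect_equal(unname(p_mine), unname(p_ref), tolerance = 1e-12)
  })
})

test_that("t-test selection ranks separating k-mers first and null ones last", {
  withr::with_seed(21, {
    n <- 40
    counts <- matrix(rpois(n * 30, 1), n, 30,
                     dimnames = list(NULL, sprintf("NNN%02d", 1:30)))
    # a k-mer present ~5x in every positive, absent in negatives
    sep <- c(rpois(n / 2, 0.2) + 5L, integer(n / 2))
    counts <- cbind(counts, SEPKM = sep)
    labels <- rep(c("+", "-"), each = n / 2)
    inst <- new("KmerInstances", counts = counts, labels = labels, k = 5L)
    res <- selectTtest(inst, m = 10)
    expect_s4_class(res, "FeatureSelectionResult")
    expect_equal(res@selected[1], "SEPKM")
    expect_length(res@selected, 10L)
    # its p-value agrees with the direct Welch computation
    ref <- stats::t.test(sep[labels == "+"], sep[labels == "-"])$p.value
    expect_equal(unname(res@scores["SEPKM"]), ref, tolerance = 1e-12)

    # identical-distribution column ranks at the bottom
    counts2 <- cbind(counts, NULLK = rep(c(3L, 3L), n / 2))
    inst2 <- new("KmerInstances", counts = counts2, labels = labels, k = 5L)
    all_ranked <- selectTtest(inst2, m = ncol(counts2))@selected
    expect_equal(all_ranked[length(all_ranked)], "NULLK")

    # permutation equivariance
    perm <- sample(n)
    inst3 <- new("KmerInstances", counts = counts[perm, ],
                 labels = labels[perm], k = 5L)
    expect_identical(selectTtest(inst3, m = 10)@selected, res@selected)
  })
})

test_that("requesting more k-mers than observed warns and returns all", {
  inst <- new("KmerInstances",
              counts = matrix(rpois(40, 1), 20, 2,
                              dimnames = list(NULL, c("AC", "GT"))),
              labels = rep(c("+", "-"), 10), k = 2L)
  expect_warning(res <- selectTtest(inst, m = 10), "only 2")
  expect_length(res@selected, 2L)
})

test_that("one RF importance run retains a planted predictor", {
  withr::with_seed(31, {
    n <- 60
    counts <- matrix(rpois(n * 30, 1), n, 30,
                     dimnames = list(NULL, sprintf("N%02d", 1:30)))
    counts <- cbind(counts, HIT = c(rpois(n / 2, 0.3) + 3L, integer(n / 2)))
    labels <- rep(c("+", "-"), each = n / 2)
    inst <- new("KmerInstances", counts = counts, labels = labels, k = 3L)
    hits <- vapply(1:25, function(s) {
      "HIT" %in% rfImportanceRun(inst, nTrees = 100, nTop = 10, seed = s)
    }, logical(1))
    expect_gte(mean(hits), 0.95)
    # nTop caps the run size
    expect_lte(length(rfImportanceRun(inst, nTrees = 50, nTop = 1, seed = 1)), 1L)
  })
})

test_that("all-constant features yield no positive z-scores", {
  counts <- matrix(2L, 30, 5, dimnames = list(NULL, paste0("C", 1:5)))
  inst <- new("KmerInstances", counts = counts,
              labels = rep(c("+", "-"), 15), k = 2L)
  expect_length(rfImportanceRun(inst, nTrees = 30, seed = 1), 0L)
})

test_that("consensus retention threshold is ceiling(p% of runs)", {
  # 30 runs at 90%: 27 appearances retained, 26 dropped
  runs <- lapply(1:30, function(i) {
    c(if (i <= 27) "KEEP", if (i <= 26) "DROP", "ALWAYS")
  })
  frac <- consensusSelect(runs, pPct = 90)
  expect_true("KEEP" %in% names(frac))
  expect_false("DROP" %in% names(frac))
  expect_equal(unname(frac["KEEP"]), 27 / 30)
  expect_equal(unname(frac["ALWAYS"]), 1)
})

test_that("raising the consensus percentage never enlarges the selection", {
  withr::with_seed(8, {
    runs <- lapply(1:20, function(i) {
      sample(sprintf("K%02d", 1:15), sample(3:10, 1))
    })
    sizes <- vapply(c(10, 30, 50, 70, 90, 100),
                    function(p) length(consensusSelect(runs, p)), numeric(1))
    expect_true(all(diff(sizes) <= 0))
  })
})

test_that("consensus RF keeps a strong planted k-mer and rejects noise", {
  withr::with_seed(41, {
    n <- 60
    counts <- matrix(rpois(n * 40, 1), n, 40,
                     dimnames = list(NULL, sprintf("N%02d", 1:40)))
    counts <- cbind(counts, HIT = c(rpois(n / 2, 0.3) + 4L, integer(n / 2)))
    labels <- rep(c("+", "-"), each = n / 2)
    inst <- new("KmerInstances", counts = counts, labels = labels, k = 3L)
    res <- selectRfConsensus(inst, kRuns = 10, nTrees = 60, nTop = 10,
                             pPct = 90, seed = 2)
    expect_true("HIT" %in% res@selected)

    # pure noise: consensus keeps (almost) nothing
    noise_sizes <- vapply(1:3, function(s) {
      counts0 <- matrix(rpois(n * 40, 1), n, 40,
                        dimnames = list(NULL, sprintf("N%02d", 1:40)))
      inst0 <- new("KmerInstances", counts = counts0, labels = labels, k = 3L)
      length(selectRfConsensus(inst0, kRuns = 10, nTrees = 60, nTop = 5,
                               pPct = 90, seed = s)@selected)
    }, numeric(1))
    expect_lt(mean(noise_sizes), 0.05 * 40)
  })
})
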