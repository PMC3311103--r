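test_that("site labels use a strict threshold", {
  ds <- make_tiny_dataset(levels_a = c(0.8, 0.5, 0.2, 0.9, 0.51),
                          levels_b = c(0, 0.01, 1))
  lab <- labelSites(ds, "ct1")
  expect_equal(lab$label[lab$amplicon == "a"], c("+", "-", "-", "+", "+"))
  lab0 <- labelSites(ds, "ct1", threshold = 0)
  expect_equal(lab0$label[lab0$amplicon == "b"], c("-", "+", "+"))
})

test_that("label-change initialization builds maximal label runs", {
  ds <- make_tiny_dataset(levels_a = c(0.9, 0.8, 0.1, 0.2, 0.9),
                          levels_b = c(0.9, 0.9, 0.9))
  cfg <- initialConfiguration(ds, "ct1")
  sg <- segmentTable(cfg)
  a <- sg[sg$amplicon == "a", ]
  # labels +,+,-,-,+  ->  segments {1,2}, {3,4}, {5}
  expect_equal(a$firstSite, c(1L, 3L, 5L))
  expect_equal(a$lastSite, c(2L, 4L, 5L))
  expect_equal(a$label, c(TRUE, FALSE, TRUE))
  # all-same labels give a single segment
  expect_equal(sum(sg$amplicon == "b"), 1L)

  singles <- segmentTable(initialConfiguration(ds, "ct1",
                                               mode = "all-boundaries"))
  expect_equal(nrow(singles), 8L)
  expect_true(all(singles$nSites == 1L))
  expect_valid(cfg)
})

test_that("segment ratios, strict labels and inverse-size weights", {
  ds <- make_tiny_dataset(levels_a = c(0.9, 0.9, 0.2, 0.8, 0.9),
                          levels_b = c(0.9, 0.1, 0.1))
  # one segment of all 5 sites in a (labels +,+,-,+,+) and the runs in b
  v <- methylseg:::cell_type_view(ds, "ct1", 0.5)
  bits <- list(a = rep(FALSE, 4), b = c(TRUE, FALSE))
  cfg <- methylseg:::configuration_from_bits(v, bits)
  w <- segmentWeights(cfg)
  # segment a: p = 4/5 -> +; b1: p = 1 -> +; b2: p = 0 -> -
  expect_equal(w$p, c(4 / 5, 1, 0))
  expect_equal(w$t, c("+", "+", "-"))
  # sizes 5, 1, 2 -> S-bar = 8/3
  expect_equal(w$w, (8 / 3) / c(5, 1, 2))

  # p exactly 0.5 is labeled '-' (strict inequality)
  ds2 <- make_tiny_dataset(levels_a = c(0.9, 0.1, 0.9, 0.1, 0.9),
                           levels_b = c(0.9, 0.1, 0.9))
  v2 <- methylseg:::cell_type_view(ds2, "ct1", 0.5)
  cfg2 <- methylseg:::configuration_from_bits(
    v2, list(a = c(FALSE, TRUE, FALSE, TRUE), b = c(FALSE, FALSE)))
  sg2 <- segmentTable(cfg2)
  expect_equal(sg2$pPlus[1], 0.5)
  expect_false(sg2$label[1])
})

test_that("segment feature counts cover the first C through the last G", {
  ds <- make_tiny_dataset()
  cfg <- initialConfiguration(ds, "ct1", mode = "all-boundaries")
  X <- segmentFeatureMatrix(cfg, c("CG", "AC"), ds)
  expect_equal(dim(X), c(8L, 2L))
  # singleton segments span exactly "CG"
  expect_true(all(X[, "CG"] == 1))
  expect_true(all(X[, "AC"] == 0))
  expect_error(segmentFeatureMatrix(cfg, character(0), ds), "non-empty")

  # merging two adjacent segments never loses counts and may add
  # junction-spanning occurrences
  v <- methylseg:::cell_type_view(ds, "ct1", 0.5)
  merged <- methylseg:::configuration_from_bits(
    v, list(a = c(FALSE, TRUE, TRUE, TRUE), b = rep(TRUE, 2)))
  Xm <- segmentFeatureMatrix(merged, c("CG", "AC"), ds)
  expect_true(all(Xm[1, ] >= pmax(X[1, ], X[2, ])))
})

test_that("the weighted squared error follows its printed arithmetic", {
  err <- methylseg:::error_from_scores
  # perfect fit
  sg <- data.frame(nSites = c(2L, 4L), label = c(TRUE, FALSE))
  expect_equal(err(sg, c(1, 0)), 0)
  # one segment, w = 1, residual 0.5
  expect_equal(err(data.frame(nSites = 3L, label = TRUE), 0.5), 0.25)
  # sizes 2 and 4, residual 0.2 each, S-bar 3: 1.5*0.04 + 0.75*0.04
  expect_equal(err(sg, c(0.8, 0.2)), 0.09)

  # and the sampling weights are the printed inverse
  se <- methylseg:::sampling_errors(sg, c(0.5, 0.5))
  expect_equal(se, c((2 / 3) * 0.25, (4 / 3) * 0.25))
  expect_equal(methylseg:::sampling_errors(sg, c(1, 0)), c(0, 0))
  # doubling the residual quadruples e_j
  expect_equal(methylseg:::sampling_errors(sg, c(0.6, 0))[1] * 4,
               methylseg:::sampling_errors(sg, c(0.2, 0))[1])
})

test_that("computeError and samplingErrorVector agree end to end", {
  ds <- make_tiny_dataset()
  cfg <- initialConfiguration(ds, "ct1")
  X <- segmentFeatureMatrix(cfg, c("CG", "TT"), ds)
  m <- fitKmerLogistic(X, segmentTable(cfg)$label, ridge = 0.05)
  yhat <- decisionScores(m, X)
  sg <- segmentTable(cfg)
  expect_equal(computeError(cfg, m, ds),
               sum((mean(sg$nSites) / sg$nSites) *
                     (yhat - as.numeric(sg$label))^2))
  expect_equal(samplingErrorVector(cfg, m, ds),
               (sg$nSites / mean(sg$nSites)) *
                 (yhat - as.numeric(sg$label))^2)
})

test_that("configuration enumeration yields exactly 2^m valid partitions", {
  ds <- make_tiny_dataset()           # 8 sites over 2 amplicons -> m = 6
  cfgs <- enumerateAllConfigurations(ds, "ct1")
  expect_length(cfgs, 2^6)
  keys <- vapply(cfgs, function(cf) {
    paste(unlist(boundaryBits(cf)), collapse = "")
  }, character(1))
  expect_equal(anyDuplicated(keys), 0L)
  for (cf in cfgs[c(1, 17, 64)]) expect_valid(cf)
  expect_error(enumerateAllConfigurations(ds, "ct1", mGuard = 3), "guard")

  # a single-CpG amplicon has exactly one configuration (m = 0)
  amp <- Biostrings::DNAStringSet(c(x = "AACGTT"))
  S4Vectors::mcols(amp) <- S4Vectors::DataFrame(
    chrom = "chrT", start = 0L, end = 6L, cpgOffsets = I(list(3L)))
  one <- assembleDataset(amp, data.frame(
    chrom = "chrT", pos = 2L, strand = "+", level = 0.9, coverage = 1L,
    cellType = "ct1"))
  expect_length(enumerateAllConfigurations(one, "ct1"), 1L)
})

test_that("parenthesization counts follow the recurrence and the enumerator", {
  expect_identical(parenthesizationCount(1), 1)
  expect_identical(parenthesizationCount(2), 1)
  expect_identical(parenthesizationCount(4), 5)
  for (n in 1:10) {
    expect_equal(parenthesizationCount(n), oracle_parenthesizations(n),
                 info = paste("n =", n))
  }
  expect_error(parenthesizationCount(0), "integer")
})

test_that("boundary bits round-trip through configurations", {
  ds <- make_tiny_dataset()
  v <- methylseg:::cell_type_view(ds, "ct1", 0.5)
  bits <- list(a = c(TRUE, FALSE, TRUE, FALSE), b = c(FALSE, TRUE))
  cfg <- methylseg:::configuration_from_bits(v, bits)
  expect_equal(boundaryBits(cfg), bits)
})
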