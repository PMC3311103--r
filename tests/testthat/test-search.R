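test_that("merge-candidate sampling is proportional to the error vector", {
  expect_equal(selectSegmentAtRandom(c(1, 2, 3), 2L), 2L)
  expect_true(is.na(selectSegmentAtRandom(c(1, 2), integer(0))))

  draws <- withr::with_seed(99, {
    vapply(1:10000, function(i) selectSegmentAtRandom(c(1, 3), c(1L, 2L)),
           integer(1))
  })
  tab <- table(draws)
  expect_gt(stats::chisq.test(tab, p = c(0.25, 0.75))$p.value, 0.01)

  # all-zero errors fall back to uniform
  draws0 <- withr::with_seed(7, {
    vapply(1:4000, function(i) selectSegmentAtRandom(c(0, 0), c(1L, 2L)),
           integer(1))
  })
  expect_gt(stats::chisq.test(table(draws0), p = c(0.5, 0.5))$p.value, 0.01)
})

test_that("a merging pass visits everything and only accepts error reductions", {
  sim <- small_strong_sim()
  ds <- sim$dataset
  cfg <- initialConfiguration(ds, "ct1", mode = "all-boundaries")
  kmers <- c(names(sim$truth$planted$kmers), "ACGTAC", "TTTTTT")
  out <- withr::with_seed(5, randomBinaryMerging(cfg, ds, kmers))
  sg0 <- segmentTable(cfg)
  sg1 <- segmentTable(out$configuration)
  expect_lte(nrow(sg1), nrow(sg0))
  expect_true(all(diff(out$acceptedErrors) < 0))
  expect_valid(out$configuration)
  # the pass result's error equals the error recomputed from scratch
  expect_equal(out$error, computeError(out$configuration, out$model, ds),
               tolerance = 1e-8)
})

test_that("an error-reducing merge is accepted and an adverse one rejected", {
  # two adjacent same-label singleton segments with identical features:
  # merging halves the number of (identically scored) residuals
  ds <- make_tiny_dataset(levels_a = c(0.9, 0.9, 0.1, 0.1, 0.1),
                          levels_b = c(0.9, 0.9, 0.1))
  v <- methylseg:::cell_type_view(ds, "ct1", 0.5)
  start <- methylseg:::configuration_from_bits(
    v, list(a = rep(TRUE, 4), b = rep(TRUE, 2)))
  out <- withr::with_seed(11, randomBinaryMerging(start, ds, c("CG", "AA")))
  expect_lt(nrow(segmentTable(out$configuration)), nrow(segmentTable(start)))
  expect_lte(out$error,
             computeError(start, fitKmerLogistic(
               segmentFeatureMatrix(start, c("CG", "AA"), ds),
               segmentTable(start)$label), ds) + 1e-12)

  # frozen-model test stage: the only eligible merge would flip the merged
  # label against strong scores, so it is rejected
  #         TTCGAAACGTTTTCGTTTCGTT  -> CpGs at 3, 8, 14, 19
  amp <- Biostrings::DNAStringSet(c(c = "TTCGAAACGTTTTCGTTTCGTT"))
  S4Vectors::mcols(amp) <- S4Vectors::DataFrame(
    chrom = "chrT", start = 0L, end = 22L,
    cpgOffsets = I(list(c(3L, 8L, 14L, 19L))))
  rec <- data.frame(chrom = "chrT", pos = c(3, 8, 14, 19) - 1, strand = "+",
                    level = c(0.9, 0.9, 0.1, 0.1), coverage = 1L,
                    cellType = "ct1")
  ds2 <- assembleDataset(amp, rec)
  init <- initialConfiguration(ds2, "ct1")
  expect_equal(nrow(segmentTable(init)), 2L)
  strong <- new("KmerLogisticModel", kmers = c("AAA", "TTT"),
                betas = c(10, 0), intercept = -5, ridge = 0,
                converged = TRUE, iterations = 1L)
  # the model scores the two segments near-perfectly before merging
  E0 <- computeError(init, strong, ds2)
  expect_lt(E0, 1e-3)
  res <- withr::with_seed(3, randomBinaryMerging(init, ds2, stage = "test",
                                                 model = strong))
  expect_equal(segmentTable(res$configuration), segmentTable(init))
  expect_equal(res$error, E0)
})

test_that("random configuration search stops on small improvements", {
  sim <- small_strong_sim()
  ds <- sim$dataset
  kmers <- c(names(sim$truth$planted$kmers), "ACGTAC")
  # a delta no pass can beat (improvement is bounded by the initial error)
  # returns the initial configuration after one pass
  res <- withr::with_seed(4, randomConfigurationSearch(ds, "ct1", kmers,
                                                       delta = 1e9))
  init <- initialConfiguration(ds, "ct1")
  expect_equal(segmentTable(res$configuration), segmentTable(init))
  expect_equal(res$trace$passes$pass, 0L)

  # accepted-state errors decrease monotonically at the default delta
  res2 <- withr::with_seed(4, randomConfigurationSearch(ds, "ct1", kmers))
  expect_true(all(diff(res2$trace$acceptedErrors) < 0))
  expect_true(all(diff(res2$trace$passes$E) < 0))
})

test_that("hill climbing keeps the best restart and is deterministic", {
  sim <- small_strong_sim(nAmplicons = 8)
  ds <- sim$dataset
  kmers <- c(names(sim$truth$planted$kmers), "ACGTAC", "GGGGGG")
  hc1 <- hillClimbingSearch(ds, "ct1", kmers, nRestarts = 3, seed = 42)
  expect_equal(hc1$error, min(hc1$trace$restarts$E))
  expect_length(hc1$trace$accepted, 3L)
  # E* is bounded by the initial configuration's own-fit error
  expect_lte(hc1$error, hc1$trace$accepted[[1]][1] + 1e-12)

  hc2 <- hillClimbingSearch(ds, "ct1", kmers, nRestarts = 3, seed = 42)
  expect_identical(segmentTable(hc1$configuration),
                   segmentTable(hc2$configuration))
  expect_identical(hc1$model@betas, hc2$model@betas)
  expect_identical(hc1$error, hc2$error)
})

test_that("merging only removes boundaries and preserves the site partition", {
  sim <- small_strong_sim(nAmplicons = 6, seed = 77)
  ds <- sim$dataset
  kmers <- c(names(sim$truth$planted$kmers), "ACGTAC")
  init <- initialConfiguration(ds, "ct1")
  hc <- hillClimbingSearch(ds, "ct1", kmers, nRestarts = 2, seed = 9)
  b0 <- boundaryBits(init)
  b1 <- boundaryBits(hc$configuration)
  for (a in names(b0)) {
    # 1 -> 0 only: every surviving boundary existed initially
    expect_true(all(b0[[a]][b1[[a]]]))
  }
  # partition invariant: segments tile every amplicon's measured sites
  sg <- segmentTable(hc$configuration)
  st <- siteTable(ds)
  for (a in unique(sg$amplicon)) {
    rows <- sg[sg$amplicon == a, ]
    n_sites <- sum(st$amplicon == a & st$cellType == "ct1")
    covered <- unlist(mapply(seq, rows$firstSite, rows$lastSite,
                             SIMPLIFY = FALSE))
    expect_equal(sort(covered), seq_len(n_sites))
  }
  expect_valid(hc$configuration)
})

test_that("search traces serialize to JSON", {
  sim <- small_strong_sim(nAmplicons = 5, seed = 13)
  hc <- hillClimbingSearch(sim$dataset, "ct1",
                           names(sim$truth$planted$kmers), nRestarts = 2,
                           seed = 1)
  f <- withr::local_tempfile(fileext = ".json")
  writeTraceJson(hc$trace, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(nrow(back$restarts), 2L)
})
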