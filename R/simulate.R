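#' Simulate amplicons with planted k-mer-driven methylation blocks
#'
#' Generates a synthetic bisulfite-style dataset in which methylation
#' susceptibility is block-structured along each amplicon and driven by
#' planted k-mers through the package's own logistic forward model, so the
#' whole pipeline can be exercised against a known ground truth.
#'
#' Per amplicon: a random background sequence is drawn and `CG` dinucleotides
#' are written at jittered grid positions to hit the target CpG density; the
#' CpG sites are partitioned into blocks whose sizes are
#' `1 + Poisson(blocksMean - 1)`; with probability `plantRate` a block
#' receives embedded copies of the planted k-mers (roughly one copy per
#' `plantEvery` bp of block span; embedding never overwrites a measured CpG).
#' For cell type \eqn{c} and block \eqn{b} the susceptibility is
#' \deqn{q_{cb} = \mathrm{logistic}(\gamma_{0c} + \sum_m \gamma_{cm}
#'   \cdot \mathrm{count}_b(m)),}
#' with counts taken from the realized sequence, and each site's methylation
#' level is drawn from `Beta(q * kappa, (1 - q) * kappa)` — continuous levels
#' in \eqn{[0,1]} like bisulfite-derived ratios, with `kappa` controlling the
#' within-block noise.
#'
#' Cell-type specificity: the planted effect alternates sign across cell
#' types (\eqn{\gamma_{cm} = \gamma_m \cdot (-1)^{c-1}}) over the shared
#' sequence. The baseline defaults to \eqn{\gamma_0 = 0}: blocks without a
#' planted copy sit at \eqn{q = 0.5} (sites there are labeled by a fair
#' coin — irreducible noise), while a single planted copy drives a block to
#' \eqn{q = \mathrm{logistic}(\pm 4) \approx 0.98} or \eqn{0.02}. With all
#' effects zero every block has \eqn{q = 0.5} and the labels are
#' independent of sequence (the null model).
#'
#' @param nAmplicons Number of amplicons (default 60).
#' @param ampliconLength Length in bp of each amplicon (default 2000).
#' @param cpgDensity Target CpG sites per bp (default 0.01, i.e. ~20 sites
#'   per 2 kb amplicon).
#' @param plantedKmers Named numeric vector: planted k-mer strings mapped to
#'   their base effect sizes \eqn{\gamma_m} (default `c(GATTAC = 4)`).
#' @param gamma0 Optional numeric vector of per-cell-type baselines; default
#'   as described above.
#' @param blocksMean Mean CpG sites per true block (default 6).
#' @param kappa Beta concentration of site-level noise (default 20).
#' @param nCellTypes Number of cell types (default 2).
#' @param plantRate Probability a block receives planted copies (default 0.5).
#' @param plantEvery Approximate bp of block span per embedded copy
#'   (default 200).
#' @param seed Integer seed; output is byte-identical given the seed.
#' @param out Optional directory; when given, writes `amplicons.fa`,
#'   `methylation.tsv` and `truth.json` there.
#' @return List with `dataset` (a [MethylationDataset-class]), `truth` (list:
#'   `boundaries` — per cell type, per amplicon logical boundary bits of the
#'   identifiable block boundaries, i.e. gaps where the susceptibility `q`
#'   changes (a gap between two equal-`q` blocks is unrecoverable by any
#'   method and is not counted); `blockBits` — the raw block partition;
#'   `blockQ` — per cell type, per amplicon block susceptibilities;
#'   `planted` — k-mers, per-cell-type effect matrix and baselines), and
#'   `records` (the methylation table as a `data.frame`).
#' @export
simulateMethylationData <- function(nAmplicons = 60, ampliconLength = 2000,
                                    cpgDensity = 0.01,
                                    plantedKmers = c(GATTAC = 4),
                                    gamma0 = NULL, blocksMean = 6,
                                    kappa = 20, nCellTypes = 2,
                                    plantRate = 0.5, plantEvery = 200,
                                    seed = 1, out = NULL) {
  stopifnot(kappa > 0, blocksMean >= 1, nAmplicons >= 1,
            plantRate >= 0, plantRate <= 1)
  kmer_names <- names(plantedKmers)
  if (length(plantedKmers) && is.null(kmer_names)) {
    stop("plantedKmers must be a named vector (kmer = effect)")
  }
  nCpg <- max(2L, round(ampliconLength * cpgDensity))
  if (nCpg * 3L > ampliconLength) stop("infeasible CpG density")
  cts <- paste0("ct", seq_len(nCellTypes))
  gmat <- outer((-1)^(seq_len(nCellTypes) - 1L), unname(plantedKmers))
  rownames(gmat) <- cts
  if (is.null(gamma0)) gamma0 <- 0
  gamma0 <- rep_len(gamma0, nCellTypes)
  names(gamma0) <- cts

  sim <- withr::with_seed(seed, {
    amp_ids <- sprintf("amp%03d", seq_len(nAmplicons))
    seq_list <- character(nAmplicons)
    off_list <- vector("list", nAmplicons)
    bits_list <- vector("list", nAmplicons)
    q_list <- lapply(cts, function(ct) vector("list", nAmplicons))
    names(q_list) <- cts
    rec <- list()

    for (i in seq_len(nAmplicons)) {
      chars <- sample(c("A", "C", "G", "T"), ampliconLength, replace = TRUE)
      spacing <- ampliconLength / nCpg
      pos <- round((seq_len(nCpg) - 0.5) * spacing +
                     stats::runif(nCpg, -0.25, 0.25) * spacing)
      pos <- pmin(pmax(pos, 2L), ampliconLength - 2L)
      pos <- sort(unique(pos))
      while (any(diff(pos) < 3L)) pos <- pos[c(TRUE, diff(pos) >= 3L)]
      chars[pos] <- "C"; chars[pos + 1L] <- "G"

      # block partition of the CpG sites
      n <- length(pos)
      sizes <- integer(0)
      while (sum(sizes) < n) {
        sizes <- c(sizes, 1L + stats::rpois(1L, max(blocksMean - 1, 0)))
      }
      sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
      if (sizes[length(sizes)] == 0L) sizes <- sizes[-length(sizes)]
      ends <- cumsum(sizes)
      starts <- ends - sizes + 1L
      bits <- rep(FALSE, n - 1L)
      bits[ends[-length(ends)]] <- TRUE

      # embed planted k-mers into randomly chosen blocks
      if (length(plantedKmers)) {
        protected <- c(pos, pos + 1L)
        for (b in seq_along(sizes)) {
          if (stats::runif(1) >= plantRate) next
          span_from <- pos[starts[b]]
          span_to <- pos[ends[b]] + 1L
          ncopies <- max(1L, round((span_to - span_from + 1L) / plantEvery))
          for (cp in seq_len(ncopies)) {
            km <- kmer_names[1L + (cp - 1L) %% length(kmer_names)]
            w <- nchar(km)
            for (try in seq_len(100L)) {
              at <- sample(span_from:max(span_from, span_to - w + 1L), 1L)
              idx <- at:(at + w - 1L)
              if (max(idx) > ampliconLength) next
              if (any(idx %in% protected)) next
              chars[idx] <- strsplit(km, "")[[1]]
              protected <- c(protected, idx)
              break
            }
          }
        }
      }

      seq_i <- paste(chars, collapse = "")
      seq_list[i] <- seq_i
      off_list[[i]] <- pos
      bits_list[[i]] <- bits

      # block susceptibilities from the realized sequence, then site levels
      spans <- substring(seq_i, pos[starts], pos[ends] + 1L)
      counts <- if (length(plantedKmers)) {
        vapply(spans, function(sp) {
          vapply(kmer_names, function(km) {
            length(gregexpr(km, sp, fixed = TRUE)[[1]][
              gregexpr(km, sp, fixed = TRUE)[[1]] > 0])
          }, numeric(1))
        }, numeric(length(plantedKmers)))
      } else matrix(0, 0, length(spans))
      counts <- matrix(counts, nrow = length(plantedKmers))
      for (ct in cts) {
        q <- stats::plogis(gamma0[[ct]] +
          if (length(plantedKmers)) drop(gmat[ct, , drop = FALSE] %*% counts)
          else 0)
        q_list[[ct]][[i]] <- unname(q)
        site_q <- rep(q, times = sizes)
        lv <- stats::rbeta(n, site_q * kappa, (1 - site_q) * kappa)
        rec[[length(rec) + 1L]] <- data.frame(
          chrom = "chr21",
          pos = (i - 1L) * (ampliconLength + 500L) + pos - 1L,
          strand = "+", level = lv,
          coverage = stats::rpois(n, 50) + 1L,
          cellType = ct, stringsAsFactors = FALSE)
      }
    }
    list(ids = amp_ids, seqs = seq_list, offsets = off_list,
         bits = bits_list, q = q_list, records = do.call(rbind, rec))
  })

  amp <- Biostrings::DNAStringSet(sim$seqs)
  names(amp) <- sim$ids
  starts <- (seq_len(nAmplicons) - 1L) * (ampliconLength + 500L)
  S4Vectors::mcols(amp) <- S4Vectors::DataFrame(
    chrom = "chr21", start = starts, end = starts + ampliconLength,
    cpgOffsets = I(lapply(seq_len(nAmplicons), function(i) {
      cg_offsets(sim$seqs[i])
    })))
  dataset <- assembleDataset(amp, sim$records)
  names(sim$bits) <- sim$ids
  for (ct in cts) names(sim$q[[ct]]) <- sim$ids
  # Identifiable truth boundaries: a gap between two blocks of equal
  # susceptibility q cannot be recovered by any method, so only gaps where q
  # changes count as true boundaries for recovery scoring.
  effective_bits <- lapply(cts, function(ct) {
    out <- lapply(seq_len(nAmplicons), function(i) {
      bits <- sim$bits[[i]]
      q <- sim$q[[ct]][[i]]
      dq <- abs(diff(q)) > 1e-12
      keep <- bits
      keep[bits] <- dq
      keep
    })
    names(out) <- sim$ids
    out
  })
  truth <- list(
    boundaries = stats::setNames(effective_bits, cts),
    blockBits = sim$bits,
    blockQ = sim$q,
    planted = list(kmers = plantedKmers, gammaByCellType = gmat,
                   gamma0 = gamma0),
    params = list(nAmplicons = nAmplicons, ampliconLength = ampliconLength,
                  cpgDensity = cpgDensity, blocksMean = blocksMean,
                  kappa = kappa, plantRate = plantRate,
                  plantEvery = plantEvery, seed = seed))

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    fa <- amp
    names(fa) <- sprintf("%s %s:%d-%d", sim$ids, "chr21", starts,
                         starts + ampliconLength)
    Biostrings::writeXStringSet(fa, file.path(out, "amplicons.fa"))
    writeMethylationTable(sim$records, file.path(out, "methylation.tsv"))
    jsonlite::write_json(
      list(boundaries = lapply(truth$boundaries[[1]], as.integer),
           blockQ = truth$blockQ,
           planted = list(kmers = as.list(plantedKmers),
                          gamma0 = as.list(gamma0)),
           params = truth$params),
      file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  list(dataset = dataset, truth = truth, records = sim$records)
}

#' Boundary recovery of a configuration against the simulation truth
#'
#' Treats boundary positions (gaps with \eqn{B_i = 1}) as a set and scores
#' the configuration's boundaries against the generator's true block
#' boundaries.
#'
#' @param configuration A [SegmentConfiguration-class].
#' @param truth The `truth` element of [simulateMethylationData()].
#' @return Named numeric: `precision`, `recall`, `f1`. With no found
#'   boundaries, precision is vacuously 1 and recall (hence F1) is 0 unless
#'   the truth is also empty.
#' @export
boundaryRecoveryScore <- function(configuration, truth) {
  found <- boundaryBits(configuration)
  tb <- truth$boundaries[[configuration@cellType]]
  if (is.null(tb)) stop("truth has no cell type '", configuration@cellType, "'")
  if (!all(names(found) %in% names(tb))) {
    stop("configuration amplicons do not match the truth")
  }
  tp <- fp <- fn <- 0L
  for (a in names(found)) {
    f <- found[[a]]; t <- tb[[a]]
    if (length(f) != length(t)) {
      stop("gap count mismatch for amplicon '", a, "'")
    }
    tp <- tp + sum(f & t); fp <- fp + sum(f & !t); fn <- fn + sum(!f & t)
  }
  precision <- if (tp + fp == 0L) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 1 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}
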