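#' Count k-mers in a sequence by sliding window
#'
#' Overlapping windows of length `k` (stride 1); any window containing a
#' non-ACGT base (e.g. `N`) is skipped, so masked sequence never contributes
#' counts. Only observed k-mers are returned.
#'
#' @param sequence A character string or [Biostrings::DNAString] over
#'   \{A,C,G,T,N\}.
#' @param k K-mer length, \eqn{1 \le k \le 8}.
#' @return Named integer vector of occurrence counts (possibly empty, e.g.
#'   when `k > nchar(sequence)`).
#' @examples
#' countKmers("ACGACG", 3)  # ACG=2, CGA=1, GAC=1
#' @importFrom Biostrings oligonucleotideFrequency DNAString
#' @export
countKmers <- function(sequence, k) {
  stopifnot(k >= 1, k <= 8)
  if (is.character(sequence)) sequence <- Biostrings::DNAString(toupper(sequence))
  if (length(sequence) < k) return(integer(0))
  counts <- Biostrings::oligonucleotideFrequency(sequence, width = k)
  counts <- counts[counts > 0]
  storage.mode(counts) <- "integer"
  counts
}

#' Extract the flanking sequence centered at a CpG site
#'
#' Returns the window of length `l` centered on the CG dinucleotide:
#' `l/2 - 1` bases left of the C through `l/2 - 1` bases right of the G.
#' Windows running past the amplicon ends are truncated, never padded.
#'
#' @param sequence Amplicon sequence (character).
#' @param cpgOffset 1-based offset of the C of the CpG in `sequence`.
#' @param l Total flank length; even, at least 2 (default 100).
#' @return Character substring of `sequence`.
#' @examples
#' extractSiteFlank("AAACGTTT", 4, l = 4)  # "ACGT"
#' @export
extractSiteFlank <- function(sequence, cpgOffset, l = 100) {
  stopifnot(l >= 2, l %% 2 == 0)
  sequence <- toupper(as.character(sequence))
  if (substring(sequence, cpgOffset, cpgOffset + 1L) != "CG") {
    stop("offset ", cpgOffset, " is not a CpG site")
  }
  from <- max(1L, cpgOffset - (l %/% 2L - 1L))
  to <- min(nchar(sequence), cpgOffset + 1L + (l %/% 2L - 1L))
  substring(sequence, from, to)
}

#' Build labeled k-mer instances from CpG-site flanks
#'
#' One instance per measured CpG site of a cell type: the k-mer counts of the
#' site's length-`l` flank, labeled `+` iff its methylation level exceeds
#' `threshold`. The k-mer universe is every k-mer observed in the instances
#' (not all \eqn{4^k} strings).
#'
#' @param dataset A [MethylationDataset-class].
#' @param cellType Cell type to take sites from.
#' @param ampliconIds Optional subset of amplicons (e.g. a training fold).
#' @param k K-mer length.
#' @param l Flank length (default 100, truncated at amplicon ends).
#' @param threshold Site labeling threshold (label `+` iff level > threshold).
#' @return A [KmerInstances-class]; rownames are `amplicon:offset`.
#' @export
siteInstances <- function(dataset, cellType, ampliconIds = NULL, k = 6,
                          l = 100, threshold = 0.5) {
  st <- siteTable(dataset)
  st <- st[st$cellType == cellType, , drop = FALSE]
  if (!is.null(ampliconIds)) st <- st[st$amplicon %in% ampliconIds, , drop = FALSE]
  if (!nrow(st)) stop("no sites for cell type '", cellType, "'")
  seqs <- as.character(ampliconSeqs(dataset))
  flanks <- mapply(function(a, o) extractSiteFlank(seqs[[a]], o, l),
                   st$amplicon, st$offset)
  counts <- kmer_count_matrix(flanks, k)
  rownames(counts) <- paste0(st$amplicon, ":", st$offset)
  new("KmerInstances", counts = counts,
      labels = plus_minus(st$level > threshold), k = as.integer(k))
}

# Observed-kmer count matrix for a character vector of sequences.
kmer_count_matrix <- function(seqs, k) {
  mat <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = k)
  mat <- mat[, colSums(mat) > 0, drop = FALSE]
  mat
}

#' Balance classes by down-sampling the majority class
#'
#' The majority class is down-sampled uniformly at random to the minority
#' size and the result is shuffled, deterministically for a given seed.
#'
#' @param instances A [KmerInstances-class] with both classes present.
#' @param seed Integer seed.
#' @return A balanced [KmerInstances-class].
#' @export
balanceClasses <- function(instances, seed) {
  lab <- instances@labels
  n_pos <- sum(lab == "+"); n_neg <- sum(lab == "-")
  if (n_pos == 0L || n_neg == 0L) {
    stop("cannot balance: one class is absent (", n_pos, " +, ", n_neg, " -)")
  }
  m <- min(n_pos, n_neg)
  keep <- withr::with_seed(seed, {
    idx <- c(sample(which(lab == "+"), m), sample(which(lab == "-"), m))
    sample(idx)
  })
  new("KmerInstances",
      counts = instances@counts[keep, , drop = FALSE],
      labels = lab[keep], k = instances@k)
}

# Vectorized two-sided Welch t-test p-values, one per column of x between the
# two label groups. Zero-variance-in-both-groups columns: p = 1 when the
# means agree (no signal), p = 0 when they differ (perfect separation);
# stats::t.test is the per-column oracle for the regular case.
welch_p_values <- function(x, plus) {
  x1 <- x[plus, , drop = FALSE]; x2 <- x[!plus, , drop = FALSE]
  n1 <- nrow(x1); n2 <- nrow(x2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- colSums(sweep(x1, 2, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(x2, 2, m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  p <- numeric(ncol(x))
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  if (any(!degen)) {
    tstat <- (m1[!degen] - m2[!degen]) / sqrt(se2[!degen])
    df <- se2[!degen]^2 /
      ((v1[!degen] / n1)^2 / (n1 - 1) + (v2[!degen] / n2)^2 / (n2 - 1))
    p[!degen] <- 2 * stats::pt(-abs(tstat), df)
  }
  names(p) <- colnames(x)
  p
}

#' Select k-mers by two-sample t-test
#'
#' For each k-mer, occurrence counts in positive vs. negative instances are
#' compared with a Welch (unequal-variance) two-sided t-test; k-mers are
#' ranked by ascending p-value (ties broken lexicographically) and either the
#' top `m` or all with `p < alpha` are returned.
#'
#' @param instances A (preferably class-balanced) [KmerInstances-class].
#' @param m Number of k-mers to select (exclusive with `alpha`).
#' @param alpha P-value threshold (exclusive with `m`).
#' @return A [FeatureSelectionResult-class] with p-values as scores.
#' @export
selectTtest <- function(instances, m = NULL, alpha = NULL) {
  if (is.null(m) == is.null(alpha)) stop("give exactly one of m or alpha")
  x <- instances@counts
  if (ncol(x) < 1L) stop("no k-mer features present")
  plus <- instances@labels == "+"
  if (!any(plus) || all(plus)) stop("both classes are required")
  p <- welch_p_values(x, plus)
  ord <- order(p, names(p))
  if (!is.null(m)) {
    if (m > length(p)) {
      warning("requested ", m, " k-mers but only ", length(p),
              " are observed; returning all")
      m <- length(p)
    }
    sel <- names(p)[ord][seq_len(m)]
  } else {
    sel <- names(p)[ord][p[ord] < alpha]
  }
  new("FeatureSelectionResult", method = "ttest", selected = sel,
      scores = p[sel],
      params = list(m = m, alpha = alpha, variant = "welch"))
}

#' One random-forest importance run
#'
#' Fits a random-forest classifier, standardizes the per-feature importances
#' to z-scores within the run (`(importance - mean) / sd` across features;
#' all z = 0 when sd = 0), and returns the top `nTop` features among those
#' with z-score > 0.
#'
#' @param instances A class-balanced [KmerInstances-class] with >= 2 features.
#' @param nTrees Trees per forest (default 100).
#' @param nTop Maximum number of features returned (default 100).
#' @param seed Integer seed.
#' @return Character vector of k-mers (possibly empty).
#' @importFrom randomForest randomForest importance
#' @export
rfImportanceRun <- function(instances, nTrees = 100, nTop = 100, seed = 1) {
  x <- instances@counts
  if (ncol(x) < 2L) stop("random-forest selection needs at least 2 features")
  stopifnot(nTrees >= 1)
  # constant features admit no split and can never earn positive importance;
  # with none varying the selection is empty by definition
  varying <- col_vars(x) > 0
  if (!any(varying)) return(character(0))
  x <- x[, varying, drop = FALSE]
  y <- factor(instances@labels, levels = c("-", "+"))
  rf <- withr::with_seed(seed,
    randomForest::randomForest(x, y, ntree = nTrees))
  imp <- randomForest::importance(rf)[, 1L]
  s <- stats::sd(imp)
  z <- if (is.na(s) || s == 0) rep(0, length(imp)) else (imp - mean(imp)) / s
  pos <- which(z > 0)
  pos <- pos[order(-imp[pos], names(imp)[pos])]
  names(imp)[utils::head(pos, nTop)]
}

#' Consensus retention rule over repeated selection runs
#'
#' A feature is retained when it appears in at least
#' `ceiling(pPct/100 * length(runSets))` of the runs.
#'
#' @param runSets List of character vectors, one per run.
#' @param pPct Consensus percentage (default 90).
#' @return Named numeric vector of appearance fractions for the retained
#'   features, ordered by descending fraction then lexicographically.
#' @export
consensusSelect <- function(runSets, pPct = 90) {
  k_runs <- length(runSets)
  need <- ceiling(pPct / 100 * k_runs)
  tab <- table(unlist(lapply(runSets, unique)))
  keep <- tab[tab >= need]
  frac <- as.numeric(keep) / k_runs
  names(frac) <- names(keep)
  frac[order(-frac, names(frac))]
}

#' Select k-mers by consensus random-forest importance
#'
#' Runs [rfImportanceRun()] `kRuns` times with derived per-run seeds and
#' keeps the k-mers appearing in at least `pPct`% of the runs. Defaults are
#' `kRuns = 30`, `nTrees = 100`, `nTop = 100`, `pPct = 90`.
#'
#' @param instances A class-balanced [KmerInstances-class].
#' @param kRuns Number of forest runs.
#' @param nTrees Trees per forest.
#' @param nTop Top features collected per run (among z-score > 0).
#' @param pPct Consensus percentage for retention.
#' @param seed Master seed; per-run seeds are derived from it.
#' @return A [FeatureSelectionResult-class] with appearance fractions as
#'   scores.
#' @export
selectRfConsensus <- function(instances, kRuns = 30, nTrees = 100,
                              nTop = 100, pPct = 90, seed = 1) {
  runs <- lapply(seq_len(kRuns), function(i) {
    rfImportanceRun(instances, nTrees = nTrees, nTop = nTop,
                    seed = derive_seed(seed, i))
  })
  frac <- consensusSelect(runs, pPct)
  new("FeatureSelectionResult", method = "rf_consensus",
      selected = names(frac), scores = frac,
      params = list(kRuns = kRuns, nTrees = nTrees, nTop = nTop,
                    pPct = pPct, seed = seed))
}
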