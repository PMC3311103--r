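# Internal per-cell-type view: for each amplicon with measurements, its
# ordered site offsets, levels and logical +/- labels. All segment and
# search code operates on this structure plus the amplicon sequences.
cell_type_view <- function(dataset, cellType, threshold = 0.5) {
  st <- siteTable(dataset)
  st <- st[st$cellType == cellType, , drop = FALSE]
  if (!nrow(st)) stop("no sites for cell type '", cellType, "'")
  seqs <- as.character(ampliconSeqs(dataset))
  amps <- intersect(names(seqs), unique(st$amplicon))
  sites <- lapply(amps, function(a) {
    rows <- st[st$amplicon == a, , drop = FALSE]
    rows <- rows[order(rows$offset), , drop = FALSE]
    list(offsets = rows$offset, levels = rows$level,
         labels = rows$level > threshold)
  })
  names(sites) <- amps
  list(cellType = cellType, threshold = threshold,
       amplicons = amps, seqs = seqs[amps], sites = sites)
}

# Build a SegmentConfiguration from a view and per-amplicon boundary bits
# (logical vectors, TRUE = B_i = 1 at the gap after site i).
configuration_from_bits <- function(view, bits) {
  rows <- lapply(view$amplicons, function(a) {
    s <- view$sites[[a]]
    n <- length(s$offsets)
    if (n == 0L) return(NULL)
    b <- bits[[a]]
    cut <- which(c(b, TRUE))           # last site index of each segment
    first <- c(1L, utils::head(cut, -1L) + 1L)
    p <- vapply(seq_along(cut), function(i) {
      mean(s$labels[first[i]:cut[i]])
    }, numeric(1))
    data.frame(amplicon = a, firstSite = first, lastSite = cut,
               nSites = cut - first + 1L, pPlus = p, label = p > 0.5,
               startOffset = s$offsets[first],
               endOffset = s$offsets[cut] + 1L,
               stringsAsFactors = FALSE)
  })
  sg <- do.call(rbind, rows)
  rownames(sg) <- NULL
  new("SegmentConfiguration", cellType = view$cellType,
      threshold = view$threshold, segments = sg)
}

#' Label CpG sites as methylation susceptible (+) or resistant (-)
#'
#' A site is labeled `+` iff its methylation level strictly exceeds the
#' threshold; a level exactly at the threshold is `-`, mirroring the strict
#' `p > 0.5` rule used for segment labels.
#'
#' @param dataset A [MethylationDataset-class].
#' @param cellType Cell type to label.
#' @param threshold Labeling threshold (default 0.5).
#' @return `data.frame` with columns `amplicon`, `offset`, `level`, `label`
#'   (`"+"`/`"-"`), ordered by amplicon then offset.
#' @export
labelSites <- function(dataset, cellType, threshold = 0.5) {
  v <- cell_type_view(dataset, cellType, threshold)
  do.call(rbind, lapply(v$amplicons, function(a) {
    s <- v$sites[[a]]
    data.frame(amplicon = a, offset = s$offsets, level = s$levels,
               label = plus_minus(s$labels), stringsAsFactors = FALSE)
  }))
}

#' Initial segment configuration
#'
#' `"label-change"` (default) sets a boundary variable \eqn{B_i = 1} at every
#' gap where the labels of the two adjacent CpG sites differ, giving the
#' configuration of smallest label-homogeneous segments (maximal runs of one
#' label). `"all-boundaries"` sets every \eqn{B_i = 1}, one singleton segment
#' per CpG site.
#'
#' @param dataset A [MethylationDataset-class].
#' @param cellType Cell type.
#' @param mode `"label-change"` or `"all-boundaries"`.
#' @param threshold Site labeling threshold.
#' @return A [SegmentConfiguration-class].
#' @export
initialConfiguration <- function(dataset, cellType,
                                 mode = c("label-change", "all-boundaries"),
                                 threshold = 0.5) {
  mode <- match.arg(mode)
  v <- cell_type_view(dataset, cellType, threshold)
  initial_configuration_view(v, mode)
}

initial_configuration_view <- function(view, mode = "label-change") {
  bits <- lapply(view$amplicons, function(a) {
    lab <- view$sites[[a]]$labels
    n <- length(lab)
    if (n <= 1L) return(logical(0))
    if (mode == "all-boundaries") rep(TRUE, n - 1L)
    else lab[-n] != lab[-1L]
  })
  names(bits) <- view$amplicons
  configuration_from_bits(view, bits)
}

#' Segment methylation ratios, labels and error weights
#'
#' For each segment: the methylation ratio \eqn{p_i} (fraction of its CpG
#' sites labeled +), the label \eqn{t_i} (`+` iff \eqn{p_i > 0.5}), and the
#' squared-error weight \eqn{w_i = \bar S / |S_i|}, where \eqn{\bar S} is the
#' mean number of CpG sites per segment in the configuration. Large segments
#' are penalized less, and vice versa.
#'
#' @param configuration A [SegmentConfiguration-class].
#' @return `data.frame` with columns `amplicon`, `nSites`, `p`, `t`
#'   (`"+"`/`"-"`), `w`.
#' @export
segmentWeights <- function(configuration) {
  sg <- segmentTable(configuration)
  sbar <- meanSegmentSize(configuration)
  data.frame(amplicon = sg$amplicon, nSites = sg$nSites, p = sg$pPlus,
             t = plus_minus(sg$label), w = sbar / sg$nSites,
             stringsAsFactors = FALSE)
}

#' K-mer occurrence matrix of a configuration's segments
#'
#' One row per segment; each entry is the occurrence count of a selected
#' k-mer within the segment's genomic span (the first CpG's C through the
#' last CpG's G, inclusive).
#'
#' @param configuration A [SegmentConfiguration-class].
#' @param kmers Non-empty character vector of equal-length k-mers.
#' @param dataset The [MethylationDataset-class] providing the sequences.
#' @return Numeric matrix (segments x k-mers).
#' @importFrom Biostrings PDict DNAStringSet vcountPDict
#' @export
segmentFeatureMatrix <- function(configuration, kmers, dataset) {
  if (!length(kmers)) stop("kmers must be non-empty")
  sg <- segmentTable(configuration)
  seqs <- as.character(ampliconSeqs(dataset))
  if (!nrow(sg)) {
    return(matrix(0, 0, length(kmers), dimnames = list(NULL, kmers)))
  }
  spans <- substring(seqs[sg$amplicon], sg$startOffset, sg$endOffset)
  span_count_matrix(spans, kmers)
}

span_count_matrix <- function(spans, kmers, pd = NULL) {
  if (is.null(pd)) pd <- Biostrings::PDict(kmers)
  m <- t(Biostrings::vcountPDict(pd, Biostrings::DNAStringSet(spans)))
  colnames(m) <- kmers
  m
}

# Count kmers in a single span with a prebuilt PDict (hot path of the
# merge search: one call per tentative merge).
span_counts <- function(span, kmers, pd = NULL) {
  if (is.null(pd)) pd <- Biostrings::PDict(kmers)
  counts <- Biostrings::countPDict(pd, Biostrings::DNAString(span))
  names(counts) <- kmers
  counts
}

#' Weighted squared configuration error
#'
#' The objective of the segment search:
#' \deqn{O(S) = \sum_i w_i (\hat y_i - t_i)^2, \quad w_i = \bar S / |S_i|,}
#' with segment labels \eqn{t_i} encoded as 1 (+) / 0 (-) and \eqn{\hat y_i}
#' the model's predicted methylation level of segment \eqn{i}.
#'
#' @param configuration A [SegmentConfiguration-class].
#' @param model A fitted [KmerLogisticModel-class].
#' @param dataset The [MethylationDataset-class] providing the sequences.
#' @return Non-negative scalar error.
#' @export
computeError <- function(configuration, model, dataset) {
  X <- segmentFeatureMatrix(configuration, model@kmers, dataset)
  error_from_scores(segmentTable(configuration), decisionScores(model, X))
}

error_from_scores <- function(sg, yhat) {
  sbar <- mean(sg$nSites)
  sum((sbar / sg$nSites) * (yhat - as.numeric(sg$label))^2)
}

#' Per-segment sampling error vector
#'
#' The weights used to bias the random choice of a merge candidate:
#' \deqn{e_j = (|S_j| / \bar S)\,(\hat y_j - t_j)^2.}
#' Note the weight is \eqn{|S_j| / \bar S} — the inverse of the error weight
#' of [computeError()] — so larger segments with poor fit are sampled more
#' often for merging.
#'
#' @inheritParams computeError
#' @return Numeric vector, one entry per segment.
#' @export
samplingErrorVector <- function(configuration, model, dataset) {
  X <- segmentFeatureMatrix(configuration, model@kmers, dataset)
  sg <- segmentTable(configuration)
  sampling_errors(sg, decisionScores(model, X))
}

sampling_errors <- function(sg, yhat) {
  sbar <- mean(sg$nSites)
  (sg$nSites / sbar) * (yhat - as.numeric(sg$label))^2
}

#' Enumerate every boundary-variable configuration
#'
#' Yields all \eqn{2^m} settings of the boundary variables of a cell type's
#' amplicons, where \eqn{m} is the total number of gaps between adjacent
#' measured CpG sites. Intended for exhaustive-search oracles on tiny
#' instances; refuses \eqn{m} above the guard.
#'
#' @param dataset A [MethylationDataset-class].
#' @param cellType Cell type.
#' @param threshold Site labeling threshold.
#' @param mGuard Maximum permitted \eqn{m} (default 20).
#' @return List of [SegmentConfiguration-class] objects, length \eqn{2^m}.
#' @export
enumerateAllConfigurations <- function(dataset, cellType, threshold = 0.5,
                                       mGuard = 20) {
  v <- cell_type_view(dataset, cellType, threshold)
  gaps <- vapply(v$sites, function(s) max(length(s$offsets) - 1L, 0L),
                 integer(1))
  m <- sum(gaps)
  if (m > mGuard) {
    stop("m = ", m, " boundary variables exceed the enumeration guard (",
         mGuard, "); 2^m configurations would be infeasible")
  }
  idx_end <- cumsum(gaps)
  idx_start <- idx_end - gaps + 1L
  lapply(seq_len(2^m) - 1L, function(mask) {
    allbits <- if (m) as.logical(bitwAnd(bitwShiftR(mask, 0:(m - 1L)), 1L)) else logical(0)
    bits <- lapply(seq_along(v$amplicons), function(i) {
      if (gaps[i] == 0L) logical(0) else allbits[idx_start[i]:idx_end[i]]
    })
    names(bits) <- v$amplicons
    configuration_from_bits(v, bits)
  })
}

#' Number of parenthesizations of n CpG sites
#'
#' The recurrence counting the full parenthesizations that motivate the
#' exponential size of the segment-configuration space:
#' \eqn{P(1) = 1}, \eqn{P(n) = \sum_{i=1}^{n-1} P(i) P(n-i)} for
#' \eqn{n \ge 2} (the shifted Catalan numbers).
#'
#' @param n Number of CpG sites, \eqn{n \ge 1}.
#' @return Exact integer count (as numeric; exact up to n = 30).
#' @examples
#' parenthesizationCount(4)  # 5
#' @export
parenthesizationCount <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n)) {
    stop("n must be a single integer >= 1")
  }
  P <- numeric(n)
  P[1] <- 1
  if (n >= 2) {
    for (m in 2:n) P[m] <- sum(P[1:(m - 1)] * P[(m - 1):1])
  }
  P[n]
}
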