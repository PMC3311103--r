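#' @import methods
#' @importFrom S4Vectors mcols mcols<-
NULL

#' MethylationDataset: amplicon sequences joined with per-site methylation
#'
#' The central container of the package. It holds promoter amplicon sequences
#' (a [Biostrings::DNAStringSet] whose metadata columns give the genomic span),
#' the 1-based offsets of every CpG dinucleotide within each amplicon, and a
#' table of per-site methylation levels, one row per (amplicon, cell type,
#' CpG offset). Methylation levels are real values in \eqn{[0, 1]}, the
#' fraction of bisulfite reads methylated at the site.
#'
#' Coordinates: genomic spans are 0-based half-open (BED convention); a CpG
#' site is addressed by the position of its C on the plus strand. Within an
#' amplicon, CpG offsets are 1-based positions of the C in the sequence
#' string, so `substring(seq, off, off + 1) == "CG"` always holds.
#'
#' @slot amplicons A `DNAStringSet`, names are amplicon ids; `mcols()` has
#'   columns `chrom`, `start`, `end` (0-based half-open genomic span).
#' @slot cpgOffsets Named list of sorted integer vectors: 1-based offsets of
#'   the C of each CpG dinucleotide in the corresponding amplicon sequence.
#' @slot sites A `data.frame` with columns `amplicon`, `cellType`, `offset`
#'   (1-based, must be a CpG offset), `level` in \eqn{[0,1]}, `coverage`.
#' @slot cellTypes Character vector of cell-type identifiers present.
#'
#' @seealso [assembleDataset()], [simulateMethylationData()]
#' @export
setClass("MethylationDataset",
  representation(
    amplicons  = "DNAStringSet",
    cpgOffsets = "list",
    sites      = "data.frame",
    cellTypes  = "character"
  )
)

setValidity("MethylationDataset", function(object) {
  amp <- object@amplicons
  ids <- names(amp)
  if (is.null(ids) || anyDuplicated(ids)) {
    return("amplicons must have unique names")
  }
  if (!setequal(names(object@cpgOffsets), ids)) {
    return("cpgOffsets names must match amplicon ids")
  }
  for (id in ids) {
    off <- object@cpgOffsets[[id]]
    if (length(off) == 0L) next
    if (is.unsorted(off, strictly = TRUE)) {
      return(sprintf("cpgOffsets for '%s' must be strictly increasing", id))
    }
    s <- as.character(amp[[id]])
    if (!all(substring(s, off, off + 1L) == "CG")) {
      return(sprintf("cpgOffsets for '%s' must index CG dinucleotides", id))
    }
  }
  st <- object@sites
  need <- c("amplicon", "cellType", "offset", "level", "coverage")
  if (!all(need %in% names(st))) {
    return("sites must have columns amplicon, cellType, offset, level, coverage")
  }
  if (nrow(st)) {
    if (any(st$level < 0 | st$level > 1)) return("site levels must lie in [0, 1]")
    if (!all(st$amplicon %in% ids)) return("site amplicon ids unknown")
    ok <- mapply(function(a, o) o %in% object@cpgOffsets[[a]], st$amplicon, st$offset)
    if (!all(ok)) return("every site offset must be a CpG offset of its amplicon")
    if (anyDuplicated(st[, c("amplicon", "cellType", "offset")])) {
      return("duplicate (amplicon, cellType, offset) measurement")
    }
  }
  TRUE
})

#' SegmentConfiguration: a partition of CpG sites into contiguous segments
#'
#' A configuration is the state searched over by the segment model: for one
#' cell type, every amplicon's ordered CpG sites are partitioned into
#' contiguous, non-overlapping segments. Equivalently, a configuration is an
#' assignment of the boundary variables \eqn{B_i \in \{0, 1\}}, one per gap
#' between adjacent CpG sites; a segment runs between two set boundaries.
#'
#' Each segment carries its methylation ratio `pPlus` (fraction of its sites
#' labeled +) and its label (`+` iff `pPlus > 0.5`, strictly).
#'
#' @slot cellType Cell type the configuration belongs to.
#' @slot threshold Site-level labeling threshold used to derive site labels.
#' @slot segments `data.frame` with one row per segment, ordered by amplicon
#'   then position: columns `amplicon`, `firstSite`, `lastSite` (1-based site
#'   indices within the amplicon's measured sites), `nSites`, `pPlus`,
#'   `label` (logical, TRUE = +), `startOffset`, `endOffset` (1-based sequence
#'   offsets of the first C and the last G spanned).
#' @export
setClass("SegmentConfiguration",
  representation(
    cellType  = "character",
    threshold = "numeric",
    segments  = "data.frame"
  )
)

setValidity("SegmentConfiguration", function(object) {
  sg <- object@segments
  need <- c("amplicon", "firstSite", "lastSite", "nSites", "pPlus", "label",
            "startOffset", "endOffset")
  if (!all(need %in% names(sg))) return("segments is missing required columns")
  if (!nrow(sg)) return(TRUE)
  if (any(sg$nSites < 1L)) return("every segment must contain at least one site")
  if (any(sg$nSites != sg$lastSite - sg$firstSite + 1L)) {
    return("nSites must equal lastSite - firstSite + 1")
  }
  if (any(sg$pPlus < 0 | sg$pPlus > 1)) return("pPlus must lie in [0, 1]")
  if (!all(sg$label == (sg$pPlus > 0.5))) {
    return("label must be + exactly when pPlus > 0.5")
  }
  for (a in unique(sg$amplicon)) {
    rows <- sg[sg$amplicon == a, ]
    if (rows$firstSite[1L] != 1L) return("segments must start at site 1")
    if (nrow(rows) > 1L &&
        !all(rows$firstSite[-1L] == rows$lastSite[-nrow(rows)] + 1L)) {
      return("segments must be contiguous and non-overlapping within an amplicon")
    }
  }
  TRUE
})

#' KmerLogisticModel: the k-mer mixture logistic regression
#'
#' Realizes the model \eqn{y = 1 / (1 + e^{-f(x)})} with
#' \eqn{f(x) = \beta_0 + \sum_i \beta_i x_i}, where each \eqn{x_i} is the
#' occurrence count of a selected k-mer and the \eqn{\beta_i} are learned by
#' (ridge-penalized) maximum likelihood. The intercept \eqn{\beta_0} is
#' included by default and never penalized; fitting with
#' `intercept = FALSE` recovers the pure mixture form.
#'
#' @slot kmers Ordered character vector of the selected k-mers \eqn{x_i}.
#' @slot betas Numeric coefficients aligned with `kmers`.
#' @slot intercept The unpenalized intercept \eqn{\beta_0} (0 when disabled).
#' @slot ridge L2 penalty strength used in fitting.
#' @slot converged Logical convergence flag of the optimizer.
#' @slot iterations Number of Newton iterations used.
#' @export
setClass("KmerLogisticModel",
  representation(
    kmers      = "character",
    betas      = "numeric",
    intercept  = "numeric",
    ridge      = "numeric",
    converged  = "logical",
    iterations = "integer"
  )
)

setValidity("KmerLogisticModel", function(object) {
  if (length(object@betas) != length(object@kmers)) {
    return("betas must align with kmers")
  }
  if (!all(is.finite(object@betas)) || !is.finite(object@intercept)) {
    return("all coefficients must be finite")
  }
  if (length(object@ridge) != 1L || object@ridge < 0) {
    return("ridge must be a single non-negative number")
  }
  TRUE
})

#' FeatureSelectionResult: outcome of k-mer feature selection
#'
#' @slot method Either `"ttest"` (Welch two-sample t-test ranking) or
#'   `"rf_consensus"` (consensus of repeated random-forest importance runs).
#' @slot selected Ordered, duplicate-free character vector of retained k-mers;
#'   for `"ttest"` ordered by ascending p-value.
#' @slot scores Named numeric: p-values (`ttest`) or appearance fractions
#'   (`rf_consensus`) for the selected k-mers.
#' @slot params List of the method parameters used.
#' @export
setClass("FeatureSelectionResult",
  representation(
    method   = "character",
    selected = "character",
    scores   = "numeric",
    params   = "list"
  )
)

setValidity("FeatureSelectionResult", function(object) {
  if (!object@method %in% c("ttest", "rf_consensus")) {
    return("method must be 'ttest' or 'rf_consensus'")
  }
  if (anyDuplicated(object@selected)) return("selected k-mers must be unique")
  if (length(object@scores) && !setequal(names(object@scores), object@selected)) {
    return("scores must be named by the selected k-mers")
  }
  if (object@method == "ttest" && length(object@selected) > 1L) {
    if (is.unsorted(object@scores[object@selected])) {
      return("ttest selection must be ordered by ascending p-value")
    }
  }
  TRUE
})

#' KmerInstances: labeled k-mer count instances
#'
#' A labeled design matrix for feature selection and model fitting: one row
#' per instance (a CpG-site flank, a segment, or a whole promoter), one
#' column per observed k-mer, entries are occurrence counts.
#'
#' @slot counts Integer/numeric matrix; rownames are instance ids, colnames
#'   are k-mers over \{A,C,G,T\}.
#' @slot labels Character vector of `"+"`/`"-"` labels, one per row.
#' @slot k The k-mer length.
#' @export
setClass("KmerInstances",
  representation(counts = "matrix", labels = "character", k = "integer")
)

setValidity("KmerInstances", function(object) {
  if (nrow(object@counts) != length(object@labels)) {
    return("labels must align with count matrix rows")
  }
  if (!all(object@labels %in% c("+", "-"))) return("labels must be '+'/'-'")
  cn <- colnames(object@counts)
  if (ncol(object@counts) &&
      (is.null(cn) || any(nchar(cn) != object@k))) {
    return("column names must be k-mers of length k")
  }
  if (length(object@counts) && any(object@counts < 0)) {
    return("counts must be non-negative")
  }
  TRUE
})

#' ExperimentReport: cross-validated evaluation of one model configuration
#'
#' @slot config List of experiment settings (resolution, k, selection method,
#'   number of k-mers, folds, seed, search parameters, cell type).
#' @slot folds `data.frame` with one row per fold: `fold`, `aucInitial`,
#'   `aucFinal` (segment resolution only, `NA` otherwise), `nTestUnits`,
#'   `skipped` (logical; AUC undefined because a fold was single-class).
#' @slot traces List of per-fold search traces (segment resolution).
#' @export
setClass("ExperimentReport",
  representation(config = "list", folds = "data.frame", traces = "list")
)

## ------------------------------------------------------------------ accessors

#' @describeIn MethylationDataset-accessors Amplicon sequences (`DNAStringSet`).
#' @export
setGeneric("ampliconSeqs", function(x) standardGeneric("ampliconSeqs"))

#' @describeIn MethylationDataset-accessors CpG offsets per amplicon.
#' @export
setGeneric("cpgOffsets", function(x) standardGeneric("cpgOffsets"))

#' @describeIn MethylationDataset-accessors Per-site methylation table.
#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))

#' @describeIn MethylationDataset-accessors Cell types present.
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' Accessors for MethylationDataset
#'
#' @param x A `MethylationDataset`.
#' @name MethylationDataset-accessors
#' @aliases ampliconSeqs cpgOffsets siteTable cellTypes
NULL

#' @export
setMethod("ampliconSeqs", "MethylationDataset", function(x) x@amplicons)
#' @export
setMethod("cpgOffsets", "MethylationDataset", function(x) x@cpgOffsets)
#' @export
setMethod("siteTable", "MethylationDataset", function(x) x@sites)
#' @export
setMethod("cellTypes", "MethylationDataset", function(x) x@cellTypes)

#' Segment table of a configuration
#'
#' @param x A `SegmentConfiguration`.
#' @return The `data.frame` of segments (see [SegmentConfiguration-class]).
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))

#' @export
setMethod("segmentTable", "SegmentConfiguration", function(x) x@segments)

#' Mean segment size of a configuration
#'
#' The average number of CpG sites per segment, written \eqn{\bar S}. It is
#' the normalizer of both the error weight \eqn{w_i = \bar S / |S_i|} and the
#' sampling weight \eqn{|S_j| / \bar S}.
#'
#' @param x A `SegmentConfiguration`.
#' @export
setGeneric("meanSegmentSize", function(x) standardGeneric("meanSegmentSize"))

#' @export
setMethod("meanSegmentSize", "SegmentConfiguration", function(x) {
  if (!nrow(x@segments)) return(NA_real_)
  mean(x@segments$nSites)
})

#' Boundary variables of a configuration
#'
#' Recovers the boundary-variable view of a configuration: for each amplicon,
#' a logical vector with one element per gap between adjacent measured CpG
#' sites, `TRUE` where the gap separates two segments (\eqn{B_i = 1}).
#'
#' @param x A `SegmentConfiguration`.
#' @return Named list of logical vectors (length = sites − 1 per amplicon).
#' @export
setGeneric("boundaryBits", function(x) standardGeneric("boundaryBits"))

#' @export
setMethod("boundaryBits", "SegmentConfiguration", function(x) {
  sg <- x@segments
  out <- list()
  for (a in unique(sg$amplicon)) {
    rows <- sg[sg$amplicon == a, ]
    n <- max(rows$lastSite)
    bits <- rep(FALSE, max(n - 1L, 0L))
    cut <- rows$lastSite[rows$lastSite < n]
    bits[cut] <- TRUE
    out[[a]] <- bits
  }
  out
})

#' @describeIn ExperimentReport-accessors Per-fold results table.
#' @export
setGeneric("foldResults", function(x) standardGeneric("foldResults"))

#' Accessors for ExperimentReport
#'
#' @param x An `ExperimentReport`.
#' @name ExperimentReport-accessors
NULL

#' @export
setMethod("foldResults", "ExperimentReport", function(x) x@folds)

#' Mean cross-validated AUC of an experiment
#'
#' Arithmetic mean over non-skipped folds.
#'
#' @param x An `ExperimentReport`.
#' @return Named numeric: `initial` and `final` mean AUC (`final` is `NA`
#'   except at segment resolution).
#' @export
setGeneric("meanAUC", function(x) standardGeneric("meanAUC"))

#' @export
setMethod("meanAUC", "ExperimentReport", function(x) {
  f <- x@folds[!x@folds$skipped, , drop = FALSE]
  c(initial = mean(f$aucInitial, na.rm = TRUE),
    final   = if (all(is.na(f$aucFinal))) NA_real_ else mean(f$aucFinal, na.rm = TRUE))
})

## ----------------------------------------------------------------- show

setMethod("show", "MethylationDataset", function(object) {
  cat(sprintf(
    "MethylationDataset: %d amplicons, %d CpG sites, %d measurements, %d cell type(s)\n",
    length(object@amplicons), sum(lengths(object@cpgOffsets)),
    nrow(object@sites), length(object@cellTypes)))
  cat("  cell types:", paste(object@cellTypes, collapse = ", "), "\n")
})

setMethod("show", "SegmentConfiguration", function(object) {
  sg <- object@segments
  cat(sprintf(
    "SegmentConfiguration (%s): %d segments over %d amplicons, mean size %.2f sites\n",
    object@cellType, nrow(sg), length(unique(sg$amplicon)),
    meanSegmentSize(object)))
  cat(sprintf("  labels: %d +, %d -\n", sum(sg$label), sum(!sg$label)))
})

setMethod("show", "KmerLogisticModel", function(object) {
  cat(sprintf(
    "KmerLogisticModel: %d k-mers, intercept %.4g, ridge %g, %s (%d iter)\n",
    length(object@kmers), object@intercept, object@ridge,
    if (object@converged) "converged" else "NOT converged", object@iterations))
  if (length(object@kmers)) {
    o <- order(-abs(object@betas))
    top <- utils::head(o, 5L)
    cat("  top |beta|:",
        paste(sprintf("%s=%.3g", object@kmers[top], object@betas[top]),
              collapse = ", "), "\n")
  }
})

setMethod("show", "FeatureSelectionResult", function(object) {
  cat(sprintf("FeatureSelectionResult (%s): %d k-mers selected\n",
              object@method, length(object@selected)))
  if (length(object@selected)) {
    cat("  head:", paste(utils::head(object@selected, 8L), collapse = ", "), "\n")
  }
})

setMethod("show", "KmerInstances", function(object) {
  cat(sprintf("KmerInstances: %d instances x %d %d-mers (%d +, %d -)\n",
              nrow(object@counts), ncol(object@counts), object@k,
              sum(object@labels == "+"), sum(object@labels == "-")))
})

setMethod("show", "ExperimentReport", function(object) {
  m <- meanAUC(object)
  cat(sprintf("ExperimentReport (%s resolution): %d folds, mean AUC initial %.3f%s\n",
              object@config$resolution %||% "?", nrow(object@folds), m[["initial"]],
              if (!is.na(m[["final"]])) sprintf(", final %.3f", m[["final"]]) else ""))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
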