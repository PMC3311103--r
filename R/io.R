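#' Read promoter/amplicon sequences from FASTA
#'
#' Reads amplicon sequences and locates every CpG dinucleotide. Headers may
#' carry a genomic span as `"id chrom:start-end"` (0-based half-open); headers
#' with a bare id get `chrom = "synthetic"`, `start = 0`.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by amplicon id, with `mcols()`
#'   columns `chrom`, `start`, `end` and a `cpgOffsets` list column holding
#'   the 1-based offsets of the C of every CpG in each (uppercased) sequence.
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGCGT"), f)
#' amp <- readAmpliconFasta(f)
#' S4Vectors::mcols(amp)$cpgOffsets[[1]]  # 2 4: the two CG starts
#' @importFrom Biostrings readDNAStringSet DNAStringSet
#' @export
readAmpliconFasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate amplicon id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(seqs) <- ids

  chrom <- rep("synthetic", length(seqs))
  start <- rep(0L, length(seqs))
  loc <- regmatches(headers,
                    regexpr("\\s+\\S+:[0-9]+-[0-9]+\\s*$", headers))
  has_loc <- lengths(regmatches(headers,
                    gregexpr("\\s+\\S+:[0-9]+-[0-9]+\\s*$", headers))) > 0
  for (i in which(has_loc)) {
    tok <- trimws(sub("^\\S+\\s+", "", headers[i]))
    chrom[i] <- sub(":.*$", "", tok)
    rng <- sub("^.*:", "", tok)
    start[i] <- as.integer(sub("-.*$", "", rng))
  }
  end <- start + Biostrings::width(seqs)
  offs <- lapply(as.character(seqs), cg_offsets)
  S4Vectors::mcols(seqs) <- S4Vectors::DataFrame(
    chrom = chrom, start = start, end = end,
    cpgOffsets = I(unname(offs)))
  seqs
}

# 1-based offsets of the C of every "CG" in a sequence string.
cg_offsets <- function(seq) {
  m <- gregexpr("CG", seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Read a per-CpG-site methylation table
#'
#' Expects a tab-separated file with header columns `chrom`, `pos` (0-based
#' genomic position of the C), `strand` (`+`/`-`), `level` in \eqn{[0,1]},
#' `coverage` (optional, may be `NA`), `cellType`.
#'
#' @param path Path to the TSV file.
#' @param skipInvalid If `TRUE`, rows failing validation are dropped with a
#'   warning instead of aborting.
#' @return A `data.frame` with the columns above, levels as numeric.
#' @export
readMethylationTable <- function(path, skipInvalid = FALSE) {
  if (!file.exists(path)) stop("methylation table not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("chrom", "pos", "strand", "level", "cellType")
  if (!all(need %in% names(tab))) {
    stop("methylation table must have columns: ",
         paste(need, collapse = ", "), " (tab-separated, with header)")
  }
  if (!"coverage" %in% names(tab)) tab$coverage <- NA_character_
  if (!nrow(tab)) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), level = numeric(),
                      coverage = integer(), cellType = character()))
  }
  pos <- suppressWarnings(as.numeric(tab$pos))
  bad_pos <- is.na(pos) | pos != floor(pos) | pos < 0
  level <- suppressWarnings(as.numeric(tab$level))
  bad_level <- is.na(level) | level < 0 | level > 1
  bad_strand <- !tab$strand %in% c("+", "-")
  bad <- bad_pos | bad_level | bad_strand
  if (any(bad)) {
    msg <- sprintf(
      "%d invalid row(s) in '%s' (first bad row: %d%s)",
      sum(bad), path, which(bad)[1],
      if (bad_level[which(bad)[1]]) ", level outside [0,1]" else
      if (bad_pos[which(bad)[1]]) ", non-integer pos" else ", bad strand")
    if (skipInvalid) warning(msg) else stop(msg)
    keep <- !bad
  } else keep <- rep(TRUE, nrow(tab))
  data.frame(
    chrom    = tab$chrom[keep],
    pos      = as.integer(pos[keep]),
    strand   = tab$strand[keep],
    level    = level[keep],
    coverage = suppressWarnings(as.integer(tab$coverage[keep])),
    cellType = tab$cellType[keep],
    stringsAsFactors = FALSE
  )
}

#' Write a methylation table
#'
#' Inverse of [readMethylationTable()]; round-trips exactly.
#'
#' @param records `data.frame` as returned by [readMethylationTable()].
#' @param path Output path.
#' @export
writeMethylationTable <- function(records, path) {
  utils::write.table(
    records[, c("chrom", "pos", "strand", "level", "coverage", "cellType")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a MethylationDataset from sequences and measurements
#'
#' Joins per-site methylation records onto amplicon CpG sites. Minus-strand
#' measurements are mapped to the plus-strand C of the same CpG dinucleotide
#' (`pos - 1`) before joining, so a CpG is one unit regardless of the strand
#' it was read on. Records falling on no amplicon CpG are dropped with a
#' warning giving the count.
#'
#' @param amplicons A `DNAStringSet` from [readAmpliconFasta()] (or built the
#'   same way).
#' @param records Methylation records from [readMethylationTable()].
#' @return A [MethylationDataset-class].
#' @export
assembleDataset <- function(amplicons, records) {
  mc <- S4Vectors::mcols(amplicons)
  ids <- names(amplicons)
  offs <- as.list(mc$cpgOffsets)
  names(offs) <- ids

  n <- nrow(records)
  amp_col <- rep(NA_character_, n)
  off_col <- rep(NA_integer_, n)
  if (n) {
    pos <- ifelse(records$strand == "-", records$pos - 1L, records$pos)
    for (i in seq_along(ids)) {
      hit <- records$chrom == mc$chrom[i] & pos >= mc$start[i] & pos < mc$end[i]
      if (!any(hit)) next
      o <- pos[hit] - mc$start[i] + 1L
      valid <- o %in% offs[[ids[i]]]
      amp_col[hit][valid] <- ids[i]
      off_col[hit][valid] <- o[valid]
    }
  }
  dropped <- if (n) sum(is.na(amp_col)) else 0L
  if (dropped > 0) {
    warning(dropped, " record(s) matched no amplicon CpG site and were dropped")
  }
  keep <- !is.na(amp_col)
  sites <- data.frame(
    amplicon = amp_col[keep],
    cellType = records$cellType[keep],
    offset   = off_col[keep],
    level    = records$level[keep],
    coverage = records$coverage[keep],
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(sites[, c("amplicon", "cellType", "offset")])) {
    stop("duplicate measurement for the same (amplicon, cellType, CpG site)")
  }
  sites <- sites[order(sites$amplicon, sites$cellType, sites$offset), ]
  rownames(sites) <- NULL
  new("MethylationDataset",
      amplicons = amplicons, cpgOffsets = offs, sites = sites,
      cellTypes = sort(unique(sites$cellType)))
}

#' Write a segment configuration as BED6
#'
#' One line per segment: `chrom`, genomic start of the first CpG's C, genomic
#' end one past the last CpG's G (0-based half-open), `name` =
#' `amplicon:index`, `score` = `round(1000 * yhat)` when model scores are
#' supplied (0 otherwise), `strand` = `+`.
#'
#' @param configuration A [SegmentConfiguration-class].
#' @param dataset The [MethylationDataset-class] the configuration lives in.
#' @param path Output path.
#' @param scores Optional numeric vector of predicted methylation levels
#'   \eqn{\hat y}, one per segment.
#' @export
writeSegmentsBed <- function(configuration, dataset, path, scores = NULL) {
  sg <- segmentTable(configuration)
  mc <- S4Vectors::mcols(ampliconSeqs(dataset))
  ids <- names(ampliconSeqs(dataset))
  if (!nrow(sg)) {
    ok <- file.create(path)
    if (!ok) stop("cannot write to ", path)
    return(invisible(path))
  }
  i <- match(sg$amplicon, ids)
  if (anyNA(i)) stop("configuration references unknown amplicons")
  score <- if (is.null(scores)) rep(0L, nrow(sg)) else {
    stopifnot(length(scores) == nrow(sg))
    as.integer(round(1000 * scores))
  }
  seg_idx <- stats::ave(seq_len(nrow(sg)), sg$amplicon, FUN = seq_along)
  bed <- data.frame(
    chrom  = mc$chrom[i],
    start  = mc$start[i] + sg$startOffset - 1L,
    end    = mc$start[i] + sg$endOffset,
    name   = paste0(sg$amplicon, ":", seg_idx),
    score  = score,
    strand = "+"
  )
  ok <- tryCatch({
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write to ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Serialize / read a fitted model as JSON
#'
#' @param model A [KmerLogisticModel-class].
#' @param path Output path.
#' @return `readModelJson` returns the reconstructed model.
#' @export
writeModelJson <- function(model, path) {
  jsonlite::write_json(
    list(kmers = model@kmers, betas = model@betas,
         intercept = model@intercept, ridge = model@ridge,
         converged = model@converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeModelJson
#' @export
readModelJson <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("KmerLogisticModel",
      kmers = as.character(x$kmers), betas = as.numeric(x$betas),
      intercept = as.numeric(x$intercept), ridge = as.numeric(x$ridge),
      converged = isTRUE(x$converged),
      iterations = NA_integer_)
}
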