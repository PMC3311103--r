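#' Seeded k-fold partition of cross-validation units
#'
#' Units (amplicon ids) are randomly partitioned into `nFolds` near-equal
#' disjoint groups covering all units. The amplicon is the CV unit, so all of
#' an amplicon's sites and segments share a fold and no amplicon sequence
#' leaks between training and test.
#'
#' @param units Character vector of unit ids (amplicons).
#' @param nFolds Number of folds (default 10; must not exceed the unit count).
#' @param seed Integer seed.
#' @return Named integer vector: fold assignment in `1..nFolds` per unit.
#' @export
kfoldSplit <- function(units, nFolds = 10, seed = 1) {
  if (length(units) < nFolds) {
    stop("only ", length(units), " units for ", nFolds,
         " folds; use a smaller nFolds")
  }
  perm <- withr::with_seed(seed, sample(units))
  fold <- rep_len(seq_len(nFolds), length(units))
  stats::setNames(fold[match(units, perm)], units)
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed from ranks (equivalent to the
#' Mann-Whitney U statistic divided by \eqn{n^+ n^-}); tied scores contribute
#' 1/2. Returns `NA` with a warning when only one class is present (the AUC
#' is then undefined and the fold is skipped by callers).
#'
#' @param scores Numeric prediction scores.
#' @param labels `+`/`-` labels (any form accepted by the package).
#' @return AUC in \eqn{[0, 1]}, or `NA_real_`.
#' @export
aucScore <- function(scores, labels) {
  lab <- as_plus_label(labels)
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Shared per-fold feature selection: flank instances from training amplicons,
# class-balanced, then t-test or consensus-RF selection.
select_fold_features <- function(dataset, cellType, trainIds, k, selection,
                                 nKmers, flank, threshold, seed,
                                 rfParams = list()) {
  inst <- siteInstances(dataset, cellType, trainIds, k = k, l = flank,
                        threshold = threshold)
  inst <- balanceClasses(inst, seed)
  if (selection == "ttest") {
    selectTtest(inst, m = nKmers)@selected
  } else {
    args <- utils::modifyList(
      list(instances = inst, seed = seed), rfParams)
    sel <- do.call(selectRfConsensus, args)@selected
    if (!length(sel)) stop("consensus selection retained no k-mers")
    sel
  }
}

experiment_config <- function(resolution, cellType, k, selection, nKmers,
                              folds, seed, ...) {
  c(list(resolution = resolution, cellType = cellType, k = k,
         selection = selection, nKmers = nKmers, folds = folds,
         seed = seed), list(...))
}

#' Cross-validated segment-resolution experiment
#'
#' The full segment-modeling pipeline under amplicon-level k-fold CV. Per
#' fold: k-mer features are selected from the training amplicons only; the
#' hill-climbing search fits the model and the segment configuration on the
#' training amplicons; on the held-out amplicons, the initial configuration's
#' segments are scored with the frozen training model (`aucInitial`), then
#' the frozen-model search refines the test segments and the final segments
#' are scored (`aucFinal`). Folds whose test segments are single-class are
#' skipped and recorded.
#'
#' @param dataset A [MethylationDataset-class].
#' @param cellType Cell type evaluated (one model per cell type).
#' @param k K-mer length (4, 5 or 6 in the standard grids).
#' @param selection `"ttest"` or `"rf"` feature selection.
#' @param nKmers Number of k-mers kept by t-test selection.
#' @param folds Number of CV folds (default 10).
#' @param seed Master seed; per-fold seeds are derived.
#' @param nRestarts Hill-climbing restarts per fold (default 2).
#' @param delta Search stopping tolerance.
#' @param flank Flank length for selection instances (default 100).
#' @param threshold Site labeling threshold.
#' @param mode Initial-configuration mode.
#' @param ridge Ridge strength.
#' @param rfParams Extra parameters for [selectRfConsensus()].
#' @return An [ExperimentReport-class].
#' @export
runSegmentExperiment <- function(dataset, cellType, k = 6,
                                 selection = c("ttest", "rf"), nKmers = 30,
                                 folds = 10, seed = 1, nRestarts = 2,
                                 delta = 1e-6, flank = 100, threshold = 0.5,
                                 mode = "label-change", ridge = 1e-6,
                                 rfParams = list()) {
  selection <- match.arg(selection)
  units <- unique(siteTable(dataset)$amplicon[
    siteTable(dataset)$cellType == cellType])
  assign <- kfoldSplit(units, folds, derive_seed(seed, 999))
  rows <- list(); traces <- list()
  for (f in seq_len(folds)) {
    testIds <- names(assign)[assign == f]
    trainIds <- setdiff(units, testIds)
    fseed <- derive_seed(seed, f)
    res <- tryCatch({
      kmers <- select_fold_features(dataset, cellType, trainIds, k,
                                    selection, nKmers, flank, threshold,
                                    fseed, rfParams)
      train <- subset_dataset(dataset, trainIds)
      fit <- hillClimbingSearch(train, cellType, kmers,
                                nRestarts = nRestarts, delta = delta,
                                seed = fseed, stage = "train",
                                mode = mode, threshold = threshold,
                                ridge = ridge)
      test <- subset_dataset(dataset, testIds)
      init <- initialConfiguration(test, cellType, mode = mode,
                                   threshold = threshold)
      Xi <- segmentFeatureMatrix(init, kmers, test)
      sgi <- segmentTable(init)
      if (all(sgi$label) || !any(sgi$label)) stop("single-class test fold")
      aucI <- aucScore(decisionScores(fit$model, Xi), sgi$label)
      fin <- hillClimbingSearch(test, cellType, kmers,
                                nRestarts = nRestarts, delta = delta,
                                seed = derive_seed(fseed, 7),
                                stage = "test", model = fit$model,
                                mode = mode, threshold = threshold,
                                ridge = ridge)
      sgf <- segmentTable(fin$configuration)
      Xf <- segmentFeatureMatrix(fin$configuration, kmers, test)
      aucF <- aucScore(decisionScores(fit$model, Xf), sgf$label)
      list(aucI = aucI, aucF = aucF, n = length(testIds),
           trace = list(
             train = fit$trace, test = fin$trace,
             scoresInitial = decisionScores(fit$model, Xi),
             labelsInitial = sgi$label,
             scoresFinal = decisionScores(fit$model, Xf),
             labelsFinal = sgf$label))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[f]] <- data.frame(fold = f, aucInitial = NA_real_,
                              aucFinal = NA_real_,
                              nTestUnits = length(testIds), skipped = TRUE)
      traces[[f]] <- list(skipped = conditionMessage(res))
    } else {
      rows[[f]] <- data.frame(fold = f, aucInitial = res$aucI,
                              aucFinal = res$aucF, nTestUnits = res$n,
                              skipped = FALSE)
      traces[[f]] <- res$trace
    }
  }
  new("ExperimentReport",
      config = experiment_config("segment", cellType, k, selection, nKmers,
                                 folds, seed, nRestarts = nRestarts,
                                 delta = delta, mode = mode),
      folds = do.call(rbind, rows), traces = traces)
}

# Restrict a dataset to a subset of amplicons.
subset_dataset <- function(dataset, ampliconIds) {
  amp <- ampliconSeqs(dataset)[ampliconIds]
  st <- siteTable(dataset)
  new("MethylationDataset", amplicons = amp,
      cpgOffsets = cpgOffsets(dataset)[ampliconIds],
      sites = st[st$amplicon %in% ampliconIds, , drop = FALSE],
      cellTypes = cellTypes(dataset))
}

# Shared CV loop for the two flat resolutions (site, promoter): instances
# are fixed (no configuration search); selection and fitting use training
# folds only.
run_flat_experiment <- function(dataset, cellType, resolution, k, selection,
                                nKmers, folds, seed, flank, threshold,
                                ridge, rfParams) {
  st <- siteTable(dataset)
  units <- unique(st$amplicon[st$cellType == cellType])
  assign <- kfoldSplit(units, folds, derive_seed(seed, 999))
  seqs <- as.character(ampliconSeqs(dataset))

  instance_set <- function(ids) {
    if (resolution == "site") {
      inst <- siteInstances(dataset, cellType, ids, k = k, l = flank,
                            threshold = threshold)
      list(seqs = NULL, labels = inst@labels, counts = inst@counts)
    } else {
      lab <- vapply(ids, function(a) {
        lv <- st$level[st$amplicon == a & st$cellType == cellType]
        mean(lv > threshold) > 0.5
      }, logical(1))
      list(seqs = seqs[ids], labels = plus_minus(lab), counts = NULL)
    }
  }

  rows <- list()
  for (f in seq_len(folds)) {
    testIds <- names(assign)[assign == f]
    trainIds <- setdiff(units, testIds)
    fseed <- derive_seed(seed, f)
    res <- tryCatch({
      kmers <- select_fold_features(dataset, cellType, trainIds, k,
                                    selection, nKmers, flank, threshold,
                                    fseed, rfParams)
      tr <- instance_set(trainIds)
      te <- instance_set(testIds)
      Xtr <- if (resolution == "site") {
        align_counts(tr$counts, kmers)
      } else kmer_matrix_for(tr$seqs, kmers)
      Xte <- if (resolution == "site") {
        align_counts(te$counts, kmers)
      } else kmer_matrix_for(te$seqs, kmers)
      model <- fitKmerLogistic(Xtr, tr$labels, ridge = ridge)
      if (all(te$labels == "+") || all(te$labels == "-")) {
        stop("single-class test fold")
      }
      list(auc = aucScore(decisionScores(model, Xte), te$labels),
           n = length(testIds))
    }, error = function(e) e)
    rows[[f]] <- if (inherits(res, "error")) {
      data.frame(fold = f, aucInitial = NA_real_, aucFinal = NA_real_,
                 nTestUnits = length(testIds), skipped = TRUE)
    } else {
      data.frame(fold = f, aucInitial = res$auc, aucFinal = NA_real_,
                 nTestUnits = res$n, skipped = FALSE)
    }
  }
  folds_df <- do.call(rbind, rows)
  if (all(folds_df$skipped)) {
    stop("degenerate data: every fold was single-class, no AUC is defined")
  }
  new("ExperimentReport",
      config = experiment_config(resolution, cellType, k, selection, nKmers,
                                 folds, seed),
      folds = folds_df, traces = list())
}

# Counts of the selected kmers, in order, from an observed-kmer matrix
# (absent kmers get zero columns).
align_counts <- function(counts, kmers) {
  out <- matrix(0, nrow(counts), length(kmers),
                dimnames = list(rownames(counts), kmers))
  hit <- intersect(kmers, colnames(counts))
  out[, hit] <- counts[, hit]
  out
}

kmer_matrix_for <- function(seqs, kmers) {
  span_count_matrix(unname(seqs), kmers)
}

#' Cross-validated CpG-site-resolution experiment
#'
#' One instance per measured CpG site: the k-mer counts of its length-`l`
#' flank, labeled by [labelSites()]. A single k-mer mixture logistic model
#' per cell type is fit on the training sites and evaluated by AUC on the
#' held-out sites.
#'
#' @inheritParams runSegmentExperiment
#' @return An [ExperimentReport-class] (`aucFinal` is `NA`; there is no
#'   configuration search at this resolution).
#' @export
runSiteExperiment <- function(dataset, cellType, k = 6,
                              selection = c("ttest", "rf"), nKmers = 30,
                              folds = 10, seed = 1, flank = 100,
                              threshold = 0.5, ridge = 1e-6,
                              rfParams = list()) {
  selection <- match.arg(selection)
  run_flat_experiment(dataset, cellType, "site", k, selection, nKmers,
                      folds, seed, flank, threshold, ridge, rfParams)
}

#' Cross-validated promoter-resolution experiment
#'
#' One instance per amplicon/promoter: the k-mer counts of the full sequence,
#' labeled `+` iff the fraction of its `+`-labeled CpG sites exceeds 0.5
#' (the majority aggregation rule applied to the whole region).
#'
#' @inheritParams runSegmentExperiment
#' @return An [ExperimentReport-class].
#' @export
runPromoterExperiment <- function(dataset, cellType, k = 6,
                                  selection = c("ttest", "rf"), nKmers = 30,
                                  folds = 10, seed = 1, flank = 100,
                                  threshold = 0.5, ridge = 1e-6,
                                  rfParams = list()) {
  selection <- match.arg(selection)
  run_flat_experiment(dataset, cellType, "promoter", k, selection, nKmers,
                      folds, seed, flank, threshold, ridge, rfParams)
}

#' K-mer-count sweep over the three modeling resolutions
#'
#' Runs site-, promoter- and segment-resolution cross-validation for every
#' requested number of t-test-selected k-mers (the standard grid is 10 to
#' 100 in steps of 10), yielding the grid used to assess how the number of
#' features affects each resolution.
#'
#' @inheritParams runSegmentExperiment
#' @param counts Integer vector of k-mer counts to sweep.
#' @return List with `grid` (a `data.frame` of resolution, count and mean
#'   AUC; the segment rows report the final-configuration AUC) and `reports`
#'   (all [ExperimentReport-class] objects, named `resolution_count`).
#' @export
kmerCountSweep <- function(dataset, cellType, k = 6,
                           counts = seq(10, 100, by = 10), folds = 10,
                           seed = 1, nRestarts = 2, delta = 1e-6,
                           flank = 100, threshold = 0.5, ridge = 1e-6) {
  reports <- list()
  grid <- list()
  for (n in counts) {
    for (res in c("site", "promoter", "segment")) {
      rep_i <- switch(res,
        site = runSiteExperiment(dataset, cellType, k, "ttest", n, folds,
                                 seed, flank, threshold, ridge),
        promoter = runPromoterExperiment(dataset, cellType, k, "ttest", n,
                                         folds, seed, flank, threshold,
                                         ridge),
        segment = runSegmentExperiment(dataset, cellType, k, "ttest", n,
                                       folds, seed, nRestarts, delta, flank,
                                       threshold, ridge = ridge))
      m <- meanAUC(rep_i)
      reports[[paste0(res, "_", n)]] <- rep_i
      grid[[paste0(res, "_", n)]] <- data.frame(
        resolution = res, nKmers = n,
        meanAUC = if (res == "segment") m[["final"]] else m[["initial"]])
    }
  }
  grid <- do.call(rbind, grid)
  rownames(grid) <- NULL
  list(grid = grid, reports = reports)
}

#' Write an experiment report as CSV
#'
#' One row per fold with the experiment settings attached.
#'
#' @param report An [ExperimentReport-class].
#' @param path Output path.
#' @export
writeReportCsv <- function(report, path) {
  f <- foldResults(report)
  cfg <- report@config
  f$resolution <- cfg$resolution
  f$cellType <- cfg$cellType
  f$k <- cfg$k
  f$selection <- cfg$selection
  f$nKmers <- cfg$nKmers
  utils::write.csv(f, path, row.names = FALSE)
  invisible(path)
}
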