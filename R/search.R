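#' Sample a merge candidate biased by prediction error
#'
#' Draws one index from `candidates` with probability proportional to
#' `errors[candidates]` (the sampling error vector \eqn{e_j}); if all
#' candidate errors are zero the draw is uniform. Uses R's current RNG
#' stream, so seed the caller for reproducibility.
#'
#' @param errors Numeric vector of per-segment sampling errors \eqn{e_j}.
#' @param candidates Integer indices of unvisited, merge-eligible segments.
#' @return One element of `candidates`, or `NA_integer_` when none remain.
#' @export
selectSegmentAtRandom <- function(errors, candidates) {
  if (!length(candidates)) return(NA_integer_)
  if (length(candidates) == 1L) return(candidates)
  w <- errors[candidates]
  if (any(w < 0)) stop("sampling errors must be non-negative")
  if (sum(w) == 0) w <- rep(1, length(candidates))
  candidates[sample.int(length(candidates), 1L, prob = w)]
}

# One full random-binary-merging pass over a search state.
#
# The state carries the segment table as plain parallel vectors plus the
# feature matrix, the current coefficient vector (intercept first) and the
# scores; S4 objects are only built at the search boundary. In the training
# stage the coefficients are refit (warm-started Newton) after every
# tentative merge; in the test stage the frozen coefficients score
# everything. A tentative merge of segment j with its right neighbour is
# accepted only if it strictly reduces the weighted squared error; accepted
# or not, the considered segments are marked visited so the pass terminates
# after every segment has been considered once. Segments with no right
# neighbour in the same amplicon are merge-ineligible.
merging_pass <- function(view, state, kmers, stage = "train", ridge = 1e-6) {
  sg <- state$sg; X <- state$X; coef <- state$coef
  yhat <- state$yhat; E <- state$E; pd <- state$pd
  n <- length(sg$amp)
  visit <- rep(FALSE, n)
  acceptedE <- numeric(0)

  repeat {
    n <- length(sg$amp)
    eligible <- c(sg$amp[-n] == sg$amp[-1L], FALSE)
    sbar <- mean(sg$n)
    e <- (sg$n / sbar) * (yhat - as.numeric(sg$label))^2
    j <- selectSegmentAtRandom(e, which(!visit & eligible))
    if (is.na(j)) break

    # tentative merge of segments j and j+1
    a <- sg$amp[j]
    s <- view$sites[[a]]
    first <- sg$first[j]; last <- sg$last[j + 1L]
    p <- mean(s$labels[first:last])
    keep <- setdiff(seq_len(n), j + 1L)
    sg2 <- list(amp = sg$amp[keep], first = sg$first[keep],
                last = sg$last[keep], n = sg$n[keep], p = sg$p[keep],
                label = sg$label[keep], startOff = sg$startOff[keep],
                endOff = sg$endOff[keep])
    sg2$first[j] <- first; sg2$last[j] <- last
    sg2$n[j] <- last - first + 1L
    sg2$p[j] <- p; sg2$label[j] <- p > 0.5
    sg2$startOff[j] <- s$offsets[first]
    sg2$endOff[j] <- s$offsets[last] + 1L
    span <- substring(view$seqs[[a]], sg2$startOff[j], sg2$endOff[j])
    X2 <- X[keep, , drop = FALSE]
    X2[j, ] <- span_counts(span, kmers, pd)

    accept <- FALSE
    if (stage == "train") {
      t01 <- as.numeric(sg2$label)
      if (any(t01 == 1) && any(t01 == 0)) {
        fit <- fit_logistic_core(X2, t01, ridge = ridge, start = coef)
        yhat2 <- clamp_prob(stats::plogis(
          drop(fit$coef[1L] + X2 %*% fit$coef[-1L])))
        E2 <- segment_error(sg2$n, yhat2, t01)
        if (E2 < E) {
          accept <- TRUE
          coef <- fit$coef
        }
      }
    } else {
      yhat2 <- yhat[keep]
      yhat2[j] <- clamp_prob(stats::plogis(
        coef[1L] + sum(X2[j, ] * coef[-1L])))
      E2 <- segment_error(sg2$n, yhat2, as.numeric(sg2$label))
      if (E2 < E) accept <- TRUE
    }

    if (accept) {
      sg <- sg2; X <- X2; yhat <- yhat2; E <- E2
      visit <- visit[keep]
      visit[j] <- TRUE                 # the merged product is visited too
      acceptedE <- c(acceptedE, E)
    } else {
      visit[j] <- TRUE
    }
  }
  list(sg = sg, X = X, coef = coef, yhat = yhat, E = E,
       acceptedE = acceptedE, pd = pd)
}

segment_error <- function(nSites, yhat, t01) {
  sum((mean(nSites) / nSites) * (yhat - t01)^2)
}

# Build the full search state for a configuration: vectorized segment
# table, feature matrix, coefficient vector (fit in training stage, frozen
# otherwise), scores and error.
make_state <- function(view, config, kmers, stage, model = NULL,
                       ridge = 1e-6, pd = NULL) {
  df <- segmentTable(config)
  sg <- list(amp = df$amplicon, first = df$firstSite, last = df$lastSite,
             n = df$nSites, p = df$pPlus, label = df$label,
             startOff = df$startOffset, endOff = df$endOffset)
  if (is.null(pd)) pd <- Biostrings::PDict(kmers)
  spans <- substring(view$seqs[sg$amp], sg$startOff, sg$endOff)
  X <- span_count_matrix(spans, kmers, pd)
  t01 <- as.numeric(sg$label)
  if (stage == "train") {
    if (all(t01 == 1) || all(t01 == 0)) {
      stop("degenerate labels: both classes are required to fit")
    }
    coef <- fit_logistic_core(X, t01, ridge = ridge)$coef
  } else {
    if (is.null(model)) {
      stop("test-stage search requires a frozen training model")
    }
    coef <- c(model@intercept, model@betas)
  }
  yhat <- clamp_prob(stats::plogis(drop(coef[1L] + X %*% coef[-1L])))
  list(sg = sg, X = X, coef = coef, yhat = yhat,
       E = segment_error(sg$n, yhat, t01), pd = pd)
}

state_to_configuration <- function(view, state) {
  sg <- state$sg
  new("SegmentConfiguration", cellType = view$cellType,
      threshold = view$threshold,
      segments = data.frame(
        amplicon = sg$amp, firstSite = sg$first, lastSite = sg$last,
        nSites = sg$n, pPlus = sg$p, label = sg$label,
        startOffset = sg$startOff, endOffset = sg$endOff,
        stringsAsFactors = FALSE))
}

state_to_model <- function(state, kmers, ridge, stage, model = NULL) {
  if (stage != "train") return(model)
  new("KmerLogisticModel", kmers = kmers,
      betas = unname(state$coef[-1L]), intercept = unname(state$coef[1L]),
      ridge = ridge, converged = TRUE, iterations = NA_integer_)
}

#' One random binary merging pass
#'
#' Repeats until every segment of the configuration has been considered for
#' merging: a segment is sampled with probability proportional to its
#' sampling error \eqn{e_j}, tentatively merged with its right neighbour in
#' the same amplicon, the model is refit (training stage) or reused (test
#' stage), and the merge is accepted only if it strictly reduces the weighted
#' squared error of [computeError()].
#'
#' Uses R's current RNG stream; wrap in `withr::with_seed()` (or see
#' [hillClimbingSearch()]) for reproducibility.
#'
#' @param configuration Starting [SegmentConfiguration-class].
#' @param dataset The [MethylationDataset-class].
#' @param kmers Selected k-mers (ignored in test stage if `model` given;
#'   defaults to the model's k-mers).
#' @param stage `"train"` (refit after each tentative merge) or `"test"`
#'   (score with the frozen `model`).
#' @param model Frozen [KmerLogisticModel-class]; required for `"test"`.
#' @param ridge Ridge strength for refits.
#' @return List with elements `configuration`, `model`, `error`, and
#'   `acceptedErrors` (the error after each accepted merge, strictly
#'   decreasing).
#' @export
randomBinaryMerging <- function(configuration, dataset, kmers = NULL,
                                stage = c("train", "test"), model = NULL,
                                ridge = 1e-6) {
  stage <- match.arg(stage)
  if (is.null(kmers)) {
    if (is.null(model)) stop("give kmers or a model")
    kmers <- model@kmers
  }
  view <- cell_type_view(dataset, configuration@cellType,
                         configuration@threshold)
  st <- make_state(view, configuration, kmers, stage, model, ridge)
  out <- merging_pass(view, st, kmers, stage, ridge)
  list(configuration = state_to_configuration(view, out),
       model = state_to_model(out, kmers, ridge, stage, model),
       error = out$E, acceptedErrors = out$acceptedE)
}

# Core of RandomConfigurationSearch on a prebuilt view. Runs full merging
# passes from the initial configuration and stops when the between-pass
# improvement is <= delta, returning the last accepted state.
random_configuration_search_core <- function(view, kmers, delta = 1e-6,
                                             stage = "train", model = NULL,
                                             mode = "label-change",
                                             ridge = 1e-6, pd = NULL) {
  config <- initial_configuration_view(view, mode)
  st <- make_state(view, config, kmers, stage, model, ridge, pd)
  acceptedE <- st$E
  passes <- data.frame(pass = 0L, E = st$E, nSegments = length(st$sg$amp))
  pass_i <- 0L
  repeat {
    pass_i <- pass_i + 1L
    out <- merging_pass(view, st, kmers, stage, ridge)
    if ((st$E - out$E) <= delta) break
    st <- out
    acceptedE <- c(acceptedE, out$acceptedE)
    passes <- rbind(passes,
                    data.frame(pass = pass_i, E = st$E,
                               nSegments = length(st$sg$amp)))
  }
  list(configuration = state_to_configuration(view, st),
       model = state_to_model(st, kmers, ridge, stage, model),
       error = st$E,
       trace = list(passes = passes, acceptedErrors = acceptedE))
}

#' Random configuration search
#'
#' Starts from the initial configuration and applies full
#' [randomBinaryMerging()] passes until the between-pass improvement in the
#' weighted squared error is at most `delta`, returning the last accepted
#' state. Uses R's current RNG stream.
#'
#' @param dataset A [MethylationDataset-class].
#' @param cellType Cell type searched.
#' @param kmers Selected k-mers.
#' @param delta Stopping tolerance on the between-pass improvement
#'   (default `1e-6`).
#' @param stage `"train"` or `"test"` (see [randomBinaryMerging()]).
#' @param model Frozen model for the test stage.
#' @param mode Initialization mode, see [initialConfiguration()].
#' @param threshold Site labeling threshold.
#' @param ridge Ridge strength.
#' @return List with `configuration`, `model`, `error`, `trace` (per-pass
#'   errors and the sequence of accepted-state errors).
#' @export
randomConfigurationSearch <- function(dataset, cellType, kmers,
                                      delta = 1e-6,
                                      stage = c("train", "test"),
                                      model = NULL, mode = "label-change",
                                      threshold = 0.5, ridge = 1e-6) {
  stage <- match.arg(stage)
  view <- cell_type_view(dataset, cellType, threshold)
  random_configuration_search_core(view, kmers, delta, stage, model, mode,
                                   ridge)
}

#' Hill-climbing configuration search
#'
#' Runs [randomConfigurationSearch()] `nRestarts` times with independent
#' derived seeds and keeps the minimum-error result. Merging only ever sets
#' boundary variables from 1 to 0 and is accepted only on a strict error
#' reduction, so the best error never exceeds the initial configuration's
#' error — a hill-climbing (descent) search over the \eqn{2^m} configuration
#' space.
#'
#' @inheritParams randomConfigurationSearch
#' @param nRestarts Number of independent restarts (default 10).
#' @param seed Master seed; restart seeds are derived from it, so identical
#'   seeds give identical results.
#' @return List with `configuration`, `model`, `error` (the best restart),
#'   and `trace`: a list with `restarts` (`data.frame` of each restart's
#'   final error and segment count) and `accepted` (per restart, the strictly
#'   decreasing accepted-state error sequence, starting at the initial
#'   configuration's error).
#' @export
hillClimbingSearch <- function(dataset, cellType, kmers, nRestarts = 10,
                               delta = 1e-6, seed = 1,
                               stage = c("train", "test"), model = NULL,
                               mode = "label-change", threshold = 0.5,
                               ridge = 1e-6) {
  stage <- match.arg(stage)
  stopifnot(nRestarts >= 1)
  view <- cell_type_view(dataset, cellType, threshold)
  pd <- Biostrings::PDict(kmers)
  best <- NULL
  restarts <- data.frame(restart = integer(), E = numeric(),
                         nSegments = integer())
  accepted <- vector("list", nRestarts)
  for (r in seq_len(nRestarts)) {
    res <- withr::with_seed(derive_seed(seed, r),
      random_configuration_search_core(view, kmers, delta, stage, model,
                                       mode, ridge, pd))
    restarts <- rbind(restarts, data.frame(
      restart = r, E = res$error,
      nSegments = nrow(segmentTable(res$configuration))))
    accepted[[r]] <- res$trace$acceptedErrors
    if (is.null(best) || res$error < best$error) best <- res
  }
  list(configuration = best$configuration, model = best$model,
       error = best$error,
       trace = list(restarts = restarts, accepted = accepted))
}

#' Write a hill-climbing search trace as JSON
#'
#' @param trace The `trace` element returned by [hillClimbingSearch()].
#' @param path Output path.
#' @export
writeTraceJson <- function(trace, path) {
  jsonlite::write_json(
    list(restarts = trace$restarts, accepted = trace$accepted),
    path, digits = NA)
  invisible(path)
}
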