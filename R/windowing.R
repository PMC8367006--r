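#' @include evaluate.R manifold.R
NULL

#' Sliding-window configuration
#'
#' Defaults follow the study's temporal analysis: 100 ms windows stepped by
#' 40 ms, spanning 0.74 s before to 1.82 s after touch onset, embedded with
#' Laplacian Eigenmaps (simple-minded, 8 neighbours, 120 dimensions, clamped
#' to the window sample count) and classified with k-NN (k = 8). Windows
#' shorter than 100 ms are rejected: below that length the neighbour graph
#' of this kind of data stops being fully connected.
#'
#' @param widthS window width in seconds (>= 0.1).
#' @param stepS step between window starts.
#' @param preSpanS,postSpanS spans tiled before/after touch onset.
#' @param nNeighbors,m,scheme,sigma embedding parameters per window.
#' @param classifier a \code{\linkS4class{ClassifierSpec}}.
#' @param subsampleStep temporal subsampling inside each window.
#' @return a list of settings for \code{\link{extractWindows}} and
#'   \code{\link{windowedDecoding}}.
#' @export
windowConfig <- function(widthS = 0.100, stepS = 0.040, preSpanS = 0.74,
                         postSpanS = 1.82, nNeighbors = 8, m = 120,
                         scheme = "simple", sigma = NULL,
                         classifier = classifierSpec("knn"),
                         subsampleStep = 5) {
  if (widthS < 0.100 - 1e-12)
    stop("windowConfig: window width ", widthS * 1000, " ms is below the ",
         "100 ms connectivity floor (the adjacency graph stops being fully ",
         "connected for shorter windows)")
  if (stepS <= 0) stop("windowConfig: stepS must be positive")
  if (preSpanS < widthS || postSpanS < widthS)
    stop("windowConfig: spans must be at least one window wide")
  list(widthS = widthS, stepS = stepS, preSpanS = preSpanS,
       postSpanS = postSpanS, nNeighbors = as.integer(nNeighbors),
       m = as.integer(m), scheme = scheme, sigma = sigma,
       classifier = classifier, subsampleStep = as.integer(subsampleStep))
}

# Window start offsets relative to touch onset. Left-aligned tiling; the
# last partial window is dropped.
.windowOffsets <- function(config) {
  pre <- seq(-config$preSpanS, by = config$stepS,
             length.out = max(0L, floor((config$preSpanS - config$widthS) /
                                          config$stepS) + 1L))
  post <- seq(0, by = config$stepS,
              length.out = floor((config$postSpanS - config$widthS) /
                                   config$stepS) + 1L)
  list(offsets = c(pre, post),
       segment = c(rep("pre_touch", length(pre)),
                   rep("post_touch", length(post))))
}

#' Extract event-aligned sliding windows from a trial
#'
#' Windows tile [-preSpan, 0) and [0, postSpan] relative to touch onset.
#' Each window is subsampled and channel-concatenated exactly like the
#' full-trial features (5 channels x 100 ms at 4 kHz with step 5 gives 400
#' features).
#'
#' @param trial a preprocessed \code{\linkS4class{EmgTrial}} spanning the
#'   configured range around its touch onset.
#' @param config a \code{\link{windowConfig}}.
#' @return list with \code{offsets} (seconds relative to touch),
#'   \code{segment} ("pre_touch"/"post_touch") and \code{values} (windows x
#'   features matrix).
#' @export
extractWindows <- function(trial, config = windowConfig()) {
  rate <- trial@samplingRate
  touch <- unname(trial@events["touch_onset"])
  dur <- ncol(trial@signal) / rate
  if (touch - config$preSpanS < -1e-9 ||
      touch + config$postSpanS > dur + 1e-9)
    stop(sprintf("extractWindows: trial %s/%d does not span [-%g, +%g] s around touch at %.3f s",
                 trial@subjectId, trial@trialIndex, config$preSpanS,
                 config$postSpanS, touch))
  tiles <- .windowOffsets(config)
  nWin <- round(config$widthS * rate)
  keep <- seq(1L, nWin, by = config$subsampleStep)
  nc <- ncol(trial@signal)
  vals <- t(vapply(tiles$offsets, function(off) {
    i0 <- min(max(.eventIndex(touch + off, rate), 1L), nc - nWin + 1L)
    as.numeric(t(trial@signal[, i0:(i0 + nWin - 1L), drop = FALSE][, keep,
                                                                   drop = FALSE]))
  }, numeric(length(keep) * nrow(trial@signal))))
  list(offsets = tiles$offsets, segment = tiles$segment, values = vals)
}

#' Sliding-window decoding across a cohort
#'
#' For every window offset and every subject: fit the window embedding on
#' the training trials' window vectors, Nystrom-extend the held-out trials,
#' classify, and record macro F1. The train/test split is stratified once
#' per subject and shared across offsets; each window offset is embedded
#' independently (no sharing across offsets). Aggregates mean and standard
#' error across subjects, separately tagged pre/post touch. A window whose
#' neighbour graph is disconnected for some subject is marked failed for
#' that subject (NA), not silently skipped.
#'
#' @param cohort a preprocessed \code{\linkS4class{EmgCohort}} whose trials
#'   span the configured range (apply \code{\link{preprocessTrial}} first).
#' @param config a \code{\link{windowConfig}}.
#' @param testFraction held-out fraction per subject.
#' @param seed integer seed for the splits.
#' @return a \code{\linkS4class{WindowSeries}}.
#' @export
windowedDecoding <- function(cohort, config = windowConfig(),
                             testFraction = 0.1, seed = 1) {
  sids <- subjects(cohort)
  tiles <- .windowOffsets(config)
  nOff <- length(tiles$offsets)
  perSubject <- matrix(NA_real_, nOff, length(sids),
                       dimnames = list(NULL, sids))
  for (si in seq_along(sids)) {
    trl <- Filter(function(t) t@subjectId == sids[si], cohort@trials)
    labels <- vapply(trl, slot, integer(1), "weightLabel")
    win <- lapply(trl, extractWindows, config = config)
    testIdx <- .withSeed(seed + si,
                         .stratifiedTestSplit(labels, testFraction))
    trainIdx <- setdiff(seq_along(trl), testIdx)
    for (oi in seq_len(nOff)) {
      Xtr <- t(vapply(win[trainIdx], function(w) w$values[oi, ],
                      numeric(ncol(win[[1]]$values))))
      Xte <- t(vapply(win[testIdx], function(w) w$values[oi, ],
                      numeric(ncol(win[[1]]$values))))
      mm <- min(config$m, length(trainIdx) - 2L)
      res <- tryCatch({
        fit <- laplacianEigenmaps(Xtr, config$nNeighbors, mm,
                                  config$scheme, config$sigma)
        pred <- classify(embedCoords(fit), labels[trainIdx],
                         nystromExtend(fit, Xte), config$classifier)
        f1Scores(labels[testIdx], pred)$macro["f1"]
      }, error = function(e) NA_real_)
      perSubject[oi, si] <- res
    }
  }
  nFailed <- rowSums(is.na(perSubject))
  series <- data.frame(
    offset = tiles$offsets, segment = tiles$segment,
    meanF1 = rowMeans(perSubject, na.rm = TRUE),
    seF1 = apply(perSubject, 1, function(r)
      stats::sd(r, na.rm = TRUE) / sqrt(sum(!is.na(r)))),
    nSubjects = length(sids), nFailed = nFailed, failed = nFailed > 0)
  series$meanF1[is.nan(series$meanF1)] <- NA_real_
  new("WindowSeries", series = series, perSubject = perSubject,
      config = config)
}

setMethod("show", "WindowSeries", function(object) {
  s <- object@series
  pre <- s$segment == "pre_touch"
  cat(sprintf("WindowSeries: %d windows (%d pre, %d post), %d subjects\n",
              nrow(s), sum(pre), sum(!pre), s$nSubjects[1]))
  cat(sprintf("  mean F1 pre %.3f / post %.3f; %d failed window-subject fits\n",
              mean(s$meanF1[pre], na.rm = TRUE),
              mean(s$meanF1[!pre], na.rm = TRUE), sum(s$nFailed)))
})
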