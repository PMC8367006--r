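#' @include cohort.R
NULL

#' Full-wave rectification
#'
#' @param signal numeric matrix (channels x time) or vector; must be finite.
#' @return elementwise absolute value, same shape.
#' @export
rectify <- function(signal) {
  if (!all(is.finite(signal))) stop("rectify: signal contains non-finite values")
  abs(signal)
}

#' Per-channel peak normalization
#'
#' Each channel is divided by its own per-trial maximum absolute value, so
#' that after rectification every channel lies in [0, 1]. The normalization
#' scheme used by the pipeline is deliberately simple; per-subject MVC-style
#' normalization can be emulated by scaling trials beforehand.
#'
#' @param signal numeric matrix, channels x time.
#' @return normalized matrix of the same shape.
#' @export
normalizeChannels <- function(signal) {
  mx <- apply(abs(signal), 1, max)
  bad <- which(mx == 0)
  if (length(bad))
    stop("normalizeChannels: channel(s) ", paste(bad, collapse = ", "),
         " are silent (all zeros)")
  signal / mx
}

# cache of squared-magnitude Butterworth responses keyed by (length, band)
.zpCache <- new.env(parent = emptyenv())

.butterResponse2 <- function(m, rateHz, lowHz, highHz, order) {
  key <- paste(m, rateHz, lowHz, highHz, order, sep = "_")
  H2 <- .zpCache[[key]]
  if (is.null(H2)) {
    bf <- signal::butter(order, c(lowHz, highHz) / (rateHz / 2), type = "pass")
    z <- exp(1i * 2 * pi * (0:(m - 1)) / m)
    H2 <- Mod(signal::polyval(rev(bf$b), z) / signal::polyval(rev(bf$a), z))^2
    .zpCache[[key]] <- H2
  }
  H2
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a 4th-order Butterworth band-pass (default 5-450 Hz) with zero
#' phase, per channel. The default implementation multiplies the signal
#' spectrum by the squared magnitude response of the filter (the response a
#' forward-backward pass applies) using reflection padding at the edges; the
#' cached response makes filtering whole cohorts fast. \code{method =
#' "filtfilt"} delegates to \code{signal::filtfilt} instead; the two agree to
#' roughly 1e-6 away from the signal edges.
#'
#' @param signal numeric matrix, channels x time (a vector is treated as one
#'   channel).
#' @param rateHz sampling rate; must exceed twice \code{highHz}.
#' @param lowHz,highHz band edges in Hz.
#' @param order filter order.
#' @param method "fft" (default) or "filtfilt".
#' @return filtered matrix, same shape as the input.
#' @export
bandpassFilter <- function(signal, rateHz, lowHz = 5, highHz = 450, order = 4,
                           method = c("fft", "filtfilt")) {
  method <- match.arg(method)
  if (highHz >= rateHz / 2)
    stop("bandpassFilter: high cutoff (", highHz,
         " Hz) must be below the Nyquist frequency (", rateHz / 2, " Hz)")
  vec <- is.null(dim(signal))
  S <- if (vec) matrix(signal, nrow = 1) else signal
  X <- t(S)                                  # time x channels
  n <- nrow(X)
  if (method == "filtfilt") {
    bf <- signal::butter(order, c(lowHz, highHz) / (rateHz / 2), type = "pass")
    Y <- apply(X, 2, function(col) signal::filtfilt(bf, col))
    if (is.null(dim(Y))) Y <- matrix(Y, ncol = ncol(X))
  } else {
    # pad to a 5-smooth length (mixed-radix FFTs degrade badly on large
    # prime factors) with >= 64 reflected samples on each side
    m <- stats::nextn(n + 128L, c(2, 3, 5))
    npadL <- min((m - n) %/% 2L, n - 1L)
    npadR <- min(m - n - npadL, n - 1L)
    m <- n + npadL + npadR
    H2 <- .butterResponse2(m, rateHz, lowHz, highHz, order)
    Xe <- rbind(X[(npadL + 1):2, , drop = FALSE], X,
                X[(n - 1):(n - npadR), , drop = FALSE])
    Y <- Re(stats::mvfft(stats::mvfft(Xe) * H2, inverse = TRUE)) / m
    Y <- Y[(npadL + 1):(npadL + n), , drop = FALSE]
  }
  out <- t(Y)
  if (vec) out[1, ] else out
}

#' Preprocess one trial
#'
#' Runs the fixed chain rectify -> per-channel peak normalization ->
#' zero-phase 4th-order Butterworth band-pass (5-450 Hz), in that order, and
#' flags the trial as preprocessed.
#'
#' @param trial an \code{\linkS4class{EmgTrial}}.
#' @param lowHz,highHz,order band-pass parameters.
#' @return the preprocessed \code{EmgTrial}.
#' @export
preprocessTrial <- function(trial, lowHz = 5, highHz = 450, order = 4) {
  sig <- bandpassFilter(normalizeChannels(rectify(trial@signal)),
                        trial@samplingRate, lowHz, highHz, order)
  new("EmgTrial", subjectId = trial@subjectId, trialIndex = trial@trialIndex,
      signal = sig, samplingRate = trial@samplingRate,
      weightLabel = trial@weightLabel, events = trial@events,
      channelNames = trial@channelNames, preprocessed = TRUE)
}

#' Truncate a trial to its first seconds
#'
#' Keeps the first \code{seconds * samplingRate} samples of every channel.
#' Shorter trials are rejected rather than padded (padding would fabricate
#' signal). Event times beyond the cut are dropped with a message; remaining
#' events keep their values.
#'
#' @param trial an \code{\linkS4class{EmgTrial}}.
#' @param seconds segment length (study value 8).
#' @return the truncated \code{EmgTrial}. Events that were dropped are set to
#'   the segment end so the event-ordering invariant still holds; a message
#'   notes each drop.
#' @export
segmentFirst <- function(trial, seconds = 8) {
  nKeep <- round(seconds * trial@samplingRate)
  if (ncol(trial@signal) < nKeep)
    stop(sprintf("segmentFirst: trial %s/%d lasts %.3f s, shorter than the %g s segment",
                 trial@subjectId, trial@trialIndex,
                 ncol(trial@signal) / trial@samplingRate, seconds))
  ev <- trial@events
  dropped <- names(ev)[ev > seconds]
  if (length(dropped)) {
    message("segmentFirst: dropping event(s) beyond ", seconds, " s: ",
            paste(dropped, collapse = ", "))
    ev[ev > seconds] <- seconds
  }
  new("EmgTrial", subjectId = trial@subjectId, trialIndex = trial@trialIndex,
      signal = trial@signal[, seq_len(nKeep), drop = FALSE],
      samplingRate = trial@samplingRate, weightLabel = trial@weightLabel,
      events = ev, channelNames = trial@channelNames,
      preprocessed = trial@preprocessed)
}

#' Assemble the trials-by-features matrix
#'
#' Per channel, samples at indices 1, 1+step, 1+2*step, ... are kept and the
#' channels are concatenated in channel order; trials are stacked as rows.
#' With 5 channels, 8 s at 4 kHz and step 5 this yields the study's
#' 5 x 8 x 800 = 32,000 features per trial.
#'
#' @param trialList list of preprocessed, equally-segmented
#'   \code{\linkS4class{EmgTrial}} objects sharing one layout.
#' @param subsampleStep integer subsampling step (study value 5).
#' @return a \code{\linkS4class{FeatureMatrix}}.
#' @export
assembleFeatures <- function(trialList, subsampleStep = 5) {
  if (!length(trialList)) stop("assembleFeatures: empty trial list")
  dims <- vapply(trialList, function(t) c(nrow(t@signal), ncol(t@signal),
                                          t@samplingRate), numeric(3))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]) ||
      any(dims[3, ] != dims[3, 1]))
    stop("assembleFeatures: trials have mixed layouts (channels/length/rate)")
  keep <- seq(1L, dims[2, 1], by = subsampleStep)
  vals <- t(vapply(trialList,
                   function(t) as.numeric(t(t@signal[, keep, drop = FALSE])),
                   numeric(length(keep) * dims[1, 1])))
  new("FeatureMatrix", values = vals,
      labels = vapply(trialList, slot, integer(1), "weightLabel"),
      subjectIds = vapply(trialList, slot, character(1), "subjectId"),
      layout = list(channels = as.integer(dims[1, 1]),
                    segment_s = dims[2, 1] / dims[3, 1],
                    subsample_step = as.integer(subsampleStep),
                    post_rate_hz = dims[3, 1] / subsampleStep))
}

#' Preprocess, segment and assemble a whole cohort
#'
#' Convenience wrapper running \code{\link{preprocessTrial}},
#' \code{\link{segmentFirst}} and \code{\link{assembleFeatures}} over a
#' cohort.
#'
#' @param cohort an \code{\linkS4class{EmgCohort}}.
#' @param segmentS segment length in seconds.
#' @param subsampleStep subsampling step.
#' @return a \code{\linkS4class{FeatureMatrix}}.
#' @export
cohortFeatures <- function(cohort, segmentS = 8, subsampleStep = 5) {
  # fused fast path; equivalent to
  # assembleFeatures(lapply(trials, \(t) segmentFirst(preprocessTrial(t), segmentS)))
  trl <- cohort@trials
  rate <- trl[[1]]@samplingRate
  nKeep <- round(segmentS * rate)
  keep <- seq(1L, nKeep, by = subsampleStep)
  vals <- t(vapply(trl, function(tr) {
    if (ncol(tr@signal) < nKeep)
      stop(sprintf("cohortFeatures: trial %s/%d is shorter than the %g s segment",
                   tr@subjectId, tr@trialIndex, segmentS))
    sig <- bandpassFilter(normalizeChannels(abs(tr@signal)), rate)
    as.numeric(t(sig[, keep, drop = FALSE]))
  }, numeric(length(keep) * nrow(trl[[1]]@signal))))
  new("FeatureMatrix", values = vals,
      labels = vapply(trl, slot, integer(1), "weightLabel"),
      subjectIds = vapply(trl, slot, character(1), "subjectId"),
      layout = list(channels = nrow(trl[[1]]@signal), segment_s = segmentS,
                    subsample_step = as.integer(subsampleStep),
                    post_rate_hz = rate / subsampleStep))
}

#' @rdname featureValues
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @rdname weightLabels
#' @export
setMethod("weightLabels", "FeatureMatrix", function(x) x@labels)

#' @rdname subjects
#' @export
setMethod("subjects", "FeatureMatrix", function(x) unique(x@subjectIds))

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d trials x %d features (%d ch, %g s, step %d)\n",
              nrow(object@values), ncol(object@values),
              object@layout$channels, object@layout$segment_s,
              object@layout$subsample_step))
})
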