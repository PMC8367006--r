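#' @include AllClasses.R AllGenerics.R
NULL

#' Muscles recorded in the reach-grasp-lift protocol
#'
#' @return character vector of the five recorded muscles.
#' @export
emgChannelNames <- function() {
  c("Anterior Deltoid", "Brachioradialis", "Flexor Digitorum",
    "Common Extensor Digitorum", "First Dorsal Interosseous")
}

#' Construct a validated EMG trial
#'
#' @param signal numeric matrix, channels x samples.
#' @param samplingRate sampling rate in Hz.
#' @param weightLabel object weight in grams: 165, 330 or 660.
#' @param events named numeric vector with \code{led_on}, \code{touch_onset},
#'   \code{led_off} in seconds from trial start.
#' @param subjectId subject identifier.
#' @param trialIndex zero-based trial index within the subject.
#' @param channelNames optional channel names; defaults to the five study
#'   muscles when the trial has five channels, else \code{"ch1"...}.
#' @param preprocessed logical flag set by the preprocessing chain.
#' @return an \code{\linkS4class{EmgTrial}}.
#' @examples
#' tr <- EmgTrial(matrix(rnorm(2 * 100), 2), samplingRate = 100,
#'                weightLabel = 330,
#'                events = c(led_on = 0.1, touch_onset = 0.3, led_off = 0.8))
#' @export
EmgTrial <- function(signal, samplingRate, weightLabel, events,
                     subjectId = "s1", trialIndex = 0L, channelNames = NULL,
                     preprocessed = FALSE) {
  signal <- as.matrix(signal)
  if (is.null(channelNames)) {
    channelNames <- if (nrow(signal) == 5L) emgChannelNames()
                    else paste0("ch", seq_len(nrow(signal)))
  }
  new("EmgTrial", subjectId = as.character(subjectId),
      trialIndex = as.integer(trialIndex), signal = signal,
      samplingRate = as.numeric(samplingRate),
      weightLabel = as.integer(weightLabel),
      events = events[c("led_on", "touch_onset", "led_off")],
      channelNames = channelNames, preprocessed = isTRUE(preprocessed))
}

#' Construct a cohort from a list of trials
#'
#' @param trials list of \code{\linkS4class{EmgTrial}}; within-subject order
#'   is preserved (it encodes the blocked design).
#' @return an \code{\linkS4class{EmgCohort}}.
#' @export
EmgCohort <- function(trials) new("EmgCohort", trials = trials)

#' @rdname trials
#' @export
setMethod("trials", "EmgCohort", function(x) x@trials)

#' @rdname subjects
#' @export
setMethod("subjects", "EmgCohort", function(x)
  unique(vapply(x@trials, slot, character(1), "subjectId")))

#' @rdname weightLabels
#' @export
setMethod("weightLabels", "EmgCohort", function(x)
  vapply(x@trials, slot, integer(1), "weightLabel"))

#' @rdname nChannels
#' @export
setMethod("nChannels", "EmgTrial", function(x) nrow(x@signal))

#' @rdname nChannels
#' @export
setMethod("nChannels", "EmgCohort", function(x) nChannels(x@trials[[1]]))

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EmgTrial", function(x) x@samplingRate)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EmgCohort", function(x) samplingRate(x@trials[[1]]))

setMethod("length", "EmgCohort", function(x) length(x@trials))

#' @rdname classCounts
#' @export
setMethod("classCounts", "EmgCohort", function(x) {
  sid <- vapply(x@trials, slot, character(1), "subjectId")
  w <- vapply(x@trials, slot, integer(1), "weightLabel")
  subj <- unique(sid)
  out <- matrix(0L, length(subj), 3L,
                dimnames = list(subj, as.character(.WEIGHT_LEVELS)))
  for (i in seq_along(sid))
    out[sid[i], as.character(w[i])] <- out[sid[i], as.character(w[i])] + 1L
  out
})

setMethod("show", "EmgTrial", function(object) {
  cat(sprintf("EmgTrial %s/%d: %d ch x %d samples @ %g Hz, %d g%s\n",
              object@subjectId, object@trialIndex, nrow(object@signal),
              ncol(object@signal), object@samplingRate, object@weightLabel,
              if (object@preprocessed) " (preprocessed)" else ""))
  cat(sprintf("  events [s]: led_on %.3f, touch %.3f, led_off %.3f\n",
              object@events["led_on"], object@events["touch_onset"],
              object@events["led_off"]))
})

setMethod("show", "EmgCohort", function(object) {
  cc <- classCounts(object)
  cat(sprintf("EmgCohort: %d trials, %d subjects, %d channels @ %g Hz\n",
              length(object@trials), nrow(cc), nChannels(object),
              samplingRate(object)))
  cat("  per-class totals:",
      paste(sprintf("%s g: %d", colnames(cc), colSums(cc)), collapse = ", "),
      "\n")
  cat(sprintf("  max imbalance ratio: %.2f\n",
              max(apply(cc, 1, function(r) imbalanceRatio(r)))))
})

#' Class imbalance ratio
#'
#' Smallest class count divided by the largest; the study reports a maximum
#' per-subject value of 0.61, which motivates F1 over raw accuracy.
#'
#' @param counts positive numeric vector (or 1-row matrix) of class counts.
#' @return ratio in (0, 1].
#' @examples
#' imbalanceRatio(c(`165` = 70, `330` = 93, `660` = 57)) # 0.6129...
#' @export
imbalanceRatio <- function(counts) {
  counts <- as.numeric(counts)
  if (any(!is.finite(counts)) || any(counts <= 0))
    stop("imbalance ratio is undefined when any class count is zero")
  min(counts) / max(counts)
}

#' Published per-subject trial counts
#'
#' The per-subject number of trials for each weight class in the 12-subject
#' reach-grasp-lift cohort (2,645 trials in total; per-class totals 840, 1122
#' and 683 for 165, 330 and 660 g).
#'
#' @return integer matrix, 12 subjects x 3 weight classes.
#' @export
studyClassCounts <- function() {
  m <- matrix(c(
    70, 93, 57,
    70, 94, 57,
    70, 93, 57,
    70, 94, 57,
    70, 94, 57,
    70, 93, 56,
    70, 94, 57,
    70, 93, 57,
    70, 93, 57,
    70, 94, 57,
    70, 94, 57,
    70, 93, 57), nrow = 12, byrow = TRUE)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(paste0("subject", 1:12), c("165", "330", "660"))
  m
}
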