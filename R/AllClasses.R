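#' @import methods
NULL

.WEIGHT_LEVELS <- c(165L, 330L, 660L)

#' Single-trial multichannel EMG recording
#'
#' An \code{EmgTrial} holds one trial's channel-by-time signal matrix together
#' with its sampling rate, object-weight label (165, 330 or 660 g), subject
#' identifier and the three behavioural event times (LED on, touch onset,
#' LED off), in seconds from trial start.
#'
#' @slot subjectId character scalar, subject identifier.
#' @slot trialIndex integer, zero-based index of the trial within its subject.
#' @slot signal numeric matrix, channels x samples. Volts before
#'   preprocessing, unitless afterwards.
#' @slot samplingRate numeric scalar, Hz (study value 4000).
#' @slot weightLabel integer, one of 165, 330, 660 (grams).
#' @slot events named numeric vector with elements \code{led_on},
#'   \code{touch_onset}, \code{led_off}, seconds from trial start.
#' @slot channelNames character vector of muscle names, one per channel.
#' @slot preprocessed logical, set by \code{\link{preprocessTrial}}.
#'
#' @seealso \code{\link{EmgTrial}} for the validating constructor.
#' @exportClass EmgTrial
setClass("EmgTrial",
  slots = c(
    subjectId    = "character",
    trialIndex   = "integer",
    signal       = "matrix",
    samplingRate = "numeric",
    weightLabel  = "integer",
    events       = "numeric",
    channelNames = "character",
    preprocessed = "logical"
  )
)

setValidity("EmgTrial", function(object) {
  msg <- character()
  sig <- object@signal
  if (!is.numeric(sig) || nrow(sig) < 1L)
    msg <- c(msg, "signal must be a numeric matrix with >= 1 channel row")
  if (!all(is.finite(sig)))
    msg <- c(msg, "signal contains non-finite values")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (!(object@weightLabel %in% .WEIGHT_LEVELS))
    msg <- c(msg, sprintf("weightLabel must be one of %s",
                          paste(.WEIGHT_LEVELS, collapse = "/")))
  ev <- object@events
  need <- c("led_on", "touch_onset", "led_off")
  if (!all(need %in% names(ev))) {
    msg <- c(msg, sprintf("events must contain %s", paste(need, collapse = ", ")))
  } else {
    dur <- ncol(sig) / object@samplingRate
    e <- ev[need]
    if (any(!is.finite(e)) || e[1] < 0 || e[1] > e[2] || e[2] > e[3] ||
        e[3] > dur + 1e-9)
      msg <- c(msg, sprintf(
        "trial %s/%d: events must satisfy 0 <= led_on <= touch_onset <= led_off <= duration (%.3f s)",
        object@subjectId, object@trialIndex, dur))
  }
  if (length(object@channelNames) != nrow(sig))
    msg <- c(msg, "channelNames must have one entry per channel")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Cohort of EMG trials across subjects
#'
#' An ordered collection of \code{\linkS4class{EmgTrial}} objects. Trial order
#' within a subject is preserved because the blocked-design analyses
#' (anticipatory pre-touch activity) depend on trial sequence.
#'
#' @slot trials list of \code{EmgTrial}.
#' @exportClass EmgCohort
setClass("EmgCohort", slots = c(trials = "list"))

setValidity("EmgCohort", function(object) {
  if (!all(vapply(object@trials, is, logical(1), "EmgTrial")))
    return("all elements of trials must be EmgTrial objects")
  for (tr in object@trials) {
    v <- validObject(tr, test = TRUE)
    if (!isTRUE(v)) return(v)
  }
  TRUE
})

#' Trials-by-features matrix produced by the preprocessing chain
#'
#' Rows are trials, columns the subsampled, channel-concatenated signal
#' samples (the x_i in R^l consumed by the embeddings). At the study layout
#' (5 channels, 8 s segment, 4 kHz, subsampling step 5) l = 32,000.
#'
#' @slot values numeric matrix, trials x features; all entries finite.
#' @slot labels integer vector of weight labels aligned with rows.
#' @slot subjectIds character vector aligned with rows.
#' @slot layout list recording channels, segment_s, subsample_step and
#'   post_rate_hz used to build the matrix.
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  slots = c(values = "matrix", labels = "integer",
            subjectIds = "character", layout = "list"))

setValidity("FeatureMatrix", function(object) {
  n <- nrow(object@values)
  if (length(object@labels) != n || length(object@subjectIds) != n)
    return("labels and subjectIds must align with rows of values")
  if (!all(is.finite(object@values)))
    return("feature values must be finite")
  if (!all(object@labels %in% .WEIGHT_LEVELS))
    return("labels must be weight classes 165/330/660")
  TRUE
})

#' Union k-nearest-neighbour graph
#'
#' Nodes i and j are joined when i is among the n nearest neighbours of j or
#' vice versa (Euclidean metric, ties broken towards the lower index). Stored
#' as an edge list with distances so that degenerate duplicate points
#' (distance exactly 0) are representable.
#'
#' @slot n integer, number of nodes.
#' @slot nNeighbors integer, the neighbourhood size used to build the graph.
#' @slot edges two-column integer matrix of undirected edges (i < j).
#' @slot distances numeric vector of Euclidean edge lengths.
#' @slot connected logical, whether the graph has a single component.
#' @exportClass NeighborGraph
setClass("NeighborGraph",
  slots = c(n = "integer", nNeighbors = "integer", edges = "matrix",
            distances = "numeric", connected = "logical"))

setValidity("NeighborGraph", function(object) {
  E <- object@edges
  if (ncol(E) != 2L) return("edges must have two columns")
  if (nrow(E) != length(object@distances))
    return("distances must align with edges")
  if (nrow(E) > 0 && any(E[, 1] == E[, 2])) return("self-edges are not allowed")
  if (object@n > 1L && nrow(E) > 0 &&
      !all(seq_len(object@n) %in% c(E[, 1], E[, 2])))
    return("every node must have degree >= 1")
  TRUE
})

#' Fitted Laplacian Eigenmaps embedding
#'
#' Holds everything needed to reproduce the spectral embedding and to extend
#' it to new points: the training data, the neighbour graph, the weight
#' matrix W, degrees D, the retained generalized eigenpairs of L f = lambda D f
#' (L = D - W, zero eigenvalue dropped) and the embedding coordinates
#' y_i = (f_1(i), ..., f_m(i)).
#'
#' Eigenvectors are normalized so that f' D f = 1 and signed so the entry of
#' largest magnitude is positive, which makes the decomposition deterministic.
#'
#' @slot X numeric matrix of training points (trials x features).
#' @slot graph \code{\linkS4class{NeighborGraph}} on X.
#' @slot scheme character, \code{"simple"} (binary weights) or \code{"heat"}.
#' @slot sigma numeric, heat-kernel bandwidth (NA for simple-minded weights);
#'   corresponds to an RBF kernel with gamma = 1/(2 sigma^2).
#' @slot W symmetric sparse weight matrix.
#' @slot degrees numeric vector, D_ii = sum_j W_ji.
#' @slot eigenvalues numeric, the m smallest nonzero generalized eigenvalues
#'   in increasing order.
#' @slot vectors numeric matrix N x m of generalized eigenvectors (columns).
#' @slot m integer, embedding dimension.
#' @exportClass SpectralModel
setClass("SpectralModel",
  slots = c(X = "matrix", graph = "NeighborGraph", scheme = "character",
            sigma = "numeric", W = "Matrix", degrees = "numeric",
            eigenvalues = "numeric", vectors = "matrix", m = "integer"))

setValidity("SpectralModel", function(object) {
  if (!object@scheme %in% c("simple", "heat"))
    return("scheme must be 'simple' or 'heat'")
  if (length(object@eigenvalues) != object@m ||
      ncol(object@vectors) != object@m)
    return("eigenpairs must match embedding dimension m")
  if (any(object@eigenvalues <= 0))
    return("retained eigenvalues must be positive (zero eigenvector dropped)")
  TRUE
})

#' Classifier specification
#'
#' @slot kind character, one of knn, linear_svm, rbf_svm, random_forest.
#' @slot knnK integer, neighbours for the bespoke k-NN voter (default 8).
#' @slot svmC numeric, SVM cost (study value 32).
#' @slot svmGamma numeric, RBF kernel gamma (study value 0.01).
#' @slot rfTrees integer, random-forest size (default 100).
#' @slot seed integer, controls classifier randomness (random forest).
#' @exportClass ClassifierSpec
setClass("ClassifierSpec",
  slots = c(kind = "character", knnK = "integer", svmC = "numeric",
            svmGamma = "numeric", rfTrees = "integer", seed = "integer"))

setValidity("ClassifierSpec", function(object) {
  if (!object@kind %in% c("knn", "linear_svm", "rbf_svm", "random_forest"))
    return("kind must be knn, linear_svm, rbf_svm or random_forest")
  if (object@knnK < 1L || object@svmC <= 0 || object@svmGamma <= 0 ||
      object@rfTrees < 1L)
    return("classifier parameters must be positive")
  TRUE
})

#' Per-subject evaluation report
#'
#' @slot subjectId character.
#' @slot scores list with per-class precision/recall/F1 table and macro
#'   averages, as returned by \code{\link{f1Scores}}.
#' @slot params list of the embedding/classifier parameters actually used.
#' @slot protocol list recording split fractions and CV fold count.
#' @slot audit list of row indices touched by each stage (leakage audit).
#' @slot grid data.frame of grid-search cells (empty when no search was run).
#' @exportClass EvalReport
setClass("EvalReport",
  slots = c(subjectId = "character", scores = "list", params = "list",
            protocol = "list", audit = "list", grid = "data.frame"))

#' Sliding-window decoding series
#'
#' @slot series data.frame with one row per window offset: offset (s, relative
#'   to touch onset), segment ("pre_touch"/"post_touch"), meanF1, seF1,
#'   nSubjects, nFailed, failed.
#' @slot perSubject numeric matrix, windows x subjects, of macro F1 (NA where
#'   the window graph was disconnected for that subject).
#' @slot config list of the window configuration used.
#' @exportClass WindowSeries
setClass("WindowSeries",
  slots = c(series = "data.frame", perSubject = "matrix", config = "list"))

#' Synthetic-cohort configuration
#'
#' Defaults reproduce the study conditions: 12 subjects with the published
#' per-subject class counts, 4 kHz sampling, 10 s trials, blocked weight
#' repetition. See the methods vignette for the generative model.
#'
#' @slot nSubjects integer.
#' @slot classCounts integer matrix, subjects x 3 (columns 165/330/660 g).
#' @slot samplingRate numeric, Hz.
#' @slot trialDuration numeric, seconds.
#' @slot classGain numeric 5 x 3 matrix of per-muscle envelope amplitude
#'   multipliers, columns strictly increasing in weight for at least one
#'   muscle.
#' @slot noiseSd nonnegative numeric, additive Gaussian noise sd.
#' @slot subjectGainSd nonnegative numeric, sd of log-normal subject gains.
#' @slot pRepeat numeric in [0,1], probability that the next trial keeps the
#'   previous trial's weight (blocked design).
#' @slot anticipationGain nonnegative numeric, scales pre-touch activity by
#'   the previous trial's weight (0 = off).
#' @slot seed integer, fully determines the cohort.
#' @exportClass SimConfig
setClass("SimConfig",
  slots = c(nSubjects = "integer", classCounts = "matrix",
            samplingRate = "numeric", trialDuration = "numeric",
            classGain = "matrix", noiseSd = "numeric",
            subjectGainSd = "numeric", pRepeat = "numeric",
            anticipationGain = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@pRepeat < 0 || object@pRepeat > 1)
    msg <- c(msg, "pRepeat must be in [0, 1]")
  if (object@noiseSd < 0 || object@subjectGainSd < 0 ||
      object@anticipationGain < 0)
    msg <- c(msg, "noise, gain-sd and anticipation parameters must be >= 0")
  cc <- object@classCounts
  if (nrow(cc) != object@nSubjects || ncol(cc) != 3L)
    msg <- c(msg, "classCounts must be an nSubjects x 3 matrix")
  else if (any(cc <= 0)) msg <- c(msg, "class counts must be positive")
  g <- object@classGain
  if (ncol(g) != 3L)
    msg <- c(msg, "classGain must have one column per weight class")
  else if (!any(g[, 1] < g[, 2] & g[, 2] < g[, 3]))
    msg <- c(msg, paste0("classGain must be strictly increasing in weight ",
                         "for at least one muscle (separability guarantee)"))
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})
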