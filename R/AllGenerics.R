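#' @include AllClasses.R
NULL

#' Extract the trials of a cohort
#' @param x an \code{\linkS4class{EmgCohort}}.
#' @return list of \code{\linkS4class{EmgTrial}}.
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))

#' Subject identifiers
#' @param x an \code{\linkS4class{EmgCohort}} or
#'   \code{\linkS4class{FeatureMatrix}}.
#' @return character vector of subject ids in order of first appearance.
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))

#' Per-subject class counts
#' @param x an \code{\linkS4class{EmgCohort}}.
#' @return integer matrix, subjects x weight classes.
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' Number of channels
#' @param x an \code{\linkS4class{EmgTrial}} or \code{\linkS4class{EmgCohort}}.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Sampling rate in Hz
#' @param x an \code{\linkS4class{EmgTrial}} or \code{\linkS4class{EmgCohort}}.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Weight labels
#' @param x an \code{\linkS4class{EmgCohort}} or
#'   \code{\linkS4class{FeatureMatrix}}.
#' @return integer vector of per-trial weight labels (grams).
#' @export
setGeneric("weightLabels", function(x) standardGeneric("weightLabels"))

#' Feature values matrix
#' @param x a \code{\linkS4class{FeatureMatrix}}.
#' @return numeric matrix, trials x features.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' Embedding coordinates of a fitted model
#' @param x a fitted embedding model.
#' @return numeric matrix, training points x embedding dimensions.
#' @export
setGeneric("embedCoords", function(x) standardGeneric("embedCoords"))

#' Map new points into a fitted low-dimensional embedding
#'
#' The out-of-sample transform of each embedding: projection for PCA/LDA,
#' reconstruction-weight extension for LLE, landmark formula for ISOMAP and
#' the Nystrom extension for Laplacian Eigenmaps.
#'
#' @param model a fitted embedding model.
#' @param newX numeric matrix of new points sharing the training feature
#'   dimension.
#' @return numeric matrix of embedded coordinates, rows matching newX.
#' @export
setGeneric("extendEmbedding",
           function(model, newX) standardGeneric("extendEmbedding"))
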