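#' @include cohort.R
NULL

.FORMAT_VERSION <- "1.0"

#' Write a cohort to disk
#'
#' Two interchange layouts are supported. The primary layout is a single
#' HDF5 file: one dataset per trial under \code{/subjects/<id>/trials/<idx>}
#' (shape channels x samples) with attributes \code{sampling_rate_hz},
#' \code{weight_label}, \code{led_on_s}, \code{touch_onset_s},
#' \code{led_off_s}, and root attributes \code{format_version} and
#' \code{channel_names}. The fallback is a plain-text directory: one CSV per
#' trial (one column per channel) plus a \code{metadata.csv} sidecar. Both
#' round-trip signals bit-exactly.
#'
#' @param cohort an \code{\linkS4class{EmgCohort}}; validated before writing.
#' @param path output file (\code{.h5}/\code{.hdf5}) or directory.
#' @param format \code{"auto"} (from the path), \code{"hdf5"} or \code{"csv"}.
#' @return invisibly, \code{path}.
#' @seealso \code{\link{readCohort}}
#' @export
writeCohort <- function(cohort, path, format = c("auto", "hdf5", "csv")) {
  format <- match.arg(format)
  v <- validObject(cohort, test = TRUE)
  if (!isTRUE(v)) stop("invalid cohort: ", v)
  if (format == "auto")
    format <- if (grepl("\\.h5$|\\.hdf5$", path)) "hdf5" else "csv"
  if (format == "hdf5") .writeCohortH5(cohort, path) else .writeCohortCsv(cohort, path)
  invisible(path)
}

#' Read a cohort from disk
#'
#' Accepts either interchange layout produced by \code{\link{writeCohort}}.
#' Invariants are re-validated on load; missing required metadata (sampling
#' rate, weight label, event times) raises a parse error naming the missing
#' piece.
#'
#' @param path an HDF5 file or a CSV directory.
#' @return an \code{\linkS4class{EmgCohort}}.
#' @export
readCohort <- function(path) {
  if (dir.exists(path)) return(.readCohortCsv(path))
  if (!file.exists(path)) stop("no such file or directory: ", path)
  .readCohortH5(path)
}

## ---- HDF5 layout ----------------------------------------------------------

.needRhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("the HDF5 layout requires the rhdf5 package; use the CSV layout instead")
}

.writeCohortH5 <- function(cohort, path) {
  .needRhdf5()
  if (file.exists(path)) unlink(path)
  fid <- rhdf5::H5Fcreate(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(.FORMAT_VERSION, fid, "format_version")
  rhdf5::h5writeAttribute(cohort@trials[[1]]@channelNames, fid, "channel_names")
  rhdf5::H5Gclose(rhdf5::H5Gcreate(fid, "subjects"))
  seen <- character()
  for (tr in cohort@trials) {
    sid <- tr@subjectId
    if (!sid %in% seen) {
      rhdf5::H5Gclose(rhdf5::H5Gcreate(fid, paste0("subjects/", sid)))
      rhdf5::H5Gclose(rhdf5::H5Gcreate(fid, paste0("subjects/", sid, "/trials")))
      seen <- c(seen, sid)
    }
    nm <- sprintf("subjects/%s/trials/%d", sid, tr@trialIndex)
    rhdf5::h5write(tr@signal, fid, nm)
    did <- rhdf5::H5Dopen(fid, nm)
    rhdf5::h5writeAttribute(tr@samplingRate, did, "sampling_rate_hz")
    rhdf5::h5writeAttribute(as.integer(tr@weightLabel), did, "weight_label")
    rhdf5::h5writeAttribute(unname(tr@events["led_on"]), did, "led_on_s")
    rhdf5::h5writeAttribute(unname(tr@events["touch_onset"]), did, "touch_onset_s")
    rhdf5::h5writeAttribute(unname(tr@events["led_off"]), did, "led_off_s")
    rhdf5::H5Dclose(did)
  }
  invisible(path)
}

.readCohortH5 <- function(path) {
  .needRhdf5()
  ls <- rhdf5::h5ls(path)
  rootAttr <- rhdf5::h5readAttributes(path, "/")
  channelNames <- as.character(rootAttr[["channel_names"]])
  dsets <- ls[ls$otype == "H5I_DATASET" & grepl("^/subjects/", ls$group), ]
  if (nrow(dsets) == 0) stop("parse error: no trial datasets under /subjects")
  sids <- sub("^/subjects/([^/]+)/trials$", "\\1", dsets$group)
  if (any(sids == dsets$group))
    stop("parse error: expected layout /subjects/<id>/trials/<idx>")
  ord <- order(match(sids, unique(sids)), as.integer(dsets$name))
  dsets <- dsets[ord, ]; sids <- sids[ord]
  trl <- vector("list", nrow(dsets))
  for (i in seq_len(nrow(dsets))) {
    nm <- paste0(dsets$group[i], "/", dsets$name[i])
    sig <- rhdf5::h5read(path, nm)
    at <- rhdf5::h5readAttributes(path, nm)
    for (req in c("sampling_rate_hz", "weight_label", "led_on_s",
                  "touch_onset_s", "led_off_s"))
      if (is.null(at[[req]]))
        stop("parse error: trial ", nm, " is missing attribute ", req)
    trl[[i]] <- EmgTrial(sig, samplingRate = as.numeric(at$sampling_rate_hz),
                         weightLabel = as.integer(at$weight_label),
                         events = c(led_on = as.numeric(at$led_on_s),
                                    touch_onset = as.numeric(at$touch_onset_s),
                                    led_off = as.numeric(at$led_off_s)),
                         subjectId = sids[i],
                         trialIndex = as.integer(dsets$name[i]),
                         channelNames = channelNames)
  }
  EmgCohort(trl)
}

## ---- CSV-directory layout -------------------------------------------------

.writeCohortCsv <- function(cohort, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(path, "trials"), showWarnings = FALSE)
  meta <- data.frame(
    subject_id = vapply(cohort@trials, slot, character(1), "subjectId"),
    trial_index = vapply(cohort@trials, slot, integer(1), "trialIndex"),
    file = NA_character_, sampling_rate_hz = NA_real_,
    weight_label = vapply(cohort@trials, slot, integer(1), "weightLabel"),
    led_on_s = NA_real_, touch_onset_s = NA_real_, led_off_s = NA_real_,
    stringsAsFactors = FALSE)
  for (i in seq_along(cohort@trials)) {
    tr <- cohort@trials[[i]]
    fn <- sprintf("%s__%04d.csv", tr@subjectId, tr@trialIndex)
    meta$file[i] <- fn
    meta$sampling_rate_hz[i] <- tr@samplingRate
    meta$led_on_s[i] <- tr@events["led_on"]
    meta$touch_onset_s[i] <- tr@events["touch_onset"]
    meta$led_off_s[i] <- tr@events["led_off"]
    # columns = channels; 17 significant digits round-trips doubles exactly
    m <- t(tr@signal)
    txt <- apply(matrix(sprintf("%.17g", m), nrow(m)), 1, paste, collapse = ",")
    writeLines(c(paste(gsub(",", ";", tr@channelNames), collapse = ","), txt),
               file.path(path, "trials", fn))
  }
  nmeta <- meta
  for (cl in c("sampling_rate_hz", "led_on_s", "touch_onset_s", "led_off_s"))
    nmeta[[cl]] <- sprintf("%.17g", meta[[cl]])
  utils::write.csv(nmeta, file.path(path, "metadata.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

.readCohortCsv <- function(path) {
  mf <- file.path(path, "metadata.csv")
  if (!file.exists(mf)) stop("parse error: metadata.csv missing in ", path)
  meta <- utils::read.csv(mf, stringsAsFactors = FALSE)
  for (req in c("subject_id", "trial_index", "file", "sampling_rate_hz",
                "weight_label", "led_on_s", "touch_onset_s", "led_off_s"))
    if (is.null(meta[[req]]))
      stop("parse error: metadata.csv is missing column ", req)
  trl <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    fp <- file.path(path, "trials", meta$file[i])
    if (!file.exists(fp)) stop("parse error: missing trial file ", meta$file[i])
    df <- utils::read.csv(fp, check.names = FALSE)
    trl[[i]] <- EmgTrial(t(as.matrix(df)),  # n_channels inferred from columns
                         samplingRate = meta$sampling_rate_hz[i],
                         weightLabel = meta$weight_label[i],
                         events = c(led_on = meta$led_on_s[i],
                                    touch_onset = meta$touch_onset_s[i],
                                    led_off = meta$led_off_s[i]),
                         subjectId = as.character(meta$subject_id[i]),
                         trialIndex = meta$trial_index[i],
                         channelNames = colnames(df))
  }
  EmgCohort(trl)
}
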