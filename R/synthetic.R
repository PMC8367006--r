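#' @include cohort.R preprocess.R
NULL

## ---- manifold fixtures ----------------------------------------------------

#' Uniform random points on the unit sphere
#'
#' @param nPoints number of points (>= 4, so that neighbour graphs are
#'   non-degenerate).
#' @param seed integer seed; the point set is fully reproducible.
#' @return numeric matrix, nPoints x 3, rows of unit Euclidean norm.
#' @export
makeSphere <- function(nPoints, seed = 1) {
  if (nPoints < 4) stop("makeSphere: need at least 4 points")
  .withSeed(seed, {
    g <- matrix(stats::rnorm(nPoints * 3), ncol = 3)
    g / sqrt(rowSums(g^2))
  })
}

#' Random points on the Swiss roll
#'
#' Standard parameterization (t cos t, h, t sin t) with t = 1.5 pi (1 + 2u),
#' u ~ U(0,1) and h ~ U(0, 21). The intrinsic coordinates (t, h) are
#' returned for ground-truth tests.
#'
#' @param nPoints number of points (>= 4).
#' @param seed integer seed.
#' @return list with \code{points} (nPoints x 3) and \code{coords}
#'   (nPoints x 2, columns t and h).
#' @export
makeSwissRoll <- function(nPoints, seed = 1) {
  if (nPoints < 4) stop("makeSwissRoll: need at least 4 points")
  .withSeed(seed, {
    t_ <- 1.5 * pi * (1 + 2 * stats::runif(nPoints))
    h <- stats::runif(nPoints, 0, 21)
    list(points = cbind(x = t_ * cos(t_), y = h, z = t_ * sin(t_)),
         coords = cbind(t = t_, h = h))
  })
}

## ---- synthetic EMG cohort -------------------------------------------------

#' Configuration for the synthetic EMG cohort generator
#'
#' Defaults reproduce the study conditions: 12 subjects with the published
#' per-subject class counts (\code{\link{studyClassCounts}}), 5 muscles at
#' 4 kHz, 10 s trials, and a blocked design in which the object weight
#' repeats between consecutive trials with probability \code{pRepeat}.
#'
#' @param nSubjects number of subjects.
#' @param classCounts integer matrix (subjects x 3) of per-subject trial
#'   counts for 165/330/660 g; defaults to the published counts (rows
#'   recycled if \code{nSubjects} differs).
#' @param samplingRate Hz; must exceed 900 (the carrier band reaches 450 Hz).
#' @param trialDuration seconds per trial.
#' @param classGain 5 x 3 matrix of per-muscle amplitude multipliers,
#'   strictly increasing in weight for at least one muscle; defaults to
#'   base_m (w/330)^alpha_m with muscle-specific exponents.
#' @param noiseSd additive Gaussian measurement-noise sd.
#' @param subjectGainSd sd of the log-normal between-subject gain.
#' @param pRepeat blocked-design repetition probability (> 1/3 gives blocks).
#' @param anticipationGain scales pre-touch preparatory activity by the
#'   previous trial's weight; 0 disables anticipation.
#' @param seed integer; together with the other fields it fully determines
#'   the generated cohort.
#' @return a \code{\linkS4class{SimConfig}}.
#' @export
simConfig <- function(nSubjects = 12, classCounts = NULL, samplingRate = 4000,
                      trialDuration = 10, classGain = NULL, noiseSd = 0.05,
                      subjectGainSd = 0.15, pRepeat = 0.6,
                      anticipationGain = 0, seed = 1) {
  if (is.null(classCounts)) {
    cc <- studyClassCounts()
    classCounts <- cc[rep_len(seq_len(nrow(cc)), nSubjects), , drop = FALSE]
    rownames(classCounts) <- paste0("subject", seq_len(nSubjects))
  }
  storage.mode(classCounts) <- "integer"
  if (is.null(classGain)) {
    base <- c(0.9, 0.8, 1.0, 0.8, 0.6)
    alpha <- c(0.6, 0.8, 1.0, 0.7, 0.5)
    classGain <- outer(seq_along(base), seq_len(3), function(m, w)
      base[m] * (.WEIGHT_LEVELS[w] / 330)^alpha[m])
    dimnames(classGain) <- list(emgChannelNames(),
                                as.character(.WEIGHT_LEVELS))
  }
  if (samplingRate <= 900)
    stop("simConfig: samplingRate must exceed 900 Hz (carrier band 20-450 Hz)")
  new("SimConfig", nSubjects = as.integer(nSubjects),
      classCounts = classCounts, samplingRate = as.numeric(samplingRate),
      trialDuration = as.numeric(trialDuration), classGain = classGain,
      noiseSd = as.numeric(noiseSd), subjectGainSd = as.numeric(subjectGainSd),
      pRepeat = as.numeric(pRepeat),
      anticipationGain = as.numeric(anticipationGain), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: %d subjects, %d trials, %g Hz, %g s trials, ",
                     "noiseSd %g, pRepeat %g, anticipation %g, seed %d\n"),
              object@nSubjects, sum(object@classCounts), object@samplingRate,
              object@trialDuration, object@noiseSd, object@pRepeat,
              object@anticipationGain, object@seed))
})

# Band-limited (20-450 Hz) unit-variance Gaussian noise carriers with a soft
# amplitude ceiling (full motor-pool recruitment bounds EMG amplitude); the
# ceiling keeps the per-trial peak statistic tight so that peak
# normalization is stable. Synthesized spectrally: a white Gaussian matrix
# is shaped by the Butterworth band magnitude in the frequency domain,
# which is distribution-identical to filtering and needs one FFT per
# channel. Returns an nChannels x n matrix.
.emgCarrier <- function(n, rateHz, nChannels) {
  m <- stats::nextn(n, c(2, 3, 5))
  H <- sqrt(.butterResponse2(m, rateHz, 20, 450, 4))  # symmetric band mask
  nPairs <- ceiling(nChannels / 2)
  out <- matrix(0, nChannels, n)
  for (p in seq_len(nPairs)) {
    # one complex inverse FFT yields two independent band-limited Gaussian
    # channels (real and imaginary parts; independence needs the symmetric
    # mask, which makes their cross-covariance an odd sum that cancels)
    spec <- H * complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
    z <- stats::fft(spec, inverse = TRUE)
    a <- 2L * p - 1L
    out[a, ] <- Re(z)[seq_len(n)]
    if (a + 1L <= nChannels) out[a + 1L, ] <- Im(z)[seq_len(n)]
  }
  out <- out / apply(out, 1, stats::sd)
  2.2 * tanh(out / 2.2)
}

# Fixed random-Fourier bases realizing Gaussian-process oscillatory drives
# over the effort latent lambda: modulation waveforms of nearby lambda are
# strongly correlated (RBF kernel, length scale 0.35), so the three weight
# classes occupy adjacent regions of one continuous manifold. Two drives are
# used: the steady-hold drive is locked to the trial clock (it carries the
# whole-trial decodability), while the early grip drive runs in
# touch-relative time so that event-aligned windows see aligned waveforms.
.TREMOR_K <- 128L
.tremorBasis <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- .withSeed(20260921L, list(
        f1 = stats::runif(.TREMOR_K, 6, 28),
        phi1 = stats::runif(.TREMOR_K, 0, 2 * pi),
        om1 = stats::rnorm(.TREMOR_K, 0, 1 / 0.35),
        psi1 = stats::runif(.TREMOR_K, 0, 2 * pi),
        f2 = stats::runif(.TREMOR_K, 8, 30),
        phi2 = stats::runif(.TREMOR_K, 0, 2 * pi),
        om2 = stats::rnorm(.TREMOR_K, 0, 1 / 0.35),
        psi2 = stats::runif(.TREMOR_K, 0, 2 * pi)))
    cache
  }
})
.tremorCosCache <- new.env(parent = emptyenv())

# GP drive on an arbitrary time grid; `which` selects the basis. The drive
# carries no content above ~30 Hz, so it is evaluated on a 500 Hz grid
# spanning the requested range (cosine basis cached per grid) and linearly
# interpolated onto the target samples.
.tremorDrive <- function(tGrid, lambda, which = 1L, amp = 1.4,
                         cacheKey = NULL) {
  b <- .tremorBasis()
  f <- b[[paste0("f", which)]]; phi <- b[[paste0("phi", which)]]
  om <- b[[paste0("om", which)]]; psi <- b[[paste0("psi", which)]]
  t0 <- tGrid[1]; t1 <- tGrid[length(tGrid)]
  coarse <- seq(t0, t1, by = 0.002)
  if (length(coarse) < 2L || coarse[length(coarse)] < t1)
    coarse <- c(coarse, t1 + 0.002)
  key <- sprintf("b%d_%.6f_%.6f_%d", which, t0, t1, length(coarse))
  CM <- .tremorCosCache[[key]]
  if (is.null(CM)) {
    CM <- cos(outer(coarse, 2 * pi * f) +
              matrix(phi, length(coarse), .TREMOR_K, byrow = TRUE))
    .tremorCosCache[[key]] <- CM
  }
  ck <- cos(om * lambda + psi)
  dv <- 1 + (amp * sqrt(2 / .TREMOR_K)) * as.numeric(CM %*% ck)
  dv <- pmin(pmax(dv, 0), 2.6)  # drive ceiling; keeps the reach burst the peak
  if (length(tGrid) == length(coarse) && isTRUE(all.equal(tGrid, coarse)))
    return(dv)
  stats::approx(coarse, dv, xout = tGrid, rule = 2)$y
}

.smoothstep <- function(t, t0, rise) {
  u <- pmin(pmax((t - t0) / rise, 0), 1)
  u * u * (3 - 2 * u)
}
.gaussBump <- function(t, center, sd) exp(-((t - center)^2) / (2 * sd^2))

# Weight class -> centre of the effort latent; a subject's trials sample
# the class range on a jittered even grid, so classes abut (a continuum is
# needed for connected neighbour graphs), overlap almost nowhere, and the
# largest within-class gap is bounded for every seed.
.LAMBDA_CENTER <- c(`165` = 0, `330` = 3.3, `660` = 6.6)
.LAMBDA_SPREAD <- 1.6

# jittered-stratified effort draws for one subject: per class, n evenly
# spaced levels with jitter, in random order
.sampleEffort <- function(countsByClass) {
  lapply(seq_along(countsByClass), function(wi) {
    n <- countsByClass[wi]
    grid <- .LAMBDA_CENTER[wi] +
      .LAMBDA_SPREAD * (2 * (seq_len(n) - 0.5) / n - 1)
    sample(grid + stats::rnorm(n, 0, .LAMBDA_SPREAD / (2 * n)))
  })
}

# One synthetic trial. All envelope time constants scale with trial duration
# (sc = dur/10) so shortened test trials keep the full movement morphology.
.simTrial <- function(weight, config, subjGain, touch, lam,
                      prevWeight = NA, prevLam = NA) {
  rate <- config@samplingRate; dur <- config@trialDuration
  sc <- dur / 10
  wi <- match(weight, .WEIGHT_LEVELS)
  ledOn <- stats::runif(1, 0.02, 0.05) * dur
  ledOff <- touch + (4.8 + stats::runif(1, -0.05, 0.05)) * sc
  nt <- round(dur * rate)
  t <- (0:(nt - 1)) / rate
  nm <- nrow(config@classGain)
  plateau <- rep_len(c(0.55, 0.65, 0.75, 0.70, 0.60), nm)
  reachAmp <- 3.8 * plateau   # the reach burst sets the per-channel peak
  riseT <- (0.05 + 0.015 * lam) * sc
  delta <- (0.10 + 0.03 * lam) * sc
  # contact grip floor at touch, then load-dependent force development
  hold <- (0.8 * .smoothstep(t, touch + 0.015 * sc, 0.015 * sc) +
           0.2 * .smoothstep(t, touch + 0.08 * sc, riseT)) *
    (1 - .smoothstep(t, ledOff, 0.08 * sc))
  # early grip drive (touch-locked time base) cross-fades into the steady
  # hold drive (trial-clock time base) as the object stabilizes
  fade <- .smoothstep(t, touch + 0.55 * sc, 0.3 * sc)
  drive <- 1 + fade * (.tremorDrive(t, lam, which = 1L,
                                    cacheKey = sprintf("clk_n%d_r%g", nt, rate)) - 1)
  early <- t >= touch & fade < 1
  drive[early] <- drive[early] + (1 - fade[early]) *
    (.tremorDrive(t[early] - touch, lam, which = 2L, amp = 1.7) - 1)
  reach <- .smoothstep(t, touch - 0.55 * sc, 0.15 * sc) *
    (1 - .smoothstep(t, touch - 0.12 * sc, 0.10 * sc))
  lift <- .gaussBump(t, touch + 0.08 * sc + delta, 0.05 * sc)
  carrier <- .emgCarrier(nt, rate, nm)
  # anticipatory preparation replays the previous lift's grip pattern
  # (touch-locked oscillation indexed by the previous trial's effort latent)
  antic <- 0
  if (config@anticipationGain > 0 && !is.na(prevWeight)) {
    if (is.na(prevLam)) prevLam <- .LAMBDA_CENTER[match(prevWeight, .WEIGHT_LEVELS)]
    antic <- config@anticipationGain * (prevWeight / 330)^0.8 *
      .gaussBump(t, touch - 0.35 * sc, 0.18 * sc)
    sup <- t < touch & antic > 1e-8 * max(antic)
    antic[sup] <- antic[sup] *
      .tremorDrive(t[sup] - touch, prevLam, which = 2L, amp = 1.7)
    antic[t >= touch] <- 0
  }
  S <- matrix(0, nm, nt)
  for (m in seq_len(nm)) {
    env <- reachAmp[m] * reach +
      plateau[m] * (1 + 0.03 * lam) * hold * drive +
      0.4 * plateau[m] * lift + antic
    gain <- config@classGain[m, wi] * subjGain * exp(stats::rnorm(1, 0, 0.05))
    S[m, ] <- gain * env * carrier[m, ]
  }
  if (config@noiseSd > 0)
    S <- S + config@noiseSd * matrix(stats::rnorm(nm * nt), nm, nt)
  list(signal = S, lam = lam,
       events = c(led_on = ledOn, touch_onset = touch, led_off = ledOff))
}

# Blocked-design weight sequence with exact class counts: with probability
# pRepeat the previous weight is kept (while trials of it remain), otherwise
# the next weight is drawn proportional to the remaining counts.
.sampleWeightSequence <- function(counts, pRepeat) {
  remaining <- as.integer(counts)
  n <- sum(remaining)
  seqW <- integer(n)
  prev <- 0L
  for (i in seq_len(n)) {
    if (prev > 0L && remaining[prev] > 0L && stats::runif(1) < pRepeat) {
      pick <- prev
    } else {
      avail <- which(remaining > 0L)
      if (prev > 0L && length(avail) > 1L) avail <- setdiff(avail, prev)
      pick <- if (length(avail) == 1L) avail
              else sample(avail, 1L, prob = remaining[avail])
    }
    seqW[i] <- pick
    remaining[pick] <- remaining[pick] - 1L
    prev <- pick
  }
  .WEIGHT_LEVELS[seqW]
}

#' Simulate a synthetic EMG cohort
#'
#' Generates trials with the statistical structure the pipeline assumes:
#' per-muscle band-limited (20-450 Hz) noise carriers multiplied by a smooth
#' activation envelope (weight-independent reach burst before touch, a
#' grasp-hold plateau with load-dependent dynamics after touch), plus
#' additive Gaussian noise. Object weight drives a continuous neuromuscular
#' effort latent controlling load-phase timing, grip-force development rate
#' and the spectral profile of an oscillatory load-stabilization drive; the
#' per-muscle \code{classGain} multipliers additionally scale raw amplitude
#' monotonically with weight. Event times are jittered but ordered, and the
#' trial sequence repeats the previous weight with probability
#' \code{pRepeat}. When \code{anticipationGain > 0}, pre-touch preparatory
#' activity scales with the previous trial's weight, so pre-touch decoding
#' becomes possible exactly through blocked repetition.
#'
#' The full default cohort (2,645 trials of 10 s at 4 kHz) occupies roughly
#' 4 GB; use \code{subjects} to generate one subject at a time. Subject
#' streams are seeded independently, so a subject's trials are identical
#' whether generated alone or within the full cohort.
#'
#' @param config a \code{\linkS4class{SimConfig}}.
#' @param subjects optional integer vector of subject indices to generate.
#' @return an \code{\linkS4class{EmgCohort}}.
#' @export
simulateCohort <- function(config, subjects = NULL) {
  v <- validObject(config, test = TRUE)
  if (!isTRUE(v)) stop("invalid SimConfig: ", v)
  if (is.null(subjects)) subjects <- seq_len(config@nSubjects)
  subjSeeds <- .withSeed(config@seed,
                         sample.int(.Machine$integer.max - 1L,
                                    config@nSubjects))
  trialsOut <- list()
  for (s in subjects) {
    sid <- rownames(config@classCounts)[s]
    if (is.null(sid)) sid <- paste0("subject", s)
    trialsOut <- c(trialsOut, .withSeed(subjSeeds[s], {
      subjGain <- exp(stats::rnorm(1, 0, config@subjectGainSd))
      touchMu <- stats::runif(1, 0.17, 0.23) * config@trialDuration
      wseq <- .sampleWeightSequence(config@classCounts[s, ], config@pRepeat)
      lamPool <- .sampleEffort(config@classCounts[s, ])
      lamUsed <- c(0L, 0L, 0L)
      out <- vector("list", length(wseq))
      prevLam <- NA_real_
      for (i in seq_along(wseq)) {
        touch <- touchMu + stats::rnorm(1, 0, 0.003 * config@trialDuration)
        touch <- min(max(touch, 0.12 * config@trialDuration),
                     0.28 * config@trialDuration)
        wi <- match(wseq[i], .WEIGHT_LEVELS)
        lamUsed[wi] <- lamUsed[wi] + 1L
        tr <- .simTrial(wseq[i], config, subjGain, touch,
                        lam = lamPool[[wi]][lamUsed[wi]],
                        prevWeight = if (i > 1) wseq[i - 1] else NA,
                        prevLam = prevLam)
        prevLam <- tr$lam
        out[[i]] <- EmgTrial(tr$signal, config@samplingRate, wseq[i],
                             tr$events, subjectId = sid, trialIndex = i - 1L,
                             channelNames = rownames(config@classGain))
      }
      out
    }))
  }
  EmgCohort(trialsOut)
}
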