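test_that("rectification is absolute value and idempotent", {
  expect_equal(rectify(c(-1, 2, -3)), c(1, 2, 3))
  expect_equal(rectify(matrix(0, 2, 5)), matrix(0, 2, 5))
  x <- matrix(rnorm(40), 4)
  expect_identical(rectify(rectify(x)), rectify(x))
  x[2, 3] <- Inf
  expect_error(rectify(x), "non-finite")
})

test_that("peak normalization scales each channel to unit maximum", {
  expect_equal(normalizeChannels(rbind(c(0, 2, 4))), rbind(c(0, 0.5, 1)))
  x <- rbind(c(0, 0.5, 1), c(-3, 1, 2))
  y <- normalizeChannels(x)
  expect_equal(y[1, ], x[1, ])                 # already normalized: unchanged
  expect_equal(unname(apply(abs(y), 1, max)), c(1, 1))
  expect_error(normalizeChannels(rbind(c(1, 2), c(0, 0))), "2")
})

test_that("band-pass filter has the designed frequency response", {
  rate <- 4000; n <- 16000
  tt <- (0:(n - 1)) / rate
  mid <- 4000:12000
  dc <- bandpassFilter(rep(1, n), rate)
  expect_lt(max(abs(dc)), 1e-3)                 # high-pass kills DC
  s50 <- bandpassFilter(sin(2 * pi * 50 * tt), rate)
  expect_true(max(abs(s50[mid])) > 0.9 && max(abs(s50[mid])) < 1.1)
  s1 <- bandpassFilter(sin(2 * pi * 1 * tt), rate)
  expect_lt(max(abs(s1[mid])), 0.1)             # stop-band attenuation
  expect_error(bandpassFilter(rnorm(100), 800, highHz = 450), "Nyquist")
})

test_that("frequency-domain filtering agrees with filtfilt away from edges", {
  set.seed(8)
  x <- matrix(rnorm(2 * 8000), 2)
  a <- bandpassFilter(x, 4000, method = "fft")
  b <- bandpassFilter(x, 4000, method = "filtfilt")
  expect_lt(max(abs(a[, 2000:6000] - b[, 2000:6000])), 5e-4)
})

test_that("the preprocessing chain equals its composed stages", {
  tr <- trials(tinyCohort(counts = c(1L, 1L, 1L), rate = 1000, dur = 1))[[1]]
  pp <- preprocessTrial(tr)
  manual <- bandpassFilter(normalizeChannels(rectify(tr@signal)),
                           tr@samplingRate)
  expect_identical(pp@signal, manual)
  expect_true(pp@preprocessed)
  expect_true(all(is.finite(pp@signal)))
  # deterministic: same input, bit-identical output
  expect_identical(preprocessTrial(tr)@signal, pp@signal)
})

test_that("zero-phase filtering preserves burst timing", {
  rate <- 2000; n <- 6000
  tt <- (0:(n - 1)) / rate
  set.seed(2)
  burst <- exp(-((tt - 1.4)^2) / (2 * 0.05^2)) * sin(2 * pi * 80 * tt)
  out <- bandpassFilter(burst, rate)
  smooth <- function(v) as.numeric(stats::filter(abs(v), rep(1 / 101, 101)))
  pin <- which.max(smooth(burst))
  pout <- which.max(smooth(out))
  expect_lt(abs(pin - pout) / rate, 0.025)      # peak moves < 25 ms
})

test_that("segmentation keeps the exact first seconds and drops late events", {
  co <- tinyCohort(counts = c(1L, 1L, 1L), rate = 4000, dur = 10, seed = 2)
  tr <- trials(co)[[1]]
  seg <- suppressMessages(segmentFirst(tr, 8))
  expect_equal(ncol(seg@signal), 32000)         # 8 s x 4 kHz
  expect_equal(seg@events[["touch_onset"]], tr@events[["touch_onset"]])
  expect_message(segmentFirst(tr, 5), "led_off")
  seg5 <- suppressMessages(segmentFirst(tr, 5))
  expect_equal(seg5@events[["led_off"]], 5)     # clamped to the cut
  short <- mkTrial(nCh = 2, n = 700, rate = 100)
  expect_error(segmentFirst(short, 8), "shorter")
})

test_that("feature assembly yields the expected dimensionality", {
  mk <- function(nCh, n, rate, w = 330L, subj = "s1")
    EmgTrial(matrix(rnorm(nCh * n) / 10, nCh), rate, w,
             c(led_on = 0.1, touch_onset = 1, led_off = n / rate * 0.9),
             subjectId = subj, preprocessed = TRUE)
  t5 <- mk(5, 32000, 4000)
  fm <- assembleFeatures(list(t5), subsampleStep = 5)
  expect_equal(ncol(fm@values), 32000)          # 5 x 8 x 800
  fm2 <- assembleFeatures(list(mk(2, 32000, 4000)), subsampleStep = 5)
  expect_equal(ncol(fm2@values), 12800)         # 2 x 8 x 800
  fm3 <- assembleFeatures(list(t5), subsampleStep = 1)
  expect_equal(ncol(fm3@values), 160000)        # concatenation only
  # first feature block is channel 1's subsampled samples, in order
  expect_equal(fm@values[1, 1:3], t5@signal[1, c(1, 6, 11)])
  expect_error(assembleFeatures(list(t5, mk(2, 32000, 4000))), "mixed")
})

test_that("feature rows stay aligned with their trials", {
  co <- tinyCohort(counts = c(2L, 2L, 2L), rate = 1000, dur = 1, seed = 3)
  # sentinel: overwrite one trial with a constant so its row is recognizable
  trl <- trials(co)
  sig <- trl[[4]]@signal; sig[] <- sig * 0.001; sig[1, 1] <- 1000
  trl[[4]]@signal <- sig
  co2 <- EmgCohort(trl)
  fm <- cohortFeatures(co2, segmentS = 0.8)
  expect_equal(which.max(abs(fm@values[, 1])), 4)
  expect_identical(fm@labels, weightLabels(co2))
  # fused path equals the composed operations
  manual <- assembleFeatures(lapply(trl, function(t)
    suppressMessages(segmentFirst(preprocessTrial(t), 0.8))), 5)
  expect_equal(fm@values, manual@values)
})
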