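test_that("sphere fixture is uniform on the unit sphere and seeded", {
  P <- makeSphere(2000, seed = 3)
  expect_equal(dim(P), c(2000, 3))
  expect_true(all(abs(sqrt(rowSums(P^2)) - 1) < 1e-12))
  expect_identical(P, makeSphere(2000, seed = 3))
  expect_false(identical(P, makeSphere(2000, seed = 4)))
  expect_true(all(abs(colMeans(P)) < 0.1))   # Monte-Carlo bound at n = 2000
  expect_error(makeSphere(3), "at least 4")
})

test_that("swiss roll reconstructs from its intrinsic coordinates", {
  sr <- makeSwissRoll(500, seed = 2)
  t_ <- sr$coords[, "t"]; h <- sr$coords[, "h"]
  expect_equal(sr$points[, 1], t_ * cos(t_))
  expect_equal(sr$points[, 2], h)
  expect_equal(sr$points[, 3], t_ * sin(t_))
  expect_equal(nrow(makeSwissRoll(4)$points), 4)   # boundary, no error
})

test_that("parameter-space neighbours mostly stay ambient neighbours", {
  sr <- makeSwissRoll(2000, seed = 1)
  D3 <- as.matrix(dist(sr$points)); DC <- as.matrix(dist(sr$coords))
  diag(D3) <- Inf; diag(DC) <- Inf
  frac <- mean(vapply(seq_len(2000), function(i)
    which.min(DC[i, ]) %in% order(D3[i, ])[1:10], logical(1)))
  expect_gt(frac, 0.85)
})

test_that("simulated cohorts are deterministic and subject-consistent", {
  cfg <- simConfig(nSubjects = 3, classCounts = matrix(rep(c(4L, 5L, 3L),
                                                           each = 3), 3),
                   samplingRate = 1200, trialDuration = 2.5, seed = 11)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(lapply(trials(a), slot, "signal"),
                   lapply(trials(b), slot, "signal"))
  expect_identical(lapply(trials(a), slot, "events"),
                   lapply(trials(b), slot, "events"))
  # a subject generated alone matches its slice of the full cohort
  sub2 <- simulateCohort(cfg, subjects = 2)
  s2 <- Filter(function(t) t@subjectId == "subject2", trials(a))
  expect_identical(lapply(s2, slot, "signal"),
                   lapply(trials(sub2), slot, "signal"))
  # exact class counts and valid, ordered events
  expect_identical(unname(classCounts(a)),
                   matrix(rep(c(4L, 5L, 3L), each = 3), 3))
  for (tr in trials(a)) {
    e <- tr@events
    expect_true(e["led_on"] <= e["touch_onset"] &&
                e["touch_onset"] <= e["led_off"])
  }
})

test_that("post-touch rectified amplitude is ordered by weight per trial", {
  co <- tinyCohort(counts = c(10L, 10L, 10L), rate = 2000, dur = 5,
                   noiseSd = 0, seed = 9)
  labs <- weightLabels(co)
  # Flexor Digitorum (channel 3) has the steepest gain-weight relation
  amp <- vapply(trials(co), function(t) {
    i0 <- round(t@events["touch_onset"] * t@samplingRate)
    mean(abs(t@signal[3, i0:(0.96 * ncol(t@signal))]))
  }, numeric(1))
  expect_lt(max(amp[labs == 165]), min(amp[labs == 330]))
  expect_lt(max(amp[labs == 330]), min(amp[labs == 660]))
})

test_that("blocked design repeats weights at the configured rate", {
  for (p in c(0.4, 0.6)) {
    sq <- emglift:::.withSeed(5,
      emglift:::.sampleWeightSequence(c(3400, 3300, 3301), p))
    expect_equal(mean(sq[-1] == sq[-length(sq)]), p, tolerance = 0.02 / p)
    expect_identical(as.integer(table(sq)), c(3400L, 3300L, 3301L))
  }
})

test_that("configuration invariants are validated", {
  expect_error(simConfig(pRepeat = 1.4), "pRepeat")
  expect_error(simConfig(noiseSd = -1), ">= 0")
  expect_error(simConfig(samplingRate = 500), "900")
  # a gain matrix decreasing in weight for every muscle is rejected
  g <- matrix(rep(c(3, 2, 1), each = 5), 5)
  expect_error(simConfig(classGain = g), "strictly increasing")
})
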