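test_that("pixelwise spectra match the naive O(N^2) DFT oracle", {
  set.seed(10)
  arr <- array(stats::rnorm(32 * 4 * 4), c(32, 4, 4))
  s <- reflectanceSequence(arr, frameInterval = 0.5)
  sp <- powerSpectrumPixelwise(s)
  for (i in 1:4) for (j in 1:4) {
    want <- naivePowerSpectrum(arr[, i, j])
    got <- sp$power[, i, j]
    expect_lt(max(abs(got - want)) / max(want), 1e-9)
  }
  expect_equal(sp$freq, (0:16) / (32 * 0.5))
  expect_equal(sp$dcBin, 1L)
})

test_that("constant traces put all power in the flagged DC bin", {
  c0 <- 3.2; n <- 24
  s <- reflectanceSequence(array(c0, c(n, 2, 2)), frameInterval = 1)
  sp <- powerSpectrumPixelwise(s)
  expect_equal(sp$power[1, 1, 1], c0^2 * n)   # |X_0|^2 / N = (cN)^2 / N
  expect_lt(max(abs(sp$power[-1, , ])), 1e-18)
})

test_that("a bin-aligned sinusoid concentrates one-sided power a^2 N / 2 in its bin", {
  n <- 64; a <- 0.7; k <- 5
  tr <- a * sin(2 * pi * k * (seq_len(n) - 1) / n + 0.4)
  s <- reflectanceSequence(array(tr, c(n, 1, 1)), frameInterval = 2)
  sp <- powerSpectrumPixelwise(s)
  px <- sp$power[, 1, 1]
  expect_equal(px[k + 1], a^2 * n / 2, tolerance = 1e-9)
  expect_lt(sum(px[-(k + 1)]), 1e-9 * px[k + 1])
})

test_that("one-sided non-DC power sums to the squared deviations (Parseval)", {
  set.seed(2)
  for (n in c(32, 33)) {                        # even and odd records
    x <- stats::rnorm(n)
    s <- reflectanceSequence(array(x, c(n, 1, 1)), frameInterval = 1)
    px <- powerSpectrumPixelwise(s)$power[, 1, 1]
    expect_equal(sum(px[-1]), sum((x - mean(x))^2), tolerance = 1e-6)
  }
})

test_that("two bin-aligned sinusoids give the closed-form power ratio a^2/b^2", {
  p <- stimulusParadigm(cycles = 3)             # f_stim on bin 3 of 360
  n <- totalFrames(p)
  t <- (seq_len(n) - 1) / p@frameRate
  a <- 0.03; b <- 0.012
  fv <- 5 / (n / p@frameRate)                   # VLF bin 5, 0.0278 Hz
  tr <- a * sin(2 * pi * stimFrequency(p) * t) + b * sin(2 * pi * fv * t + 1)
  s <- reflectanceSequence(array(tr, c(n, 1, 1)),
                           frameInterval = 1 / p@frameRate)
  am <- computeActivityMap(s, p)
  expect_equal(ratioMap(am)[1, 1], a^2 / b^2, tolerance = 1e-6)

  amA <- computeActivityMap(s, p, measure = "amplitude")
  expect_equal(ratioMap(amA)[1, 1], a / b, tolerance = 1e-6)
})

test_that("zero-variance pixels get ratio zero and are counted", {
  p <- stimulusParadigm(cycles = 3)
  n <- totalFrames(p)
  s <- reflectanceSequence(array(1.5, c(n, 2, 2)),
                           frameInterval = 1 / p@frameRate)
  am <- computeActivityMap(s, p)
  expect_true(all(ratioMap(am) == 0))
  expect_true(all(stimPower(am) == 0))
  expect_equal(am@zeroDenominatorCount, 4L)
})

test_that("the ratio map is invariant to gain and, after detrending, to offset", {
  cfg <- smallScene(seed = 6, grid = 12)
  seq0 <- detrendPixelwise(simulateSequence(cfg)$sequence)
  am0 <- computeActivityMap(seq0, cfg@paradigm)

  g <- 3.7
  scaled <- reflectanceSequence(frames(seq0) * g, frameInterval(seq0))
  amG <- computeActivityMap(scaled, cfg@paradigm)
  expect_lt(max(abs(ratioMap(amG) - ratioMap(am0))), 1e-9 * max(ratioMap(am0)))

  shifted <- simulateSequence(cfg)$sequence
  shifted <- reflectanceSequence(frames(shifted) + 11, frameInterval(shifted))
  amS <- computeActivityMap(detrendPixelwise(shifted), cfg@paradigm)
  expect_lt(max(abs(ratioMap(amS) - ratioMap(am0))), 1e-9 * max(ratioMap(am0)))
})

test_that("off-bin stimulation frequencies are rejected with guidance", {
  p <- stimulusParadigm(cycles = 3)
  s <- reflectanceSequence(array(stats::rnorm(100 * 4), c(100, 2, 2)),
                           frameInterval = 0.5)
  expect_error(computeActivityMap(s, p), "bin-aligned record lengths")
})

test_that("the VLF band is half-open and guard bins shield the stimulation line", {
  # paradigm: f_stim = 1/25 Hz on bin 4 of a 100-frame, 1 fps record
  p <- stimulusParadigm(restDuration = 15, stimDuration = 10, cycles = 4,
                        frameRate = 1)
  n <- totalFrames(p)
  t <- seq_len(n) - 1
  edge <- 20 / n                                # bin 20 exactly at vlfMax
  tr <- 0.5 * sin(2 * pi * stimFrequency(p) * t) + 0.3 * sin(2 * pi * edge * t)
  s <- reflectanceSequence(array(tr, c(n, 1, 1)), frameInterval = 1)
  am <- suppressWarnings(computeActivityMap(s, p, vlfMax = edge))
  # the edge bin is excluded (half-open band) and the stimulation bin is
  # guarded, so no band power remains at this pixel
  expect_equal(vlfPower(am)[1, 1], 0, tolerance = 1e-12)
  expect_equal(am@excludedBins, c(0L, 3L, 4L, 5L))

  amIn <- suppressWarnings(
    computeActivityMap(s, p, vlfMax = edge + 1e-6,
                       excludeStimBinFromVlf = FALSE))
  expect_gt(vlfPower(amIn)[1, 1], 0)
  expect_equal(amIn@excludedBins, 0L)
})

test_that("a Hann window still localizes the stimulation line", {
  cfg <- smallScene(seed = 0, grid = 8, noiseSd = 0)
  seqd <- detrendPixelwise(simulateSequence(cfg)$sequence)
  am <- computeActivityMap(seqd, cfg@paradigm, window = "hann")
  act <- simulateSequence(cfg)$truth@activationMask
  expect_gt(mean(ratioMap(am)[act]), mean(ratioMap(am)[!act]))
})

test_that("activation pixels carry higher ratios than the rest of the trepanation", {
  hits <- 0L
  for (seed in 0:4) {
    cfg <- smallScene(seed = seed)
    sim <- simulateSequence(cfg)
    am <- computeActivityMap(detrendPixelwise(sim$sequence), cfg@paradigm)
    act <- sim$truth@activationMask
    bg <- sim$truth@trepanationMask & !act
    if (mean(ratioMap(am)[act]) > mean(ratioMap(am)[bg])) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("doubling the activation amplitude never weakens the in-mask ratio", {
  cfg1 <- smallScene(seed = 9, activationAmplitude = -0.02)
  cfg2 <- smallScene(seed = 9, activationAmplitude = -0.04)
  m1 <- computeActivityMap(detrendPixelwise(simulateSequence(cfg1)$sequence),
                           cfg1@paradigm)
  m2 <- computeActivityMap(detrendPixelwise(simulateSequence(cfg2)$sequence),
                           cfg2@paradigm)
  act <- simulateSequence(cfg1)$truth@activationMask
  expect_gte(median(ratioMap(m2)[act]), median(ratioMap(m1)[act]))
})
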