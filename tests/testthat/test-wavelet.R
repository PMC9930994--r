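test_that("wavelet grid is geometric, ordered and spans the usable band", {
  g <- waveletGrid(250)
  expect_true(all(diff(gridScales(g)) > 0))
  expect_true(all(diff(gridFrequencies(g)) < 0))
  expect_lte(min(gridFrequencies(g)), 1.5)
  expect_gte(max(gridFrequencies(g)), 125)
  # 12 voices per octave: constant frequency ratio of 2^(1/12)
  ratios <- gridFrequencies(g)[-length(gridFrequencies(g))] /
    gridFrequencies(g)[-1]
  expect_equal(ratios, rep(2^(1 / 12), length(ratios)), tolerance = 1e-12)
})

test_that("CWT localizes a sinusoid, is linear and rejects bad input", {
  g <- waveletGrid(250)
  tt <- seq(0, 0.7, by = 1 / 250)
  x <- sin(2 * pi * 6 * tt)
  W <- analyticMorletCWT(x, 250, g)
  fPeak <- gridFrequencies(g)[which.max(rowMeans(Mod(W)))]
  expect_lt(abs(log2(fPeak / 6)), 1 / 12)          # within one voice
  # zero signal -> all-zero coefficients
  expect_equal(max(Mod(analyticMorletCWT(numeric(176), 250, g))), 0)
  # linearity to machine precision
  set.seed(1)
  y <- rnorm(176)
  expect_lt(max(Mod(analyticMorletCWT(2.5 * y, 250, g) -
                    2.5 * analyticMorletCWT(y, 250, g))), 1e-10)
  expect_error(analyticMorletCWT(c(y[-1], NaN), 250, g), "finite")
  expect_error(analyticMorletCWT(y[1:8], 250, g), "32")
})

test_that("smoothing operator matches a naive direct-convolution oracle", {
  g16 <- smallGrid(16)
  set.seed(2)
  M <- matrix(rnorm(16 * 64), 16, 64)
  S <- smoothSpectrum(M, g16, 250)
  Sref <- naiveSmoothOracle(M, gridScales(g16), 12, 250)
  expect_lt(max(abs(S - Sref)), 1e-10)
  # complex matrices smooth channel-wise
  Mc <- M + 1i * matrix(rnorm(16 * 64), 16, 64)
  Sc <- smoothSpectrum(Mc, g16, 250)
  ScRef <- naiveSmoothOracle(Re(Mc), gridScales(g16), 12, 250) +
    1i * naiveSmoothOracle(Im(Mc), gridScales(g16), 12, 250)
  expect_lt(max(Mod(Sc - ScRef)), 1e-10)
})

test_that("smoothing preserves constants and conserves interior mass", {
  g16 <- smallGrid(16)
  K <- matrix(3.7, 16, 64)
  expect_lt(max(abs(smoothSpectrum(K, g16, 250) - 3.7)), 1e-9)
  # single interior impulse: total mass conserved within 2 percent
  M <- matrix(0, 16, 64); M[8, 32] <- 1
  expect_lt(abs(sum(smoothSpectrum(M, g16, 250)) - 1), 0.02)
})

test_that("self-coherence and scale invariance hold for broadband input", {
  set.seed(3)
  x <- rnorm(176)
  expect_gte(min(mswcMatrix(mswc(x, x, 250))), 1 - 1e-6)
  expect_gte(min(mswcMatrix(mswc(x, 0.8 * x, 250))), 1 - 1e-6)
})

test_that("mswc validates its inputs", {
  x <- rnorm(176)
  expect_error(mswc(x, x[-1], 250), "equal length")
  expect_error(mswc(numeric(176), x, 250), "degenerate")
  expect_error(mswc(x, c(x[-1], Inf), 250), "finite")
})

test_that("coherence is degenerate (identically 1) without smoothing", {
  set.seed(4)
  x <- rnorm(176); y <- rnorm(176)
  raw <- mswcMatrix(mswc(x, y, 250, smooth = FALSE))
  expect_gte(min(raw), 1 - 1e-3)     # up to the denominator guard only
  smoothed <- mswcMatrix(mswc(x, y, 250))
  expect_lt(min(smoothed), 0.5)      # smoothing restores discrimination
})

test_that("mswc stays in [0, 1] over many random pairs", {
  set.seed(5)
  for (i in 1:40) {
    n <- sample(c(96, 176, 256), 1)
    v <- mswcMatrix(mswc(rnorm(n), rnorm(n), 250))
    expect_gte(min(v), 0)
    expect_lte(max(v), 1 + 1e-9)
  }
})

test_that("same-shift of both inputs leaves interior coherence unchanged", {
  # restricted to scales whose daughter wavelets lie fully inside the
  # analytic band (35-70 Hz): near DC and Nyquist the one-sided spectral
  # truncation gives the filters slowly decaying tails, and near the grid
  # ends the time-smoothing kernels reach the (differing) record edges
  set.seed(5)
  n <- 176; k <- 12
  x <- rnorm(n + k); y <- 0.7 * x + 0.5 * rnorm(n + k)
  mA <- mswcMatrix(mswc(x[1:n], y[1:n], 250))
  mB <- mswcMatrix(mswc(x[(1 + k):(n + k)], y[(1 + k):(n + k)], 250))
  fr <- gridFrequencies(waveletGrid(250))
  rows <- which(fr >= 35 & fr <= 70)
  cols <- 61:115
  expect_lt(max(abs(mA[rows, cols + k] - mB[rows, cols])), 1e-6)
})

test_that("independent noise pairs stay far below the qualifying level", {
  set.seed(6)
  grand <- replicate(30, mean(mswcMatrix(mswc(rnorm(501), rnorm(501), 250))))
  expect_lt(mean(grand), 0.6)               # well under the 0.9 threshold
  # under independence the scan yields the 0 sentinel or, by chance, a
  # qualification confined to the bottom grid rows: below ~3 Hz a 0.7 s
  # record holds under two cycles, the smoother has about one degree of
  # freedom there, and the estimate can exceed any threshold. The null
  # never reaches the physiological 4-8 Hz impulse band.
  sent <- replicate(20, coherentFrequency(mswc(rnorm(176), rnorm(176), 250)))
  expect_true(any(sent == 0))
  expect_lt(max(sent), 4)
})

test_that("coherent-frequency scan follows the contiguity rule", {
  g <- waveletGrid(250)
  fr <- gridFrequencies(g)
  # perfect coherence -> top of the scan range
  m <- constantMap(1, g)
  expect_equal(coherentFrequency(m), max(fr))
  # lowest frequency failing -> 0 sentinel
  m2 <- constantMap(0.95, g)
  m2@mswc[nrow(m2@mswc), ] <- 0.1
  expect_equal(coherentFrequency(m2), 0)
  # band 1.4..6 Hz qualifying, a higher detached band must not count
  m3 <- constantMap(0.2, g)
  m3@mswc[fr <= 6, ] <- 0.95
  m3@mswc[fr >= 40 & fr <= 60, ] <- 0.99
  fTop <- coherentFrequency(m3)
  expect_lt(abs(log2(fTop / max(fr[fr <= 6]))), 1e-9)
  expect_equal(coherentFrequency(m3, rule = "global"),
               max(fr[fr >= 40 & fr <= 60]))
  expect_error(coherentFrequency(m3, timeWindow = c(2, 3)), "empty")
  expect_error(coherentFrequency(m3, threshold = 0), "threshold")
})

test_that("coherent frequency degrades monotonically with noise", {
  h <- simulateHeadImpulse()
  sds <- c(0, 5, 15, 40)
  recs <- sapply(seq_len(20), function(s) {
    e0 <- 0.9 * h
    sapply(seq_along(sds), function(j) {
      set.seed(1000 + 20 * j + s)
      e <- e0 + if (sds[j] > 0) rnorm(length(h), sd = sds[j]) else 0
      coherentFrequency(mswc(h, e, 250))
    })
  })
  m <- rowMeans(recs)
  worst <- max(diff(m))                     # increases would be positive
  expect_lt(worst, m[1] * (2^(1 / 24) - 1)) # at most half a voice inversion
  expect_lt(m[4], m[1])
})

test_that("frequency-averaged mswc ranks pairs like classical coherence", {
  set.seed(7)
  tt <- seq(0, 4, by = 1 / 250)
  sigmas <- exp(seq(log(0.2), log(5), length.out = 10))
  waveletMean <- numeric(10); classicalMean <- numeric(10)
  for (i in seq_along(sigmas)) {
    x <- rnorm(length(tt))
    y <- x + sigmas[i] * rnorm(length(tt))
    waveletMean[i] <- mean(mswcMatrix(mswc(x, y, 250)))
    sp <- stats::spec.pgram(cbind(x, y), spans = c(11, 11), plot = FALSE)
    classicalMean[i] <- mean(sp$coh)
  }
  expect_gt(cor(waveletMean, classicalMean, method = "spearman"), 0.9)
})

test_that("cone of influence narrows toward the record edges", {
  m <- mswc(rnorm(176), rnorm(176), 250)
  coi <- m@coi
  expect_true(is.infinite(coi[1]) && is.infinite(coi[length(coi)]))
  mid <- ceiling(length(coi) / 2)
  expect_true(all(diff(coi[2:mid]) <= 1e-9))   # boundary drops inward
})
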