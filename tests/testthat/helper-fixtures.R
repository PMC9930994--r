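# shared fixtures and independent oracles; heavier objects are built once
# per test run and memoised here

.fx <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fx[[key]])) .fx[[key]] <- builder()
  .fx[[key]]
}

# a CoherenceMap with the given constant coherence value everywhere
constantMap <- function(value, grid = waveletGrid(250), nTimes = 176,
                        samplingRate = 250) {
  M <- matrix(value, length(gridFrequencies(grid)), nTimes)
  times <- (seq_len(nTimes) - 1) / samplingRate
  new("CoherenceMap", mswc = M, crossPower = M, grid = grid, times = times,
      coi = rep(Inf, nTimes), coherentFrequency = 0)
}

# independent O(n^2) smoothing oracle: per-scale Gaussian in time with
# reflected edges, then a truncated boxcar spanning 0.6 octave of scales
naiveSmoothOracle <- function(M, scales, voices, samplingRate) {
  n <- ncol(M); dt <- 1 / samplingRate; L <- n - 1
  out <- M
  for (j in seq_along(scales)) {
    k <- exp(-(((-L):L) * dt)^2 / (2 * scales[j]^2)); k <- k / sum(k)
    xp <- c(M[j, (L + 1):2], M[j, ], M[j, (n - 1):(n - L)])
    for (i in seq_len(n)) out[j, i] <- sum(xp[i:(i + 2 * L)] * k)
  }
  win <- max(1, round(0.6 * voices)); if (win %% 2 == 0) win <- win + 1
  half <- (win - 1) / 2; ns <- nrow(M); out2 <- out
  for (i in seq_len(ns))
    out2[i, ] <- colMeans(out[max(1, i - half):min(ns, i + half), ,
                              drop = FALSE])
  out2
}

# small WaveletGrid built from the leading scales of the default grid
smallGrid <- function(nScales = 16, samplingRate = 250) {
  g <- waveletGrid(samplingRate)
  sc <- gridScales(g)[seq_len(nScales)]
  new("WaveletGrid", scales = sc,
      frequencies = gridFrequencies(g)[seq_len(nScales)],
      voicesPerOctave = 12L, omega0 = 6)
}

# noise-free trace with a known gain (full-band coupling)
pureGainTrace <- function(gain, scc = "posterior", samplingRate = 250) {
  h <- simulateHeadImpulse(samplingRate = samplingRate)
  impulseTrace(h, gain * h, samplingRate, scc = scc,
               trueParams = list(gain = gain))
}

# trace with injected Gaussian saccade pulses on top of a pure-gain eye
injectSaccades <- function(gain, saccades, samplingRate = 250,
                           scc = "posterior") {
  h <- simulateHeadImpulse(samplingRate = samplingRate)
  e <- simulateEyeResponse(h, samplingRate, gain, samplingRate / 2,
                           saccades = saccades, noiseSd = 0)
  impulseTrace(h, e, samplingRate, scc = scc,
               trueParams = list(gain = gain, saccades = saccades))
}

saccadeEvent <- function(onset, duration, peak, kind) {
  data.frame(onset = onset, duration = duration, peak_velocity = peak,
             kind = kind, stringsAsFactors = FALSE)
}

# minimal classification samples with explicit feature vectors
featureSample <- function(id, features, label) {
  list(id = id, label = label, features = features)
}

# ---- heavier shared fixtures (built once per run) -------------------------

# the default 64-patient study cohort
studyCohort <- function() memo("cohort64", function()
  simulateCohort(cohortConfig(seed = 20260901)))

# full coherence analysis of the study cohort (representative maps kept)
studyAnalysis <- function() memo("analysis64", function()
  analyzeCohort(studyCohort()))

studyFeatureTable <- function() memo("featTab64", function()
  buildFeatureTable(studyCohort(), studyAnalysis()))

# representative samples with horizontal-style backbone features attached
studySamples <- function() memo("samples64", function() {
  cohort <- studyCohort(); an <- studyAnalysis()
  bb <- fixtureBackbone()
  samples <- representativeSamples(cohort, an)
  for (i in seq_along(samples)) {
    maps <- lapply(an[[i]]$scc, function(s) s$repMap)
    img <- cropAndTile(maps, "horizontal", patientId = samples[[i]]$id)
    samples[[i]]$features <- extractFeatures(img, bb)
  }
  samples
})

studyLabels <- function()
  vapply(studySamples(), `[[`, character(1), "label")

# featurize any sample (e.g. an ITS blend) through the full image pipeline
pipelineFeaturize <- function(sample) {
  bb <- memo("fixtureBackbone", fixtureBackbone)
  g <- memo("grid250", function() waveletGrid(250))
  extractFeatures(sampleTiledImage(sample, "horizontal", grid = g), bb)
}
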