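#' @include vhitwca-package.R
NULL

SCC_LEVELS <- c("horizontal", "anterior", "posterior")
OUTCOME_LEVELS <- c("CR", "PR", "NR")

#' WaveletGrid: scale/frequency grid for the analytic Morlet transform
#'
#' Geometric grid of wavelet scales together with the equivalent Fourier
#' frequencies. Frequencies derive from scales through the Morlet Fourier
#' factor \eqn{\lambda = 4\pi/(\omega_0 + \sqrt{2 + \omega_0^2})}, i.e.
#' \eqn{f = 1/(\lambda s)}.
#'
#' @slot scales numeric, strictly increasing wavelet scales (seconds).
#' @slot frequencies numeric, strictly decreasing equivalent frequencies (Hz).
#' @slot voicesPerOctave integer, scales per frequency octave.
#' @slot omega0 numeric, Morlet center frequency (dimensionless).
#' @exportClass WaveletGrid
setClass("WaveletGrid",
  representation(scales = "numeric", frequencies = "numeric",
                 voicesPerOctave = "integer", omega0 = "numeric"))

setValidity("WaveletGrid", function(object) {
  msg <- character()
  if (length(object@scales) < 2L) msg <- c(msg, "grid needs at least 2 scales")
  if (any(diff(object@scales) <= 0)) msg <- c(msg, "scales must be strictly increasing")
  if (any(diff(object@frequencies) >= 0)) msg <- c(msg, "frequencies must be strictly decreasing")
  if (length(object@scales) != length(object@frequencies))
    msg <- c(msg, "scales and frequencies must have equal length")
  if (length(msg)) msg else TRUE
})

#' ImpulseTrace: one vHIT repeat
#'
#' Paired head and eye angular-velocity series for a single head impulse,
#' sampled uniformly over a 0.7 s window with head-rotation onset fixed at
#' 0.1 s. Both channels are stored sign-rectified (the VOR response is
#' positive), as vHIT devices display them.
#'
#' @slot time numeric, sample times in seconds starting at 0.
#' @slot headVelocity numeric, head angular velocity (deg/s).
#' @slot eyeVelocity numeric, eye angular velocity (deg/s).
#' @slot samplingRate numeric, Hz.
#' @slot onsetTime numeric, head-rotation onset (s), fixed at 0.1.
#' @slot scc character, one of "horizontal", "anterior", "posterior".
#' @slot trueParams list, optional generator ground truth (gain, coupling
#'   cutoff, saccades, noise sd).
#' @exportClass ImpulseTrace
setClass("ImpulseTrace",
  representation(time = "numeric", headVelocity = "numeric",
                 eyeVelocity = "numeric", samplingRate = "numeric",
                 onsetTime = "numeric", scc = "character",
                 trueParams = "list"))

setValidity("ImpulseTrace", function(object) {
  msg <- character()
  n <- length(object@time)
  if (length(object@headVelocity) != n || length(object@eyeVelocity) != n)
    msg <- c(msg, "time, headVelocity and eyeVelocity must have equal length")
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be positive")
  dur <- (n - 1) / object@samplingRate
  if (abs(dur - 0.7) > 1 / object@samplingRate + 1e-9)
    msg <- c(msg, "record duration must be 0.7 s within one sample")
  if (abs(object@onsetTime - 0.1) > 1e-9)
    msg <- c(msg, "onsetTime must be 0.1 s")
  if (!object@scc %in% SCC_LEVELS)
    msg <- c(msg, "scc must be one of horizontal/anterior/posterior")
  if (length(msg)) msg else TRUE
})

#' CoherenceMap: magnitude-squared wavelet coherence over time and frequency
#'
#' @slot mswc numeric matrix (n_freq x n_time) of squared coherence in [0,1];
#'   rows follow the grid ordering (decreasing frequency).
#' @slot crossPower numeric matrix, magnitude of the smoothed, scale-weighted
#'   cross-wavelet spectrum.
#' @slot grid a \linkS4class{WaveletGrid}.
#' @slot times numeric, sample times (s).
#' @slot coi numeric, per-time cone-of-influence boundary frequency (Hz):
#'   estimates at frequencies below it are edge-affected.
#' @slot coherentFrequency numeric, derived coherent frequency in Hz
#'   (0 when the lowest grid frequency already fails the threshold).
#' @exportClass CoherenceMap
setClass("CoherenceMap",
  representation(mswc = "matrix", crossPower = "matrix", grid = "WaveletGrid",
                 times = "numeric", coi = "numeric",
                 coherentFrequency = "numeric"))

setValidity("CoherenceMap", function(object) {
  msg <- character()
  nf <- length(object@grid@frequencies); nt <- length(object@times)
  if (!all(dim(object@mswc) == c(nf, nt)))
    msg <- c(msg, "mswc must be n_freq x n_time")
  if (!all(dim(object@crossPower) == c(nf, nt)))
    msg <- c(msg, "crossPower must be n_freq x n_time")
  rng <- range(object@mswc)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    msg <- c(msg, "mswc entries must lie in [0, 1]")
  if (length(object@coi) != nt) msg <- c(msg, "coi must match times")
  if (length(msg)) msg else TRUE
})

#' CohortConfig: parameters of the synthetic vHIT cohort generator
#'
#' @slot nPatients named integer, patients per outcome class (CR, PR, NR).
#' @slot classParams nested list: class -> SCC -> distribution parameters
#'   (gain mean/sd, coupling-cutoff mean/sd in Hz, overt/total saccade
#'   probabilities, saccade peak-velocity range, noise sd). See
#'   \code{\link{defaultClassParams}}.
#' @slot repeats integer, impulses recorded per SCC (>= 1).
#' @slot samplingRate numeric, Hz.
#' @slot seed numeric, master seed; every random draw descends from it.
#' @exportClass CohortConfig
setClass("CohortConfig",
  representation(nPatients = "integer", classParams = "list",
                 repeats = "integer", samplingRate = "numeric",
                 seed = "numeric"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (!all(OUTCOME_LEVELS %in% names(object@nPatients)))
    msg <- c(msg, "nPatients must be named CR, PR, NR")
  if (any(object@nPatients < 1L)) msg <- c(msg, "every class needs >= 1 patient")
  if (object@repeats < 1L) msg <- c(msg, "repeats must be >= 1")
  if (object@samplingRate < 100) msg <- c(msg, "samplingRate must be >= 100 Hz")
  for (cls in intersect(OUTCOME_LEVELS, names(object@classParams)))
    for (scc in names(object@classParams[[cls]])) {
      p <- object@classParams[[cls]][[scc]]
      if (is.null(p$noiseSd)) p$noiseSd <- 8
      if (p$gainSd < 0 || p$cutoffSd < 0 || p$noiseSd < 0)
        msg <- c(msg, "all sds must be >= 0")
      if (p$overtProb < 0 || p$overtProb > 1 || p$totalProb < 0 || p$totalProb > 1 ||
          p$totalProb < p$overtProb)
        msg <- c(msg, "saccade probabilities must satisfy 0 <= overt <= total <= 1")
    }
  if (length(msg)) unique(msg) else TRUE
})

#' PatientRecord: per-patient exam sets for the three semicircular canals
#'
#' @slot patientId character.
#' @slot outcome character, "CR", "PR" or "NR".
#' @slot exams named list (horizontal/anterior/posterior), each a list of
#'   \linkS4class{ImpulseTrace} repeats.
#' @slot derived list, optional per-patient derived results.
#' @exportClass PatientRecord
setClass("PatientRecord",
  representation(patientId = "character", outcome = "character",
                 exams = "list", derived = "list"))

setValidity("PatientRecord", function(object) {
  msg <- character()
  if (!object@outcome %in% OUTCOME_LEVELS)
    msg <- c(msg, "outcome must be CR, PR or NR")
  if (!identical(sort(names(object@exams)), sort(SCC_LEVELS)))
    msg <- c(msg, "exams must have exactly the three SCC keys")
  else if (any(vapply(object@exams, length, 1L) == 0L))
    msg <- c(msg, "every SCC repeat set must be nonempty")
  if (length(msg)) msg else TRUE
})

#' AugmentedSet: class-balanced sample set with provenance
#'
#' @slot samples list of samples; each sample is a list with elements
#'   \code{id}, \code{label} and \code{traces} (named list of
#'   \linkS4class{ImpulseTrace} per SCC).
#' @slot provenance data.frame with one row per sample: \code{sample_id},
#'   \code{type} (original / OS-copy / EDE-extract / ITS-blend),
#'   \code{parents}, \code{weight}.
#' @exportClass AugmentedSet
setClass("AugmentedSet",
  representation(samples = "list", provenance = "data.frame"))

setValidity("AugmentedSet", function(object) {
  if (length(object@samples) != nrow(object@provenance))
    "provenance must have one row per sample" else TRUE
})

#' CropStyle: one of the three named coherence-plot cropping presets
#'
#' Presets: horizontal (0.1-0.35 s x 4-8 Hz, tiles left-to-right), vertical
#' (0.1-0.2 s x 0-12 Hz, tiles top-to-bottom), subtotal (0.1-0.3 s x
#' 0-125 Hz, tiles left-to-right).
#'
#' @slot name character preset name.
#' @slot timeWindow numeric length-2, seconds.
#' @slot freqWindow numeric length-2, Hz.
#' @slot tiling character, "left-to-right" or "top-to-bottom".
#' @exportClass CropStyle
setClass("CropStyle",
  representation(name = "character", timeWindow = "numeric",
                 freqWindow = "numeric", tiling = "character"))

setValidity("CropStyle", function(object) {
  msg <- character()
  if (!object@name %in% c("horizontal", "vertical", "subtotal"))
    msg <- c(msg, "name must be horizontal, vertical or subtotal")
  if (!object@tiling %in% c("left-to-right", "top-to-bottom"))
    msg <- c(msg, "tiling must be left-to-right or top-to-bottom")
  if (diff(object@timeWindow) <= 0) msg <- c(msg, "timeWindow must be increasing")
  if (diff(object@freqWindow) <= 0) msg <- c(msg, "freqWindow must be increasing")
  if (length(msg)) msg else TRUE
})

#' TiledImage: per-patient tiled coherence raster
#'
#' Three single-SCC crops tiled in the fixed order horizontal, anterior,
#' posterior, then resized to the backbone input size.
#'
#' @slot pixels numeric array H x W x 3, RGB in [0, 1].
#' @slot style a \linkS4class{CropStyle}.
#' @slot patientId character.
#' @slot sccOrder character, always horizontal/anterior/posterior.
#' @exportClass TiledImage
setClass("TiledImage",
  representation(pixels = "array", style = "CropStyle",
                 patientId = "character", sccOrder = "character"))

setValidity("TiledImage", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L) msg <- c(msg, "pixels must be H x W x 3")
  if (!identical(object@sccOrder, SCC_LEVELS))
    msg <- c(msg, "sccOrder is fixed at horizontal, anterior, posterior")
  if (length(msg)) msg else TRUE
})

#' BackboneSpec: a feature-extraction backbone
#'
#' The default "fixture" backbone is a small convolutional stack with
#' seed-fixed random weights used as a deterministic random-projection
#' feature extractor; it requires no downloads.
#'
#' @slot name character.
#' @slot inputSize integer, square input edge in pixels.
#' @slot featureDim integer, output feature dimension.
#' @slot source character, "fixture" or "pretrained".
#' @slot weights list of layer weights.
#' @exportClass BackboneSpec
setClass("BackboneSpec",
  representation(name = "character", inputSize = "integer",
                 featureDim = "integer", source = "character",
                 weights = "list"))

#' CVConfig: repeated stratified k-fold cross-validation settings
#'
#' @slot k integer, folds (default 5).
#' @slot repeats integer, repetitions (default 10).
#' @slot stratified logical, always TRUE.
#' @slot seed numeric.
#' @slot placement character, "within-folds" (augment training folds only)
#'   or "paper-mode" (augment the whole set before splitting).
#' @exportClass CVConfig
setClass("CVConfig",
  representation(k = "integer", repeats = "integer", stratified = "logical",
                 seed = "numeric", placement = "character"))

setValidity("CVConfig", function(object) {
  msg <- character()
  if (object@k < 2L) msg <- c(msg, "k must be >= 2")
  if (object@repeats < 1L) msg <- c(msg, "repeats must be >= 1")
  if (!isTRUE(object@stratified)) msg <- c(msg, "stratified must be TRUE")
  if (!object@placement %in% c("within-folds", "paper-mode"))
    msg <- c(msg, "placement must be within-folds or paper-mode")
  if (length(msg)) msg else TRUE
})

#' CVResult: per-fold accuracies with aggregate mean and standard deviation
#'
#' @slot foldAccuracy numeric matrix (repeats x k) of fold accuracies in
#'   percent.
#' @slot meanAccuracy numeric, mean over all folds (percent).
#' @slot sdAccuracy numeric, sd over all folds (percent).
#' @slot confusion table, pooled confusion counts (truth x prediction).
#' @slot config the \linkS4class{CVConfig} used.
#' @exportClass CVResult
setClass("CVResult",
  representation(foldAccuracy = "matrix", meanAccuracy = "numeric",
                 sdAccuracy = "numeric", confusion = "table",
                 config = "CVConfig"))

setValidity("CVResult", function(object) {
  msg <- character()
  fa <- object@foldAccuracy
  if (any(fa < 0 | fa > 100)) msg <- c(msg, "fold accuracies must be in [0, 100]")
  if (abs(mean(fa) - object@meanAccuracy) > 1e-9)
    msg <- c(msg, "meanAccuracy inconsistent with fold accuracies")
  if (abs(sd(as.numeric(fa)) - object@sdAccuracy) > 1e-9)
    msg <- c(msg, "sdAccuracy inconsistent with fold accuracies")
  if (length(msg)) msg else TRUE
})
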