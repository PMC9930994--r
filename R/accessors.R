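#' @include AllGenerics.R
NULL

#' @rdname ImpulseTrace-class
setMethod("headVelocity", "ImpulseTrace", function(x) x@headVelocity)
#' @rdname ImpulseTrace-class
setMethod("eyeVelocity", "ImpulseTrace", function(x) x@eyeVelocity)
#' @rdname ImpulseTrace-class
setMethod("sampleTimes", "ImpulseTrace", function(x) x@time)
#' @rdname ImpulseTrace-class
setMethod("samplingRate", "ImpulseTrace", function(x) x@samplingRate)
#' @rdname ImpulseTrace-class
setMethod("sccLabel", "ImpulseTrace", function(x) x@scc)
#' @rdname ImpulseTrace-class
setMethod("trueParams", "ImpulseTrace", function(x) x@trueParams)

#' @rdname CoherenceMap-class
setMethod("mswcMatrix", "CoherenceMap", function(x) x@mswc)
#' @rdname CoherenceMap-class
setMethod("gridFrequencies", "CoherenceMap", function(x) x@grid@frequencies)
#' @rdname CoherenceMap-class
setMethod("gridScales", "CoherenceMap", function(x) x@grid@scales)
#' @rdname WaveletGrid-class
#' @param x a WaveletGrid.
setMethod("gridFrequencies", "WaveletGrid", function(x) x@frequencies)
#' @rdname WaveletGrid-class
setMethod("gridScales", "WaveletGrid", function(x) x@scales)

#' @rdname PatientRecord-class
setMethod("patientId", "PatientRecord", function(x) x@patientId)
#' @rdname PatientRecord-class
setMethod("outcomeLabel", "PatientRecord", function(x) x@outcome)
#' @rdname PatientRecord-class
setMethod("patientExams", "PatientRecord", function(x) x@exams)

#' @rdname AugmentedSet-class
setMethod("augmentedSamples", "AugmentedSet", function(x) x@samples)
#' @rdname AugmentedSet-class
setMethod("provenance", "AugmentedSet", function(x) x@provenance)

#' @rdname TiledImage-class
setMethod("imagePixels", "TiledImage", function(x) x@pixels)

#' @rdname CVResult-class
setMethod("foldAccuracies", "CVResult", function(x) x@foldAccuracy)
#' @rdname CVResult-class
setMethod("meanAccuracy", "CVResult", function(x) x@meanAccuracy)
#' @rdname CVResult-class
setMethod("sdAccuracy", "CVResult", function(x) x@sdAccuracy)

setMethod("show", "ImpulseTrace", function(object) {
  cat(sprintf("ImpulseTrace (%s SCC): %d samples @ %g Hz, onset %g s\n",
              object@scc, length(object@time), object@samplingRate,
              object@onsetTime))
  cat(sprintf("  peak head %.1f deg/s, peak eye %.1f deg/s\n",
              max(object@headVelocity), max(object@eyeVelocity)))
  if (length(object@trueParams))
    cat(sprintf("  ground truth: gain %.3f, coupling cutoff %.2f Hz\n",
                object@trueParams$gain %||% NA_real_,
                object@trueParams$couplingCutoff %||% NA_real_))
})

setMethod("show", "WaveletGrid", function(object) {
  cat(sprintf("WaveletGrid: %d scales, %d voices/octave, omega0 = %g\n",
              length(object@scales), object@voicesPerOctave, object@omega0))
  cat(sprintf("  frequencies %.2f .. %.2f Hz\n",
              min(object@frequencies), max(object@frequencies)))
})

setMethod("show", "CoherenceMap", function(object) {
  cat(sprintf("CoherenceMap: %d frequencies x %d times\n",
              nrow(object@mswc), ncol(object@mswc)))
  cat(sprintf("  coherent frequency: %.2f Hz (threshold 0.9)\n",
              object@coherentFrequency))
})

setMethod("show", "PatientRecord", function(object) {
  cat(sprintf("PatientRecord %s (%s): %s repeats per SCC\n",
              object@patientId, object@outcome,
              paste(vapply(object@exams[SCC_LEVELS], length, 1L),
                    collapse = "/")))
})

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf("CohortConfig: %s patients, %d repeats/SCC @ %g Hz, seed %g\n",
              paste(sprintf("%d %s", object@nPatients[OUTCOME_LEVELS],
                            OUTCOME_LEVELS), collapse = " + "),
              object@repeats, object@samplingRate, object@seed))
})

setMethod("show", "CropStyle", function(object) {
  cat(sprintf("CropStyle '%s': %g-%g s x %g-%g Hz, tiling %s\n",
              object@name, object@timeWindow[1], object@timeWindow[2],
              object@freqWindow[1], object@freqWindow[2], object@tiling))
})

setMethod("show", "TiledImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("TiledImage patient %s, style '%s': %d x %d x %d\n",
              object@patientId, object@style@name, d[1], d[2], d[3]))
})

setMethod("show", "BackboneSpec", function(object) {
  cat(sprintf("BackboneSpec '%s' (%s): input %d px, %d features\n",
              object@name, object@source, object@inputSize,
              object@featureDim))
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: %d x %d-fold CV, accuracy %.1f%% [%.1f]\n",
              nrow(object@foldAccuracy), ncol(object@foldAccuracy),
              object@meanAccuracy, object@sdAccuracy))
})

setMethod("show", "AugmentedSet", function(object) {
  cat(sprintf("AugmentedSet: %d samples (%s)\n", length(object@samples),
              paste(sprintf("%d %s", table(object@provenance$type),
                            names(table(object@provenance$type))),
                    collapse = ", ")))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
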