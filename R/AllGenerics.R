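#' @include AllClasses.R
NULL

#' @rdname ImpulseTrace-class
#' @param object,x an object.
#' @export
setGeneric("headVelocity", function(x) standardGeneric("headVelocity"))
#' @rdname ImpulseTrace-class
#' @export
setGeneric("eyeVelocity", function(x) standardGeneric("eyeVelocity"))
#' @rdname ImpulseTrace-class
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))
#' @rdname ImpulseTrace-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname ImpulseTrace-class
#' @export
setGeneric("sccLabel", function(x) standardGeneric("sccLabel"))
#' @rdname ImpulseTrace-class
#' @export
setGeneric("trueParams", function(x) standardGeneric("trueParams"))

#' @rdname CoherenceMap-class
#' @export
setGeneric("mswcMatrix", function(x) standardGeneric("mswcMatrix"))
#' @rdname CoherenceMap-class
#' @export
setGeneric("gridFrequencies", function(x) standardGeneric("gridFrequencies"))
#' @rdname CoherenceMap-class
#' @export
setGeneric("gridScales", function(x) standardGeneric("gridScales"))

#' Coherent frequency of a coherence map
#'
#' Scans the grid frequencies upward from the lowest resolvable one; a
#' frequency qualifies when MSWC stays at or above \code{threshold} at every
#' time sample inside \code{timeWindow}. The statistic is the top of the
#' contiguous qualifying band that starts at the lowest frequency, or 0 when
#' the lowest frequency already fails.
#'
#' @param map a \linkS4class{CoherenceMap}.
#' @param threshold coherence threshold in (0, 1]; default 0.9.
#' @param timeWindow numeric length-2 window in seconds; default the whole
#'   exam.
#' @param rule "contiguous" (default: band must start at the lowest
#'   frequency) or "global" (highest qualifying frequency anywhere).
#' @param maskCoi if TRUE, time-frequency cells outside the cone of
#'   influence are ignored in the min-over-time; default FALSE (the scan
#'   covers the entire exam).
#' @return frequency in Hz (0 sentinel when no frequency qualifies).
#' @export
setGeneric("coherentFrequency",
  function(map, threshold = 0.9, timeWindow = NULL,
           rule = c("contiguous", "global"), maskCoi = FALSE)
    standardGeneric("coherentFrequency"))

#' @rdname PatientRecord-class
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname PatientRecord-class
#' @export
setGeneric("outcomeLabel", function(x) standardGeneric("outcomeLabel"))
#' @rdname PatientRecord-class
#' @export
setGeneric("patientExams", function(x) standardGeneric("patientExams"))

#' @rdname AugmentedSet-class
#' @export
setGeneric("augmentedSamples", function(x) standardGeneric("augmentedSamples"))
#' @rdname AugmentedSet-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname TiledImage-class
#' @export
setGeneric("imagePixels", function(x) standardGeneric("imagePixels"))

#' @rdname CVResult-class
#' @export
setGeneric("foldAccuracies", function(x) standardGeneric("foldAccuracies"))
#' @rdname CVResult-class
#' @export
setGeneric("meanAccuracy", function(x) standardGeneric("meanAccuracy"))
#' @rdname CVResult-class
#' @export
setGeneric("sdAccuracy", function(x) standardGeneric("sdAccuracy"))
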