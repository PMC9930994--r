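#' @include classify.R
NULL

#' Write / read an impulse trace as CSV
#'
#' One file per repeat with header
#' \code{time_s,head_velocity_dps,eye_velocity_dps}. Values are written
#' with \code{\%.10g} formatting, so identical traces serialize to
#' identical bytes.
#'
#' @param trace an \linkS4class{ImpulseTrace}.
#' @param path file path.
#' @return the path (write) or an \linkS4class{ImpulseTrace} (read),
#'   invisibly for the writer.
#' @export
writeImpulseTrace <- function(trace, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("time_s,head_velocity_dps,eye_velocity_dps", con)
  writeLines(sprintf("%.10g,%.10g,%.10g", trace@time, trace@headVelocity,
                     trace@eyeVelocity), con)
  invisible(path)
}

#' @rdname writeImpulseTrace
#' @param scc,samplingRate,trueParams metadata for the reader (the CSV
#'   stores only the series; sampling rate defaults to the time step).
#' @export
readImpulseTrace <- function(path, scc = "posterior", samplingRate = NULL,
                             trueParams = list()) {
  d <- read.csv(path)
  fs <- samplingRate %||% (1 / (d$time_s[2] - d$time_s[1]))
  impulseTrace(d$head_velocity_dps, d$eye_velocity_dps, round(fs),
               scc = scc, trueParams = trueParams)
}

#' Write / read a patient metadata sidecar (JSON)
#'
#' @param record a \linkS4class{PatientRecord}.
#' @param path file path.
#' @param samplingRate Hz recorded in the sidecar.
#' @export
writePatientSidecar <- function(record, path, samplingRate) {
  meta <- list(patient_id = record@patientId, outcome = record@outcome,
               scc = SCC_LEVELS, sampling_rate = samplingRate,
               repeats = vapply(record@exams[SCC_LEVELS], length, 1L),
               true_params = lapply(record@exams[SCC_LEVELS], function(reps)
                 lapply(reps, function(tr)
                   tr@trueParams[c("gain", "couplingCutoff", "noiseSd")])))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writePatientSidecar
#' @export
readPatientSidecar <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Write the per-patient feature table as CSV
#'
#' @param table data.frame from \code{\link{buildFeatureTable}}.
#' @param path file path.
#' @export
writeFeatureTable <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize / restore a coherence map
#'
#' Writes a JSON header (grid, times, cone of influence, coherent
#' frequency) next to a CSV dump of the MSWC matrix.
#'
#' @param map a \linkS4class{CoherenceMap}.
#' @param basePath path prefix; writes \code{<basePath>.json} and
#'   \code{<basePath>.csv}.
#' @export
writeCoherenceMap <- function(map, basePath) {
  hdr <- list(scales = map@grid@scales, frequencies = map@grid@frequencies,
              voices_per_octave = map@grid@voicesPerOctave,
              omega0 = map@grid@omega0, times = map@times, coi = map@coi,
              coherent_frequency = map@coherentFrequency)
  jsonlite::write_json(hdr, paste0(basePath, ".json"), auto_unbox = TRUE,
                       digits = NA)
  write.csv(as.data.frame(map@mswc), paste0(basePath, ".csv"),
            row.names = FALSE)
  invisible(basePath)
}

#' @rdname writeCoherenceMap
#' @export
readCoherenceMap <- function(basePath) {
  hdr <- jsonlite::read_json(paste0(basePath, ".json"),
                             simplifyVector = TRUE)
  m <- as.matrix(read.csv(paste0(basePath, ".csv")))
  dimnames(m) <- NULL
  grid <- new("WaveletGrid", scales = hdr$scales,
              frequencies = hdr$frequencies,
              voicesPerOctave = as.integer(hdr$voices_per_octave),
              omega0 = hdr$omega0)
  coi <- hdr$coi
  coi[!is.finite(coi)] <- Inf
  new("CoherenceMap", mswc = m, crossPower = matrix(0, nrow(m), ncol(m)),
      grid = grid, times = hdr$times, coi = coi,
      coherentFrequency = hdr$coherent_frequency)
}
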