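#' @include simulate.R
NULL

#' VOR gain of an impulse trace
#'
#' Ratio of the eye to the head velocity response over the impulse window
#' (0.1 to 0.2 s in the exam timeline). The default "area" method uses the
#' ratio of summed velocities over the window -- the convention of clinical
#' vHIT devices and robust to single-sample peaks -- with samples belonging
#' to detected covert saccades excised from both channels first. A
#' "peak" method (ratio of channel maxima inside the window) is also
#' available.
#'
#' @param trace an \linkS4class{ImpulseTrace}.
#' @param method "area" (default) or "peak".
#' @param exciseSaccades excise detected saccade samples before the area
#'   ratio; default TRUE.
#' @param window impulse window in seconds; default c(0.1, 0.2), fixed by
#'   the exam timeline rather than estimated per trace.
#' @return VOR gain (positive ratio).
#' @export
vorGain <- function(trace, method = c("area", "peak"),
                    exciseSaccades = TRUE, window = c(0.1, 0.2)) {
  method <- match.arg(method)
  t <- trace@time
  w <- which(t >= window[1] & t <= window[2])
  h <- trace@headVelocity[w]; e <- trace@eyeVelocity[w]
  if (max(abs(h)) <= 0) stop("flat head trace: peak velocity is zero",
                             call. = FALSE)
  if (method == "peak") return(max(e) / max(h))
  keep <- rep(TRUE, length(w))
  if (exciseSaccades) {
    raw <- sum(e) / sum(h)
    sac <- detectSaccades(trace, gainEstimate = raw)
    if (nrow(sac) > 0)
      for (i in seq_len(nrow(sac))) {
        lo <- sac$onset[i] - sac$duration[i] / 2
        hi <- sac$onset[i] + 1.5 * sac$duration[i]
        keep <- keep & !(t[w] >= lo & t[w] <= hi)
      }
    if (!any(keep)) keep <- rep(TRUE, length(w))
  }
  sum(e[keep]) / sum(h[keep])
}

#' Detect corrective saccades in the residual eye velocity
#'
#' Events are maximal runs where the residual eye velocity (eye minus
#' gain-scaled head) exceeds \code{threshold} for at least
#' \code{minDuration}. The residual is signed: in the sign-rectified vHIT
#' convention corrective saccades are positive velocity pulses, and a
#' signed test avoids false detections on the negative residual dip that a
#' band-limited VOR response leaves at mid-impulse. An event is covert when
#' its onset falls at or before 0.2 s (during the impulse), overt
#' afterwards.
#'
#' @param trace an \linkS4class{ImpulseTrace}.
#' @param gainEstimate VOR gain used to form the residual; default the raw
#'   area ratio over the impulse window.
#' @param threshold residual velocity threshold (deg/s); default 60.
#' @param minDuration minimum event duration (s); default 0.010.
#' @return data.frame with columns \code{onset}, \code{duration},
#'   \code{peak_velocity}, \code{kind} (covert/overt), one row per event.
#' @export
detectSaccades <- function(trace, gainEstimate = NULL, threshold = 60,
                           minDuration = 0.010) {
  t <- trace@time
  if (is.null(gainEstimate)) {
    w <- t >= 0.1 & t <= 0.2
    sh <- sum(trace@headVelocity[w])
    gainEstimate <- if (sh > 0) sum(trace@eyeVelocity[w]) / sh else 0
  }
  resid <- trace@eyeVelocity - gainEstimate * trace@headVelocity
  empty <- data.frame(onset = numeric(0), duration = numeric(0),
                      peak_velocity = numeric(0), kind = character(0),
                      stringsAsFactors = FALSE)
  above <- resid > threshold
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  starts <- starts[r$values]; ends <- ends[r$values]
  # refine event boundaries outward to where the residual falls below a
  # third of the main threshold (standard onset refinement: the peak
  # criterion finds the event, the lower criterion its true extent)
  lowThr <- threshold / 3
  n <- length(resid)
  for (i in seq_along(starts)) {
    while (starts[i] > 1L && resid[starts[i] - 1L] > lowThr)
      starts[i] <- starts[i] - 1L
    while (ends[i] < n && resid[ends[i] + 1L] > lowThr)
      ends[i] <- ends[i] + 1L
  }
  # merge runs that overlap after refinement
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  keepRun <- rep(TRUE, length(starts))
  last <- 1L
  for (i in seq_along(starts)[-1]) {
    if (starts[i] <= ends[last]) {
      ends[last] <- max(ends[last], ends[i]); keepRun[i] <- FALSE
    } else last <- i
  }
  starts <- starts[keepRun]; ends <- ends[keepRun]
  keep <- (ends - starts + 1L) >= ceiling(minDuration * trace@samplingRate)
  starts <- starts[keep]; ends <- ends[keep]
  if (!length(starts)) return(empty)
  onset <- t[starts]
  data.frame(onset = onset, duration = t[ends] - t[starts] + 1 / trace@samplingRate,
             peak_velocity = vapply(seq_along(starts), function(i)
               max(resid[starts[i]:ends[i]]), numeric(1)),
             kind = ifelse(onset <= 0.2, "covert", "overt"),
             stringsAsFactors = FALSE)
}

#' Saccade percentages over a repeat set
#'
#' Overt percentage is the share of repeats containing at least one overt
#' event; total percentage the share containing any event.
#'
#' @param exams nonempty list of \linkS4class{ImpulseTrace}.
#' @param ... passed to \code{\link{detectSaccades}}.
#' @return named numeric: \code{overt} and \code{total}, both in [0, 100].
#' @export
saccadePercentages <- function(exams, ...) {
  stopIfNot(length(exams) > 0, "empty repeat list")
  det <- lapply(exams, detectSaccades, ...)
  anyOvert <- vapply(det, function(d) any(d$kind == "overt"), logical(1))
  anySac <- vapply(det, function(d) nrow(d) > 0, logical(1))
  c(overt = 100 * mean(anyOvert), total = 100 * mean(anySac))
}

# lower-median index: for even counts the lower of the two central values;
# among ties the earliest repeat
lowerMedianIndex <- function(values) {
  ord <- order(values)
  med <- values[ord[floor((length(values) + 1) / 2)]]
  which(values == med)[1]
}

#' Select the representative repeat by median coherent frequency
#'
#' Returns the repeat whose coherent frequency is the median of the repeat
#' set; even counts take the lower median, ties the earliest repeat.
#'
#' @param repeats nonempty list of \linkS4class{ImpulseTrace}.
#' @param frequencies numeric coherent frequency per repeat (Hz).
#' @return the chosen trace, with attributes \code{index} and
#'   \code{frequency}.
#' @export
selectRepresentative <- function(repeats, frequencies) {
  stopIfNot(length(repeats) > 0, "empty repeat list")
  stopIfNot(length(repeats) == length(frequencies),
            "one frequency per repeat required")
  i <- lowerMedianIndex(frequencies)
  out <- repeats[[i]]
  attr(out, "index") <- i
  attr(out, "frequency") <- frequencies[i]
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties, as used for relating the
#' coherent frequency to gain and saccade percentages.
#'
#' @param x,y equal-length numeric vectors, length >= 3.
#' @return correlation in [-1, 1].
#' @export
spearmanRho <- function(x, y) {
  stopIfNot(length(x) == length(y) && length(x) >= 3,
            "x and y must have equal length >= 3")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("undefined correlation: constant input", call. = FALSE)
  cor(x, y, method = "spearman")
}

#' Run the coherence analysis over a cohort
#'
#' Computes the MSWC coherent frequency of every repeat of every SCC of
#' every patient and selects the representative repeat per SCC (median
#' coherent frequency). Representative coherence maps are retained for
#' imaging; per-repeat maps are discarded to bound memory.
#'
#' @param cohort list of \linkS4class{PatientRecord}.
#' @param threshold coherence threshold; default 0.9.
#' @param grid optional shared \linkS4class{WaveletGrid}.
#' @param keepMaps "representative" (default) or "none".
#' @return named list (by patient id); each element has \code{outcome} and,
#'   per SCC, \code{frequencies} (per repeat), \code{repIndex},
#'   \code{repFrequency} and \code{repMap}.
#' @export
analyzeCohort <- function(cohort, threshold = 0.9, grid = NULL,
                          keepMaps = c("representative", "none")) {
  keepMaps <- match.arg(keepMaps)
  out <- lapply(cohort, function(pat) {
    sccs <- lapply(pat@exams, function(reps) {
      fs <- reps[[1]]@samplingRate
      g <- if (is.null(grid)) waveletGrid(fs) else grid
      maps <- lapply(reps, function(tr)
        mswc(tr@headVelocity, tr@eyeVelocity, fs, grid = g,
             threshold = threshold))
      freqs <- vapply(maps, slot, numeric(1), "coherentFrequency")
      i <- lowerMedianIndex(freqs)
      list(frequencies = freqs, repIndex = i, repFrequency = freqs[i],
           repMap = if (keepMaps == "representative") maps[[i]] else NULL)
    })
    list(outcome = pat@outcome, scc = sccs)
  })
  names(out) <- vapply(cohort, patientId, character(1))
  out
}

#' Assemble the per-patient, per-SCC feature table
#'
#' One row per patient and SCC: mean VOR gain over repeats, overt and total
#' saccade percentages, and the representative coherent frequency.
#'
#' @param cohort list of \linkS4class{PatientRecord}.
#' @param analyses result of \code{\link{analyzeCohort}} on the same cohort.
#' @return data.frame with columns \code{patient_id}, \code{outcome},
#'   \code{scc}, \code{vor_gain}, \code{overt_saccade_pct},
#'   \code{total_saccade_pct}, \code{coherent_freq_hz}.
#' @export
buildFeatureTable <- function(cohort, analyses) {
  rows <- lapply(cohort, function(pat) {
    an <- analyses[[pat@patientId]]
    if (is.null(an)) stop("no analysis for patient ", pat@patientId,
                          call. = FALSE)
    do.call(rbind, lapply(SCC_LEVELS, function(scc) {
      reps <- pat@exams[[scc]]
      if (is.null(reps) || is.null(an$scc[[scc]]))
        stop("missing SCC '", scc, "' for patient ", pat@patientId,
             call. = FALSE)
      sp <- saccadePercentages(reps)
      data.frame(patient_id = pat@patientId, outcome = pat@outcome,
                 scc = scc,
                 vor_gain = mean(vapply(reps, vorGain, numeric(1))),
                 overt_saccade_pct = sp[["overt"]],
                 total_saccade_pct = sp[["total"]],
                 coherent_freq_hz = an$scc[[scc]]$repFrequency,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
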