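#' @include wavelet.R
NULL

#' Simulate a head-impulse velocity profile
#'
#' Raised-cosine (Hann-shaped) angular-velocity bump: zero outside the
#' impulse, \eqn{v(t) = (A/D)(1 - \cos(2\pi (t - t_0)/D))} inside, so the
#' time integral equals the rotation amplitude \eqn{A} and the peak velocity
#' is \eqn{2A/D} (100 deg/s for the default 5 degrees in 100 ms).
#'
#' @param rotationAmplitude total rotation in degrees; default 5.
#' @param impulseDuration impulse duration in seconds, in (0, 0.2];
#'   default 0.1.
#' @param samplingRate Hz, >= 100; default 250.
#' @param onsetTime impulse onset in seconds; default 0.1.
#' @param totalDuration record length in seconds; default 0.7.
#' @return numeric head angular-velocity series (deg/s), one value per
#'   sample over [0, totalDuration].
#' @examples
#' v <- simulateHeadImpulse()
#' sum(v) / 250   # integrates to ~5 degrees
#' @export
simulateHeadImpulse <- function(rotationAmplitude = 5, impulseDuration = 0.1,
                                samplingRate = 250, onsetTime = 0.1,
                                totalDuration = 0.7) {
  stopIfNot(rotationAmplitude > 0, "rotationAmplitude must be positive")
  stopIfNot(impulseDuration > 0 && impulseDuration <= 0.2,
            "impulseDuration must lie in (0, 0.2]")
  stopIfNot(samplingRate >= 100, "samplingRate must be >= 100 Hz")
  t <- seq(0, totalDuration, by = 1 / samplingRate)
  v <- numeric(length(t))
  inb <- t >= onsetTime & t <= onsetTime + impulseDuration
  tau <- (t[inb] - onsetTime) / impulseDuration
  v[inb] <- (rotationAmplitude / impulseDuration) * (1 - cos(2 * pi * tau))
  v
}

# ---- coupling-edge calibration -------------------------------------------
#
# The coherent-frequency statistic reads the 0.9-coherence crossing of the
# head/eye pair. Because the Morlet is constant-Q, a spectral edge at f is
# read back systematically below f. The generator therefore calibrates
# itself: it computes, once per (rate, record length, impulse shape, grid),
# the deterministic map from brick-wall edge position to recovered coherent
# frequency on its own noise-free reference impulse, and inverts that map so
# that the configured coupling cutoff equals the frequency the analysis
# recovers.

.calibCache <- new.env(parent = emptyenv())

# expected read-back of a brick-wall edge under the generator's operating
# conditions: the deterministic band-limited response plus the analytic
# expectation of the smoothed high-passed-noise auto-power (white noise of
# sd noiseSd has E|W(s,.)|^2 = (sd^2/npad) * sum_k |H_s(w_k)|^2 over the
# retained band; time smoothing leaves that constant, scale smoothing is
# the boxcar)
calibrationSweep <- function(samplingRate, n, impulseDuration = 0.1,
                             onsetTime = 0.1, grid = NULL, noiseSd = 8,
                             gain = 0.9) {
  if (is.null(grid)) grid <- waveletGrid(samplingRate)
  key <- paste(samplingRate, n, impulseDuration, onsetTime,
               length(grid@scales), grid@voicesPerOctave, noiseSd, gain,
               sep = "|")
  if (!is.null(.calibCache[[key]])) return(.calibCache[[key]])
  totalDuration <- (n - 1) / samplingRate
  head <- simulateHeadImpulse(5, impulseDuration, samplingRate, onsetTime,
                              totalDuration)
  npad <- 2^ceiling(log2(4 * n))
  w <- 2 * pi * samplingRate * (0:(npad - 1)) / npad
  keepPos <- w > 0 & w <= pi * samplingRate
  wPos <- w[keepPos]
  P <- exp(-(outer(grid@scales, wPos) - grid@omega0)^2) / sqrt(pi) *
    (2 * pi * grid@scales * samplingRate)       # |H_s(w)|^2, n_scale x n_pos
  Wx <- analyticMorletCWT(head, samplingRate, grid)
  sinv <- 1 / grid@scales
  Sxx <- smoothSpectrum(sinv * Mod(Wx)^2, grid, samplingRate)
  times <- (seq_len(n) - 1) / samplingRate
  edges <- exp(seq(log(2), log(min(30, samplingRate / 2 * 0.9)),
                   length.out = 70))
  rec <- vapply(edges, function(e) {
    eye <- gain * fftLowpass(head, samplingRate, e)
    Wy <- analyticMorletCWT(eye, samplingRate, grid)
    Syy <- smoothSpectrum(sinv * Mod(Wy)^2, grid, samplingRate)
    Sxy <- smoothSpectrum(sinv * (Wx * Conj(Wy)), grid, samplingRate)
    nPow <- noiseSd^2 / npad * rowSums(P[, wPos / (2 * pi) > e, drop = FALSE])
    nPow <- as.numeric(smoothScale(matrix(sinv * nPow), grid))
    denom <- Sxx * (Syy + nPow)
    denom <- pmax(denom, 1e-12 * max(denom))
    R2 <- pmin(pmax(Mod(Sxy)^2 / denom, 0), 1)
    map <- new("CoherenceMap", mswc = R2, crossPower = Mod(Sxy),
               grid = grid, times = times,
               coi = coiFrequencies(times, grid@omega0),
               coherentFrequency = 0)
    coherentFrequency(map)
  }, numeric(1))
  rec <- cummax(rec)                        # enforce monotone read-back
  out <- list(edges = edges, recovered = rec, grid = grid)
  .calibCache[[key]] <- out
  out
}

# invert the sweep: edge whose noise-free read-back is the grid frequency
# nearest the requested cutoff (geometric midpoint of the matching interval)
edgeForCutoff <- function(cutoff, samplingRate, n, impulseDuration = 0.1,
                          onsetTime = 0.1, grid = NULL, noiseSd = 8) {
  if (cutoff >= samplingRate / 2) return(cutoff)
  sw <- calibrationSweep(samplingRate, n, impulseDuration, onsetTime, grid,
                         noiseSd = noiseSd)
  freqs <- sort(sw$grid@frequencies)
  target <- freqs[which.min(abs(log(freqs) - log(cutoff)))]
  hit <- which(abs(sw$recovered - target) < 1e-9)
  if (length(hit) > 0)
    return(exp(mean(log(sw$edges[range(hit)]))))
  above <- which(sw$recovered >= target)
  if (length(above) > 0) return(sw$edges[above[1]])
  # beyond the sweep: extrapolate with the last edge/read-back ratio
  cutoff * sw$edges[length(sw$edges)] / max(sw$recovered)
}

#' Simulate the eye-velocity response to a head impulse
#'
#' Realizes the causal model in which the eye trace is driven solely by the
#' VOR response and corrective saccades: a band-limited copy of the head
#' velocity scaled by the VOR gain, plus Gaussian-pulse saccades, plus
#' independent noise whose spectrum dominates above the coupling cutoff
#' (white noise high-passed at the coupling edge).
#'
#' Band limitation uses a zero-phase brick-wall low-pass, so coherence (not
#' lag) carries the class signal. Two calibrations make the configured
#' parameters exact in the analysis' own units: the spectral-edge position
#' is chosen so the recovered coherent frequency equals
#' \code{couplingCutoff} (see the package vignette), and the VOR component
#' is rescaled so that the impulse-window area ratio equals \code{gain}
#' (the band-limit redistributes a little energy outside the window). With
#' \code{couplingCutoff} at Nyquist and no noise these reduce to
#' \code{eye = gain * head} exactly.
#'
#' @param head numeric head-velocity series (deg/s).
#' @param samplingRate Hz.
#' @param gain VOR gain, >= 0.
#' @param couplingCutoff coupling cutoff in Hz, in (0, Nyquist].
#' @param saccades NULL or a data.frame with columns \code{onset},
#'   \code{duration} (s), \code{peak_velocity} (deg/s), \code{kind}.
#' @param noiseSd sd of the high-passed measurement noise (deg/s);
#'   default 8.
#' @param seed optional seed for the noise draw.
#' @param calibrateEdge if FALSE the brick-wall edge is placed at
#'   \code{couplingCutoff} itself, without read-back calibration.
#' @param impulseWindow window (s) over which the area gain is normalized;
#'   default c(0.1, 0.2).
#' @return numeric eye-velocity series.
#' @export
simulateEyeResponse <- function(head, samplingRate, gain, couplingCutoff,
                                saccades = NULL, noiseSd = 8, seed = NULL,
                                calibrateEdge = TRUE,
                                impulseWindow = c(0.1, 0.2)) {
  stopIfNot(gain >= 0, "gain must be >= 0")
  stopIfNot(couplingCutoff > 0 && couplingCutoff <= samplingRate / 2,
            "couplingCutoff must lie in (0, Nyquist]")
  n <- length(head)
  edge <- if (calibrateEdge)
    edgeForCutoff(couplingCutoff, samplingRate, n, noiseSd = noiseSd)
  else couplingCutoff
  edge <- min(edge, samplingRate / 2)
  vor <- gain * fftLowpass(head, samplingRate, edge)
  t <- (seq_len(n) - 1) / samplingRate
  w <- t >= impulseWindow[1] & t <= impulseWindow[2]
  aHead <- sum(head[w]); aVor <- sum(fftLowpass(head, samplingRate, edge)[w])
  if (aHead > 0 && abs(aVor) > 1e-12 * aHead)
    vor <- vor * (aHead / aVor)
  eye <- vor
  if (!is.null(saccades) && nrow(saccades) > 0)
    for (i in seq_len(nrow(saccades))) {
      ctr <- saccades$onset[i] + saccades$duration[i] / 2
      sig <- saccades$duration[i] / 6
      eye <- eye + saccades$peak_velocity[i] * exp(-(t - ctr)^2 / (2 * sig^2))
    }
  if (noiseSd > 0)
    eye <- eye + withSeed(seed,
      noiseSd * fftHighpass(rnorm(n), samplingRate, edge))
  eye
}

# draw the saccade events for one repeat from the per-class probabilities;
# overt share of repeats = overtProb, any-saccade share = totalProb
drawSaccades <- function(overtProb, totalProb, peakRange) {
  u <- runif(1)
  mk <- function(kind) {
    if (kind == "overt")
      data.frame(onset = runif(1, 0.21, 0.45), duration = runif(1, 0.04, 0.07),
                 peak_velocity = runif(1, peakRange[1], peakRange[2]),
                 kind = "overt", stringsAsFactors = FALSE)
    else
      data.frame(onset = runif(1, 0.12, 0.19), duration = runif(1, 0.03, 0.05),
                 peak_velocity = runif(1, peakRange[1], peakRange[2]),
                 kind = "covert", stringsAsFactors = FALSE)
  }
  if (u < overtProb) mk("overt")
  else if (u < totalProb) mk("covert")
  else data.frame(onset = numeric(0), duration = numeric(0),
                  peak_velocity = numeric(0), kind = character(0),
                  stringsAsFactors = FALSE)
}

#' Construct an ImpulseTrace
#'
#' @param headVelocity,eyeVelocity equal-length velocity series (deg/s).
#' @param samplingRate Hz.
#' @param scc SCC label.
#' @param onsetTime onset in seconds (fixed at 0.1).
#' @param trueParams optional generator ground truth.
#' @return an \linkS4class{ImpulseTrace}.
#' @export
impulseTrace <- function(headVelocity, eyeVelocity, samplingRate,
                         scc = "posterior", onsetTime = 0.1,
                         trueParams = list()) {
  n <- length(headVelocity)
  new("ImpulseTrace", time = (seq_len(n) - 1) / samplingRate,
      headVelocity = headVelocity, eyeVelocity = eyeVelocity,
      samplingRate = samplingRate, onsetTime = onsetTime, scc = scc,
      trueParams = trueParams)
}

#' Simulate a repeat set of impulses for one semicircular canal
#'
#' Draws per-repeat gains, coupling cutoffs and saccades independently from
#' the class distribution and builds one \linkS4class{ImpulseTrace} per
#' repeat, each carrying its ground truth in \code{trueParams}.
#'
#' @param scc SCC label.
#' @param classParams list with elements \code{gainMean}, \code{gainSd},
#'   \code{cutoffMean}, \code{cutoffSd} (Hz), \code{overtProb},
#'   \code{totalProb}, and optionally \code{saccadePeakRange} (deg/s,
#'   default c(100, 250)), \code{noiseSd} (default 8),
#'   \code{amplitude}/\code{amplitudeSd} (deg, defaults 5/0.1),
#'   \code{impulseDuration}/\code{durationSd} (s, defaults 0.1/0.004).
#' @param repeats number of impulses; default 10.
#' @param samplingRate Hz; default 250.
#' @param seed optional seed; a fixed seed regenerates the set bit for bit.
#' @return list of \linkS4class{ImpulseTrace}.
#' @export
simulateExamSet <- function(scc, classParams, repeats = 10,
                            samplingRate = 250, seed = NULL) {
  stopIfNot(repeats >= 1, "repeats must be >= 1")
  p <- classParams
  p$saccadePeakRange <- p$saccadePeakRange %||% c(100, 250)
  p$noiseSd <- p$noiseSd %||% 8
  p$amplitude <- p$amplitude %||% 5
  p$amplitudeSd <- p$amplitudeSd %||% 0.1
  p$impulseDuration <- p$impulseDuration %||% 0.1
  p$durationSd <- p$durationSd %||% 0.004
  withSeed(seed, lapply(seq_len(repeats), function(r) {
    gain <- rtruncnorm(1, p$gainMean, p$gainSd, 0.05, 1.5)
    cutoff <- rtruncnorm(1, p$cutoffMean, p$cutoffSd, 2,
                         min(15, samplingRate / 2))
    amp <- rtruncnorm(1, p$amplitude, p$amplitudeSd,
                      0.7 * p$amplitude, 1.3 * p$amplitude)
    dur <- rtruncnorm(1, p$impulseDuration, p$durationSd, 0.06, 0.14)
    sac <- drawSaccades(p$overtProb, p$totalProb, p$saccadePeakRange)
    head <- simulateHeadImpulse(amp, dur, samplingRate)
    eye <- simulateEyeResponse(head, samplingRate, gain, cutoff,
                               saccades = sac, noiseSd = p$noiseSd)
    impulseTrace(head, eye, samplingRate, scc = scc,
                 trueParams = list(gain = gain, couplingCutoff = cutoff,
                                   saccades = sac, noiseSd = p$noiseSd,
                                   amplitude = amp, impulseDuration = dur))
  }))
}

#' Default per-class, per-SCC generator calibration
#'
#' Distribution parameters for the three outcome classes (CR = complete
#' recovery; PR/NR = partial/no recovery, which share the published
#' incomplete-recovery statistics). Gains and coherent-frequency (coupling
#' cutoff) means/sds for the incomplete class, and the overall per-SCC
#' means, follow the printed clinical cohort statistics; the CR means are
#' recovered from the 20/44 class mixture identity. Saccade probabilities
#' are per-repeat probabilities of an overt (or any) saccade.
#'
#' @return nested list: class -> SCC -> parameter list (see
#'   \code{\link{simulateExamSet}}).
#' @export
defaultClassParams <- function() {
  cr <- list(
    horizontal = list(gainMean = 1.02, gainSd = 0.10, cutoffMean = 6.30,
                      cutoffSd = 1.0, overtProb = 0.15, totalProb = 0.17),
    anterior   = list(gainMean = 0.98, gainSd = 0.10, cutoffMean = 6.96,
                      cutoffSd = 1.0, overtProb = 0.01, totalProb = 0.04),
    posterior  = list(gainMean = 0.99, gainSd = 0.10, cutoffMean = 6.40,
                      cutoffSd = 1.0, overtProb = 0.05, totalProb = 0.10))
  inc <- list(
    horizontal = list(gainMean = 0.96, gainSd = 0.28, cutoffMean = 5.21,
                      cutoffSd = 2.03, overtProb = 0.4666, totalProb = 0.5130),
    anterior   = list(gainMean = 0.95, gainSd = 0.20, cutoffMean = 6.32,
                      cutoffSd = 1.57, overtProb = 0.0248, totalProb = 0.1136),
    posterior  = list(gainMean = 0.83, gainSd = 0.30, cutoffMean = 4.94,
                      cutoffSd = 2.28, overtProb = 0.2180, totalProb = 0.3043))
  list(CR = cr, PR = inc, NR = inc)
}

#' Construct a cohort configuration
#'
#' @param nCR,nPR,nNR patients per outcome class; defaults 20/18/26.
#' @param classParams nested parameter list; default
#'   \code{\link{defaultClassParams}()}.
#' @param repeats impulses per SCC; default 10.
#' @param samplingRate Hz; default 250.
#' @param seed master seed; default 1.
#' @return a \linkS4class{CohortConfig}.
#' @export
cohortConfig <- function(nCR = 20, nPR = 18, nNR = 26,
                         classParams = defaultClassParams(), repeats = 10,
                         samplingRate = 250, seed = 1) {
  stopIfNot(nCR >= 1 && nPR >= 1 && nNR >= 1,
            "every outcome class needs at least one patient")
  new("CohortConfig",
      nPatients = setNames(as.integer(c(nCR, nPR, nNR)), OUTCOME_LEVELS),
      classParams = classParams, repeats = as.integer(repeats),
      samplingRate = samplingRate, seed = seed)
}

#' Simulate a whole synthetic vHIT cohort
#'
#' Generates one \linkS4class{PatientRecord} per patient with exam sets for
#' all three SCCs. A latent per-patient severity factor correlates the
#' patient-level gain, coupling cutoff and saccade propensity across SCCs
#' (higher severity: lower gain, lower cutoff, more saccades), emulating
#' common vestibular end-organ damage. All randomness descends from the
#' config seed through per-patient substreams, so identical configs
#' regenerate identical cohorts.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @return list of \linkS4class{PatientRecord} (CR patients first, then PR,
#'   then NR).
#' @examples
#' \donttest{
#' cfg <- cohortConfig(nCR = 1, nPR = 1, nNR = 1, repeats = 2)
#' cohort <- simulateCohort(cfg)
#' length(cohort)
#' }
#' @export
simulateCohort <- function(config) {
  validObject(config)
  nTot <- sum(config@nPatients)
  seeds <- childSeeds(config@seed, nTot)
  classes <- rep(OUTCOME_LEVELS, config@nPatients[OUTCOME_LEVELS])
  out <- vector("list", nTot)
  for (i in seq_len(nTot)) {
    cls <- classes[i]
    out[[i]] <- withSeed(seeds[i], {
      z <- rnorm(1)                          # latent severity
      exams <- lapply(setNames(SCC_LEVELS, SCC_LEVELS), function(scc) {
        p <- config@classParams[[cls]][[scc]]
        # truncated draws by rejection on the idiosyncratic component, so
        # the severity correlation survives and no mass piles at the bounds
        drawTrunc <- function(mean, s, lower, upper) {
          for (i in 1:1000) {
            x <- mean + s * (-0.5 * z + sqrt(0.75) * rnorm(1))
            if (x >= lower && x <= upper) return(x)
          }
          min(max(mean, lower), upper)
        }
        pg <- drawTrunc(p$gainMean, p$gainSd, 0.05, 1.5)
        pc <- drawTrunc(p$cutoffMean, p$cutoffSd, 2, 15)
        shift <- function(prob) {
          if (prob <= 0) return(0)
          if (prob >= 1) return(1)
          stats::plogis(stats::qlogis(prob) + 0.6 * z)
        }
        po <- shift(p$overtProb); pt <- max(shift(p$totalProb), po)
        pp <- p
        pp$gainMean <- pg; pp$gainSd <- 0.02
        pp$cutoffMean <- pc; pp$cutoffSd <- 0.15
        pp$overtProb <- po; pp$totalProb <- pt
        simulateExamSet(scc, pp, repeats = config@repeats,
                        samplingRate = config@samplingRate)
      })
      new("PatientRecord", patientId = sprintf("P%03d", i), outcome = cls,
          exams = exams, derived = list())
    })
  }
  out
}
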