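#' @include AllClasses.R
NULL

# Morlet Fourier factor: lambda = 4*pi / (omega0 + sqrt(2 + omega0^2));
# equivalent frequency of scale s is f = 1/(lambda*s)
morletFourierFactor <- function(omega0 = 6) 4 * pi / (omega0 + sqrt(2 + omega0^2))

#' Construct the wavelet scale/frequency grid
#'
#' Geometric grid with \code{voicesPerOctave} scales per octave. The smallest
#' scale is chosen so the top grid frequency equals the Nyquist frequency,
#' and scales extend until the grid reaches \code{minFrequency} (default
#' 1.4 Hz, the full-record period of a 0.7 s exam). At 250 Hz sampling the
#' grid therefore spans roughly 1.4 to 125 Hz.
#'
#' @param samplingRate sampling rate in Hz.
#' @param voicesPerOctave scales per octave; default 12.
#' @param minFrequency lowest frequency to cover (Hz); default 1.4.
#' @param omega0 Morlet center frequency; default 6.
#' @return a \linkS4class{WaveletGrid}.
#' @examples
#' g <- waveletGrid(250)
#' range(gridFrequencies(g))
#' @export
waveletGrid <- function(samplingRate, voicesPerOctave = 12L,
                        minFrequency = 1.4, omega0 = 6) {
  stopIfNot(samplingRate > 0, "samplingRate must be positive")
  stopIfNot(minFrequency > 0 && minFrequency < samplingRate / 2,
            "minFrequency must lie in (0, Nyquist)")
  ff <- morletFourierFactor(omega0)
  s0 <- 1 / (ff * samplingRate / 2)          # top frequency = Nyquist
  sMax <- 1 / (ff * minFrequency)
  v <- as.integer(voicesPerOctave)
  J <- ceiling(v * log2(sMax / s0))
  scales <- s0 * 2^((0:J) / v)
  new("WaveletGrid", scales = scales, frequencies = 1 / (ff * scales),
      voicesPerOctave = v, omega0 = omega0)
}

#' Analytic Morlet continuous wavelet transform
#'
#' FFT implementation of the CWT with the analytic Morlet mother wavelet
#' \eqn{\hat\psi(\omega) = \pi^{-1/4} e^{-(s\omega-\omega_0)^2/2}} for
#' \eqn{\omega > 0}. The signal is zero-padded (to at least four times its
#' length, rounded to a power of two) to suppress circular wrap-around at
#' the largest scales.
#'
#' @param signal numeric vector, at least 32 finite samples.
#' @param samplingRate Hz.
#' @param grid a \linkS4class{WaveletGrid}.
#' @return complex matrix, n_freq x n_time, rows in grid order (decreasing
#'   frequency as row index increases? no: rows follow \code{gridScales},
#'   i.e. increasing scale / decreasing frequency).
#' @examples
#' g <- waveletGrid(250)
#' x <- sin(2 * pi * 6 * seq(0, 0.7, by = 1/250))
#' W <- analyticMorletCWT(x, 250, g)
#' gridFrequencies(g)[which.max(rowMeans(Mod(W)))]
#' @export
analyticMorletCWT <- function(signal, samplingRate, grid) {
  stopIfNot(is.numeric(signal) && length(signal) >= 32,
            "signal must be numeric with at least 32 samples")
  stopIfNot(all(is.finite(signal)), "signal must contain only finite values")
  stopIfNot(is(grid, "WaveletGrid") && length(grid@scales) > 0,
            "grid must be a non-empty WaveletGrid")
  n <- length(signal)
  npad <- 2^ceiling(log2(4 * n))
  fx <- fft(c(signal, rep(0, npad - n)))
  w <- 2 * pi * samplingRate * (0:(npad - 1)) / npad
  w[w > pi * samplingRate] <- w[w > pi * samplingRate] - 2 * pi * samplingRate
  pos <- w > 0
  # daughter filter bank: npad x n_scale, positive frequencies only
  H <- matrix(0, npad, length(grid@scales))
  sw <- outer(w[pos], grid@scales)
  H[pos, ] <- pi^(-0.25) * exp(-(sw - grid@omega0)^2 / 2)
  H <- H * rep(sqrt(2 * pi * grid@scales * samplingRate), each = npad)
  W <- mvfft(fx * H, inverse = TRUE) / npad
  t(W[seq_len(n), , drop = FALSE])
}

#' Smoothing operator for wavelet spectra
#'
#' Applies the two-stage smoothing used in wavelet-coherence estimation:
#' first in time with a per-scale Gaussian kernel \eqn{e^{-t^2/(2s^2)}}
#' (edges handled by reflection), then across scales with a boxcar spanning
#' 0.6 of an octave (truncated at the grid ends). Constants are the
#' published defaults for the Morlet at \eqn{\omega_0 = 6}.
#'
#' @param mat numeric or complex matrix, n_scale x n_time, rows in grid
#'   order.
#' @param grid the \linkS4class{WaveletGrid} the rows correspond to.
#' @param samplingRate Hz.
#' @return smoothed matrix of the same shape and mode.
#' @export
smoothSpectrum <- function(mat, grid, samplingRate) {
  stopIfNot(is.matrix(mat) && nrow(mat) == length(grid@scales),
            "mat must have one row per grid scale")
  smoothScale(smoothTime(mat, grid, samplingRate), grid)
}

# per-scale Gaussian time smoothing, reflection at edges, all rows at once
smoothTime <- function(mat, grid, samplingRate) {
  n <- ncol(mat)
  dt <- 1 / samplingRate
  L <- n - 1                                 # uniform full-width kernels
  # reflected padding: [x_L+1..x_2, x_1..x_n, x_n-1..x_n-L]
  pad <- cbind(mat[, (L + 1):2, drop = FALSE], mat,
               mat[, (n - 1):(n - L), drop = FALSE])
  m <- ncol(pad)
  klen <- 2 * L + 1
  nf <- 2^ceiling(log2(m + klen))
  tgrid <- (-L:L) * dt
  K <- exp(-outer(grid@scales^-2, tgrid^2) / 2)  # n_scale x klen
  K <- K / rowSums(K)
  Pf <- mvfft(t(cbind(pad, matrix(0, nrow(mat), nf - m))))
  Kf <- mvfft(t(cbind(K, matrix(0, nrow(mat), nf - klen))))
  conv <- mvfft(Pf * Kf, inverse = TRUE) / nf
  # trace sample i sits at padded index i+L; kernel center offset is L+1
  out <- t(conv)[, (2 * L + 1):(2 * L + n), drop = FALSE]
  if (is.complex(mat)) out else Re(out)
}

# boxcar across scales spanning 0.6 octave, truncated at the grid ends
smoothScale <- function(mat, grid) {
  win <- max(1L, round(0.6 * grid@voicesPerOctave))
  if (win %% 2L == 0L) win <- win + 1L
  half <- (win - 1L) %/% 2L
  ns <- nrow(mat)
  out <- mat
  for (i in seq_len(ns)) {
    lo <- max(1L, i - half); hi <- min(ns, i + half)
    out[i, ] <- colMeans(mat[lo:hi, , drop = FALSE])
  }
  out
}

#' Magnitude-squared wavelet coherence between head and eye velocity
#'
#' Computes \deqn{R^2_n(s) = \frac{|S(s^{-1} W^{XY}_n(s))|^2}
#' {S(s^{-1}|W^X_n(s)|^2)\, S(s^{-1}|W^Y_n(s)|^2)}} where \eqn{W^X},
#' \eqn{W^Y} are the analytic Morlet transforms of the two series,
#' \eqn{W^{XY} = W^X \overline{W^Y}} is the cross-wavelet spectrum and
#' \eqn{S} the smoothing operator of \code{\link{smoothSpectrum}}. The
#' denominator is guarded with \eqn{\epsilon = 10^{-12} \max} power and the
#' result clipped to [0, 1]. Without smoothing the ratio is identically 1
#' for any pair; \code{smooth = FALSE} exposes that degeneracy for testing.
#'
#' @param head,eye equal-length finite numeric series (deg/s).
#' @param samplingRate Hz.
#' @param grid optional \linkS4class{WaveletGrid}; default
#'   \code{waveletGrid(samplingRate)}.
#' @param smooth logical; if FALSE the smoothing operator is skipped
#'   (diagnostic use only).
#' @param threshold coherence threshold used for the stored coherent
#'   frequency; default 0.9.
#' @return a \linkS4class{CoherenceMap}.
#' @examples
#' tr <- simulateHeadImpulse()
#' m <- mswc(tr, 0.8 * tr, 250)
#' range(mswcMatrix(m))
#' @export
mswc <- function(head, eye, samplingRate, grid = NULL, smooth = TRUE,
                 threshold = 0.9) {
  stopIfNot(length(head) == length(eye),
            "head and eye series must have equal length")
  stopIfNot(all(is.finite(head)) && all(is.finite(eye)),
            "series must contain only finite values")
  if (all(head == 0) || all(eye == 0))
    stop("degenerate input: a series is identically zero", call. = FALSE)
  if (is.null(grid)) grid <- waveletGrid(samplingRate)
  Wx <- analyticMorletCWT(head, samplingRate, grid)
  Wy <- analyticMorletCWT(eye, samplingRate, grid)
  sinv <- 1 / grid@scales
  S <- if (smooth) function(M) smoothSpectrum(M, grid, samplingRate)
       else identity
  Sxx <- S(sinv * Mod(Wx)^2)
  Syy <- S(sinv * Mod(Wy)^2)
  Sxy <- S(sinv * (Wx * Conj(Wy)))
  denom <- Sxx * Syy
  eps <- 1e-12 * max(denom)      # floor for cells with negligible power
  R2 <- Mod(Sxy)^2 / pmax(denom, eps)
  R2 <- pmin(pmax(R2, 0), 1)
  n <- length(head)
  times <- (seq_len(n) - 1) / samplingRate
  map <- new("CoherenceMap", mswc = R2, crossPower = Mod(Sxy), grid = grid,
             times = times, coi = coiFrequencies(times, grid@omega0),
             coherentFrequency = 0)
  map@coherentFrequency <- coherentFrequency(map, threshold = threshold)
  map
}

# cone of influence: at time t the e-folding time sqrt(2)*s of the Morlet
# reaches the nearer record edge for scales s > d/sqrt(2); frequencies below
# 1/(lambda * d/sqrt(2)) are edge-affected
coiFrequencies <- function(times, omega0 = 6) {
  d <- pmin(times - min(times), max(times) - times)
  ff <- morletFourierFactor(omega0)
  out <- rep(Inf, length(d))
  pos <- d > 0
  out[pos] <- sqrt(2) / (ff * d[pos])
  out
}

#' @rdname coherentFrequency
setMethod("coherentFrequency", "CoherenceMap",
  function(map, threshold = 0.9, timeWindow = NULL,
           rule = c("contiguous", "global"), maskCoi = FALSE) {
    rule <- match.arg(rule)
    stopIfNot(threshold > 0 && threshold <= 1, "threshold must be in (0, 1]")
    if (is.null(timeWindow)) timeWindow <- range(map@times)
    keep <- map@times >= timeWindow[1] & map@times <= timeWindow[2]
    stopIfNot(any(keep), "empty time window")
    R2 <- map@mswc[, keep, drop = FALSE]
    freqs <- map@grid@frequencies           # decreasing along rows
    if (maskCoi) {
      coi <- map@coi[keep]
      mask <- outer(freqs, coi, `>=`)       # TRUE = inside cone, reliable
      R2[!mask] <- NA_real_
    }
    minOverTime <- apply(R2, 1, function(r) {
      r <- r[!is.na(r)]
      if (!length(r)) Inf else min(r)       # fully masked rows qualify
    })
    ord <- order(freqs)                     # ascending frequency
    qual <- (minOverTime >= threshold)[ord]
    fAsc <- freqs[ord]
    if (rule == "global") {
      if (!any(qual)) return(0)
      return(fAsc[max(which(qual))])
    }
    if (!qual[1]) return(0)
    firstFail <- which(!qual)[1]
    if (is.na(firstFail)) fAsc[length(fAsc)] else fAsc[firstFail - 1]
  })
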