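# internal helpers shared across modules

# evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards; seed = NULL runs in the ambient stream
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# deterministic substream seeds: one master seed -> n child seeds < 2^31
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# truncated-normal draw by rejection (bounds are a few sd away in practice)
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lower), upper), n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  guard <- 0L
  while (length(bad) > 0L && guard < 1000L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] > upper]
    guard <- guard + 1L
  }
  if (length(bad) > 0L) out[bad] <- pmin(pmax(mean, lower), upper)
  out
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# zero-phase brick-wall FFT filters; exact identity when the band keeps all
# frequencies (low-pass with fc >= Nyquist, high-pass with fc <= 0)
fftLowpass <- function(x, samplingRate, fc) {
  if (fc >= samplingRate / 2) return(x)
  applyBrickwall(x, samplingRate, function(f) f <= fc)
}

fftHighpass <- function(x, samplingRate, fc) {
  if (fc <= 0) return(x)
  applyBrickwall(x, samplingRate, function(f) f > fc)
}

applyBrickwall <- function(x, samplingRate, keep) {
  n <- length(x)
  npad <- 2^ceiling(log2(2 * n))
  xp <- c(x, rep(0, npad - n))
  f <- (0:(npad - 1)) / npad * samplingRate
  f <- pmin(f, samplingRate - f)      # folded (absolute) frequency axis
  H <- as.numeric(keep(f))
  Re(fft(fft(xp) * H, inverse = TRUE) / npad)[seq_len(n)]
}
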