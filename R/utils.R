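# Internal numerical helpers shared across modules.

addProvenance <- function(object, op, params = list()) {
  object@provenance <- c(object@provenance, list(list(op = op, params = params)))
  object
}

#' Canonical EEG frequency bands
#'
#' The five-band table used throughout the package: delta 1-4, theta 4-8,
#' alpha 8-13, beta 13-30, gamma 30-50 Hz. An alternative table
#' (\code{resultsSectionBands}) with alpha 8-14, beta 14-31, gamma 31-50 Hz is
#' shipped as well because both conventions circulate; they are never merged
#' silently — every result records which table produced it.
#'
#' @return data.frame with columns \code{name}, \code{lo}, \code{hi} (Hz).
#' @export
#' @examples
#' canonicalBands()
canonicalBands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    lo = c(1, 4, 8, 13, 30),
    hi = c(4, 8, 13, 30, 50),
    stringsAsFactors = FALSE
  )
}

#' @rdname canonicalBands
#' @export
resultsSectionBands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    lo = c(1, 4, 8, 14, 31),
    hi = c(4, 8, 14, 31, 50),
    stringsAsFactors = FALSE
  )
}

#' Band membership of a frequency
#'
#' Which named band owns frequency \code{f}, under the half-open convention
#' [lo, hi): a shared band edge belongs to the upper band (13 Hz is beta, not
#' alpha).
#'
#' @param f frequency in Hz (vectorized).
#' @param bands band table, default \code{\link{canonicalBands}}.
#' @return character band name (NA outside all bands).
#' @export
bandOf <- function(f, bands = canonicalBands()) {
  vapply(f, function(fi) {
    hit <- which(fi >= bands$lo & fi < bands$hi)
    if (length(hit)) bands$name[hit[1]] else NA_character_
  }, character(1))
}

bandRow <- function(band, bands = canonicalBands()) {
  if (is.data.frame(band)) return(band)
  i <- match(band, bands$name)
  if (is.na(i)) stop(sprintf("unknown band '%s'; known: %s", band,
                             paste(bands$name, collapse = ", ")))
  bands[i, , drop = FALSE]
}

# Hann window of length n (periodic form, standard for Welch averaging).
hannWindow <- function(n) {
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)
}

# Trapezoid integral of y over the uniform grid x (used for band power).
trapezoid <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# 1/f ("pink") noise with unit standard deviation, via FFT amplitude shaping.
# Power ~ 1/f down to a low-frequency shoulder so variance stays finite.
pinkNoise <- function(n, fs) {
  nf <- n %/% 2 + 1L
  f <- seq(0, fs / 2, length.out = nf)
  amp <- 1 / sqrt(pmax(f, 1))           # flat below 1 Hz, 1/f above
  amp[1] <- 0                            # no DC
  phase <- runif(nf, 0, 2 * pi)
  spec <- amp * exp(1i * phase)
  full <- c(spec, Conj(rev(spec[2:(n - nf + 1L)])))
  x <- Re(fft(full, inverse = TRUE))
  x <- x - mean(x)
  x / sd(x)
}

# Analytic signal via the FFT-based Hilbert transform.
analyticSignal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Band-limited unit-variance noise source confined to [lo, hi) Hz, returned
# as an analytic (complex) signal so per-channel phase offsets can be applied
# by complex rotation. Synthesized in the frequency domain: coefficients are
# i.i.d. complex Gaussian on the band's positive-frequency bins and exactly
# zero elsewhere, so planted coupling cannot leak into neighboring bands
# (a time-domain filter's transition skirts would).
narrowbandSource <- function(n, fs, lo, hi) {
  f <- (seq_len(n) - 1) * fs / n
  sel <- which(f >= lo & f < hi & f <= fs / 2)
  spec <- rep(0 + 0i, n)
  spec[sel] <- complex(real = rnorm(length(sel)),
                       imaginary = rnorm(length(sel)))
  z <- fft(spec, inverse = TRUE) / n
  z / sd(Re(z))
}

# Deterministic per-task seed derivation, kept below 2^31. The final
# multiplicative step spreads consecutive inputs (e.g. subject indices) far
# apart: Mersenne-Twister streams seeded with adjacent integers are weakly
# correlated, which would couple subjects that must be independent.
deriveSeed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  s <- 0
  for (p in parts) s <- (s * 69069 + as.numeric(p) + 1) %% 2147483647
  s <- (s * 1566083941) %% 2147483647
  s <- (s * 69069 + 1) %% 2147483647
  as.integer(s)
}

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
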