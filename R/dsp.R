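# Digital signal processing primitives: Butterworth IIR design in
# zero-pole-gain form, second-order-section (biquad) zero-phase filtering,
# anti-aliased decimation, and Welch PSD estimation.  These are the standard
# textbook constructions; filters are designed via the bilinear transform with
# frequency pre-warping and applied as cascaded biquads, which stays
# numerically stable for the very narrow normalized bands used with gastric
# slow waves (0.05-0.7 Hz at 200 Hz).

# Analog Butterworth prototype: n poles on the unit circle, no zeros, gain 1.
butter_prototype <- function(n) {
  m <- seq(-n + 1, n - 1, by = 2)
  list(z = complex(0), p = -exp(1i * pi * m / (2 * n)), k = 1)
}

# Lowpass prototype -> lowpass at cutoff w (rad/s).
lp2lp_zpk <- function(zpk, w) {
  degree <- length(zpk$p) - length(zpk$z)
  list(z = zpk$z * w, p = zpk$p * w, k = zpk$k * w^degree)
}

# Lowpass prototype -> bandpass between wl and wh (rad/s).
lp2bp_zpk <- function(zpk, wl, wh) {
  bw <- wh - wl
  w0 <- sqrt(wl * wh)
  degree <- length(zpk$p) - length(zpk$z)
  scale_bp <- function(x) {
    xb <- x * bw / 2
    c(xb + sqrt(xb^2 - w0^2), xb - sqrt(xb^2 - w0^2))
  }
  z <- if (length(zpk$z)) scale_bp(zpk$z) else complex(0)
  p <- scale_bp(zpk$p)
  # bandpass transform adds one zero at s = 0 per excess pole
  z <- c(z, rep(0 + 0i, degree))
  list(z = z, p = p, k = zpk$k * bw^degree)
}

# Bilinear transform at sample rate fs (analog frequencies must be pre-warped).
bilinear_zpk <- function(zpk, fs) {
  fs2 <- 2 * fs
  zd <- (fs2 + zpk$z) / (fs2 - zpk$z)
  pd <- (fs2 + zpk$p) / (fs2 - zpk$p)
  degree <- length(zpk$p) - length(zpk$z)
  kd <- zpk$k * Re(prod(fs2 - zpk$z) / prod(fs2 - zpk$p))
  list(z = c(zd, rep(-1 + 0i, degree)), p = pd, k = kd)
}

prewarp <- function(f_hz, fs) 2 * fs * tan(pi * f_hz / fs)

# Split a set of roots (closed under conjugation) into conjugate pairs plus
# real leftovers.  Returns a list of length-1 or length-2 complex vectors.
conj_pairs <- function(r, tol = 1e-8) {
  out <- list()
  cplx <- r[Im(r) > tol]
  for (p in cplx) out[[length(out) + 1L]] <- c(p, Conj(p))
  reals <- sort(Re(r[abs(Im(r)) <= tol]))
  i <- 1L
  while (i <= length(reals)) {
    if (i + 1L <= length(reals)) {
      out[[length(out) + 1L]] <- complex(real = reals[c(i, i + 1L)])
      i <- i + 2L
    } else {
      out[[length(out) + 1L]] <- complex(real = reals[i])
      i <- i + 1L
    }
  }
  out
}

poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (ri in r) coefs <- c(coefs, 0i) - c(0i, coefs * ri)
  Re(coefs)
}

# Pair pole groups with zero groups into biquad sections (rows: b0 b1 b2
# a0 a1 a2).  Poles nearest the unit circle are paired with the zeros
# nearest to them; all gain is carried by the first section.
zpk2sos <- function(zpk) {
  pg <- conj_pairs(zpk$p)
  zg <- conj_pairs(zpk$z)
  # order pole groups: closest to unit circle first
  pg <- pg[order(vapply(pg, function(g) min(abs(1 - abs(g))), 0))]
  sos <- matrix(0, nrow = length(pg), ncol = 6)
  used <- rep(FALSE, length(zg))
  for (i in seq_along(pg)) {
    a <- poly_from_roots(pg[[i]])
    # pick the nearest unused zero group of matching (or smaller) size
    zi <- integer(0)
    if (any(!used)) {
      d <- vapply(seq_along(zg), function(j) {
        if (used[j]) return(Inf)
        mean(abs(zg[[j]][1] - pg[[i]][1]))
      }, 0)
      j <- which.min(d)
      used[j] <- TRUE
      zi <- j
    }
    b <- if (length(zi)) poly_from_roots(zg[[zi]]) else 1
    b <- c(b, rep(0, 3 - length(b)))
    a <- c(a, rep(0, 3 - length(a)))
    sos[i, ] <- c(b, a)
  }
  sos[1, 1:3] <- sos[1, 1:3] * zpk$k
  sos
}

#' Design a digital Butterworth filter as second-order sections
#'
#' @param n filter order (per pass; a bandpass of order `n` has `2n` poles).
#' @param cutoff_hz cutoff frequency in Hz (length 1 for `"low"`, length 2 for
#'   `"bandpass"`).
#' @param fs sampling rate in Hz.
#' @param type `"low"` or `"bandpass"`.
#' @return numeric matrix with one biquad per row, columns
#'   `b0,b1,b2,a0,a1,a2`.
#' @keywords internal
butter_sos <- function(n, cutoff_hz, fs, type = c("low", "bandpass")) {
  type <- match.arg(type)
  if (any(cutoff_hz <= 0) || any(cutoff_hz >= fs / 2)) {
    stop("cutoff frequencies must lie strictly inside (0, fs/2); got ",
         paste(cutoff_hz, collapse = ", "), " Hz at fs = ", fs, " Hz")
  }
  proto <- butter_prototype(n)
  w <- prewarp(cutoff_hz, fs)
  zpk <- if (type == "low") {
    stopifnot(length(cutoff_hz) == 1L)
    lp2lp_zpk(proto, w)
  } else {
    stopifnot(length(cutoff_hz) == 2L, cutoff_hz[1] < cutoff_hz[2])
    lp2bp_zpk(proto, w[1], w[2])
  }
  zpk2sos(bilinear_zpk(zpk, fs))
}

# Single-pass IIR filtering of one biquad section, vectorized through
# stats::filter (C implementation): MA part by convolution, AR part by the
# recursive filter.
biquad_filter <- function(b, a, x) {
  n <- length(x)
  xp <- c(0, 0, x)
  ma <- stats::filter(xp, b, method = "convolution", sides = 1)
  ma <- as.numeric(ma[3:(n + 2)])
  ar <- a[2:3]
  if (all(ar == 0)) return(ma)
  as.numeric(stats::filter(ma, -ar, method = "recursive"))
}

sosfilt <- function(sos, x) {
  for (i in seq_len(nrow(sos))) {
    x <- biquad_filter(sos[i, 1:3], sos[i, 4:6], x)
  }
  x
}

#' Zero-phase (forward-backward) filtering with odd-extension padding
#'
#' @param sos second-order sections from [butter_sos()].
#' @param x numeric signal.
#' @param padlen number of samples of odd extension at each end (clamped to
#'   `length(x) - 1`).
#' @keywords internal
filtfilt_sos <- function(sos, x, padlen = 3L * (2L * nrow(sos) + 1L)) {
  n <- length(x)
  if (n < 2L) stop("signal too short to filter (length ", n, ")")
  p <- min(as.integer(padlen), n - 1L)
  if (p > 0L) {
    head_ext <- 2 * x[1] - x[(p + 1L):2L]
    tail_ext <- 2 * x[n] - x[(n - 1L):(n - p)]
    xe <- c(head_ext, x, tail_ext)
  } else xe <- x
  y <- sosfilt(sos, xe)
  y <- rev(sosfilt(sos, rev(y)))
  if (p > 0L) y[(p + 1L):(p + n)] else y
}

#' Decimate a signal by an integer factor with an anti-aliasing filter
#'
#' An order-8 zero-phase Butterworth low-pass at 80% of the output Nyquist
#' precedes subsampling, so spectral content above the new Nyquist is
#' suppressed rather than aliased.
#'
#' @param x numeric signal.
#' @param q integer decimation factor.
#' @param fs input sampling rate in Hz.
#' @return numeric vector of length `ceiling(length(x)/q)`.
#' @keywords internal
decimate_signal <- function(x, q, fs) {
  q <- as.integer(q)
  stopifnot(q >= 1L)
  if (q == 1L) return(x)
  fs_out <- fs / q
  sos <- butter_sos(8L, 0.8 * fs_out / 2, fs, type = "low")
  y <- filtfilt_sos(sos, x, padlen = min(length(x) - 1L, 10L * q))
  y[seq(1L, length(y), by = q)]
}

#' Welch power spectral density of a single channel
#'
#' Averaged modified periodograms of Hamming-tapered, mean-detrended,
#' 50%-overlapping segments, each zero-padded to `nfft` points.  Returned as a
#' one-sided density in units of `x^2`/Hz (scaling `1/(fs * sum(w^2))`, with
#' interior bins doubled).
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param nfft FFT length (default 16384).
#' @param n_segments target segment count used to choose the segment length
#'   (`floor(2n/(k+1))` at 50% overlap); a single full-length segment is used
#'   when `n_segments = 1`.
#' @param nperseg explicit segment length, overriding `n_segments`.
#' @return list with `freqs_hz` and `power`.
#' @keywords internal
welch_psd_vector <- function(x, fs, nfft = 16384L, n_segments = 8L,
                             nperseg = NULL) {
  n <- length(x)
  stopifnot(n >= 2L, n_segments >= 1L)
  if (is.null(nperseg)) {
    nperseg <- if (n_segments == 1L) n else max(8L, floor(2 * n / (n_segments + 1)))
  }
  nperseg <- min(nperseg, n)
  if (nfft < nperseg) {
    stop("nfft (", nfft, ") must be >= segment length (", nperseg, ")")
  }
  step <- max(1L, floor(nperseg / 2))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1))
  scale <- 1 / (fs * sum(w^2))
  nbins <- nfft %/% 2L + 1L
  acc <- numeric(nbins)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    spec <- stats::fft(c(seg, numeric(nfft - nperseg)))[1:nbins]
    acc <- acc + Re(spec * Conj(spec))
  }
  pxx <- acc / length(starts) * scale
  # one-sided: double everything except DC (and Nyquist for even nfft)
  dbl <- rep(2, nbins)
  dbl[1] <- 1
  if (nfft %% 2L == 0L) dbl[nbins] <- 1
  list(freqs_hz = seq(0, nbins - 1) * fs / nfft, power = pxx * dbl)
}
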