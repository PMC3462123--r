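#' Design a digital Butterworth band-pass filter as second-order sections
#'
#' Poles of the analog Butterworth prototype are mapped through the standard
#' low-pass to band-pass transform with pre-warped edge frequencies and then
#' through the bilinear transform. The digital filter is returned as a cascade
#' of biquads (second-order sections), the numerically robust representation
#' for high-order narrow-band filters; each section carries a pair of zeros at
#' z = +1 and z = -1. The overall gain normalises the response to unity at the
#' geometric centre of the pass-band.
#'
#' @param order analog prototype order n (the digital band-pass has 2n poles).
#' @param f_lo,f_hi pass-band edges in Hz, 0 < f_lo < f_hi < fs/2.
#' @param fs sampling rate in samples/second.
#' @return an object of class `butter_sos`: list with `sos` (n x 6 matrix of
#'   b0 b1 b2 a0 a1 a2 rows, a0 = 1) and the design parameters.
#' @examples
#' bp <- butter_bandpass(8, 0.5, 30, fs = 256)
#' f <- seq(0, 60, by = 0.25)
#' H <- sos_freq_response(bp, f, fs = 256)
#' @export
butter_bandpass <- function(order, f_lo, f_hi, fs) {
  stopifnot(order >= 1, f_lo > 0, f_lo < f_hi, f_hi < fs / 2)
  n <- as.integer(order)
  k <- seq_len(n)
  # analog prototype poles on the unit circle, left half-plane
  p_proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # pre-warped analog band edges
  w1 <- 2 * fs * tan(pi * f_lo / fs)
  w2 <- 2 * fs * tan(pi * f_hi / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  # low-pass -> band-pass: each prototype pole p yields the two roots of
  # s^2 - p*bw*s + w0^2 = 0
  half <- p_proto * bw / 2
  disc <- sqrt(half^2 - w0^2)
  poles_a <- c(half + disc, half - disc)
  # bilinear transform
  poles_z <- (1 + poles_a / (2 * fs)) / (1 - poles_a / (2 * fs))

  sos <- pair_poles_to_sos(poles_z)
  # unity gain at the digital centre frequency
  obj <- list(sos = sos, gain = 1, order = n, f_lo = f_lo, f_hi = f_hi, fs = fs)
  class(obj) <- "butter_sos"
  fc <- sqrt(f_lo * f_hi)
  g <- Mod(sos_response_complex(obj, fc, fs))
  obj$gain <- 1 / g
  obj
}

# Group complex poles into conjugate-pair biquads; real poles are paired in
# order of decreasing magnitude. Each section gets zeros at z = +1 and z = -1
# (the band-pass zeros), i.e. numerator (1, 0, -1).
pair_poles_to_sos <- function(poles_z) {
  tol <- 1e-9
  cplx <- poles_z[Im(poles_z) > tol]
  real <- sort(Re(poles_z[abs(Im(poles_z)) <= tol]), decreasing = TRUE)
  secs <- list()
  for (p in cplx) {
    secs[[length(secs) + 1L]] <- c(1, 0, -1, 1, -2 * Re(p), Mod(p)^2)
  }
  if (length(real) %% 2L != 0L) {
    stop("internal error: odd number of real poles in band-pass design")
  }
  while (length(real) >= 2L) {
    p1 <- real[1]; p2 <- real[2]; real <- real[-(1:2)]
    secs[[length(secs) + 1L]] <- c(1, 0, -1, 1, -(p1 + p2), p1 * p2)
  }
  do.call(rbind, secs)
}

# Complex frequency response of the cascade at frequencies f (Hz).
sos_response_complex <- function(filt, f, fs) {
  z1 <- exp(-1i * 2 * pi * f / fs)   # z^-1
  H <- rep(filt$gain + 0i, length(f))
  for (s in seq_len(nrow(filt$sos))) {
    b <- filt$sos[s, 1:3]; a <- filt$sos[s, 4:6]
    H <- H * (b[1] + b[2] * z1 + b[3] * z1^2) / (a[1] + a[2] * z1 + a[3] * z1^2)
  }
  H
}

#' Magnitude response of a second-order-section filter
#'
#' @param filt a `butter_sos` object.
#' @param f frequencies in Hz.
#' @param fs sampling rate in samples/second.
#' @return magnitude |H(f)|, same length as `f`.
#' @export
sos_freq_response <- function(filt, f, fs = filt$fs) {
  Mod(sos_response_complex(filt, f, fs))
}

#' Apply a second-order-section filter causally (forward, zero initial state)
#'
#' Columns of a matrix are filtered independently, which is how per-epoch
#' filtering of many epochs is vectorised. The recursion runs through
#' [stats::filter()] so the per-sample loop is in C.
#'
#' @param x numeric vector, or matrix with one signal per column.
#' @param filt a `butter_sos` object.
#' @return filtered signal, same shape as `x`.
#' @export
sos_filter <- function(x, filt) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(as.numeric(x), ncol = 1L) else x
  if (nrow(m) == 0L) return(x)
  y <- sosfilt_cpp(m, filt$sos, filt$gain)
  if (vec) as.numeric(y) else y
}

#' Zero-phase forward-backward second-order-section filtering
#'
#' Filters forward and then backward so the pass-band phase is zero and the
#' start-up transient does not bias per-window amplitude statistics. Edge
#' effects are suppressed by odd-reflection padding of `pad` samples at each
#' end before filtering (the padding is discarded afterwards).
#'
#' @param x numeric vector or matrix (signals in columns).
#' @param filt a `butter_sos` object.
#' @param pad padding length in samples; defaults to min(3 x fs / f_lo, n-1).
#' @return filtered signal, same shape as `x`.
#' @export
sos_filtfilt <- function(x, filt, pad = NULL) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(as.numeric(x), ncol = 1) else x
  nr <- nrow(m)
  if (nr == 0L) return(x)
  if (is.null(pad)) pad <- min(nr - 1L, ceiling(3 * filt$fs / filt$f_lo))
  pad <- as.integer(max(0L, min(pad, nr - 1L)))
  if (pad > 0L) {
    top <- 2 * m[rep(1L, pad), , drop = FALSE] - m[(pad + 1L):2L, , drop = FALSE]
    bot <- 2 * m[rep(nr, pad), , drop = FALSE] - m[(nr - 1L):(nr - pad), , drop = FALSE]
    m <- rbind(top, m, bot)
  }
  y <- sos_filter(m, filt)
  y <- sos_filter(y[nrow(y):1L, , drop = FALSE], filt)
  y <- y[nrow(y):1L, , drop = FALSE]
  if (pad > 0L) y <- y[(pad + 1L):(pad + nr), , drop = FALSE]
  if (vec) as.numeric(y) else y
}
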