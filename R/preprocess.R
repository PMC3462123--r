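#' Resample a signal to 256 samples/second
#'
#' Band-limited (FFT) resampling: the spectrum is truncated at the output
#' Nyquist and inverse-transformed on the new grid, so pass-band content below
#' 30 Hz is preserved to well within 1 % amplitude. Only down-sampling is
#' supported (fs_in >= 256); fs_in = 256 is an identity path.
#'
#' @param x numeric signal.
#' @param fs_in input sampling rate in samples/second.
#' @return numeric signal at 256 samples/second, duration preserved to within
#'   one sample.
#' @export
resample_to_256 <- function(x, fs_in) {
  if (fs_in < 256) stop("fs_in must be >= 256 (upsampling unsupported)")
  if (fs_in == 256) return(x)
  n_in <- length(x)
  if (n_in == 0L) return(x)
  n_out <- round(n_in * 256 / fs_in)
  resample_fft(x, n_out)
}

# FFT resampling of x to n_out samples (n_out <= length(x)).
resample_fft <- function(x, n_out) {
  n_in <- length(x)
  X <- stats::fft(x)
  Y <- complex(n_out)
  Y[1] <- X[1]
  K <- (n_out - 1L) %/% 2L
  if (K >= 1) {
    k <- seq_len(K)
    Y[k + 1] <- X[k + 1]
    Y[n_out - k + 1] <- X[n_in - k + 1]
  }
  if (n_out %% 2L == 0L) {
    h <- n_out %/% 2L       # shared Nyquist bin: fold the symmetric pair
    Y[h + 1] <- X[h + 1] + X[n_in - h + 1]
  }
  Re(stats::fft(Y, inverse = TRUE)) / n_in
}

#' Band-pass filter a channel by its physiological role
#'
#' EEG and EOG get the 0.5-30 Hz eighth-order Butterworth band-pass; EMG gets
#' 5-100 Hz, also eighth order (at 256 samples/second the 100 Hz upper edge is
#' below the 128 Hz Nyquist, so no clipping is needed). Filtering is causal
#' (forward only) by default, matching an online-capable system; set
#' `zero_phase = TRUE` for forward-backward filtering.
#'
#' @param x numeric signal at 256 samples/second.
#' @param role one of "EEG", "EOG", "EMG".
#' @param fs sampling rate (must match the 256 Hz pipeline default).
#' @param zero_phase use zero-phase forward-backward filtering.
#' @return filtered signal, same length.
#' @export
filter_channel <- function(x, role = c("EEG", "EOG", "EMG"), fs = 256,
                           zero_phase = FALSE) {
  role <- match.arg(role)
  filt <- channel_filter(role, fs)
  if (zero_phase) sos_filtfilt(x, filt) else sos_filter(x, filt)
}

# filter design cache (designs are deterministic; avoid redoing root-finding)
.filter_cache <- new.env(parent = emptyenv())

channel_filter <- function(role, fs = 256) {
  key <- paste0(role, "@", fs)
  if (is.null(.filter_cache[[key]])) {
    .filter_cache[[key]] <- switch(role,
      EEG = butter_bandpass(8, 0.5, 30, fs),
      EOG = butter_bandpass(8, 0.5, 30, fs),
      EMG = butter_bandpass(8, 5, min(100, 0.99 * fs / 2), fs),
      stop("unknown channel role: ", role))
  }
  .filter_cache[[key]]
}

feature_filter <- function(name, fs = 256) {
  key <- paste0(name, "@", fs)
  if (is.null(.filter_cache[[key]])) {
    .filter_cache[[key]] <- switch(name,
      alpha = butter_bandpass(8, 8, 13, fs),
      beta  = butter_bandpass(8, 22, 30, fs),
      sigma = butter_bandpass(8, 12, 15, fs),
      delta = butter_bandpass(3, 0.5, 2, fs),
      stop("unknown feature filter: ", name))
  }
  .filter_cache[[key]]
}

#' Condition a raw PSG recording (resample then filter all channels)
#'
#' @param rec a `psg_recording` at any supported rate.
#' @param zero_phase passed to [filter_channel()].
#' @return a `psg_recording` at 256 samples/second with filtered channels.
#' @export
preprocess_recording <- function(rec, zero_phase = FALSE) {
  eeg <- resample_to_256(rec$eeg, rec$fs)
  eog <- resample_to_256(rec$eog, rec$fs)
  emg <- resample_to_256(rec$emg, rec$fs)
  new_psg_recording(
    filter_channel(eeg, "EEG", zero_phase = zero_phase),
    filter_channel(eog, "EOG", zero_phase = zero_phase),
    filter_channel(emg, "EMG", zero_phase = zero_phase),
    fs = 256, subject_id = rec$subject_id)
}

#' Segment a 256 Hz recording into 30-s epochs
#'
#' @param rec a `psg_recording` at 256 samples/second.
#' @return list of `epoch_signals` (eeg/eog/emg of 7680 samples each plus a
#'   0-based `epoch_index`); a trailing partial epoch is discarded and a
#'   recording shorter than one epoch yields an empty list.
#' @export
segment_epochs <- function(rec) {
  stopifnot(rec$fs == 256)
  n <- 7680L
  n_ep <- length(rec$eeg) %/% n
  lapply(seq_len(n_ep), function(e) {
    i <- ((e - 1L) * n + 1L):(e * n)
    structure(list(eeg = rec$eeg[i], eog = rec$eog[i], emg = rec$emg[i],
                   epoch_index = e - 1L),
              class = "epoch_signals")
  })
}

#' Averaged power spectrum of one 30-s epoch
#'
#' The 7680-sample channel is cut into fifteen non-overlapping 512-sample
#' (2-s) windows; each window's 512-point FFT power spectrum is computed and
#' the fifteen spectra are averaged arithmetically. No taper is applied.
#' Power is kept on a linear scale (see the package vignette on why ratios
#' and spectral means require linear power).
#'
#' @param epoch an `epoch_signals` object (or a bare 7680-sample vector).
#' @param channel which channel ("EEG", "EOG", "EMG") when `epoch` is an
#'   `epoch_signals`.
#' @return an `epoch_spectrum`: list with `power` (257 bins), `freq`
#'   (0 to 128 Hz in 0.5 Hz steps) and `channel`.
#' @export
epoch_spectrum <- function(epoch, channel = "EEG") {
  x <- if (inherits(epoch, "epoch_signals")) {
    epoch[[tolower(channel)]]
  } else as.numeric(epoch)
  if (length(x) != 7680L) stop("epoch_spectrum expects 7680 samples (30 s at 256 Hz)")
  pw <- window_power_matrix(matrix(x, ncol = 1), 512L)  # 257 x 15
  structure(list(power = rowMeans(pw), freq = seq(0, 128, by = 0.5),
                 channel = channel),
            class = "epoch_spectrum")
}

# Split the columns of m (signal per column, nrow divisible by win) into
# windows of length win and return |FFT|^2 of every window: a
# (win/2 + 1) x (ncol(m) * nrow(m)/win) matrix, windows of column 1 first.
window_power_matrix <- function(m, win) {
  stopifnot(nrow(m) %% win == 0)
  w <- matrix(as.numeric(m), nrow = win)
  P <- Mod(stats::mvfft(w))^2
  P[seq_len(win %/% 2L + 1L), , drop = FALSE]
}

#' Movement-epoch detection
#'
#' An epoch is flagged as movement when the EEG amplitude exceeds 200 uV
#' anywhere in the epoch (strict inequality).
#'
#' @param epoch an `epoch_signals` object or numeric EEG vector.
#' @return logical.
#' @export
detect_movement <- function(epoch) {
  x <- if (inherits(epoch, "epoch_signals")) epoch$eeg else as.numeric(epoch)
  if (length(x) == 0L) return(FALSE)
  max(abs(x)) > 200
}
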