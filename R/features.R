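#' @name features
#' @title The thirteen sleep-scoring features
#'
#' @description
#' Each 30-s epoch is summarised by 13 real-valued features, in fixed order:
#' EEG total power (0-30 Hz); EMG total power (0-30 Hz); EEG power ratios
#' 0-4, 4-8, 8-13 and 22-30 Hz (each relative to 0-30 Hz); EOG power ratio
#' 0-4 Hz; EEG and EMG mean spectral frequency; alpha, spindle and slow-wave
#' duration ratios; and EMG mean absolute amplitude. Spectral features come
#' from the averaged 2-s/512-point epoch spectrum; duration ratios count 1-s
#' windows that satisfy a band-specific amplitude or power criterion.
NULL

feature_names <- function() {
  c("eeg_total_power", "emg_total_power",
    "eeg_pr_0_4", "eeg_pr_4_8", "eeg_pr_8_13", "eeg_pr_22_30",
    "eog_pr_0_4", "eeg_sf", "emg_sf",
    "alpha_ratio", "spindle_ratio", "sws_ratio", "emg_energy")
}

# Band bin-selection convention: a band [lo, hi) by bin centre frequency,
# except that the terminal 30 Hz edge is inclusive (so the 0-30 Hz total has
# 61 bins at 0.5 Hz resolution and the whole-band ratio is exactly 1).
band_bins <- function(freq, lo, hi) {
  freq >= lo & (freq < hi | (hi == 30 & freq == 30))
}

#' Total spectral power over 0-30 Hz
#'
#' @param spectrum an `epoch_spectrum` (or list with `power` and `freq`).
#' @return sum of per-bin power over the 0-30 Hz band (30 Hz inclusive).
#' @export
total_power <- function(spectrum) {
  sum(spectrum$power[band_bins(spectrum$freq, 0, 30)])
}

#' Band power ratio relative to the 0-30 Hz total
#'
#' @param spectrum an `epoch_spectrum`.
#' @param band_low,band_high band edges in Hz, 0 <= band_low < band_high <= 30.
#' @return band power / total power, in `[0, 1]`; 0 when the total is 0.
#' @export
power_ratio <- function(spectrum, band_low, band_high) {
  if (!(band_low >= 0 && band_low < band_high && band_high <= 30))
    stop("invalid band: need 0 <= band_low < band_high <= 30")
  tot <- total_power(spectrum)
  if (tot == 0) return(0)
  sum(spectrum$power[band_bins(spectrum$freq, band_low, band_high)]) / tot
}

#' Mean spectral frequency over 0-30 Hz
#'
#' Power-weighted mean of the bin frequencies; 0 when total power is 0.
#'
#' @param spectrum an `epoch_spectrum`.
#' @return frequency in Hz.
#' @export
spectral_frequency <- function(spectrum) {
  b <- band_bins(spectrum$freq, 0, 30)
  tot <- sum(spectrum$power[b])
  if (tot == 0) return(0)
  sum(spectrum$freq[b] * spectrum$power[b]) / tot
}

get_channel <- function(epoch, channel) {
  if (inherits(epoch, "epoch_signals")) {
    x <- epoch[[tolower(channel)]]
    if (is.null(x)) stop("missing channel: ", channel)
    x
  } else as.numeric(epoch)
}

# Squared magnitude response of a Butterworth filter on the n-point DFT grid
# (symmetric about Nyquist). Multiplying a spectrum by this and inverting is
# exact zero-phase (forward-backward) Butterworth filtering under circular
# extension -- the batched equivalent of sos_filtfilt, without its cost.
zero_phase_gain2 <- function(name, n, fs = 256) {
  key <- paste0("zp_", name, "@", n, "@", fs)
  if (is.null(.filter_cache[[key]])) {
    f <- (seq_len(n) - 1) * fs / n
    f <- pmin(f, fs - f)
    .filter_cache[[key]] <- sos_freq_response(feature_filter(name, fs), f, fs)^2
  }
  .filter_cache[[key]]
}

# zero-phase filter all epoch columns given their forward DFT `Fm`
apply_gain2 <- function(Fm, g2) {
  Re(stats::mvfft(Fm * g2, inverse = TRUE)) / nrow(Fm)
}

#' Alpha duration ratio of an epoch
#'
#' The EEG is passed through 8-13 Hz and 22-30 Hz eighth-order Butterworth
#' band-passes (zero-phase); the two filtered signals are summed and the epoch
#' is divided into 1-s windows. A window counts as an alpha window when the
#' RMS of the combined signal exceeds 0.5 times the RMS of the broadband
#' input in that window; windows with zero broadband RMS never count.
#'
#' @param epoch an `epoch_signals` or a 7680-sample EEG vector.
#' @return fraction of alpha windows, in `[0, 1]`.
#' @export
alpha_ratio <- function(epoch) {
  x <- get_channel(epoch, "EEG")
  as.numeric(batch_alpha_ratio(matrix(x, ncol = 1)))
}

#' Spindle duration ratio of an epoch
#'
#' A 1-s window is a spindle window when (a) its sigma-band (12-15 Hz) power
#' exceeds half of its 0-30 Hz power, and (b) the peak amplitude of the
#' 12-15 Hz filtered signal in the window exceeds twice the epoch-median
#' window peak (the "large, sudden amplitude change" test, which rejects
#' steady sigma-band activity).
#'
#' @param epoch an `epoch_signals` or a 7680-sample EEG vector.
#' @return fraction of spindle windows, in `[0, 1]`.
#' @export
spindle_ratio <- function(epoch) {
  x <- get_channel(epoch, "EEG")
  as.numeric(batch_spindle_ratio(matrix(x, ncol = 1)))
}

#' Slow-wave duration ratio of an epoch
#'
#' The EEG is filtered 0.5-2 Hz with a third-order Butterworth band-pass
#' (zero-phase); a 1-s window is a slow-wave window when its peak absolute
#' filtered amplitude exceeds 75 uV (the high-voltage delta criterion).
#'
#' @param epoch an `epoch_signals` or a 7680-sample EEG vector.
#' @return fraction of slow-wave windows, in `[0, 1]`.
#' @export
sws_ratio <- function(epoch) {
  x <- get_channel(epoch, "EEG")
  as.numeric(batch_sws_ratio(matrix(x, ncol = 1)))
}

#' EMG energy: mean absolute amplitude over the epoch
#'
#' @param epoch an `epoch_signals` or an EMG vector.
#' @return mean of `abs(x)` in uV.
#' @export
emg_energy <- function(epoch) {
  x <- get_channel(epoch, "EMG")
  if (length(x) == 0L) return(0)
  mean(abs(x))
}

#' Extract the 13-feature vector of one epoch
#'
#' @param epoch an `epoch_signals` with eeg, eog and emg channels.
#' @return named numeric vector of length 13 in canonical feature order.
#' @export
extract_features <- function(epoch) {
  for (ch in c("eeg", "eog", "emg")) {
    if (is.null(epoch[[ch]])) stop("missing channel: ", toupper(ch))
  }
  extract_features_matrix(matrix(epoch$eeg, ncol = 1),
                          matrix(epoch$eog, ncol = 1),
                          matrix(epoch$emg, ncol = 1))[1, ]
}

#' Extract features for every epoch of a preprocessed recording
#'
#' Vectorised across epochs (identical numerics to [extract_features()] on
#' each epoch, which the tests assert).
#'
#' @param rec a filtered `psg_recording` at 256 samples/second.
#' @return numeric matrix, one row per epoch, 13 named columns.
#' @export
featurize_recording <- function(rec) {
  stopifnot(rec$fs == 256)
  n <- 7680L
  n_ep <- length(rec$eeg) %/% n
  if (n_ep == 0L) {
    return(matrix(numeric(0), 0, 13, dimnames = list(NULL, feature_names())))
  }
  keep <- seq_len(n_ep * n)
  extract_features_matrix(matrix(rec$eeg[keep], nrow = n),
                          matrix(rec$eog[keep], nrow = n),
                          matrix(rec$emg[keep], nrow = n))
}

# ---- batched kernels (columns = epochs of 7680 samples) ---------------------

# averaged 512-point spectra for every epoch-column: 257 x n_ep
batch_epoch_spectra <- function(m) {
  P <- window_power_matrix(m, 512L)              # 257 x (15 * n_ep)
  n_ep <- ncol(m)
  A <- array(P, c(257L, 15L, n_ep))
  B <- aperm(A, c(2L, 1L, 3L))                   # 15 x 257 x n_ep
  matrix(colMeans(B), nrow = 257L)
}

col_max_abs <- function(m) {
  m <- abs(m)
  out <- m[1L, ]
  nr <- nrow(m)
  if (nr > 1L) for (i in 2:nr) out <- pmax(out, m[i, ])
  out
}

win_stat_per_epoch <- function(flag, n_ep) {
  colMeans(matrix(as.numeric(flag), nrow = 30L))
}

batch_alpha_ratio <- function(eeg, Fm = stats::mvfft(eeg)) {
  n <- nrow(eeg)
  comb <- apply_gain2(Fm, zero_phase_gain2("alpha", n) +
                          zero_phase_gain2("beta", n))
  rms_c <- sqrt(colMeans(matrix(comb, nrow = 256L)^2))
  rms_b <- sqrt(colMeans(matrix(eeg, nrow = 256L)^2))
  flag <- rms_b > 0 & rms_c > 0.5 * rms_b
  win_stat_per_epoch(flag, ncol(eeg))
}

batch_spindle_ratio <- function(eeg, Fm = stats::mvfft(eeg)) {
  n_ep <- ncol(eeg)
  Pw <- window_power_matrix(eeg, 256L)           # 129 x (30 * n_ep), 1 Hz bins
  fw <- 0:128
  sig <- colSums(Pw[band_bins(fw, 12, 15), , drop = FALSE])
  tot <- colSums(Pw[band_bins(fw, 0, 30), , drop = FALSE])
  frac_ok <- tot > 0 & sig > 0.5 * tot
  s <- apply_gain2(Fm, zero_phase_gain2("sigma", nrow(eeg)))
  wpk <- matrix(col_max_abs(matrix(s, nrow = 256L)), nrow = 30L)  # 30 x n_ep
  med <- apply(wpk, 2L, stats::median)
  burst_ok <- wpk > 2 * rep(med, each = 30L)
  win_stat_per_epoch(frac_ok & as.vector(burst_ok), n_ep)
}

batch_sws_ratio <- function(eeg, Fm = stats::mvfft(eeg)) {
  s <- apply_gain2(Fm, zero_phase_gain2("delta", nrow(eeg)))
  wpk <- col_max_abs(matrix(s, nrow = 256L))
  win_stat_per_epoch(wpk > 75, ncol(eeg))
}

extract_features_matrix <- function(eeg, eog, emg) {
  stopifnot(nrow(eeg) == 7680L, all(dim(eog) == dim(eeg)), all(dim(emg) == dim(eeg)))
  n_ep <- ncol(eeg)
  freq <- seq(0, 128, by = 0.5)
  b_tot <- band_bins(freq, 0, 30)
  Pe <- batch_epoch_spectra(eeg)
  Po <- batch_epoch_spectra(eog)
  Pm <- batch_epoch_spectra(emg)
  Fe <- stats::mvfft(eeg)                        # shared by the duration ratios
  tp_e <- colSums(Pe[b_tot, , drop = FALSE])
  tp_o <- colSums(Po[b_tot, , drop = FALSE])
  tp_m <- colSums(Pm[b_tot, , drop = FALSE])
  pr <- function(P, tp, lo, hi) {
    num <- colSums(P[band_bins(freq, lo, hi), , drop = FALSE])
    ifelse(tp > 0, num / tp, 0)
  }
  sf <- function(P, tp) {
    num <- colSums(P[b_tot, , drop = FALSE] * freq[b_tot])
    ifelse(tp > 0, num / tp, 0)
  }
  out <- cbind(
    eeg_total_power = tp_e,
    emg_total_power = tp_m,
    eeg_pr_0_4   = pr(Pe, tp_e, 0, 4),
    eeg_pr_4_8   = pr(Pe, tp_e, 4, 8),
    eeg_pr_8_13  = pr(Pe, tp_e, 8, 13),
    eeg_pr_22_30 = pr(Pe, tp_e, 22, 30),
    eog_pr_0_4   = pr(Po, tp_o, 0, 4),
    eeg_sf = sf(Pe, tp_e),
    emg_sf = sf(Pm, tp_m),
    alpha_ratio   = batch_alpha_ratio(eeg, Fe),
    spindle_ratio = batch_spindle_ratio(eeg, Fe),
    sws_ratio     = batch_sws_ratio(eeg, Fe),
    emg_energy    = colMeans(abs(emg))
  )
  rownames(out) <- NULL
  out
}
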