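#' Default per-stage signal parameters for the synthetic PSG generator
#'
#' One row per stage; amplitudes in uV. The values encode the visual-scoring
#' criteria the feature set targets: Wake is alpha-dominant with high tonic
#' EMG and visible beta; S1 is low-voltage theta with slow rolling eye
#' movements; S2 is theta with sleep-spindle bursts; SWS is dominated by
#' high-voltage (> 75 uV) sub-2 Hz delta; REM is low-voltage mixed frequency
#' with rapid eye movements and the lowest chin EMG. `Mov` (if requested from
#' [synthesize_epoch()]) is a high-amplitude artifact exceeding the 200 uV
#' movement threshold. Amplitudes are spaced so that between-stage feature
#' differences exceed 2 pooled standard deviations (the separability the
#' end-to-end tests rely on); they are a stated world, not tuning knobs.
#'
#' @return data.frame with one row per stage and the amplitude/rate columns.
#' @export
default_stage_params <- function() {
  p <- data.frame(
    stage        = c("Wake", "S1", "S2", "SWS", "REM", "Mov"),
    delta        = c(5,  10, 25, 90,  6, 250),
    theta        = c(5,  25, 20, 10, 12, 30),
    alpha        = c(30,  8,  5,  3,  6, 10),
    sigma        = c(0,   0,  0,  0,  0, 0),   # tonic sigma; spindles are bursts
    beta         = c(10,  3,  2,  1,  6, 10),
    spindle_amp  = c(0,   0, 40,  0,  0, 0),
    spindle_rate = c(0,   0,  3,  0,  0, 0),   # bursts per 30-s epoch
    eog_slow     = c(3,  40,  5,  5,  5, 10),
    eog_rapid    = c(0,   0,  0,  0, 60, 0),
    emg          = c(30, 15, 10,  8,  3, 60),
    noise        = c(5,   5,  5,  5,  5, 10),
    stringsAsFactors = FALSE
  )
  rownames(p) <- p$stage
  p
}

#' Default stage-transition probabilities for hypnogram simulation
#'
#' A realistic overnight Markov chain on the five stages, consistent with the
#' default transition mask (zero on every disallowed cell): stages are sticky
#' (self-transition about 0.9 at the 30-s epoch scale), sleep onset passes
#' through S1, SWS is entered and left via S2.
#'
#' @return list with stochastic matrix `A`, initial distribution `pi` and the
#'   `mask` they respect.
#' @export
default_chain <- function() {
  labs <- stage_labels(FALSE)
  A <- matrix(0, 5, 5, dimnames = list(labs, labs))
  A["Wake", ] <- c(0.90, 0.10, 0,    0,    0)
  A["S1", ]   <- c(0.05, 0.70, 0.23, 0,    0.02)
  A["S2", ]   <- c(0.01, 0.03, 0.87, 0.06, 0.03)
  A["SWS", ]  <- c(0,    0,    0.10, 0.90, 0)
  A["REM", ]  <- c(0.02, 0.03, 0.05, 0,    0.90)
  list(A = A, pi = c(Wake = 0.8, S1 = 0.2, S2 = 0, SWS = 0, REM = 0),
       mask = default_transition_mask())
}

#' Simulate a hypnogram from a transition-constrained Markov chain
#'
#' @param A_true row-stochastic transition matrix over the stages.
#' @param pi_true initial stage distribution.
#' @param mask a `transition_mask`; `A_true` must be zero wherever the mask
#'   disallows, otherwise the pair is rejected naming the offending transition.
#' @param n_epochs number of 30-s epochs to draw.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return a `hypnogram`: character vector of stage labels with attributes
#'   `epoch_duration_s` (30) and `state_names`.
#' @export
generate_hypnogram <- function(A_true, pi_true, mask = default_transition_mask(),
                               n_epochs, seed = 1L) {
  N <- nrow(mask)
  stopifnot(nrow(A_true) == N, ncol(A_true) == N, length(pi_true) == N)
  if (any(abs(rowSums(A_true) - 1) > 1e-8)) stop("rows of A_true must sum to 1")
  if (abs(sum(pi_true) - 1) > 1e-8) stop("pi_true must sum to 1")
  bad <- which(!unclass(mask) & A_true > 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    labs <- rownames(mask)
    stop("A_true puts probability on a disallowed transition: ",
         labs[bad[1, 1]], " -> ", labs[bad[1, 2]])
  }
  labs <- rownames(mask)
  st <- integer(n_epochs)
  if (n_epochs > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    st[1] <- sample.int(N, 1, prob = pi_true)
    if (n_epochs > 1) {
      u <- stats::runif(n_epochs - 1)
      cums <- lapply(seq_len(N), function(i) cumsum(A_true[i, ]))
      for (t in 2:n_epochs) {
        st[t] <- findInterval(u[t - 1], cums[[st[t - 1]]], left.open = TRUE) + 1L
      }
    }
  }
  new_hypnogram(labs[st], state_names = labs)
}

new_hypnogram <- function(stages, state_names = stage_labels(any(stages == "Mov"))) {
  structure(as.character(stages), class = "hypnogram",
            epoch_duration_s = 30, state_names = state_names)
}

#' @export
print.hypnogram <- function(x, ...) {
  cat("Hypnogram:", length(x), "epochs of", attr(x, "epoch_duration_s"), "s\n")
  tb <- table(factor(unclass(x), levels = attr(x, "state_names")))
  print(tb)
  invisible(x)
}

# save/restore the RNG state so seeded generators do not disturb the caller
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

band_tone <- function(n, fs, amp, f_range) {
  if (amp <= 0) return(numeric(n))
  f <- stats::runif(1, f_range[1], f_range[2])
  ph <- stats::runif(1, 0, 2 * pi)
  amp * sin(2 * pi * f * seq_len(n) / fs + ph)
}

#' Synthesize one 30-s three-channel PSG epoch for a given stage
#'
#' EEG is a sum of band-limited oscillations (delta 0.75-1.6 Hz, theta 4-7.5,
#' alpha 8-13, beta 22-29) weighted by the stage row of `params`, plus, for
#' S2, amplitude-modulated 13.5 Hz spindle bursts of 0.5-1.5 s; EOG carries
#' slow (0.5-0.8 Hz) deflections in S1 and rapid (1.5-2.5 Hz) deflections in
#' REM; EMG is band-limited white noise at the stage's tonic level (lowest in
#' REM). Additive Gaussian noise on every channel. Deterministic given `seed`.
#'
#' @param stage one of the stage labels.
#' @param params per-stage parameter table as from [default_stage_params()].
#' @param fs sampling rate in samples/second (>= 200).
#' @param seed integer seed.
#' @return list with numeric `eeg`, `eog`, `emg` (each `30 * fs` samples, uV).
#' @export
synthesize_epoch <- function(stage, params = default_stage_params(), fs = 256,
                             seed = 1L) {
  if (fs < 200) stop("fs must be >= 200 samples/second")
  if (!stage %in% rownames(params)) stop("unknown stage label: ", stage)
  p <- params[stage, ]
  n <- as.integer(30 * fs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  # delta stays within 0.75-1.6 Hz, the flat region of the 0.5-2 Hz slow-wave
  # detector filter, so the >75 uV criterion is met by construction in SWS
  eeg <- band_tone(n, fs, p$delta, c(0.75, 1.6)) +
         band_tone(n, fs, p$theta, c(4, 7.5)) +
         band_tone(n, fs, p$alpha, c(8, 13)) +
         band_tone(n, fs, p$beta,  c(22, 29))
  if (p$spindle_amp > 0 && p$spindle_rate > 0) {
    n_burst <- stats::rpois(1, p$spindle_rate)
    t <- seq_len(n) / fs
    for (b in seq_len(n_burst)) {
      dur <- stats::runif(1, 0.5, 1.5)
      onset <- stats::runif(1, 0, 30 - dur)
      idx <- which(t >= onset & t < onset + dur)
      env <- sin(pi * (t[idx] - onset) / dur)^2       # Hann-like envelope
      eeg[idx] <- eeg[idx] + p$spindle_amp * env * sin(2 * pi * 13.5 * t[idx])
    }
  }
  eog <- band_tone(n, fs, p$eog_slow, c(0.5, 0.8)) +
         band_tone(n, fs, p$eog_rapid, c(1.5, 2.5)) +
         0.2 * eeg                                   # frontal EEG leak into EOG
  emg <- if (p$emg > 0) stats::rnorm(n, 0, p$emg) else numeric(n)
  if (p$noise > 0) {
    eeg <- eeg + stats::rnorm(n, 0, p$noise)
    eog <- eog + stats::rnorm(n, 0, p$noise)
  }
  list(eeg = eeg, eog = eog, emg = emg)
}

#' Render a hypnogram into a continuous synthetic PSG recording
#'
#' Concatenates per-epoch segments from [synthesize_epoch()]; epoch seeds are
#' derived from `seed` so the whole recording is reproducible.
#'
#' @param hypnogram a `hypnogram` (nonempty).
#' @param params per-stage parameters ([default_stage_params()]).
#' @param fs sampling rate in samples/second.
#' @param seed integer seed.
#' @param subject_id identifier stored on the recording.
#' @return a `psg_recording`: list with `eeg`, `eog`, `emg` (uV), `fs`,
#'   `subject_id`.
#' @export
generate_recording <- function(hypnogram, params = default_stage_params(),
                               fs = 256, seed = 1L, subject_id = "synthetic") {
  n_ep <- length(hypnogram)
  if (n_ep == 0) stop("hypnogram must be nonempty")
  n <- as.integer(30 * fs)
  eeg <- numeric(n_ep * n); eog <- numeric(n_ep * n); emg <- numeric(n_ep * n)
  # epoch seeds derived from the master seed, kept within 32-bit range
  ep_seed <- (as.double(seed) * 10007 + seq_len(n_ep) * 7919) %% 2147483647
  for (e in seq_len(n_ep)) {
    seg <- synthesize_epoch(unclass(hypnogram)[e], params, fs, seed = ep_seed[e])
    i <- ((e - 1L) * n + 1L):(e * n)
    eeg[i] <- seg$eeg; eog[i] <- seg$eog; emg[i] <- seg$emg
  }
  new_psg_recording(eeg, eog, emg, fs, subject_id)
}

new_psg_recording <- function(eeg, eog, emg, fs, subject_id = "unknown") {
  stopifnot(length(eeg) == length(eog), length(eeg) == length(emg), fs > 0)
  structure(list(eeg = eeg, eog = eog, emg = emg, fs = fs,
                 subject_id = subject_id),
            class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat(sprintf("PSG recording '%s': %d samples/channel at %g Hz (%.1f min)\n",
              x$subject_id, length(x$eeg), x$fs, length(x$eeg) / x$fs / 60))
  invisible(x)
}

#' Generate a cohort of synthetic subjects
#'
#' Convenience wrapper: for each subject draws a hypnogram from the default
#' (or supplied) chain and renders the recording.
#'
#' @param n_subjects number of subjects.
#' @param n_epochs epochs per subject (default 900, a full night).
#' @param fs sampling rate.
#' @param seed master seed; per-subject seeds are derived from it.
#' @param chain list(A, pi, mask) as from [default_chain()].
#' @param params stage parameter table.
#' @return list of `list(recording, hypnogram)` per subject.
#' @export
generate_cohort <- function(n_subjects, n_epochs = 900, fs = 256, seed = 1L,
                            chain = default_chain(),
                            params = default_stage_params()) {
  lapply(seq_len(n_subjects), function(s) {
    s_seed <- (as.double(seed) * 104729 + s * 1299709) %% 2147483647
    hyp <- generate_hypnogram(chain$A, chain$pi, chain$mask, n_epochs,
                              seed = s_seed)
    rec <- generate_recording(hyp, params, fs, seed = s_seed + 1,
                              subject_id = sprintf("synth%02d", s))
    list(recording = rec, hypnogram = hyp)
  })
}
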