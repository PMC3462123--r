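test_that("spectral features match direct-summation oracles", {
  set.seed(21)
  for (rep in 1:5) {
    spec <- list(power = stats::runif(257), freq = seq(0, 128, by = 0.5))
    expect_equal(total_power(spec), oracle_band_sum(spec, 0, 30),
                 tolerance = 1e-12)
    for (band in list(c(0, 4), c(4, 8), c(8, 13), c(22, 30))) {
      expect_equal(power_ratio(spec, band[1], band[2]),
                   oracle_band_sum(spec, band[1], band[2]) /
                     oracle_band_sum(spec, 0, 30),
                   tolerance = 1e-12)
    }
    expect_equal(spectral_frequency(spec), oracle_spectral_frequency(spec),
                 tolerance = 1e-12)
  }
})

test_that("spectral features: closed-form and guard cases", {
  z <- list(power = numeric(257), freq = seq(0, 128, by = 0.5))
  expect_equal(total_power(z), 0)
  expect_equal(power_ratio(z, 0, 4), 0)
  expect_equal(spectral_frequency(z), 0)
  flat <- list(power = rep(1, 257), freq = seq(0, 128, by = 0.5))
  expect_equal(total_power(flat), 61)        # 61 half-Hz bins from 0 to 30
  expect_equal(power_ratio(flat, 0, 30), 1)  # whole-band identity
  expect_equal(power_ratio(flat, 0, 4), 8 / 61)
  pm <- z; pm$power[pm$freq == 10] <- 3
  expect_equal(spectral_frequency(pm), 10)
  sym <- z; sym$power[sym$freq %in% c(5, 15)] <- 2
  expect_equal(spectral_frequency(sym), 10)
  expect_error(power_ratio(flat, 8, 4), "band")
})

test_that("EEG power-ratio features over a 0-30 Hz partition sum to ~1", {
  set.seed(8)
  x <- rnorm(7680)
  spec <- epoch_spectrum(x)
  parts <- list(c(0, 4), c(4, 8), c(8, 13), c(13, 22), c(22, 30))
  s <- sum(vapply(parts, function(b) power_ratio(spec, b[1], b[2]), numeric(1)))
  # convention leaves at most the two seam bins unaccounted
  expect_lt(abs(s - 1), 2 * max(spec$power) / total_power(spec))
})

test_that("duration ratios: closed-form pure-tone and zero cases", {
  expect_equal(alpha_ratio(sine_epoch(10)), 1.0)
  expect_equal(alpha_ratio(sine_epoch(2)), 0.0)
  expect_equal(alpha_ratio(numeric(7680)), 0.0)
  expect_equal(sws_ratio(sine_epoch(1, 100)), 1.0)
  expect_equal(sws_ratio(sine_epoch(1, 50)), 0.0)
  expect_equal(sws_ratio(numeric(7680)), 0.0)
  # steady sigma tone: high sigma fraction but no sudden amplitude change
  expect_equal(spindle_ratio(sine_epoch(13.5, 30)), 0.0)
  expect_equal(spindle_ratio(numeric(7680)), 0.0)
})

test_that("spindle ratio counts burst windows", {
  # theta background with three 1-s spindle bursts at known onsets
  fs <- 256
  t <- seq_len(7680) / fs
  x <- 15 * sin(2 * pi * 5.3 * t)
  for (onset in c(4, 14, 24)) {
    idx <- which(t > onset & t <= onset + 1)
    env <- sin(pi * (t[idx] - onset))^2
    x[idx] <- x[idx] + 50 * env * sin(2 * pi * 13.5 * t[idx])
  }
  r <- spindle_ratio(x)
  expect_gte(r, 2 / 30); expect_lte(r, 4 / 30)
})

test_that("EMG energy is the mean absolute amplitude", {
  expect_equal(emg_energy(rep(5, 7680)), 5)
  expect_equal(emg_energy(rep(c(3, -3), 3840)), 3)
  set.seed(33)
  sigma <- 10
  x <- rnorm(7680, 0, sigma)
  se <- sigma * sqrt(1 - 2 / pi) / sqrt(7680)
  expect_lt(abs(emg_energy(x) - sigma * sqrt(2 / pi)), 3 * se)
})

test_that("the 13-feature vector has the documented layout and invariants", {
  z <- make_epoch()
  expect_equal(unname(extract_features(z)), numeric(13))
  expect_error(extract_features(structure(list(eeg = numeric(7680)),
                                          class = "epoch_signals")),
               "missing channel")
  ep <- synthesize_epoch("Wake", fs = 256, seed = 9)
  fv <- extract_features(make_epoch(ep$eeg, ep$eog, ep$emg))
  expect_named(fv, c("eeg_total_power", "emg_total_power", "eeg_pr_0_4",
                     "eeg_pr_4_8", "eeg_pr_8_13", "eeg_pr_22_30",
                     "eog_pr_0_4", "eeg_sf", "emg_sf", "alpha_ratio",
                     "spindle_ratio", "sws_ratio", "emg_energy"))
  # Wake: the alpha power ratio dominates the four EEG PR features
  expect_equal(which.max(fv[3:6]), c(eeg_pr_8_13 = 3L))
  # ratio-type features live in [0, 1]
  expect_true(all(fv[c(3:7, 10:12)] >= 0 & fv[c(3:7, 10:12)] <= 1))
  # consistency under duplication: features of an epoch equal those computed
  # batched together with a copy of itself
  two <- extract_features_matrix(cbind(ep$eeg, ep$eeg), cbind(ep$eog, ep$eog),
                                 cbind(ep$emg, ep$emg))
  expect_equal(two[1, ], two[2, ])
  expect_equal(two[1, ], fv)
})

test_that("batched featurization equals per-epoch extraction", {
  h <- generate_hypnogram(default_chain()$A, default_chain()$pi,
                          default_chain()$mask, 6, seed = 44)
  rec <- preprocess_recording(generate_recording(h, fs = 256, seed = 44))
  fm <- featurize_recording(rec)
  eps <- segment_epochs(rec)
  for (e in c(1, 4, 6)) {
    expect_equal(fm[e, ], extract_features(eps[[e]]))
  }
})
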