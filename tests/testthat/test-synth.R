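chain <- default_chain()

test_that("hypnogram generation: edge cases and mask consistency", {
  h0 <- generate_hypnogram(chain$A, chain$pi, chain$mask, 0, seed = 1)
  expect_length(h0, 0)
  # absorbing chain stays put
  A <- diag(5); dimnames(A) <- dimnames(chain$A)
  h <- generate_hypnogram(A, c(1, 0, 0, 0, 0), chain$mask, 10, seed = 3)
  expect_equal(unclass(h), rep("Wake", 10), ignore_attr = TRUE)
  # probability on a disallowed transition is rejected, naming the pair
  bad <- chain$A
  bad["Wake", "SWS"] <- 0.1; bad["Wake", "Wake"] <- bad["Wake", "Wake"] - 0.1
  expect_error(generate_hypnogram(bad, chain$pi, chain$mask, 5, seed = 1),
               "Wake -> SWS")
  expect_error(generate_hypnogram(chain$A, c(0.5, 0.5, 0.5, 0, 0),
                                  chain$mask, 5, seed = 1), "sum to 1")
})

test_that("sampled chains reproduce A_true and its stationary distribution", {
  n <- 100000
  h <- generate_hypnogram(chain$A, chain$pi, chain$mask, n, seed = 99)
  st <- stage_index(unclass(h))
  from <- st[-n]; to <- st[-1]
  # no masked transition ever appears
  expect_true(all(unclass(chain$mask)[cbind(from, to)]))
  # per-cell empirical frequencies within 3 standard errors
  for (i in 1:5) {
    ni <- sum(from == i)
    for (j in 1:5) {
      p <- chain$A[i, j]
      phat <- sum(from == i & to == j) / ni
      se <- sqrt(p * (1 - p) / ni)
      expect_lte(abs(phat - p), max(3 * se, 1e-12))
    }
  }
  # long-run frequencies converge to the stationary distribution (TV < 0.02)
  ev <- eigen(t(chain$A))
  statd <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  statd <- statd / sum(statd)
  emp <- tabulate(st, 5) / n
  expect_lt(sum(abs(emp - statd)) / 2, 0.02)
})

test_that("synthesized epochs meet the per-stage scoring criteria", {
  # SWS: > 50% of 1-s windows with a 0.5-2 Hz component above 75 uV peak
  for (seed in 1:3) {
    ep <- synthesize_epoch("SWS", fs = 256, seed = seed)
    expect_gt(sws_ratio(ep$eeg), 0.5)
  }
  # Wake: alpha band power exceeds delta band power
  spec <- epoch_spectrum(synthesize_epoch("Wake", fs = 256, seed = 5)$eeg)
  expect_gt(oracle_band_sum(spec, 8, 13), oracle_band_sum(spec, 0.5, 4))
  # null parameters give a silent epoch
  p0 <- default_stage_params()
  p0[, !(colnames(p0) %in% "stage")] <- 0
  ep0 <- synthesize_epoch("S2", params = p0, fs = 256, seed = 1)
  expect_equal(ep0$eeg, numeric(7680))
  expect_equal(ep0$emg, numeric(7680))
  expect_error(synthesize_epoch("NotAStage"), "unknown stage")
  expect_error(synthesize_epoch("Wake", fs = 100), "fs")
  # determinism given seed
  a <- synthesize_epoch("S2", fs = 256, seed = 7)
  b <- synthesize_epoch("S2", fs = 256, seed = 7)
  expect_identical(a, b)
})

test_that("recordings concatenate epochs and keep per-stage band ordering", {
  h <- generate_hypnogram(chain$A, chain$pi, chain$mask, 4, seed = 2)
  rec <- generate_recording(h, fs = 256, seed = 10)
  expect_length(rec$eeg, 4 * 30 * 256)
  # single-epoch hypnogram reproduces synthesize_epoch modulo the seed schedule
  h1 <- new_hypnogram("SWS")
  r1 <- generate_recording(h1, fs = 256, seed = 3)
  expect_length(r1$eeg, 7680)
  expect_gt(sws_ratio(r1$eeg), 0.5)
  # different seeds: different samples, same dominant-band structure per stage
  hh <- new_hypnogram(c("Wake", "SWS"))
  ra <- generate_recording(hh, fs = 256, seed = 1)
  rb <- generate_recording(hh, fs = 256, seed = 2)
  expect_false(isTRUE(all.equal(ra$eeg, rb$eeg)))
  for (r in list(ra, rb)) {
    s_wake <- epoch_spectrum(r$eeg[1:7680])
    s_sws <- epoch_spectrum(r$eeg[7681:15360])
    expect_gt(oracle_band_sum(s_wake, 8, 13), oracle_band_sum(s_wake, 0.5, 4))
    expect_gt(oracle_band_sum(s_sws, 0.5, 4), oracle_band_sum(s_sws, 8, 13))
  }
})

test_that("stages are separable in feature space (> 2 pooled SD somewhere)", {
  reps <- 12
  labs <- stage_labels()
  feats <- lapply(labs, function(stg) {
    do.call(rbind, lapply(seq_len(reps), function(s) {
      ep <- synthesize_epoch(stg, fs = 256, seed = 1000 + 37 * s + match(stg, labs))
      extract_features(make_epoch(ep$eeg, ep$eog, ep$emg))
    }))
  })
  names(feats) <- labs
  for (i in 1:4) for (j in (i + 1):5) {
    mi <- colMeans(feats[[i]]); mj <- colMeans(feats[[j]])
    vi <- apply(feats[[i]], 2, var); vj <- apply(feats[[j]], 2, var)
    pooled <- sqrt((vi + vj) / 2)
    d <- abs(mi - mj) / pmax(pooled, 1e-12)
    expect_gt(max(d), 2)
  }
})
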