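five <- default_transition_mask()

test_that("model construction validates its invariants", {
  m <- random_dhmm(5, 10, five, seed = 1)
  expect_equal(rowSums(m$A), rep(1, 5), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(rowSums(m$B), rep(1, 5), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(sum(m$pi), 1, tolerance = 1e-12)
  expect_true(all(m$A[!unclass(five)] == 0))
  A <- m$A; A["Wake", "SWS"] <- 0.1
  expect_error(dhmm_model(A, m$B, m$pi, five), "masked|sum")
})

test_that("closed-form likelihoods: T = 1 and deterministic chains", {
  m <- random_dhmm(3, 4, seed = 2)
  o1 <- 3L
  expect_equal(likelihood_bruteforce(m, o1), sum(m$pi * m$B[, 3]))
  expect_equal(exp(forward_dhmm(m, o1)$loglik), sum(m$pi * m$B[, 3]))
  # fully deterministic model: probability 1 for the consistent sequence
  A <- rbind(c(0, 1), c(1, 0)); B <- rbind(c(1, 0), c(0, 1))
  dm <- dhmm_model(A, B, c(1, 0))
  expect_equal(likelihood_bruteforce(dm, c(1L, 2L, 1L)), 1)
  expect_equal(likelihood_bruteforce(dm, c(1L, 1L)), 0)
  expect_equal(forward_dhmm(dm, c(1L, 2L, 1L))$loglik, 0)
  expect_equal(forward_dhmm(dm, c(1L, 1L))$loglik, -Inf)
  expect_equal(viterbi(dm, c(1L, 2L, 1L))$path, c(1L, 2L, 1L))
  expect_error(forward_dhmm(m, c(1L, 9L)), "out of range")
  expect_error(likelihood_bruteforce(random_dhmm(3, 3), rep(1L, 12)), "guard")
})

test_that("vectorized enumeration agrees with independent recursion", {
  set.seed(77)
  for (trial in 1:10) {
    N <- sample(2:3, 1); M <- sample(2:4, 1); T_ <- sample(1:5, 1)
    m <- random_dhmm(N, M, rand_mask(N), seed = 1000 + trial)
    obs <- sample.int(M, T_, replace = TRUE)
    expect_equal(likelihood_bruteforce(m, obs),
                 oracle_likelihood_recursive(m, obs), tolerance = 1e-12)
  }
})

test_that("masked zeros behave identically to explicit zeros", {
  m <- random_dhmm(5, 6, five, seed = 4)
  nomask <- dhmm_model(m$A, m$B, m$pi)   # same numbers, all-allowed mask
  obs <- sample_obs_from(m, 40, seed = 5)
  expect_equal(forward_dhmm(m, obs)$loglik, forward_dhmm(nomask, obs)$loglik)
  expect_equal(viterbi(m, obs)$path, viterbi(nomask, obs)$path)
})

test_that("decoded paths never traverse a_14 = 0 (Wake -> SWS)", {
  m <- random_dhmm(5, 8, five, seed = 6)
  for (s in 1:5) {
    obs <- sample.int(8, 200, replace = TRUE)
    path <- viterbi(m, obs)$path
    steps <- cbind(path[-200], path[-1])
    expect_false(any(steps[, 1] == 1 & steps[, 2] == 4))
    expect_true(all(unclass(five)[steps]))
  }
})

test_that("forward scaling survives T = 5000 without underflow", {
  m <- random_dhmm(5, 10, five, seed = 8)
  obs <- sample_obs_from(m, 5000, seed = 9)
  fw <- forward_dhmm(m, obs)
  expect_true(is.finite(fw$loglik))
  expect_equal(fw$loglik, sum(fw$log_scale))
  expect_lt(fw$loglik, 0)
  # raw likelihood would underflow: loglik far below log(.Machine$double.xmin)
  expect_lt(fw$loglik, log(.Machine$double.xmin))
})

test_that("event counting matches hand counts", {
  cnt <- count_events(list(c("Wake", "Wake", "S1")), list(c(2L, 2L, 1L)),
                      5, 3, stage_labels())
  expect_equal(cnt$n_ij[1, 1], 1L)
  expect_equal(cnt$n_ij[1, 2], 1L)
  expect_equal(sum(cnt$n_ij), 2L)
  expect_equal(cnt$n_h, c(1L, 0L, 0L, 0L, 0L))
  expect_equal(cnt$n_jk[1, 2], 2L)   # Wake emitted code 2 twice
  expect_equal(cnt$n_jk[2, 1], 1L)
  expect_equal(cnt$n_TD, 1L)
  e <- count_events(list(), list(), 5, 3)
  expect_equal(sum(e$n_ij) + sum(e$n_jk) + sum(e$n_h), 0L)
  expect_equal(e$n_TD, 0L)
  expect_error(count_events(list(1:3), list(1:4), 5, 5), "lengths differ")
})

test_that("counted transition frequencies converge to the chain", {
  ch <- default_chain()
  seqs <- lapply(1:10, function(s) {
    stage_index(unclass(generate_hypnogram(ch$A, ch$pi, ch$mask, 900,
                                           seed = 100 + s)))
  })
  obs <- lapply(seqs, function(st) rep(1L, length(st)))
  cnt <- count_events(seqs, obs, 5, 1)
  ni <- rowSums(cnt$n_ij)
  for (i in 1:5) for (j in 1:5) {
    p <- ch$A[i, j]
    se <- sqrt(p * (1 - p) / ni[i])
    expect_lte(abs(cnt$n_ij[i, j] / ni[i] - p), max(3 * se, 1e-12))
  }
})

test_that("parameter updates divide counts and honour the mask", {
  cnt <- count_events(list(c(1L, 1L, 2L)), list(c(1L, 1L, 2L)), 5, 2)
  m <- update_parameters(cnt, default_transition_mask(), smoothing = 1)
  expect_equal(m$A[1, 1], 0.5)
  expect_equal(m$A[1, 2], 0.5)
  expect_equal(m$pi[["Wake"]], 1)
  # counts on a masked cell are zeroed and the row renormalised
  cnt2 <- cnt
  cnt2$n_ij[1, 4] <- 5L   # impossible Wake -> SWS observations
  m2 <- update_parameters(cnt2, default_transition_mask(), smoothing = 1)
  expect_equal(m2$A[1, 4], 0)
  expect_equal(sum(m2$A[1, ]), 1, tolerance = 1e-12)
  expect_equal(m2$A[1, 1], 0.5)
  # Laplace smoothing: zero emission counts give the uniform row
  expect_equal(unname(m$B[3, ]), c(0.5, 0.5))
  expect_error(update_parameters(cnt, default_transition_mask(), smoothing = 0),
               "S2|zero")
})

test_that("supervised training recovers a known constrained model", {
  ch <- default_chain()
  M <- 10
  set.seed(55)
  B_true <- diag(5)[, c(1:5, 1:5)] * 0.5 * 0.9 + 0.1 / M
  B_true <- B_true / rowSums(B_true)
  seqs <- list(); obs <- list()
  for (s in 1:10) {
    st <- stage_index(unclass(generate_hypnogram(ch$A, ch$pi, ch$mask, 900,
                                                 seed = 500 + s)))
    seqs[[s]] <- st
    obs[[s]] <- sample_obs_codes(st, B_true)
  }
  model <- train_dhmm(obs, seqs, mask = ch$mask, m = M)
  allowed <- unclass(ch$mask)
  expect_lte(max(abs(model$A - ch$A)[allowed]), 0.03)
  expect_lte(max(abs(model$B - B_true)), 0.05)
})

test_that("segmental refinement converges to a fixed point of its own decode", {
  ch <- default_chain()
  set.seed(10)
  obs <- lapply(1:4, function(s) sample.int(6, 300, replace = TRUE))
  conv <- train_dhmm(obs, NULL, mask = ch$mask, m = 6, seed = 3,
                     max_iter = 100, tol = 1e-12)
  trace <- attr(conv, "score_trace")
  expect_true(all(diff(trace) >= -1e-9))   # recorded scores never decrease
  # at convergence, decoding + recounting reproduces the same parameters ...
  dec <- lapply(obs, function(o) viterbi(conv, o)$path)
  m1 <- train_dhmm(obs, dec, mask = ch$mask, m = 6)
  expect_equal(m1$A, conv$A, tolerance = 1e-9)
  expect_equal(m1$B, conv$B, tolerance = 1e-9)
  # ... and restarting refinement from those labels moves nothing
  m2 <- train_dhmm(obs, dec, mask = ch$mask, m = 6, refine = TRUE,
                   max_iter = 10)
  expect_equal(m2$A, m1$A, tolerance = 1e-9)
  expect_equal(m2$B, m1$B, tolerance = 1e-9)
})

test_that("refinement keeps accuracy close to the supervised fit", {
  ch <- default_chain()
  M <- 10
  set.seed(66)
  B_true <- 0.9 * diag(5)[, c(1:5, 1:5)] * 0.5
  B_true <- B_true + 0.1 / M
  B_true <- B_true / rowSums(B_true)
  seqs <- list(); obs <- list()
  for (s in 1:6) {
    st <- stage_index(unclass(generate_hypnogram(ch$A, ch$pi, ch$mask, 600,
                                                 seed = 700 + s)))
    seqs[[s]] <- st
    obs[[s]] <- sample_obs_codes(st, B_true)
  }
  sup <- train_dhmm(obs, seqs, mask = ch$mask, m = M)
  ref <- train_dhmm(obs, seqs, mask = ch$mask, m = M, refine = TRUE,
                    max_iter = 20)
  acc <- function(model) {
    mean(unlist(lapply(seq_along(obs), function(s) {
      viterbi(model, obs[[s]])$path == seqs[[s]]
    })))
  }
  expect_gte(acc(ref), acc(sup) - 0.05)
})

test_that("model JSON round-trip is bit-exact", {
  m <- random_dhmm(5, 12, five, seed = 13)
  path <- withr::local_tempfile(fileext = ".json")
  write_dhmm(m, path)
  m2 <- read_dhmm(path)
  expect_identical(m2$A, m$A)
  expect_identical(m2$B, m$B)
  expect_identical(unname(m2$pi), unname(m$pi))
  expect_equal(unclass(m2$mask), unclass(m$mask), ignore_attr = TRUE)
  expect_identical(m2$state_names, m$state_names)
})
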