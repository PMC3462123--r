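# Independent oracles the implementation is checked against. These stay
# deliberately naive (loops, direct summation) and share no code with the
# package internals they verify.

# recursive enumeration of P(O | lambda) -- independent of the package's
# vectorized brute force; only usable at very small N, T
oracle_likelihood_recursive <- function(model, obs) {
  N <- model$N
  rec <- function(t, prev) {
    if (t > length(obs)) return(1)
    total <- 0
    for (j in seq_len(N)) {
      tr <- if (t == 1) model$pi[[j]] else model$A[prev, j]
      if (tr > 0) total <- total + tr * model$B[j, obs[t]] * rec(t + 1, j)
    }
    total
  }
  unname(rec(1, NA))
}

# exhaustive best-path search: returns max joint probability and one argmax
oracle_viterbi_enum <- function(model, obs) {
  T_ <- length(obs); N <- model$N
  Q <- as.matrix(expand.grid(rep(list(seq_len(N)), T_)))
  p <- model$pi[Q[, 1]] * model$B[cbind(Q[, 1], obs[1])]
  if (T_ > 1) {
    for (t in 2:T_) {
      p <- p * model$A[cbind(Q[, t - 1], Q[, t])] * model$B[cbind(Q[, t], obs[t])]
    }
  }
  best <- which.max(p)
  list(prob = unname(p[best]), path = as.integer(Q[best, ]))
}

# averaged 2-s/512-point spectrum by direct looping (oracle for epoch_spectrum)
oracle_epoch_spectrum <- function(x) {
  stopifnot(length(x) == 7680)
  acc <- numeric(257)
  for (w in 1:15) {
    seg <- x[((w - 1) * 512 + 1):(w * 512)]
    acc <- acc + Mod(stats::fft(seg))[1:257]^2
  }
  list(power = acc / 15, freq = seq(0, 128, by = 0.5))
}

# direct band summation with the package's stated bin convention
oracle_band_sum <- function(spec, lo, hi) {
  s <- 0
  for (i in seq_along(spec$freq)) {
    f <- spec$freq[i]
    if (f >= lo && (f < hi || (hi == 30 && f == 30))) s <- s + spec$power[i]
  }
  s
}

oracle_spectral_frequency <- function(spec) {
  num <- 0; den <- 0
  for (i in seq_along(spec$freq)) {
    f <- spec$freq[i]
    if (f <= 30) { num <- num + f * spec$power[i]; den <- den + spec$power[i] }
  }
  if (den == 0) 0 else num / den
}

# kappa coded directly from its definition (second implementation)
oracle_kappa <- function(cm) {
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- 0
  for (i in seq_len(nrow(cm))) pe <- pe + sum(cm[i, ]) * sum(cm[, i]) / n^2
  (po - pe) / (1 - pe)
}

# random stochastic matrix respecting a mask
rand_constrained_A <- function(mask) {
  N <- nrow(mask)
  A <- matrix(0, N, N)
  for (i in seq_len(N)) {
    g <- stats::rgamma(N, 1) * unclass(mask)[i, ]
    A[i, ] <- g / sum(g)
  }
  dimnames(A) <- dimnames(mask)
  A
}

# sample observation codes from B given a state path
sample_obs_codes <- function(states, B) {
  M <- ncol(B)
  vapply(states, function(s) sample.int(M, 1, prob = B[s, ]), integer(1))
}

# sample a full observation sequence from a model (states, then emissions)
sample_obs_from <- function(model, T_, seed) {
  set.seed(seed)
  N <- model$N
  st <- integer(T_)
  st[1] <- sample.int(N, 1, prob = model$pi)
  if (T_ > 1) {
    for (t in 2:T_) st[t] <- sample.int(N, 1, prob = model$A[st[t - 1], ])
  }
  sample_obs_codes(st, model$B)
}

# a small random mask: self-transitions always allowed, others Bernoulli
rand_mask <- function(N, p_allow = 0.6) {
  m <- matrix(stats::runif(N * N) < p_allow, N, N)
  diag(m) <- TRUE
  class(m) <- c("transition_mask", class(m))
  m
}

# build a 30-s epoch_signals object from raw channel vectors
make_epoch <- function(eeg = numeric(7680), eog = numeric(7680),
                       emg = numeric(7680)) {
  structure(list(eeg = eeg, eog = eog, emg = emg, epoch_index = 0L),
            class = "epoch_signals")
}

sine_epoch <- function(freq, amp = 1, fs = 256, n = 7680) {
  amp * sin(2 * pi * freq * seq_len(n) / fs)
}
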