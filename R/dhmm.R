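#' Construct a transition-constrained discrete HMM
#'
#' The model is `lambda = (A, B, pi)` with `A` the N x N stage-transition
#' matrix, `B` the N x M emission matrix over observation codes and `pi` the
#' initial-stage distribution, plus the boolean mask of allowed transitions.
#' Validation enforces: rows of `A` sum to 1 (tolerance 1e-9), each row of
#' `B` sums to 1, `pi` sums to 1, and `A` is exactly zero wherever the mask
#' disallows.
#'
#' @param A,B,pi model matrices (`B` is N x M, one row per state).
#' @param mask a `transition_mask` (defaults to all-allowed).
#' @param state_names stage labels (defaults to the mask's names).
#' @return a `dhmm` object.
#' @export
dhmm_model <- function(A, B, pi, mask = NULL, state_names = NULL) {
  N <- nrow(A)
  if (is.null(mask)) {
    mask <- matrix(TRUE, N, N)
    class(mask) <- c("transition_mask", class(mask))
  }
  if (is.null(state_names)) {
    state_names <- rownames(mask) %||% paste0("state", seq_len(N))
  }
  dimnames(A) <- list(state_names, state_names)
  rownames(B) <- state_names
  names(pi) <- state_names
  dimnames(mask) <- list(state_names, state_names)
  model <- structure(list(A = A, B = B, pi = pi, mask = mask,
                          state_names = state_names, N = N, M = ncol(B)),
                     class = "dhmm")
  validate_dhmm(model)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_dhmm <- function(model, tol = 1e-9) {
  with(model, {
    stopifnot(nrow(A) == N, ncol(A) == N, nrow(B) == N, length(pi) == N)
    if (any(A < 0) || any(B < 0) || any(pi < 0)) stop("negative probability")
    if (any(abs(rowSums(A) - 1) > tol)) stop("rows of A must sum to 1")
    if (any(abs(rowSums(B) - 1) > tol)) stop("rows of B must sum to 1")
    if (abs(sum(pi) - 1) > tol) stop("pi must sum to 1")
    if (any(A[!unclass(mask)] != 0)) stop("A is nonzero on a masked transition")
  })
  invisible(model)
}

#' @export
print.dhmm <- function(x, ...) {
  cat(sprintf("Transition-constrained DHMM: %d states, %d observation codes\n",
              x$N, x$M))
  cat("States:", paste(x$state_names, collapse = ", "), "\n")
  cat(sprintf("Masked (disallowed) transitions: %d of %d\n",
              sum(!unclass(x$mask)), x$N^2))
  invisible(x)
}

check_obs <- function(model, obs) {
  obs <- as.integer(obs)
  if (length(obs) < 1L) stop("observation sequence must be nonempty")
  if (any(obs < 1L | obs > model$M))
    stop("observation code out of range [1, ", model$M, "]")
  obs
}

#' Brute-force likelihood by enumeration over all state sequences
#'
#' The exponential-time reference: sums `pi * b * a * b ...` over all `N^T`
#' state paths. Guarded to tiny instances; this is the oracle the scaled
#' forward recursion is verified against.
#'
#' @param model a `dhmm`.
#' @param obs integer observation codes.
#' @return the likelihood `P(O | lambda)` (not log).
#' @export
likelihood_bruteforce <- function(model, obs) {
  obs <- check_obs(model, obs)
  T_ <- length(obs); N <- model$N
  if (T_ > 8 || N > 5) stop("brute-force enumeration guarded to T <= 8, N <= 5")
  Q <- as.matrix(expand.grid(rep(list(seq_len(N)), T_)))
  p <- model$pi[Q[, 1]] * model$B[cbind(Q[, 1], obs[1])]
  if (T_ > 1) {
    for (t in 2:T_) {
      p <- p * model$A[cbind(Q[, t - 1], Q[, t])] * model$B[cbind(Q[, t], obs[t])]
    }
  }
  sum(p)
}

#' Scaled forward algorithm
#'
#' Forward recursion with per-step normalisation: `alpha_1(i) = pi_i b_i(o_1)`
#' then `alpha_{t+1}(j) = sum_i alpha_t(i) a_ij b_j(o_{t+1})`, each column
#' rescaled to sum 1 so that arbitrarily long sequences do not underflow. The
#' log-likelihood is the sum of the log scaling factors. Cost is O(N^2 T).
#'
#' @param model a `dhmm`.
#' @param obs integer observation codes in `[1, M]`.
#' @return list with `loglik` (log P(O | lambda); `-Inf` when the sequence
#'   has zero probability), `alpha` (T x N scaled forward matrix) and
#'   `log_scale` (per-step log scaling factors).
#' @export
forward_dhmm <- function(model, obs) {
  obs <- check_obs(model, obs)
  T_ <- length(obs); N <- model$N
  alpha <- matrix(0, T_, N)
  log_scale <- numeric(T_)
  a <- model$pi * model$B[, obs[1]]
  for (t in seq_len(T_)) {
    if (t > 1) a <- as.numeric(alpha[t - 1, ] %*% model$A) * model$B[, obs[t]]
    s <- sum(a)
    if (s == 0) {
      return(list(loglik = -Inf, alpha = alpha, log_scale = log_scale))
    }
    alpha[t, ] <- a / s
    log_scale[t] <- log(s)
  }
  list(loglik = sum(log_scale), alpha = alpha, log_scale = log_scale)
}

#' Viterbi decoding in log space
#'
#' Computes the single most probable state path and its log joint probability
#' `log P*` by the delta/psi recursion with backtracking. Because masked
#' transitions have `a_ij = 0` (log -Inf), a decoded path can never traverse
#' one as long as some unmasked path has positive probability.
#'
#' @param model a `dhmm`.
#' @param obs integer observation codes.
#' @return list with `path` (integer states), `labels` (stage names),
#'   `logp` (log P*).
#' @export
viterbi <- function(model, obs) {
  obs <- check_obs(model, obs)
  T_ <- length(obs); N <- model$N
  logA <- log(model$A); logB <- log(model$B); logpi <- log(model$pi)
  delta <- matrix(-Inf, T_, N)
  psi <- matrix(0L, T_, N)
  delta[1, ] <- logpi + logB[, obs[1]]
  if (T_ > 1) {
    for (t in 2:T_) {
      cand <- delta[t - 1, ] + logA          # N x N: previous state in rows
      best <- apply(cand, 2, which.max)
      delta[t, ] <- cand[cbind(best, seq_len(N))] + logB[, obs[t]]
      psi[t, ] <- best
    }
  }
  logp <- max(delta[T_, ])
  if (!is.finite(logp))
    stop("no positive-probability state path for this observation sequence")
  path <- integer(T_)
  path[T_] <- which.max(delta[T_, ])
  if (T_ > 1) for (t in (T_ - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  list(path = path, labels = model$state_names[path], logp = logp)
}

#' Count transition, emission and initial-state events
#'
#' @param state_sequences list of integer (or stage-label) state sequences.
#' @param obs_sequences list of integer observation-code sequences, paired
#'   with and equal in length to the state sequences.
#' @param N,M numbers of states and observation codes.
#' @param state_names optional labels used to translate character sequences.
#' @return a `dhmm_counts` list: `n_ij` (N x N transition counts), `n_jk`
#'   (N x M emission counts), `n_h` (initial-state counts), `n_TD` (number of
#'   sequences).
#' @export
count_events <- function(state_sequences, obs_sequences, N, M,
                         state_names = NULL) {
  if (!is.list(state_sequences)) state_sequences <- list(state_sequences)
  if (!is.list(obs_sequences)) obs_sequences <- list(obs_sequences)
  if (length(state_sequences) != length(obs_sequences))
    stop("state and observation sequence lists differ in length")
  n_ij <- matrix(0L, N, N)
  n_jk <- matrix(0L, N, M)
  n_h <- integer(N)
  for (s in seq_along(state_sequences)) {
    st <- state_sequences[[s]]
    if (is.character(st) || inherits(st, "hypnogram")) {
      st <- match(unclass(st), state_names %||% stage_labels(any(st == "Mov")))
    }
    st <- as.integer(st)
    ob <- as.integer(obs_sequences[[s]])
    if (length(st) != length(ob))
      stop("sequence ", s, ": state and observation lengths differ")
    if (length(st) == 0L) next
    if (any(st < 1L | st > N)) stop("state index out of range in sequence ", s)
    if (any(ob < 1L | ob > M)) stop("observation code out of range in sequence ", s)
    n_h[st[1]] <- n_h[st[1]] + 1L
    if (length(st) > 1L) {
      tr <- table(factor(st[-length(st)], levels = 1:N),
                  factor(st[-1], levels = 1:N))
      n_ij <- n_ij + unclass(tr)
    }
    em <- table(factor(st, levels = 1:N), factor(ob, levels = 1:M))
    n_jk <- n_jk + unclass(em)
  }
  structure(list(n_ij = n_ij, n_jk = n_jk, n_h = n_h,
                 n_TD = length(state_sequences)),
            class = "dhmm_counts")
}

#' Turn event counts into a constrained DHMM
#'
#' `a_ij = n_ij / n_i.` restricted to mask-allowed cells and renormalised per
#' row (so any counts that fell on a disallowed cell are zeroed and the row
#' re-sums to 1); `b_j(k) = (n_jk + s) / (n_j. + M s)` with Laplace
#' pseudo-count `s` so codes unseen in training keep nonzero emission
#' probability; `pi_i = n_h(i) / n_TD`.
#'
#' A state with no allowed outgoing counts gets a uniform row over its
#' allowed cells when `smoothing > 0`, and is an error when `smoothing = 0`.
#'
#' @param counts a `dhmm_counts`.
#' @param mask a `transition_mask`.
#' @param smoothing emission pseudo-count (default 1).
#' @return a `dhmm`.
#' @export
update_parameters <- function(counts, mask, smoothing = 1) {
  N <- nrow(counts$n_ij); M <- ncol(counts$n_jk)
  stopifnot(nrow(mask) == N)
  state_names <- rownames(mask) %||% paste0("state", 1:N)
  A <- counts$n_ij * unclass(mask)
  rs <- rowSums(A)
  for (i in seq_len(N)) {
    if (rs[i] > 0) {
      A[i, ] <- A[i, ] / rs[i]
    } else if (smoothing > 0) {
      A[i, ] <- unclass(mask)[i, ] / sum(unclass(mask)[i, ])
    } else {
      stop("state ", state_names[i],
           " has zero outgoing counts and smoothing is disabled")
    }
  }
  B <- (counts$n_jk + smoothing) / (rowSums(counts$n_jk) + M * smoothing)
  if (smoothing == 0 && any(rowSums(counts$n_jk) == 0))
    stop("state ", state_names[which(rowSums(counts$n_jk) == 0)[1]],
         " has zero emission counts and smoothing is disabled")
  if (counts$n_TD == 0) stop("no training sequences (n_TD = 0)")
  pi <- counts$n_h / counts$n_TD
  dhmm_model(A, B, pi, mask, state_names)
}

#' Train the transition-constrained DHMM
#'
#' Supervised mode (labels given): one pass of event counting followed by the
#' constrained update -- the primary path, matching training on expert-scored
#' recordings. Refinement mode (`labels = NULL`, or `refine = TRUE` after a
#' supervised start): segmental (Viterbi) re-estimation -- decode every
#' sequence with the current model, recount, update -- iterated until the
#' largest parameter change is below `tol` or `max_iter` is reached. The
#' summed Viterbi log score is tracked and the iteration stops if it ever
#' fails to increase, so the recorded trace is non-decreasing.
#'
#' @param obs_sequences list of integer observation-code sequences.
#' @param labels list of state sequences (integers or stage labels) or NULL.
#' @param mask a `transition_mask`.
#' @param m number of observation codes (defaults to the max observed code).
#' @param seed seed for the random initial model in unsupervised mode.
#' @param max_iter,tol refinement controls.
#' @param smoothing emission pseudo-count.
#' @param refine also run Viterbi refinement after a supervised start.
#' @return a `dhmm` with attribute `score_trace` (refinement mode).
#' @export
train_dhmm <- function(obs_sequences, labels = NULL,
                       mask = default_transition_mask(), m = NULL, seed = 1L,
                       max_iter = 50L, tol = 1e-6, smoothing = 1,
                       refine = FALSE) {
  if (!is.list(obs_sequences)) obs_sequences <- list(obs_sequences)
  if (length(obs_sequences) == 0L) stop("no observation sequences supplied")
  N <- nrow(mask)
  if (is.null(m)) m <- max(unlist(obs_sequences))
  if (!is.null(labels)) {
    if (!is.list(labels)) labels <- list(labels)
    counts <- count_events(labels, obs_sequences, N, m, rownames(mask))
    model <- update_parameters(counts, mask, smoothing)
    if (!refine) return(model)
  } else {
    model <- random_dhmm(N, m, mask, seed)
  }
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    dec <- lapply(obs_sequences, function(o) viterbi(model, o))
    score <- sum(vapply(dec, `[[`, numeric(1), "logp"))
    if (length(trace) > 0 && score < trace[length(trace)] - 1e-9) break
    trace <- c(trace, score)
    counts <- count_events(lapply(dec, `[[`, "path"), obs_sequences, N, m,
                           rownames(mask))
    new_model <- update_parameters(counts, mask, smoothing)
    delta <- max(abs(new_model$A - model$A), abs(new_model$B - model$B),
                 abs(new_model$pi - model$pi))
    model <- new_model
    if (delta < tol) break
  }
  attr(model, "score_trace") <- trace
  model
}

#' Draw a random constrained DHMM (uniform Dirichlet rows)
#'
#' Used for unsupervised initialisation and for the randomized property tests.
#'
#' @param N,M numbers of states and codes.
#' @param mask a `transition_mask` (defaults to all-allowed).
#' @param seed integer seed.
#' @return a `dhmm`.
#' @export
random_dhmm <- function(N, M, mask = NULL, seed = 1L) {
  if (is.null(mask)) {
    mask <- matrix(TRUE, N, N)
    class(mask) <- c("transition_mask", class(mask))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  A <- matrix(0, N, N)
  for (i in seq_len(N)) {
    g <- stats::rgamma(N, 1) * unclass(mask)[i, ]
    A[i, ] <- g / sum(g)
  }
  Bg <- matrix(stats::rgamma(N * M, 1), N, M)
  B <- Bg / rowSums(Bg)
  pg <- stats::rgamma(N, 1)
  dhmm_model(A, B, pg / sum(pg), mask, rownames(mask))
}

#' Read / write a DHMM as JSON
#'
#' Full-precision (digits = NA) serialisation of `state_names`, `M`, `A`,
#' `B`, `pi` and the mask; the round-trip is bit-exact.
#'
#' @param model a `dhmm`.
#' @param path file path.
#' @export
write_dhmm <- function(model, path) {
  jsonlite::write_json(
    list(state_names = model$state_names, M = model$M,
         A = unname(model$A), B = unname(model$B), pi = unname(model$pi),
         mask = matrix(as.integer(unclass(model$mask)), model$N)),
    path, digits = I(17), matrix = "rowmajor", auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_dhmm
#' @export
read_dhmm <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  fixm <- function(x) if (is.list(x)) do.call(rbind, x) else x
  mask <- fixm(j$mask) != 0
  class(mask) <- c("transition_mask", class(mask))
  dhmm_model(fixm(j$A), fixm(j$B), as.numeric(j$pi), mask, j$state_names)
}
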