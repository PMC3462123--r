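#' Confusion matrix between reference and predicted hypnograms
#'
#' Rows are the reference (manual) stages, columns the predicted stages.
#'
#' @param reference,predicted equal-length stage-label vectors (or
#'   `hypnogram`s).
#' @param state_names stage vocabulary (default: five-stage).
#' @return integer matrix of class `stage_confusion`.
#' @export
confusion <- function(reference, predicted, state_names = stage_labels()) {
  r <- unclass(reference); p <- unclass(predicted)
  if (length(r) != length(p))
    stop("reference and predicted hypnograms differ in length")
  if (is.numeric(r)) r <- state_names[r]
  if (is.numeric(p)) p <- state_names[p]
  cm <- table(factor(r, levels = state_names), factor(p, levels = state_names))
  cm <- unclass(cm)
  dimnames(cm) <- list(reference = state_names, predicted = state_names)
  structure(cm, class = c("stage_confusion", "matrix"))
}

#' @export
print.stage_confusion <- function(x, ...) {
  cat("Stage confusion matrix (rows = manual scoring, row %):\n")
  rp <- round(100 * unclass(x) / pmax(rowSums(unclass(x)), 1), 2)
  print(rp)
  cat(sprintf("Overall agreement: %.2f%%   kappa: %.3f\n",
              m_ssrr(x), tryCatch(cohen_kappa(x), error = function(e) NA)))
  invisible(x)
}

#' Overall sleep-stage recognition rate (percent)
#'
#' `100 * sum_i C_i / E_T`: correctly recognised epochs (diagonal) over total
#' epochs.
#'
#' @param cm a `stage_confusion` matrix.
#' @return percentage in `[0, 100]`.
#' @export
m_ssrr <- function(cm) {
  cm <- unclass(cm)
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix")
  100 * sum(diag(cm)) / tot
}

#' Cohen's kappa of a confusion matrix
#'
#' `K = (P_o - P_e) / (1 - P_e)` with observed agreement `P_o = trace/total`
#' and chance agreement `P_e = sum_i row_i * col_i / total^2`.
#'
#' @param cm a `stage_confusion` matrix.
#' @return kappa (<= 1); error when `P_e = 1` (degenerate single category).
#' @export
cohen_kappa <- function(cm) {
  cm <- unclass(cm)
  tot <- sum(cm)
  if (tot == 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / tot
  pe <- sum(rowSums(cm) * colSums(cm)) / tot^2
  if (abs(1 - pe) < 1e-12)
    stop("kappa undefined: chance agreement P_e = 1 (single category)")
  (po - pe) / (1 - pe)
}

#' Landis-Koch interpretation of a kappa value
#'
#' Bins: < 0 poor; 0-0.20 slight; 0.21-0.40 fair; 0.41-0.60 moderate;
#' 0.61-0.80 substantial; > 0.80 excellent.
#'
#' @param k kappa value (<= 1).
#' @return one of "poor", "slight", "fair", "moderate", "substantial",
#'   "excellent".
#' @export
interpret_kappa <- function(k) {
  stopifnot(k <= 1 + 1e-12)
  if (k < 0) "poor"
  else if (k <= 0.20) "slight"
  else if (k <= 0.40) "fair"
  else if (k <= 0.60) "moderate"
  else if (k <= 0.80) "substantial"
  else "excellent"
}

#' Per-stage sensitivity and overall agreement report
#'
#' @param cm a `stage_confusion` matrix.
#' @return an `agreement_report`: list with `per_stage_sensitivity` (percent;
#'   `NA` for stages absent from the reference), `m_ssrr`, `kappa`,
#'   `kappa_band`.
#' @export
agreement_report <- function(cm) {
  cmu <- unclass(cm)
  rs <- rowSums(cmu)
  sens <- ifelse(rs > 0, 100 * diag(cmu) / rs, NA_real_)
  names(sens) <- rownames(cmu)
  k <- cohen_kappa(cm)
  structure(list(per_stage_sensitivity = sens, m_ssrr = m_ssrr(cm),
                 kappa = k, kappa_band = interpret_kappa(k)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("Per-stage sensitivity (%):\n")
  print(round(x$per_stage_sensitivity, 2))
  cat(sprintf("Overall agreement: %.2f%%   kappa: %.3f (%s)\n",
              x$m_ssrr, x$kappa, x$kappa_band))
  invisible(x)
}

#' Repeated two-fold cross-validation of the staging pipeline
#'
#' Each repeat shuffles the subjects, splits them into two halves, and for
#' each fold trains the codebook and the constrained DHMM on one half
#' (supervised, using the reference hypnograms) and scores the other half by
#' Viterbi decoding. Movement-flagged epochs are excluded from agreement
#' computation when `exclude_movement` (they can instead be scored as Wake).
#'
#' @param subjects list of per-subject `list(features, hypnogram)` (features:
#'   epochs x 13 matrix) -- as produced by [featurize_cohort()]. A per-subject
#'   logical `movement` vector is honoured if present.
#' @param m codebook size (default 50).
#' @param n_repeats number of shuffled repeats (default 5).
#' @param seed master seed.
#' @param mask transition mask.
#' @param smoothing emission pseudo-count.
#' @param exclude_movement drop movement epochs from scoring.
#' @return a `crossval_result`: list with `fold_reports` (2 x n_repeats
#'   `agreement_report`s), `mean_agreement`, `sd_agreement`,
#'   `majority_baseline` (percent agreement of always predicting the most
#'   frequent reference stage).
#' @export
cross_validate <- function(subjects, m = 50, n_repeats = 5, seed = 1L,
                           mask = default_transition_mask(), smoothing = 1,
                           exclude_movement = TRUE) {
  n_sub <- length(subjects)
  if (n_sub < 2) stop("cross-validation needs at least 2 subjects")
  state_names <- rownames(mask)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  fold_reports <- list()
  fold_agreement <- numeric(0)
  for (rep_i in seq_len(n_repeats)) {
    ord <- sample.int(n_sub)
    half <- n_sub %/% 2
    folds <- list(ord[seq_len(half)], ord[(half + 1):n_sub])
    for (f in 1:2) {
      test_idx <- folds[[f]]
      train_idx <- setdiff(ord, test_idx)
      fit <- fit_pipeline(subjects[train_idx], m = m,
                          seed = as.integer((seed * 131 + rep_i * 17 + f) %% 2147483647),
                          mask = mask, smoothing = smoothing)
      ref <- character(0); pred <- character(0)
      for (s in test_idx) {
        sc <- score_subject(fit, subjects[[s]]$features)
        keep <- rep(TRUE, length(sc))
        mov <- subjects[[s]]$movement
        if (exclude_movement && !is.null(mov)) keep <- !mov
        ref <- c(ref, unclass(subjects[[s]]$hypnogram)[keep])
        pred <- c(pred, sc[keep])
      }
      cm <- confusion(ref, pred, state_names)
      rp <- agreement_report(cm)
      fold_reports[[length(fold_reports) + 1L]] <- rp
      fold_agreement <- c(fold_agreement, rp$m_ssrr)
    }
  }
  all_ref <- unlist(lapply(subjects, function(s) unclass(s$hypnogram)))
  maj <- 100 * max(table(factor(all_ref, levels = state_names))) / length(all_ref)
  structure(list(fold_reports = fold_reports,
                 fold_agreement = fold_agreement,
                 mean_agreement = mean(fold_agreement),
                 sd_agreement = stats::sd(fold_agreement),
                 majority_baseline = maj),
            class = "crossval_result")
}

#' @export
print.crossval_result <- function(x, ...) {
  cat(sprintf(paste0("Repeated 2-fold cross-validation: %d folds\n",
                     "  overall agreement %.2f%% (SD %.2f)\n",
                     "  majority-class baseline %.2f%%\n"),
              length(x$fold_agreement), x$mean_agreement, x$sd_agreement,
              x$majority_baseline))
  invisible(x)
}
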