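#' Pipeline configuration
#'
#' Central place for the tunables of the staging pipeline. Defaults follow
#' the experimental dimensioning the method was designed around: 30-s epochs,
#' 256 samples/second target rate, 0.5-30 Hz (EEG/EOG) and 5-100 Hz (EMG)
#' eighth-order Butterworth band-passes, 1-s duration-ratio windows, codebook
#' size 50 (of the candidate sizes 30/40/50/60, 50 is the operating point),
#' Laplace emission pseudo-count 1.
#'
#' @param m codebook size.
#' @param smoothing emission pseudo-count.
#' @param mask transition mask (or a path to a mask JSON).
#' @param seed master seed.
#' @param exclude_movement drop movement-flagged epochs from scoring metrics.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(m = 50, smoothing = 1,
                            mask = default_transition_mask(), seed = 1L,
                            exclude_movement = TRUE) {
  if (is.character(mask)) mask <- read_mask(mask)
  stopifnot(m >= 1)
  structure(list(m = as.integer(m), epoch_s = 30, fs_target = 256,
                 window_s = 1, smoothing = smoothing, mask = mask,
                 seed = as.integer(seed), exclude_movement = exclude_movement),
            class = "pipeline_config")
}

#' Preprocess and featurize a cohort of recordings
#'
#' Runs resampling, filtering, epoch segmentation, movement detection and
#' feature extraction for each subject.
#'
#' @param cohort list of `list(recording, hypnogram)` (hypnogram optional for
#'   scoring-only use), e.g. from [generate_cohort()].
#' @return list of `list(features, hypnogram, movement, subject_id)`.
#' @export
featurize_cohort <- function(cohort) {
  lapply(cohort, function(sub) {
    rec <- preprocess_recording(sub$recording)
    feats <- featurize_recording(rec)
    n_ep <- nrow(feats)
    n <- 7680L
    mov <- vapply(seq_len(n_ep), function(e) {
      detect_movement(rec$eeg[((e - 1L) * n + 1L):(e * n)])
    }, logical(1))
    hyp <- sub$hypnogram
    if (!is.null(hyp) && length(hyp) > n_ep) {
      hyp <- new_hypnogram(unclass(hyp)[seq_len(n_ep)], attr(hyp, "state_names"))
    }
    list(features = feats, hypnogram = hyp, movement = mov,
         subject_id = sub$recording$subject_id)
  })
}

#' Generate and featurize a synthetic cohort one subject at a time
#'
#' Streaming variant of [generate_cohort()] + [featurize_cohort()]: each
#' subject's raw and preprocessed signals are discarded as soon as its
#' features are extracted, so a 20-subject full-night cohort fits in a
#' fraction of the memory. Seeds follow the [generate_cohort()] schedule, so
#' the result is identical to the two-step path.
#'
#' @inheritParams generate_cohort
#' @return list of `list(features, hypnogram, movement, subject_id)`.
#' @export
synthesize_featurized_cohort <- function(n_subjects, n_epochs = 900, fs = 256,
                                         seed = 1L, chain = default_chain(),
                                         params = default_stage_params()) {
  lapply(seq_len(n_subjects), function(s) {
    s_seed <- (as.double(seed) * 104729 + s * 1299709) %% 2147483647
    hyp <- generate_hypnogram(chain$A, chain$pi, chain$mask, n_epochs,
                              seed = s_seed)
    rec <- generate_recording(hyp, params, fs, seed = s_seed + 1,
                              subject_id = sprintf("synth%02d", s))
    out <- featurize_cohort(list(list(recording = rec, hypnogram = hyp)))[[1]]
    rm(rec)
    out
  })
}

#' Fit the codebook + constrained DHMM on labelled training subjects
#'
#' Step 1: train the vector-quantization codebook on the pooled training
#' feature vectors. Step 2: encode each training subject to observation codes.
#' Step 3: supervised count-based training of the transition-constrained
#' DHMM from the reference hypnograms.
#'
#' @param subjects list of `list(features, hypnogram)`.
#' @param m codebook size.
#' @param seed integer seed (codebook initialisation).
#' @param mask transition mask.
#' @param smoothing emission pseudo-count.
#' @param refine also run Viterbi refinement after the supervised pass.
#' @return a `staging_fit`: list with `codebook`, `model`, `mask`.
#' @export
fit_pipeline <- function(subjects, m = 50, seed = 1L,
                         mask = default_transition_mask(), smoothing = 1,
                         refine = FALSE) {
  feats <- do.call(rbind, lapply(subjects, `[[`, "features"))
  cb <- train_codebook(feats, m, seed = seed)
  obs <- lapply(subjects, function(s) encode(s$features, cb))
  labels <- lapply(subjects, `[[`, "hypnogram")
  model <- train_dhmm(obs, labels, mask = mask, m = m, seed = seed,
                      smoothing = smoothing, refine = refine)
  structure(list(codebook = cb, model = model, mask = mask),
            class = "staging_fit")
}

#' Score one subject's feature matrix with a fitted pipeline
#'
#' Encodes the epochs with the fitted codebook and Viterbi-decodes the code
#' sequence with the constrained DHMM.
#'
#' @param fit a `staging_fit`.
#' @param features epochs x 13 feature matrix.
#' @return character vector of predicted stage labels (a `hypnogram`).
#' @export
score_subject <- function(fit, features) {
  obs <- encode(features, fit$codebook)
  if (length(obs) == 0L) return(new_hypnogram(character(0)))
  v <- viterbi(fit$model, obs)
  new_hypnogram(v$labels, fit$model$state_names)
}

#' Run the full train-and-evaluate pipeline on a labelled cohort
#'
#' Convenience driver: featurizes the cohort (unless already featurized),
#' fits codebook and DHMM on the training subjects, decodes the test
#' subjects and reports agreement against their reference hypnograms.
#'
#' @param config a `pipeline_config`.
#' @param cohort list of `list(recording, hypnogram)` or pre-featurized
#'   subjects (`list(features, hypnogram, ...)`).
#' @param train_idx,test_idx subject index vectors; default: first half
#'   trains, second half tests.
#' @return list with `fit`, `scored` (per-test-subject hypnograms),
#'   `report` (pooled `agreement_report`), `confusion`.
#' @export
run_pipeline <- function(config, cohort, train_idx = NULL, test_idx = NULL) {
  subjects <- if (!is.null(cohort[[1]]$features)) cohort else featurize_cohort(cohort)
  n_sub <- length(subjects)
  if (is.null(train_idx)) train_idx <- seq_len(ceiling(n_sub / 2))
  if (is.null(test_idx)) test_idx <- setdiff(seq_len(n_sub), train_idx)
  fit <- fit_pipeline(subjects[train_idx], m = config$m, seed = config$seed,
                      mask = config$mask, smoothing = config$smoothing)
  scored <- list(); ref <- character(0); pred <- character(0)
  for (s in test_idx) {
    sc <- score_subject(fit, subjects[[s]]$features)
    scored[[subjects[[s]]$subject_id %||% as.character(s)]] <- sc
    keep <- rep(TRUE, length(sc))
    if (config$exclude_movement && !is.null(subjects[[s]]$movement))
      keep <- !subjects[[s]]$movement
    ref <- c(ref, unclass(subjects[[s]]$hypnogram)[keep])
    pred <- c(pred, unclass(sc)[keep])
  }
  cm <- confusion(ref, pred, rownames(config$mask))
  list(fit = fit, scored = scored, report = agreement_report(cm),
       confusion = cm)
}
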