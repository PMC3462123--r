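---
title: "Automatic sleep staging with a transition-constrained discrete HMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic sleep staging with a transition-constrained discrete HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepdhmm)
```

## The problem

Overnight polysomnography (PSG) is scored by experts into 30-second epochs
labelled Wake, S1, S2, SWS (slow-wave sleep, the merged stages 3+4) and REM,
following the classical Rechtschaffen & Kales visual criteria. Manual scoring
of a full night (about 900 epochs) is slow and subjective. `sleepdhmm`
implements an automatic scorer that uses one central EEG channel (e.g. C3-A2),
a derived EOG channel and the chin EMG.

The key modelling idea is that sleep stages evolve with strong temporal
structure: the next stage depends on the current one, and some transitions are
physiologically impossible (a sleeper does not jump from Wake directly into
SWS). A hidden Markov model captures exactly this, and *constraining* its
transition matrix — pinning the impossible transitions to zero during training
— is what distinguishes this scorer from a per-epoch classifier or an
unconstrained HMM.

## Pipeline

1. **Preprocess.** Signals are down-sampled to 256 samples/s. EEG and EOG are
   band-passed 0.5–30 Hz and the EMG 5–100 Hz, with eighth-order Butterworth
   filters, then cut into 30-s epochs (7680 samples). Each epoch/channel
   spectrum is the average of fifteen non-overlapping 2-s, 512-point FFT power
   spectra (0.5 Hz resolution, no taper).
2. **Features.** Thirteen per-epoch features: EEG and EMG total power
   (0–30 Hz); EEG power ratios 0–4, 4–8, 8–13 and 22–30 Hz and EOG power ratio
   0–4 Hz (each relative to the 0–30 Hz total); EEG and EMG mean spectral
   frequency; alpha, spindle and slow-wave duration ratios (fractions of 1-s
   windows meeting a band-specific criterion); and EMG mean absolute
   amplitude.
3. **Vector quantization.** The 13-dimensional feature vectors are quantized
   with an `m`-centre codebook (default `m = 50`; 30/40/50/60 are the
   candidate sizes, with 50 the operating point). Initialisation divides each
   feature's training range into `m` equal subintervals and draws centre `k`
   inside subinterval `k`; training is plain Lloyd/k-means with Euclidean
   distance on raw (unscaled) features.
4. **Constrained DHMM.** A five-state discrete HMM `lambda = (A, B, pi)` over
   the observation codes. Supervised training is count-based:
   `a_ij = n(E_ij)/n(E_i.)`, `b_j(k) = n(state j, code k)/n(state j)` with a
   Laplace pseudo-count, `pi_i = n(E_hi)/n_TD`; cells of `A` disallowed by the
   transition mask are zeroed and each row renormalised. Decoding uses the
   scaled forward recursion for likelihood and log-space Viterbi with
   backtracking for the stage sequence.
5. **Evaluation.** Confusion matrix against the reference hypnogram, per-stage
   sensitivity, overall agreement (correct epochs / total epochs, in percent),
   Cohen's kappa with the Landis–Koch interpretation, and a repeated two-fold
   cross-validation protocol over subjects.

## The transition mask

Only the two qualitative facts are fixed by the source material: Wake → SWS is
impossible, and Wake following SWS is (at most) improbable. The full arrow set
of the published transition diagram is not enumerated anywhere in the text, so
the default mask is this package's own choice and is deliberately
conservative:

```{r}
default_transition_mask()
```

Self-transitions are always allowed; sleep onset passes through S1; SWS is
entered and left only via S2; REM returns to Wake, S1 or S2. The mask is data,
not code — it ships as `inst/extdata/default_mask.json`, can be edited and
passed to every training function, and models serialise the mask they were
trained with.

## The synthetic-data generator

The twenty clinical recordings behind the method are not deposited anywhere,
so the package ships a generator that emulates their statistical structure:

* **Stage sequences** come from a first-order Markov chain on the five stages
  (`default_chain()`), zero on every masked transition, with sticky
  self-transitions (~0.9 at the 30-s epoch scale).
* **Signals**: per stage, the EEG is a sum of band-limited oscillations
  (delta 0.75–1.6 Hz — inside the flat region of the 0.5–2 Hz slow-wave
  detector filter, so the >75 uV SWS criterion is met by construction —
  theta 4–7.5 Hz, alpha 8–13 Hz, beta 22–29 Hz) whose
  amplitudes encode the visual-scoring criteria — Wake alpha-dominant, S1
  low-voltage theta, S2 theta plus 13.5 Hz spindle bursts of 0.5–1.5 s with a
  Hann-like envelope, SWS dominated by >75 uV sub-2 Hz delta, REM low-voltage
  mixed. The EOG carries slow (0.5–0.8 Hz) deflections in S1 and rapid
  deflections in REM; the EMG is band-limited white noise with tonic level
  highest in Wake and lowest in REM. Noise is additive Gaussian.

The published study never quantifies the per-stage spectra of its recordings,
so the default amplitudes (`default_stage_params()`) were chosen once for
*between-stage separability* (every stage pair differs by more than two pooled
standard deviations in at least one feature), not for physiological fidelity.
They are a stated world: the end-to-end tests assert properties of the
pipeline under this world, and a green run establishes that the machinery is
correct and that separable inputs are staged accurately — it does **not**
establish clinical-grade accuracy on real PSG, where stage boundaries are far
blurrier, artifacts abound and S1 in particular overlaps heavily with Wake
and REM.

## Numerical choices

* **Filters** are designed as cascades of second-order sections via the
  bilinear transform (no `signal`-package dependency); the causal cascade runs
  in compiled code. Channel-level filtering is causal (an online-capable
  choice). The duration-ratio sub-band filters are applied **zero-phase**: a
  causal 0.5–2 Hz filter has a multi-second start-up transient that would make
  the first windows of every epoch miss their amplitude thresholds. In the
  batched path, zero-phase filtering is applied exactly, per epoch, by
  multiplying the epoch's DFT with the squared Butterworth magnitude response
  (circular forward–backward filtering); the per-epoch and batched paths are
  bit-identical by construction.
* **Spectra** are kept on a linear power scale throughout. A dB reading of the
  summed spectrum is only a display matter: band-power *ratios* and the
  power-weighted mean frequency are meaningless on a log scale.
* **Band edges** follow one convention everywhere: a band `[lo, hi)` includes
  bins with centre frequency `lo <= f < hi`, except that the terminal 30 Hz
  edge is inclusive. This makes the four EEG ratio bands disjoint at the 4, 8
  and 13 Hz seams (13–22 Hz is deliberately unassigned) and the whole-band
  ratio exactly 1.
* **Thresholds** the source leaves unquantified, fixed here once: duration
  ratios use 1-s windows (the shortest window resolving a 0.5-s spindle); the
  alpha detector's 0.5 threshold is read as an RMS fraction of the broadband
  signal; a spindle's "sudden amplitude change" is a window peak exceeding
  twice the epoch-median window peak; the movement rule is a strict
  `> 200 uV` on the EEG.
* **HMM numerics**: per-step scaling in the forward recursion and log-space
  Viterbi, so full-night (and much longer) sequences cannot underflow.
  Emission rows get a Laplace pseudo-count of 1 so codes unseen in training do
  not zero a test subject's likelihood. Ties in nearest-centre assignment and
  in Viterbi argmaxes break towards the lowest index.
* **Degenerate inputs**: all ratio and mean-frequency features return 0 when
  total power is 0; an all-zero window is never an alpha/spindle/slow-wave
  window; empty k-means clusters keep their stale centre so the codebook stays
  at size `m`.
* **Viterbi refinement** (the unsupervised/iterative training mode) is
  segmental k-means: decode, recount, update. With smoothing the textbook
  monotonicity argument is only approximate, so the loop additionally stops if
  the summed Viterbi score ever fails to increase; the recorded score trace is
  therefore non-decreasing. Supervised counting from expert labels is the
  primary, recommended path.

## Design points that were genuinely open

* **Resampling** uses FFT (band-limited) resampling for any rational ratio,
  rather than a polyphase implementation; below 30 Hz the two agree to well
  under 1 % and the FFT route has far less machinery.
* **EDF input/output is not implemented.** No EDF reader/writer is available
  in the dependency envelope, and EDF is binary; the delimited-text signal
  format plus the hypnogram TSV carry the interchange duties.
* **Movement (Mov) epochs**: the model runs with five states by default (the
  temporary Mov label is supported end to end but off by default), and
  movement-flagged epochs are excluded from agreement metrics rather than
  recoded as Wake — the conservative reading; a flag reverses it.
* **Feature scaling**: quantization distances use raw feature units, which
  lets the large-magnitude power features dominate the geometry. That is what
  the count-based design implies, and on separable data it is immaterial; a
  z-scoring flag exists in spirit via pre-scaling the feature matrix before
  `train_codebook()` if a user needs it.

## Known limitations

* The synthetic world is easier than clinical PSG; reported synthetic
  agreements (typically >95 %) say nothing about performance on real
  recordings.
* Only one EEG channel is modelled; no artifact handling beyond the 200 uV
  movement rule; no smoothing post-processing (the transition constraint is
  the temporal regulariser, and that is the point of the method).
* Codebook training is sensitive to the random subinterval initialisation;
  seeds are threaded through every API so runs are reproducible.
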