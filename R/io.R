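#' Write / read a hypnogram as TSV
#'
#' Two named columns: 0-based `epoch_index` and the text `stage` label
#' (Wake/S1/S2/SWS/REM/Mov). Stage labels are always written as text, never
#' as integers.
#'
#' @param hyp a `hypnogram` (or character vector of stage labels).
#' @param path file path.
#' @export
write_hypnogram <- function(hyp, path) {
  df <- data.frame(epoch_index = seq_along(hyp) - 1L, stage = unclass(hyp))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("integer", "character"))
  df <- df[order(df$epoch_index), , drop = FALSE]
  new_hypnogram(df$stage)
}

#' Write / read a feature matrix as TSV
#'
#' One row per epoch: `epoch_index` (0-based) plus the 13 named feature
#' columns in canonical order. Full precision (digits = 17).
#'
#' @param features epochs x 13 matrix.
#' @param path file path.
#' @export
write_features <- function(features, path) {
  df <- data.frame(epoch_index = seq_len(nrow(features)) - 1L,
                   features, check.names = FALSE)
  old <- options(digits = 17); on.exit(options(old))
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, setdiff(colnames(df), "epoch_index"), drop = FALSE])
  rownames(m) <- NULL
  m
}

#' Write / read a PSG recording as delimited text
#'
#' Header line `# fs=<rate> subject=<id>` followed by a TSV of three columns
#' (eeg, eog, emg, in uV). Values carry full double precision.
#'
#' @param rec a `psg_recording`.
#' @param path file path.
#' @export
write_psg_text <- function(rec, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# fs=%g subject=%s", rec$fs, rec$subject_id), con)
  writeLines("eeg\teog\temg", con)
  m <- cbind(rec$eeg, rec$eog, rec$emg)
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_psg_text
#' @export
read_psg_text <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "# fs=")) stop("not a PSG text file (missing '# fs=' header)")
  fs <- as.numeric(sub("^# fs=([0-9.eE+-]+).*$", "\\1", hdr))
  subject <- sub("^.*subject=(\\S+).*$", "\\1", hdr)
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L)
  new_psg_recording(df$eeg, df$eog, df$emg, fs, subject)
}
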