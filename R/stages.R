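#' Sleep stage labels
#'
#' The canonical five-stage vocabulary (AASM-merged slow-wave sleep), in the
#' fixed internal order Wake, S1, S2, SWS, REM. A sixth temporary label `Mov`
#' (arousal / body movement, EEG amplitude over 200 uV) can be enabled.
#'
#' @param include_mov add the `Mov` label as a sixth state.
#' @return character vector of stage names in canonical order.
#' @export
stage_labels <- function(include_mov = FALSE) {
  s <- c("Wake", "S1", "S2", "SWS", "REM")
  if (include_mov) c(s, "Mov") else s
}

#' Convert stage labels to canonical integer codes
#'
#' Integer order is an internal convention only (files always carry text
#' labels); `Wake` = 1 ... `REM` = 5 (`Mov` = 6) so that entry (1, 4) of a
#' transition matrix is the Wake to SWS transition.
#'
#' @param x character vector of stage labels (or already-integer codes).
#' @param include_mov allow the `Mov` label.
#' @return integer vector.
#' @export
stage_index <- function(x, include_mov = FALSE) {
  labs <- stage_labels(include_mov || any(x == "Mov"))
  if (is.numeric(x)) {
    xi <- as.integer(x)
    if (any(xi < 1L | xi > length(labs))) stop("stage code out of range")
    return(xi)
  }
  i <- match(x, labs)
  if (anyNA(i)) stop("unknown stage label: ", paste(unique(x[is.na(i)]), collapse = ", "))
  i
}

#' Allowed sleep-stage transition mask
#'
#' Boolean N x N matrix of physiologically allowed stage-to-stage transitions
#' (row = from, column = to). The default encodes: all self-transitions; sleep
#' onset goes through S1 (Wake -> S1 only); S1 exchanges with Wake, deepens to
#' S2 or drops into REM; S2 reaches every stage; SWS is entered and left only
#' via S2 (in particular Wake following SWS and SWS following Wake are
#' disallowed); REM returns to Wake, S1 or S2. When `Mov` is enabled it
#' connects to and from every stage. The mask is data, not code: it can be
#' read from / written to JSON with [read_mask()] / [write_mask()], and a copy
#' ships in `inst/extdata/default_mask.json`.
#'
#' @param include_mov include the `Mov` state.
#' @return logical matrix with stage-name dimnames, class `transition_mask`.
#' @export
default_transition_mask <- function(include_mov = FALSE) {
  labs <- stage_labels(FALSE)
  m <- matrix(FALSE, 5, 5, dimnames = list(labs, labs))
  allow <- list(
    Wake = c("Wake", "S1"),
    S1   = c("Wake", "S1", "S2", "REM"),
    S2   = c("Wake", "S1", "S2", "SWS", "REM"),
    SWS  = c("S2", "SWS"),
    REM  = c("Wake", "S1", "S2", "REM")
  )
  for (from in labs) m[from, allow[[from]]] <- TRUE
  if (include_mov) {
    labs6 <- stage_labels(TRUE)
    m6 <- matrix(TRUE, 6, 6, dimnames = list(labs6, labs6))
    m6[1:5, 1:5] <- m
    m <- m6
  }
  class(m) <- c("transition_mask", class(m))
  validate_mask(m)
  m
}

validate_mask <- function(mask) {
  stopifnot(is.matrix(mask), nrow(mask) == ncol(mask))
  if (!all(diag(mask)))
    stop("transition mask must allow all self-transitions")
  if (any(rowSums(mask) < 1))
    stop("transition mask has a row with no allowed transition")
  invisible(mask)
}

#' @export
print.transition_mask <- function(x, ...) {
  cat("Allowed sleep-stage transitions (row = from, col = to):\n")
  print(matrix(ifelse(unclass(x), ".", "0"), nrow(x), dimnames = dimnames(x)),
        quote = FALSE)
  invisible(x)
}

#' Read / write a transition mask as JSON
#'
#' The JSON object holds `state_names` and the 0/1 `allowed` matrix, so masks
#' can be edited by hand and every experiment can log the mask it used.
#'
#' @param path file path.
#' @return `read_mask` returns a `transition_mask`; `write_mask` invisibly
#'   returns `path`.
#' @export
read_mask <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  am <- j$allowed
  if (is.list(am)) am <- do.call(rbind, am)
  m <- matrix(am != 0, length(j$state_names),
              dimnames = list(j$state_names, j$state_names))
  class(m) <- c("transition_mask", class(m))
  validate_mask(m)
}

#' @rdname read_mask
#' @param mask a `transition_mask`.
#' @export
write_mask <- function(mask, path) {
  jsonlite::write_json(
    list(state_names = rownames(mask),
         allowed = matrix(as.integer(unclass(mask)), nrow(mask))),
    path, matrix = "rowmajor", auto_unbox = FALSE)
  invisible(path)
}
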