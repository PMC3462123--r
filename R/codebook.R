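#' Initialise a vector-quantization codebook on per-dimension subintervals
#'
#' For every feature dimension the training range `[lower, upper]` is divided
#' into `m` equal subintervals; element `d` of centre `k` is drawn uniformly
#' within the `k`-th subinterval of dimension `d`. A constant dimension
#' (upper == lower) yields that constant in every centre. Deterministic given
#' `seed`.
#'
#' @param feature_vectors numeric matrix, one feature vector per row (at
#'   least `m` rows).
#' @param m codebook size (number of centres / observation codes).
#' @param seed integer seed.
#' @return a `codebook`: list with `centers` (m x d), `m`, `feature_ranges`
#'   (d x 2 matrix of lower/upper bounds).
#' @export
init_codebook <- function(feature_vectors, m, seed = 1L) {
  X <- as.matrix(feature_vectors)
  if (m < 1) stop("m must be >= 1")
  if (nrow(X) < m) stop("need at least m = ", m, " feature vectors, got ", nrow(X))
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  width <- (hi - lo) / m
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  d <- ncol(X)
  centers <- matrix(0, m, d)
  for (k in seq_len(m)) {
    u <- stats::runif(d)
    centers[k, ] <- lo + (k - 1) * width + u * width
  }
  colnames(centers) <- colnames(X)
  structure(list(centers = centers, m = as.integer(m),
                 feature_ranges = cbind(lower = lo, upper = hi)),
            class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("Vector-quantization codebook: %d centres in %d dimensions\n",
              x$m, ncol(x$centers)))
  invisible(x)
}

# squared Euclidean distances between rows of X (n x d) and rows of C (m x d)
dist2_matrix <- function(X, C) {
  n2x <- rowSums(X^2)
  n2c <- rowSums(C^2)
  D <- outer(n2x, n2c, "+") - 2 * X %*% t(C)
  D[D < 0] <- 0
  D
}

#' Assign feature vectors to their nearest codebook centre
#'
#' Euclidean nearest-centre assignment; ties are broken towards the smallest
#' code index.
#'
#' @param v_f a single feature vector or a matrix of row vectors.
#' @param codebook a `codebook`.
#' @return integer code(s) in `[1, m]`.
#' @export
assign_code <- function(v_f, codebook) {
  X <- if (is.null(dim(v_f))) matrix(v_f, nrow = 1) else as.matrix(v_f)
  D <- dist2_matrix(X, codebook$centers)
  as.integer(apply(D, 1, which.min))   # which.min is first-index on ties
}

#' Train a codebook by Lloyd iterations (k-means)
#'
#' Alternates nearest-centre assignment with centre recomputation (each centre
#' becomes the mean of its assigned vectors; a centre whose group is empty is
#' kept unchanged so the codebook size stays at `m`). Iterates until the
#' maximum centre displacement drops below `tol` or `max_iter` is reached.
#' The quantization error (mean squared distance to the assigned centre) is
#' non-increasing across iterations and is returned as a trace.
#'
#' @param feature_vectors numeric matrix of row vectors (>= m rows).
#' @param m codebook size.
#' @param seed seed for the subinterval initialisation.
#' @param max_iter iteration cap (default 300).
#' @param tol convergence threshold on centre displacement (default 1e-6).
#' @return a trained `codebook` with an `error_trace` element.
#' @export
train_codebook <- function(feature_vectors, m, seed = 1L, max_iter = 300L,
                           tol = 1e-6) {
  X <- as.matrix(feature_vectors)
  if (nrow(X) == 0L) stop("no feature vectors supplied")
  cb <- init_codebook(X, m, seed)
  C <- cb$centers
  err <- numeric(0)
  for (it in seq_len(max_iter)) {
    D <- dist2_matrix(X, C)
    idx <- max.col(-D, ties.method = "first")
    err <- c(err, mean(D[cbind(seq_len(nrow(X)), idx)]))
    Cnew <- C
    for (k in seq_len(m)) {
      members <- idx == k
      if (any(members)) Cnew[k, ] <- colMeans(X[members, , drop = FALSE])
    }
    disp <- max(abs(Cnew - C))
    C <- Cnew
    if (disp < tol) break
  }
  cb$centers <- C
  cb$error_trace <- err
  cb$quantization_error <- {
    D <- dist2_matrix(X, C)
    mean(D[cbind(seq_len(nrow(X)), max.col(-D, ties.method = "first"))])
  }
  cb
}

#' Encode a feature matrix into an observation-code sequence
#'
#' @param feature_matrix numeric matrix, one epoch per row.
#' @param codebook a trained `codebook`.
#' @param subject_id identifier carried on the sequence.
#' @return an `observation_sequence`: integer vector of codes in `[1, m]`
#'   with attributes `m` and `subject_id`.
#' @export
encode <- function(feature_matrix, codebook, subject_id = "unknown") {
  X <- as.matrix(feature_matrix)
  codes <- if (nrow(X) == 0L) integer(0) else assign_code(X, codebook)
  structure(codes, class = "observation_sequence", m = codebook$m,
            subject_id = subject_id)
}

#' Read / write a codebook as JSON
#'
#' @param codebook a `codebook`.
#' @param path file path.
#' @return `read_codebook` returns a `codebook`; the writer invisibly returns
#'   `path`. The round-trip preserves full double precision.
#' @export
write_codebook <- function(codebook, path) {
  jsonlite::write_json(
    list(m = codebook$m,
         feature_names = colnames(codebook$centers),
         feature_ranges = unname(codebook$feature_ranges),
         centers = unname(codebook$centers)),
    path, digits = I(17), matrix = "rowmajor", auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  centers <- j$centers
  if (is.list(centers)) centers <- do.call(rbind, centers)
  colnames(centers) <- j$feature_names
  fr <- j$feature_ranges
  if (is.list(fr)) fr <- do.call(rbind, fr)
  colnames(fr) <- c("lower", "upper")
  rownames(fr) <- j$feature_names
  structure(list(centers = centers, m = as.integer(j$m), feature_ranges = fr),
            class = "codebook")
}
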