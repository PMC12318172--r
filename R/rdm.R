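#' Condition-level representational dissimilarity matrix
#'
#' Computes the 1 - Pearson correlation distance between every pair of
#' condition patterns (rows of a condition x voxel matrix). Entries lie in
#' [0, 2] with a zero diagonal.
#'
#' @param patterns Condition x voxel numeric matrix with >= 2 condition
#'   rows and >= 3 voxel columns; row names are condition labels.
#' @return Symmetric condition x condition matrix with attribute
#'   `metric = "one_minus_pearson"`.
#' @examples
#' p <- rbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4), c = c(4, 3, 2, 1))
#' neural_rdm(p)["a", "b"] # 1 - 0.8 = 0.2
#' @export
neural_rdm <- function(patterns) {
  if (!is.matrix(patterns) || !is.numeric(patterns))
    stop_input("patterns must be a numeric matrix")
  if (nrow(patterns) < 2L || ncol(patterns) < 3L)
    stop_input("patterns must have >= 2 conditions and >= 3 voxels")
  if (anyNA(patterns) || any(!is.finite(patterns)))
    stop_input("patterns contain missing or non-finite values")
  v <- apply(patterns, 1L, stats::var)
  if (any(v == 0)) {
    bad <- rownames(patterns)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    stop_input("zero-variance pattern for condition(s): ",
               paste(bad, collapse = ", "), " (correlation undefined)")
  }
  D <- 1 - stats::cor(t(patterns))
  D <- (D + t(D)) / 2
  diag(D) <- 0
  attr(D, "metric") <- "one_minus_pearson"
  D
}

#' Vectorize the strict lower triangle of a symmetric matrix
#'
#' Returns the k(k-1)/2 below-diagonal entries in row-major order by
#' (row, col) with row > col: for a 3 x 3 matrix, the order is (2,1),
#' (3,1), (3,2). This fixed convention is used by every downstream
#' statistic in the package.
#'
#' @param M Square symmetric numeric matrix (asymmetry beyond 1e-10 is an
#'   error).
#' @return Numeric vector of length `nrow(M) * (nrow(M) - 1) / 2`.
#' @export
vectorize_lower <- function(M) {
  check_square_symmetric(M, "M")
  # for a symmetric matrix, the column-major upper triangle equals the
  # row-major strict lower triangle
  M[upper.tri(M)]
}

#' Participant-by-participant neural dissimilarity
#'
#' The intersubject Spearman correlation dissimilarity: each participant's
#' RDM is vectorized with [vectorize_lower()], and the entry for a pair is
#' 1 minus the Spearman rank correlation of the two vectors (range [0, 2]).
#'
#' @param rdms Named list of same-shaped condition RDMs, one per
#'   participant (names are participant ids).
#' @return Symmetric zero-diagonal participant x participant matrix with
#'   attribute `source = "neural"`.
#' @export
subject_dissimilarity <- function(rdms) {
  if (!is.list(rdms) || length(rdms) < 2L)
    stop_input("rdms must be a list of at least 2 matrices")
  dims <- vapply(rdms, nrow, integer(1L))
  if (length(unique(dims)) != 1L)
    stop_input("all RDMs must share the same condition set")
  V <- vapply(rdms, vectorize_lower, numeric(dims[1L] * (dims[1L] - 1L) / 2L))
  cst <- apply(V, 2L, function(x) diff(range(x)) == 0)
  if (any(cst))
    stop_input("constant vectorized RDM for participant(s): ",
               paste(colnames(V)[cst], collapse = ", "),
               " (Spearman undefined)")
  R <- apply(V, 2L, rank)
  D <- 1 - stats::cor(R)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(names(rdms), names(rdms))
  attr(D, "source") <- "neural"
  D
}

#' Univariate-control distance matrices
#'
#' Control analysis for multivariate effects: from one scalar mean signal
#' change per participant and condition, builds per-participant
#' condition-level distance matrices as absolute differences of the
#' scalars. Feeding these into [subject_dissimilarity()] and the Mantel
#' test asks whether overall activity levels alone could reproduce the
#' pattern-level result.
#'
#' @param levels Participant x condition numeric matrix (row names =
#'   participant ids, column names = condition ids); no missing values.
#' @return Named list of symmetric condition x condition matrices with
#'   attribute `metric = "euclidean_univariate"`.
#' @export
univariate_distance <- function(levels) {
  if (!is.matrix(levels) || !is.numeric(levels))
    stop_input("levels must be a numeric matrix")
  if (anyNA(levels) || any(!is.finite(levels)))
    stop_input("levels contain missing or non-finite cells")
  ids <- rownames(levels)
  if (is.null(ids)) ids <- sprintf("sub%03d", seq_len(nrow(levels)))
  out <- lapply(seq_len(nrow(levels)), function(k) {
    x <- levels[k, ]
    D <- abs(outer(x, x, `-`))
    dimnames(D) <- list(colnames(levels), colnames(levels))
    attr(D, "metric") <- "euclidean_univariate"
    D
  })
  names(out) <- ids
  out
}

#' Extract an ROI pattern matrix from t-statistic volumes
#'
#' Reads one condition x voxel matrix out of a set of 3-D t-maps (or a 4-D
#' array with conditions along the fourth dimension) restricted to a binary
#' region-of-interest mask. Voxels are the mask entries > 0.5, taken in
#' ascending linear-index order; no resampling is ever performed, and a
#' grid or orientation mismatch is a hard error.
#'
#' @param tmaps A 4-D array (x, y, z, condition), or a list of 3-D arrays,
#'   of t-statistic values. `RNifti` images are accepted.
#' @param mask 3-D array on the same grid; voxels with value > 0.5 are in
#'   the region (>= 3 required).
#' @param condition_ids Optional condition labels (defaults to names of
#'   `tmaps` or `cond1..condK`).
#' @return Condition x voxel matrix; columns named by linear voxel index.
#' @export
extract_roi_patterns <- function(tmaps, mask, condition_ids = NULL) {
  if (is.list(tmaps)) {
    if (is.null(condition_ids)) condition_ids <- names(tmaps)
    vols <- lapply(tmaps, function(v) array(as.numeric(v), dim = dim(v)))
  } else {
    dt <- dim(tmaps)
    if (length(dt) != 4L) stop_input("tmaps must be a 4-D array or a list of 3-D volumes")
    vols <- lapply(seq_len(dt[4L]), function(j)
      array(as.numeric(tmaps[, , , j]), dim = dt[1:3]))
  }
  if (is.null(condition_ids)) condition_ids <- sprintf("cond%d", seq_along(vols))
  mdim <- dim(mask)
  if (length(mdim) != 3L) stop_input("mask must be a 3-D volume")
  for (j in seq_along(vols)) {
    if (!identical(dim(vols[[j]]), mdim))
      stop_input("grid mismatch between mask and condition volume ",
                 condition_ids[j], " (no resampling is performed)")
  }
  if (inherits(mask, "niftiImage") && inherits(tmaps, "niftiImage")) {
    xa <- RNifti::xform(mask); xb <- RNifti::xform(tmaps)
    if (max(abs(xa - xb)) > 1e-4)
      stop_input("affine mismatch between mask and t-maps (no resampling is performed)")
  }
  idx <- which(as.numeric(mask) > 0.5)
  if (length(idx) < 3L)
    stop_input("mask selects fewer than 3 voxels")
  out <- t(vapply(vols, function(v) as.numeric(v)[idx], numeric(length(idx))))
  dimnames(out) <- list(condition_ids, sprintf("vox%06d", idx))
  out
}
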