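# Condition-specific splits and run-level reliability checks.

#' Restrict condition RDMs to one referential target
#'
#' Splits each condition RDM into the submatrix of conditions sharing the
#' requested referential target (e.g., the 4 x 4 self-condition block of
#' an 8 x 8 matrix), for condition-specific intersubject analysis. A
#' design with fewer than four valence levels per target is refused: the
#' resulting 3 x 3 block has only three unique cells, too few for a
#' rank-based matrix statistic.
#'
#' @param rdms Named list of condition RDMs whose dimnames are
#'   `condition_id`s of `design`.
#' @param design The [make_design()] object the RDMs were computed under.
#' @param target `"self"` or `"partner"`.
#' @return Named list of reduced RDMs.
#' @export
split_by_condition <- function(rdms, design, target = c("self", "partner")) {
  target <- match.arg(target)
  stopifnot(inherits(design, "ft_design"))
  keep <- design$conditions$condition_id[design$conditions$target == target]
  if (length(keep) < 4L)
    stop_input("condition-specific split needs >= 4 conditions per target; ",
               "a ", length(keep), "-condition block has only ",
               length(keep) * (length(keep) - 1L) / 2L,
               " unique cells, too few for a rank-based matrix statistic")
  lapply(rdms, function(D) {
    if (!all(keep %in% rownames(D)))
      stop_input("RDM is missing conditions: ",
                 paste(setdiff(keep, rownames(D)), collapse = ", "))
    D[keep, keep]
  })
}

#' Split-half pattern reliability
#'
#' Enumerates every unordered way of dividing an even number of runs into
#' two halves (10 runs give choose(10, 5)/2 = 126 splits). For each split
#' the run-level patterns are averaged within each half, a condition RDM
#' is computed per half, and the two halves' vectorized RDMs are Pearson
#' correlated per participant. High mean split-half correlations indicate
#' that the condition-level representational geometry is stable across
#' independent subsets of the data.
#'
#' @param run_patterns Named list (per participant) of lists (per run) of
#'   condition x voxel matrices, as produced by
#'   [generate_patterns()]` with `return_runs = TRUE`.
#' @return List with `per_participant` (named vector of mean split-half
#'   correlations) and `n_splits`.
#' @export
split_half_rsa <- function(run_patterns) {
  if (!is.list(run_patterns) || !length(run_patterns))
    stop_input("run_patterns must be a non-empty list")
  R <- length(run_patterns[[1L]])
  if (R %% 2L != 0L) stop_input("split-half reliability requires an even run count")
  halves <- utils::combn(R, R %/% 2L)
  # keep splits whose first half contains run 1: each unordered split once
  halves <- halves[, halves[1L, ] == 1L, drop = FALSE]
  per <- vapply(run_patterns, function(runs) {
    rs <- vapply(seq_len(ncol(halves)), function(s) {
      h1 <- halves[, s]
      h2 <- setdiff(seq_len(R), h1)
      m1 <- Reduce(`+`, runs[h1]) / length(h1)
      m2 <- Reduce(`+`, runs[h2]) / length(h2)
      stats::cor(vectorize_lower(neural_rdm(m1)), vectorize_lower(neural_rdm(m2)))
    }, numeric(1L))
    mean(rs)
  }, numeric(1L))
  list(per_participant = per, n_splits = ncol(halves))
}

#' Cross-run representational dissimilarity
#'
#' Correlates condition patterns across independent runs: for every
#' unordered run pair, the cross-run condition correlation matrix is
#' computed, symmetrized, inverted to a dissimilarity, and averaged over
#' run pairs. Because the two patterns entering each correlation come from
#' different runs, run-specific noise cannot inflate the diagonal
#' similarity structure.
#'
#' @inheritParams split_half_rsa
#' @return List with `mean_rdm` (named list of condition matrices, one per
#'   participant) and `n_pairs` (number of unordered run pairs).
#' @export
cross_run_rsa <- function(run_patterns) {
  if (!is.list(run_patterns) || !length(run_patterns))
    stop_input("run_patterns must be a non-empty list")
  R <- length(run_patterns[[1L]])
  if (R < 2L) stop_input("cross-run analysis requires at least 2 runs")
  pairs <- utils::combn(R, 2L)
  rdms <- lapply(run_patterns, function(runs) {
    acc <- 0
    for (s in seq_len(ncol(pairs))) {
      Cm <- stats::cor(t(runs[[pairs[1L, s]]]), t(runs[[pairs[2L, s]]]))
      acc <- acc + (1 - (Cm + t(Cm)) / 2)
    }
    D <- acc / ncol(pairs)
    dimnames(D) <- dimnames(runs[[1L]])[c(1L, 1L)]
    D
  })
  list(mean_rdm = rdms, n_pairs = ncol(pairs))
}
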