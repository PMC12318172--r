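# Behavioral dissimilarity models built from a trait score. Both model
# families predict which participant pairs should carry similar neural
# representations: the nearest-neighbor model predicts similarity for
# pairs with close scores at any level; the Anna Karenina models predict
# similarity only for pairs in which both members score high.

check_traits <- function(traits) {
  if (!is.data.frame(traits) || !all(c("participant_id", "optimism") %in% names(traits)))
    stop_input("traits must be a data frame with participant_id and optimism columns")
  if (nrow(traits) < 2L) stop_input("at least 2 participants are required")
  if (anyDuplicated(traits$participant_id))
    stop_input("duplicate participant_id in trait table")
  if (anyNA(traits$optimism)) stop_input("missing optimism scores")
  if (diff(range(traits$optimism)) == 0)
    stop_input("all trait scores are equal: model undefined after normalization")
  invisible(TRUE)
}

model_matrix <- function(D, ids, tag) {
  dimnames(D) <- list(ids, ids)
  attr(D, "model") <- tag
  D
}

#' Nearest-neighbor trait dissimilarity model
#'
#' Pair dissimilarity is the absolute trait-score difference, normalized by
#' the largest pairwise difference so entries span [0, 1]:
#' \eqn{D_{ij} = |s_i - s_j| / \max_{kl} |s_k - s_l|}.
#'
#' @param traits Data frame with `participant_id` and `optimism` columns;
#'   scores must not all be equal.
#' @return Symmetric zero-diagonal participant matrix, max entry exactly 1.
#' @examples
#' nn_model(data.frame(participant_id = c("a", "b", "c"),
#'                     optimism = c(10, 12, 16)))
#' @export
nn_model <- function(traits) {
  check_traits(traits)
  s <- traits$optimism
  D <- abs(outer(s, s, `-`))
  D <- D / max(D)
  model_matrix(D, traits$participant_id, "nn")
}

#' Anna Karenina model from normalized trait ranks
#'
#' Participants are ranked by trait score (average ranks for ties) and each
#' rank normalized to \eqn{u_i = (r_i - 1)/(n - 1) \in [0, 1]}. Pair
#' dissimilarity is one minus the pair's mean normalized rank,
#' \eqn{D_{ij} = 1 - (u_i + u_j)/2}, so the two highest-scoring
#' participants attain the matrix minimum. The diagonal is kept at its
#' formula value \eqn{1 - u_i}; matrix statistics in this package use only
#' the off-diagonal triangle.
#'
#' @inheritParams nn_model
#' @return Symmetric participant matrix with entries in [0, 1].
#' @export
annak_rank_model <- function(traits) {
  check_traits(traits)
  u <- trait_rank_u(traits$optimism)
  D <- 1 - outer(u, u, `+`) / 2
  model_matrix(D, traits$participant_id, "annak_rank")
}

#' Anna Karenina model from mean trait scores
#'
#' Variant built from raw scores rather than ranks: the pair mean
#' \eqn{m_{ij} = (s_i + s_j)/2} is min-max normalized over unordered pairs
#' (i < j) and subtracted from 1. Unlike [annak_rank_model()], this variant
#' is sensitive to the score spacing (but invariant to positive affine
#' transforms of the score).
#'
#' @inheritParams nn_model
#' @return Symmetric participant matrix; off-diagonal entries in [0, 1].
#' @export
annak_mean_model <- function(traits) {
  check_traits(traits)
  s <- traits$optimism
  M <- outer(s, s, `+`) / 2
  off <- M[upper.tri(M)]
  D <- 1 - (M - min(off)) / (max(off) - min(off))
  model_matrix(D, traits$participant_id, "annak_mean")
}
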