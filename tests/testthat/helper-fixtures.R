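# Shared helpers for building small in-code fixtures.

# Random symmetric zero-diagonal dissimilarity matrix (Euclidean distances
# of random points, so always a valid dissimilarity).
random_dissim <- function(n, seed = NULL, ids = sprintf("s%02d", seq_len(n))) {
  make <- function() {
    D <- as.matrix(stats::dist(matrix(stats::rnorm(n * 3L), n)))
    dimnames(D) <- list(ids, ids)
    D
  }
  if (is.null(seed)) make() else withr::with_seed(seed, make())
}

trait_table <- function(scores, ids = sprintf("s%02d", seq_along(scores))) {
  data.frame(participant_id = ids, optimism = scores, stringsAsFactors = FALSE)
}

# Match fitted INDSCAL axes to planted axes by absolute config correlation
# (axis order and sign are not identified jointly with the truth).
align_axes <- function(fitted_config, true_config) {
  a <- abs(stats::cor(fitted_config, true_config, method = "spearman"))
  if (a[1L, 1L] + a[2L, 2L] >= a[1L, 2L] + a[2L, 1L]) c(1L, 2L) else c(2L, 1L)
}

# Off-diagonal upper-triangle pair (i, j) value lookup for hand checks.
pair_value <- function(M, i, j) M[i, j]
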