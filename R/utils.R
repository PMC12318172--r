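# Internal helpers shared across modules. None of these are exported.

stop_input <- function(...) stop(..., call. = FALSE)

#' @noRd
check_square_symmetric <- function(M, name = "matrix", tol = 1e-10) {
  if (!is.matrix(M) || !is.numeric(M) || nrow(M) != ncol(M))
    stop_input(name, " must be a square numeric matrix")
  if (anyNA(M) || any(!is.finite(M)))
    stop_input(name, " contains missing or non-finite entries")
  dif <- abs(M - t(M))
  if (any(dif > tol)) {
    ij <- which(dif == max(dif), arr.ind = TRUE)[1L, ]
    stop_input(sprintf(
      "%s is not symmetric: cell (%d, %d) differs from (%d, %d) by %.3g",
      name, ij[1L], ij[2L], ij[2L], ij[1L], max(dif)))
  }
  invisible(TRUE)
}

# Evaluate `code` under a temporary RNG seed (global stream untouched);
# if seed is NULL, use the current stream.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# Small deterministic string hash, used to derive per-test permutation
# seeds from a master seed so results do not depend on evaluation order.
hash_tag <- function(tag) {
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 31 + k) %% 1048576L
  as.integer(h)
}

derive_seed <- function(master, tag) {
  as.integer((as.numeric(master) + hash_tag(tag)) %% 2147483647)
}

# n x n matrix whose (i, j) entry is the position of unordered pair {i, j}
# in the vectorize_lower() order (0 on the diagonal).
pair_index <- function(n) {
  P <- matrix(0L, n, n)
  P[upper.tri(P)] <- seq_len((n * (n - 1L)) %/% 2L)
  P + t(P)
}

# All n! permutations of 1..n, one per row. Only used for n <= 8.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (pos in seq_len(n)) {
    blk <- matrix(0L, nrow(sub), n)
    blk[, pos] <- n
    blk[, -pos] <- sub
    out[row + seq_len(nrow(sub)), ] <- blk
    row <- row + nrow(sub)
  }
  out
}

# Align a named vector-producing table to a participant order.
match_participants <- function(ids, have, what) {
  idx <- match(ids, have)
  if (anyNA(idx))
    stop_input("participant order mismatch in ", what, ": missing ",
               paste(ids[is.na(idx)], collapse = ", "))
  idx
}

spearman <- function(x, y) stats::cor(rank(x), rank(y))
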