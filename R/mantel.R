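# Mantel permutation tests on participant-level dissimilarity matrices.
# The statistic is the Spearman rank correlation between the vectorized
# lower triangles; the null is generated by jointly relabeling rows and
# columns of one matrix.

check_pair <- function(A, B, min_n = 5L) {
  check_square_symmetric(A, "A")
  check_square_symmetric(B, "B")
  if (nrow(A) != nrow(B)) stop_input("A and B must have the same participants")
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B)))
    stop_input("participant order differs between A and B")
  if (nrow(A) < min_n) stop_input("at least ", min_n, " participants are required")
  invisible(nrow(A))
}

check_nonconstant <- function(v, name) {
  if (diff(range(v)) == 0)
    stop_input("lower triangle of ", name, " is constant: statistic undefined")
  invisible(TRUE)
}

mantel_result <- function(statistic, p_value, n, n_perm, tail, method, seed, tag) {
  out <- list(statistic = statistic, p_value = p_value, n = n,
              n_perm = n_perm, tail = tail, method = method, seed = seed,
              matrices_tag = tag)
  class(out) <- "mantel_result"
  out
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("<mantel_result%s> rho = %.4f, p = %.4g (%s, %s, %d permutations, n = %d)\n",
              if (is.null(x$matrices_tag)) "" else paste0(": ", x$matrices_tag),
              x$statistic, x$p_value, x$tail, x$method, x$n_perm, x$n))
  invisible(x)
}

#' Mantel permutation test (Spearman statistic)
#'
#' Tests the association between two participant-level dissimilarity
#' matrices. The observed statistic is the Spearman rank correlation
#' between the two vectorized lower triangles. Each permutation applies
#' one random relabeling of participants to the rows and columns of `B`
#' jointly; the sampled p-value includes the observed statistic in the
#' null set, \eqn{p = (1 + \#\{\rho^* \ge \rho\}) / (1 + n_{perm})}, so
#' \eqn{p \ge 1/(1 + n_{perm})}. For `n <= 8` participants (method
#' `"auto"`) the test enumerates all `n!` relabelings instead and reports
#' the exact permutation p-value.
#'
#' @param A,B Symmetric zero-diagonal matrices over the same participant
#'   order (>= 5 participants).
#' @param n_perm Number of sampled permutations (default 10000).
#' @param tail `"upper"` (one-tailed, the default) or `"two_sided"`.
#' @param seed Optional integer seed for the permutation stream.
#' @param method `"auto"` (exhaustive when `n <= 8`), `"sampled"`, or
#'   `"exhaustive"`.
#' @param tag Optional label stored in the result.
#' @return A `mantel_result`: statistic, p_value, n, n_perm, tail, method,
#'   seed.
#' @export
mantel_test <- function(A, B, n_perm = 10000L,
                        tail = c("upper", "two_sided"),
                        seed = NULL, method = c("auto", "sampled", "exhaustive"),
                        tag = NULL) {
  tail <- match.arg(tail)
  method <- match.arg(method)
  n <- check_pair(A, B)
  if (n_perm < 1L) stop_input("n_perm must be >= 1")
  a <- vectorize_lower(A)
  b <- vectorize_lower(B)
  check_nonconstant(a, "A")
  check_nonconstant(b, "B")
  ra <- rank(a)
  rb <- rank(b)
  obs <- stats::cor(ra, rb)
  PI <- pair_index(n)
  ut <- upper.tri(PI)
  perm_stat <- function(p) {
    stats::cor(ra, rb[PI[p, p][ut]])
  }
  if (method == "auto") method <- if (n <= 8L) "exhaustive" else "sampled"
  eps <- 1e-12
  if (method == "exhaustive") {
    perms <- all_permutations(n)
    stats_null <- apply(perms, 1L, perm_stat)
    hits <- if (tail == "upper") sum(stats_null >= obs - eps)
            else sum(abs(stats_null) >= abs(obs) - eps)
    p <- hits / nrow(perms)
    n_used <- nrow(perms)
  } else {
    stats_null <- with_seed_if(seed, {
      vapply(seq_len(n_perm), function(i) perm_stat(sample.int(n)), numeric(1L))
    })
    hits <- if (tail == "upper") sum(stats_null >= obs - eps)
            else sum(abs(stats_null) >= abs(obs) - eps)
    p <- (1 + hits) / (1 + n_perm)
    n_used <- as.integer(n_perm)
  }
  mantel_result(obs, p, n, n_used, tail, method, seed, tag)
}

# Spearman partial correlation of a and b given c, all pre-ranked vectors.
partial_cor <- function(ra, rb, rc) {
  r_ab <- stats::cor(ra, rb)
  r_ac <- stats::cor(ra, rc)
  r_bc <- stats::cor(rb, rc)
  (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
}

#' Partial Mantel test
#'
#' Association between `A` and `B` controlling for a covariate matrix `C`.
#' The statistic is the Spearman partial correlation of the vectorized
#' triangles of `A` and `B` given `C`; permutations jointly relabel `A`'s
#' rows and columns and recompute the partial statistic each time
#' (Legendre-style first-matrix permutation).
#'
#' @inheritParams mantel_test
#' @param C Covariate dissimilarity matrix, same participant order.
#' @return A `mantel_result`.
#' @export
partial_mantel_test <- function(A, B, C, n_perm = 10000L,
                                tail = c("upper", "two_sided"),
                                seed = NULL,
                                method = c("auto", "sampled", "exhaustive"),
                                tag = NULL) {
  tail <- match.arg(tail)
  method <- match.arg(method)
  n <- check_pair(A, B, min_n = 6L)
  check_pair(B, C, min_n = 6L)
  a <- vectorize_lower(A); b <- vectorize_lower(B); cc <- vectorize_lower(C)
  check_nonconstant(a, "A"); check_nonconstant(b, "B"); check_nonconstant(cc, "C")
  ra <- rank(a); rb <- rank(b); rc <- rank(cc)
  if (abs(stats::cor(rb, rc)) > 1 - 1e-10)
    stop_input("B and C are perfectly collinear in ranks: partial statistic undefined")
  obs <- partial_cor(ra, rb, rc)
  PI <- pair_index(n)
  ut <- upper.tri(PI)
  perm_stat <- function(p) partial_cor(ra[PI[p, p][ut]], rb, rc)
  if (method == "auto") method <- if (n <= 8L) "exhaustive" else "sampled"
  eps <- 1e-12
  if (method == "exhaustive") {
    perms <- all_permutations(n)
    stats_null <- apply(perms, 1L, perm_stat)
    hits <- if (tail == "upper") sum(stats_null >= obs - eps)
            else sum(abs(stats_null) >= abs(obs) - eps)
    p <- hits / nrow(perms)
    n_used <- nrow(perms)
  } else {
    stats_null <- with_seed_if(seed, {
      vapply(seq_len(n_perm), function(i) perm_stat(sample.int(n)), numeric(1L))
    })
    hits <- if (tail == "upper") sum(stats_null >= obs - eps)
            else sum(abs(stats_null) >= abs(obs) - eps)
    p <- (1 + hits) / (1 + n_perm)
    n_used <- as.integer(n_perm)
  }
  mantel_result(obs, p, n, n_used, tail, method, seed, tag)
}

#' Bonferroni correction across regions of interest
#'
#' Multiplies each raw permutation p-value by the number of tests (default
#' 11, the size of the default-mode-network ROI set) and caps at 1.
#'
#' @param results A list of `mantel_result` objects, or a numeric vector of
#'   raw p-values.
#' @param n_tests Number of tests corrected for; must be at least the
#'   number of results.
#' @param roi_ids Optional labels for the rows of the returned table.
#' @return Data frame with `roi`, `rho`, `p`, `p_corrected`, `n_tests`.
#' @examples
#' bonferroni_correct(c(0.004, 0.5), n_tests = 11)
#' @export
bonferroni_correct <- function(results, n_tests = 11L, roi_ids = NULL) {
  if (n_tests < 1L) stop_input("n_tests must be >= 1")
  if (is.numeric(results)) {
    p <- results
    rho <- rep(NA_real_, length(p))
  } else {
    p <- vapply(results, function(r) r$p_value, numeric(1L))
    rho <- vapply(results, function(r) r$statistic, numeric(1L))
    if (is.null(roi_ids)) roi_ids <- names(results)
  }
  if (n_tests < length(p))
    stop_input("n_tests must be at least the number of results")
  if (is.null(roi_ids)) roi_ids <- sprintf("roi%d", seq_along(p))
  data.frame(roi = roi_ids, rho = rho, p = p,
             p_corrected = stats::p.adjust(p, method = "bonferroni", n = n_tests),
             n_tests = as.integer(n_tests), stringsAsFactors = FALSE)
}
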