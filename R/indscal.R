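# Individual-differences scaling (INDSCAL): a weighted-Euclidean MDS in
# which all subjects share one condition configuration X and each subject
# k stretches it by non-negative dimension weights w_kd, so that
# d_ab^(k) = sqrt( sum_d w_kd (x_ad - x_bd)^2 ). Fitted by alternating
# SMACOF majorization (per-subject Guttman step) with closed-form updates
# of the shared configuration and the per-subject dimension scales.

# Disparity transform, applied unconditionally: one transform is fitted to
# the pooled (dissimilarity, distance) pairs of all subjects, so each
# subject's overall weight scale stays identified (a per-subject rescaling
# would absorb it).
indscal_disparities <- function(delta, d, transform) {
  switch(transform,
    ratio = {
      b <- sum(delta * d) / sum(delta^2)
      pmax(b, 0) * delta
    },
    interval = {
      fit <- stats::lm.fit(cbind(1, delta), d)
      pmax(fit$coefficients[1L] + fit$coefficients[2L] * delta, 0)
    },
    ordinal = ordinal_disparities(delta, d))
}

# Per-subject weighted distances, concatenated in subject order.
indscal_distances <- function(X, C) {
  unlist(lapply(seq_len(nrow(C)), function(k)
    config_distances(sweep(X, 2L, C[k, ], `*`))), use.names = FALSE)
}

# Stress-1 over all subjects for configuration X and scale matrix C
# (C[k, d] = sqrt(w_kd)); delta_all is the concatenated vectorized RDMs.
indscal_stress <- function(X, C, delta_all, transform) {
  d <- indscal_distances(X, C)
  dhat <- indscal_disparities(delta_all, d, transform)
  sqrt(sum((dhat - d)^2) / sum(d^2))
}

#' Fit the INDSCAL weighted-Euclidean model
#'
#' Fits a shared condition configuration and non-negative per-subject
#' dimension weights to a collection of condition RDMs, minimizing
#' Kruskal stress-1 of the subject-wise weighted Euclidean distances
#' against per-subject disparities (`"ratio"` rescaling by default;
#' `"interval"` and `"ordinal"` transforms available). The algorithm
#' alternates a per-subject Guttman majorization step with closed-form
#' least-squares updates of the shared configuration and the per-subject
#' dimension scales (clipped at zero), so stress is monotone
#' non-increasing. Initialization is classical scaling of the mean RDM
#' with unit weights, making the fit deterministic.
#'
#' Identification: configuration columns are normalized to unit root mean
#' square with the scale absorbed into the weights, dimensions are ordered
#' by total subject weight (descending), and each dimension's sign is
#' fixed so the first condition's coordinate is non-negative. Axes of the
#' weighted model are not rotatable, which is what makes the dimensions
#' interpretable.
#'
#' @param rdms Named list of symmetric condition RDMs, one per subject,
#'   sharing one condition set (>= 2 subjects).
#' @param n_dim Number of dimensions (`<= conditions - 1`).
#' @param transform `"ratio"`, `"interval"`, or `"ordinal"`.
#' @param tol Stress-decrease convergence tolerance (default 1e-6).
#' @param max_iter Maximum iterations (default 500).
#' @param seed Unused by the deterministic default; reserved for random
#'   initializations.
#' @return An object of class `indscal_solution`: `config` (condition x
#'   n_dim), `weights` (subject x n_dim, \eqn{w = c^2}), `stress1`,
#'   `stress_path`, `n_iter`, `converged`, `transform`.
#' @export
fit_indscal <- function(rdms, n_dim = 2L, transform = c("ratio", "interval", "ordinal"),
                        tol = 1e-6, max_iter = 500L, seed = NULL) {
  transform <- match.arg(transform)
  if (!is.list(rdms) || length(rdms) < 2L)
    stop_input("at least 2 subjects are required")
  for (k in seq_along(rdms)) check_square_symmetric(rdms[[k]], paste0("rdms[[", k, "]]"))
  n_cond <- nrow(rdms[[1L]])
  if (any(vapply(rdms, nrow, integer(1L)) != n_cond))
    stop_input("all RDMs must share the same condition set")
  if (n_dim > n_cond - 1L) stop_input("n_dim must be at most conditions - 1")
  deltas <- lapply(rdms, vectorize_lower)
  if (any(vapply(deltas, function(x) all(x == 0), logical(1L))))
    stop_input("degenerate all-zero RDM")
  delta_all <- unlist(deltas, use.names = FALSE)
  n_sub <- length(rdms)
  n_pair <- (n_cond * (n_cond - 1L)) %/% 2L
  PI <- pair_index(n_cond)
  ut <- upper.tri(PI)

  Dbar <- Reduce(`+`, rdms) / n_sub
  X <- stats::cmdscale(stats::as.dist(Dbar), k = n_dim)
  if (ncol(X) < n_dim)
    X <- cbind(X, matrix(1e-6 * seq_len(n_cond * (n_dim - ncol(X))), n_cond))
  # start at unit RMS columns, unit scales
  X <- sweep(X, 2L, sqrt(colMeans(X^2)), `/`)
  C <- matrix(1, n_sub, n_dim)

  s_prev <- indscal_stress(X, C, delta_all, transform)
  path <- s_prev
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    X_old <- X; C_old <- C
    # pooled disparity transform, then per-subject Guttman targets in the
    # subject's stretched space
    d_all <- indscal_distances(X, C)
    dhat_all <- indscal_disparities(delta_all, d_all, transform)
    Zs <- vector("list", n_sub)
    for (k in seq_len(n_sub)) {
      Yk <- sweep(X, 2L, C[k, ], `*`)
      dhat <- dhat_all[(k - 1L) * n_pair + seq_len(n_pair)]
      Zs[[k]] <- guttman_update(Yk, dhat, PI, ut)
    }
    # shared configuration: column-separable least squares over subjects
    for (dd in seq_len(n_dim)) {
      num <- 0; den <- 0
      for (k in seq_len(n_sub)) {
        num <- num + C[k, dd] * Zs[[k]][, dd]
        den <- den + C[k, dd]^2
      }
      if (den > 0) X[, dd] <- num / den
    }
    X <- scale(X, center = TRUE, scale = FALSE)
    # per-subject non-negative dimension scales, column-separable
    for (k in seq_len(n_sub)) {
      for (dd in seq_len(n_dim)) {
        xx <- sum(X[, dd]^2)
        C[k, dd] <- if (xx > 0) max(0, sum(X[, dd] * Zs[[k]][, dd]) / xx) else 0
      }
    }
    s_new <- indscal_stress(X, C, delta_all, transform)
    if (s_new > s_prev + 1e-10) { # safeguard: majorization bound hit numerics
      X <- X_old; C <- C_old
      converged <- TRUE
      break
    }
    path <- c(path, s_new)
    if (s_prev - s_new < tol) {
      s_prev <- s_new
      converged <- TRUE
      break
    }
    s_prev <- s_new
  }

  # identification: unit-RMS columns, weights absorb scale
  rms <- sqrt(colMeans(X^2))
  rms[rms == 0] <- 1
  X <- sweep(X, 2L, rms, `/`)
  C <- sweep(C, 2L, rms, `*`)
  W <- C^2
  # order dimensions by total subject weight, fix signs
  ord <- order(colSums(W), decreasing = TRUE)
  X <- X[, ord, drop = FALSE]
  W <- W[, ord, drop = FALSE]
  sgn <- ifelse(X[1L, ] < 0, -1, 1)
  X <- sweep(X, 2L, sgn, `*`)
  dimnames(X) <- list(rownames(rdms[[1L]]), sprintf("dim%d", seq_len(n_dim)))
  dimnames(W) <- list(names(rdms), sprintf("dim%d", seq_len(n_dim)))

  out <- list(config = X, weights = W, stress1 = s_prev, stress_path = path,
              n_iter = iter, converged = converged, transform = transform,
              n_dim = as.integer(n_dim))
  class(out) <- "indscal_solution"
  out
}

#' @export
print.indscal_solution <- function(x, ...) {
  cat(sprintf("<indscal_solution> %d conditions, %d subjects, %d dims, stress-1 = %.4f (%s, %d iterations)\n",
              nrow(x$config), nrow(x$weights), x$n_dim, x$stress1,
              x$transform, x$n_iter))
  invisible(x)
}

#' Recompute stress-1 of a fitted INDSCAL solution
#'
#' Reconstructs each subject's model distances from the stored
#' configuration and weights and recomputes stress-1 against the supplied
#' RDMs; used to verify that a reported fit is reproducible from its
#' stored fields.
#'
#' @param sol An `indscal_solution`.
#' @param rdms The RDM list the solution was fitted to.
#' @return Stress-1 value.
#' @export
indscal_stress1 <- function(sol, rdms) {
  delta_all <- unlist(lapply(rdms, vectorize_lower), use.names = FALSE)
  indscal_stress(sol$config, sqrt(sol$weights), delta_all, sol$transform)
}

#' Stress across candidate dimensionalities
#'
#' Fits the INDSCAL model once per requested dimensionality with shared
#' settings and tabulates stress-1. The table is reported as a scree; no
#' automatic elbow selection is applied, since the choice of
#' dimensionality trades fit against interpretability.
#'
#' @inheritParams fit_indscal
#' @param dims Integer vector of dimensionalities (e.g., `c(2, 3, 4)`).
#' @return Data frame with `n_dim`, `stress1`, `converged` (NA rows where
#'   a fit failed, with the error message in `error`).
#' @export
stress_scree <- function(rdms, dims = c(2L, 3L, 4L),
                         transform = "ratio", tol = 1e-6, max_iter = 500L) {
  if (!length(dims)) stop_input("dims must be non-empty")
  rows <- lapply(dims, function(k) {
    res <- tryCatch(
      fit_indscal(rdms, n_dim = k, transform = transform, tol = tol,
                  max_iter = max_iter),
      error = function(e) e)
    if (inherits(res, "error"))
      data.frame(n_dim = k, stress1 = NA_real_, converged = NA,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    else
      data.frame(n_dim = k, stress1 = res$stress1, converged = res$converged,
                 error = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlate a configuration dimension with a condition attribute
#'
#' Spearman correlation between one column of the fitted configuration and
#' a per-condition attribute (e.g., independently rated valence, or a
#' referential-target code). The p-value is one-tailed in the direction of
#' the observed sign by default, and the absolute correlation is reported
#' alongside the signed one because the sign of a scaling dimension is
#' data-arbitrary.
#'
#' @param sol An `indscal_solution`.
#' @param attribute Numeric vector, one value per condition, in the
#'   configuration's condition order.
#' @param dim_index Which dimension to interpret.
#' @param tail `"one_tailed"` (default) or `"two_sided"`.
#' @return List with `dim_index`, `rho`, `abs_rho`, `p`, `tail`.
#' @export
interpret_dimension <- function(sol, attribute, dim_index = 1L,
                                tail = c("one_tailed", "two_sided")) {
  tail <- match.arg(tail)
  x <- sol$config[, dim_index]
  if (length(attribute) != length(x))
    stop_input("attribute length must equal the number of conditions")
  if (diff(range(attribute)) == 0) stop_input("constant attribute")
  rho <- spearman(x, attribute)
  alt <- if (tail == "two_sided") "two.sided" else if (rho >= 0) "greater" else "less"
  ct <- suppressWarnings(
    stats::cor.test(x, attribute, method = "spearman", exact = FALSE,
                    alternative = alt))
  list(dim_index = as.integer(dim_index), rho = unname(ct$estimate),
       abs_rho = abs(unname(ct$estimate)), p = ct$p.value, tail = tail)
}

#' Correlate subject weights with the trait score
#'
#' Spearman correlation (two-sided p) between the fitted weights of one
#' dimension and the participants' trait scores. A positive correlation on
#' a valence dimension means high-trait participants stretch that
#' dimension, i.e., represent the corresponding contrast more distinctly.
#'
#' @param sol An `indscal_solution` whose weight rows are named by
#'   participant.
#' @param traits Trait table with `participant_id` and `optimism`.
#' @param dim_index Which dimension's weights to use.
#' @return List with `rho`, `p`, `n`, `dim_index`.
#' @export
weights_trait_correlation <- function(sol, traits, dim_index = 1L) {
  w <- sol$weights[, dim_index]
  if (is.null(names(w)))
    stop_input("weights carry no participant names; cannot align with traits")
  idx <- match_participants(names(w), traits$participant_id, "traits")
  s <- traits$optimism[idx]
  ct <- suppressWarnings(
    stats::cor.test(w, s, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(w),
       dim_index = as.integer(dim_index))
}
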