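# Nonmetric multidimensional scaling by SMACOF with ordinal scaling, and
# the kernel-density convergence analysis of the resulting embedding.

# Distances between configuration rows, in vectorize_lower() pair order.
config_distances <- function(X) {
  vectorize_lower(as.matrix(stats::dist(X)))
}

# Kruskal stress-1 for distances d and disparities dhat.
stress1_of <- function(d, dhat) sqrt(sum((dhat - d)^2) / sum(d^2))

# Monotone (primary ties) regression of d onto the order of delta.
ordinal_disparities <- function(delta, d) {
  ord <- order(delta, d) # primary approach: ties untied freely
  dhat <- numeric(length(d))
  dhat[ord] <- stats::isoreg(d[ord])$yf
  dhat
}

# One Guttman transform of X toward disparities dhat (uniform weights).
guttman_update <- function(X, dhat, PI, ut) {
  n <- nrow(X)
  d <- as.matrix(stats::dist(X))
  Dh <- matrix(0, n, n)
  Dh[ut] <- dhat[PI[ut]]
  Dh <- Dh + t(Dh)
  ratio <- ifelse(d > 0, Dh / d, 0)
  diag(ratio) <- 0
  B <- -ratio
  diag(B) <- rowSums(ratio)
  (B %*% X) / n
}

#' Nonmetric multidimensional scaling (SMACOF, ordinal)
#'
#' Embeds a participant dissimilarity matrix into `n_dim` dimensions by
#' SMACOF majorization with ordinal scaling: each iteration replaces the
#' disparities by the isotonic (primary-ties) regression of the current
#' configuration distances onto the dissimilarity order, then applies one
#' Guttman transform. Initialization is classical (Torgerson) scaling, so
#' the solution is deterministic; `init = "random"` with a seed is
#' available for stress-sensitivity checks. Iteration stops when Kruskal
#' stress-1 decreases by less than `tol` or after `max_iter` iterations;
#' non-convergence is reported in the result, not raised.
#'
#' @param D Symmetric zero-diagonal dissimilarity matrix (>= 4 rows).
#' @param n_dim Embedding dimension (default 2).
#' @param tol Stress-decrease convergence tolerance (default 1e-6).
#' @param max_iter Maximum iterations (default 300).
#' @param init `"classical"` or `"random"`.
#' @param seed Seed for `init = "random"`.
#' @return An object of class `isrsa_embedding`: `coords` (centered
#'   participant x n_dim matrix), `stress1`, `stress_path`, `n_iter`,
#'   `converged`.
#' @export
nonmetric_mds <- function(D, n_dim = 2L, tol = 1e-6, max_iter = 300L,
                          init = c("classical", "random"), seed = NULL) {
  init <- match.arg(init)
  check_square_symmetric(D, "D")
  n <- nrow(D)
  if (n < 4L) stop_input("at least 4 points are required")
  delta <- vectorize_lower(D)
  check_nonconstant(delta, "D")
  PI <- pair_index(n)
  ut <- upper.tri(PI)
  X <- if (init == "classical") {
    X0 <- stats::cmdscale(stats::as.dist(D), k = n_dim)
    if (ncol(X0) < n_dim) # rank-deficient input: pad with tiny jitter
      X0 <- cbind(X0, with_seed_if(if (is.null(seed)) 0L else seed,
        matrix(stats::rnorm(n * (n_dim - ncol(X0)), sd = 1e-6), n)))
    X0
  } else {
    with_seed_if(seed, matrix(stats::rnorm(n * n_dim), n, n_dim))
  }
  X <- scale(X, center = TRUE, scale = FALSE)
  d <- config_distances(X)
  dhat <- ordinal_disparities(delta, d)
  s_prev <- stress1_of(d, dhat)
  path <- s_prev
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    X_new <- guttman_update(X, dhat, PI, ut)
    d_new <- config_distances(X_new)
    dhat_new <- ordinal_disparities(delta, d_new)
    s_new <- stress1_of(d_new, dhat_new)
    if (s_new > s_prev + 1e-12) { # numerical safeguard; keep previous state
      iter <- iter - 1L
      converged <- TRUE
      break
    }
    X <- X_new; d <- d_new; dhat <- dhat_new
    path <- c(path, s_new)
    if (s_prev - s_new < tol) {
      s_prev <- s_new
      converged <- TRUE
      break
    }
    s_prev <- s_new
  }
  X <- scale(X, center = TRUE, scale = FALSE)
  attr(X, "scaled:center") <- NULL
  rownames(X) <- rownames(D)
  colnames(X) <- sprintf("dim%d", seq_len(n_dim))
  out <- list(coords = X, stress1 = s_prev, stress_path = path,
              n_iter = iter, converged = converged, n_dim = n_dim)
  class(out) <- "isrsa_embedding"
  out
}

#' @export
print.isrsa_embedding <- function(x, ...) {
  cat(sprintf("<isrsa_embedding> %d points in %d dims, stress-1 = %.4f (%s, %d iterations)\n",
              nrow(x$coords), x$n_dim, x$stress1,
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' Densest point of a 2-D embedding by Gaussian kernel density
#'
#' Evaluates a product-Gaussian kernel density estimate of the embedded
#' points on a regular grid spanning the bounding box expanded by 5% per
#' side, and locates the center of the grid cell with maximal density.
#' Bandwidths default to Scott's rule per axis
#' (\eqn{h_j = \hat\sigma_j n^{-1/6}} for two dimensions). Per-participant
#' Euclidean distances from the densest point quantify each participant's
#' proximity to the most populated region of the embedding.
#'
#' @param emb An `isrsa_embedding` (or any participant x 2 coordinate
#'   matrix) with >= 5 points and nonzero variance on both axes.
#' @param grid_n Grid resolution per axis (default 200).
#' @param bandwidth Optional length-2 bandwidth vector overriding Scott's
#'   rule.
#' @param pad Bounding-box expansion fraction per side (default 0.05).
#' @return List with `densest_point`, `distances` (named per-participant
#'   vector), `bandwidth`, `grid_n`, and the `density` matrix.
#' @export
densest_point <- function(emb, grid_n = 200L, bandwidth = NULL, pad = 0.05) {
  coords <- if (inherits(emb, "isrsa_embedding")) emb$coords else as.matrix(emb)
  if (ncol(coords) != 2L) stop_input("densest_point requires a 2-D embedding")
  n <- nrow(coords)
  if (n < 5L) stop_input("at least 5 points are required")
  sds <- apply(coords, 2L, stats::sd)
  if (any(sds == 0)) stop_input("zero-variance embedding axis: density undefined")
  if (is.null(bandwidth)) bandwidth <- sds * n^(-1 / 6) # Scott's rule, d = 2
  rng <- apply(coords, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  lims <- c(rng[1L, 1L] - pad * span[1L], rng[2L, 1L] + pad * span[1L],
            rng[1L, 2L] - pad * span[2L], rng[2L, 2L] + pad * span[2L])
  # MASS::kde2d uses dnorm(. / (h/4)): pass 4 * sd to get kernel sd `bandwidth`
  kde <- MASS::kde2d(coords[, 1L], coords[, 2L], h = 4 * bandwidth,
                     n = grid_n, lims = lims)
  top <- which(kde$z == max(kde$z))
  if (length(top) > 1L)
    warning("density maximum attained in ", length(top),
            " grid cells; keeping the lowest grid index")
  top <- top[1L]
  ij <- arrayInd(top, dim(kde$z))
  dp <- c(kde$x[ij[1L]], kde$y[ij[2L]])
  dists <- sqrt((coords[, 1L] - dp[1L])^2 + (coords[, 2L] - dp[2L])^2)
  names(dists) <- rownames(coords)
  list(densest_point = dp, distances = dists, bandwidth = bandwidth,
       grid_n = as.integer(grid_n), density = kde$z,
       grid = list(x = kde$x, y = kde$y))
}

#' Correlate distance-from-densest-point with the trait score
#'
#' Spearman correlation (two-sided p) between each participant's Euclidean
#' distance from the densest region of the embedding and the trait score.
#' A negative correlation means high-trait participants sit closer to the
#' most populated region, i.e., their neural representations converge.
#'
#' @param dens Result of [densest_point()].
#' @param traits Trait table with `participant_id` and `optimism`.
#' @return List with `rho`, `p`, `n`.
#' @export
distance_trait_correlation <- function(dens, traits) {
  d <- dens$distances
  if (is.null(names(d)))
    stop_input("distances carry no participant names; cannot align with traits")
  idx <- match_participants(names(d), traits$participant_id, "traits")
  s <- traits$optimism[idx]
  ct <- suppressWarnings(
    stats::cor.test(d, s, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(d))
}
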