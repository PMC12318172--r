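# Nonmetric MDS, kernel-density mode, and the convergence correlation.

test_that("perfectly embeddable distances are recovered with near-zero stress", {
  set.seed(1)
  X <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(dist(X))
  dimnames(D) <- list(paste0("s", 1:10), paste0("s", 1:10))
  e <- nonmetric_mds(D)
  expect_lt(e$stress1, 0.01)
  expect_true(e$converged)
  d_fit <- vectorize_lower(as.matrix(dist(e$coords)))
  expect_gte(cor(d_fit, vectorize_lower(D), method = "spearman"), 0.99)
  expect_equal(colMeans(e$coords), c(dim1 = 0, dim2 = 0), tolerance = 1e-10)
})

test_that("stress is non-increasing across iterations and under monotone transforms", {
  D <- random_dissim(15, seed = 2)
  e <- nonmetric_mds(D, max_iter = 500)
  expect_true(all(diff(e$stress_path) <= 1e-10))

  # ordinal scaling: squaring the dissimilarities preserves their order,
  # so the final configuration agrees up to rotation/scale
  e2 <- nonmetric_mds(D^2, max_iter = 500)
  expect_equal(e$stress1, e2$stress1, tolerance = 0.01)
  pr <- vegan::procrustes(e$coords, e2$coords, symmetric = TRUE)
  expect_lt(pr$ss, 0.01)
})

test_that("our stress agrees with MASS::isoMDS on the same data", {
  D <- random_dissim(15, seed = 3)
  e <- nonmetric_mds(D, max_iter = 1000)
  iso <- MASS::isoMDS(stats::as.dist(D), k = 2, trace = FALSE, maxit = 100)
  expect_equal(e$stress1, iso$stress / 100, tolerance = 0.02)
})

test_that("mds validates input and reports non-convergence without raising", {
  D <- random_dissim(10, seed = 4)
  Dbad <- D; Dbad[2, 3] <- Dbad[3, 2] <- NA
  expect_error(nonmetric_mds(Dbad), "missing or non-finite")
  expect_error(nonmetric_mds(D[1:3, 1:3]), "at least 4")
  e <- nonmetric_mds(D, max_iter = 2)
  expect_false(e$converged)
})

test_that("densest point lands in the populated region and is grid-stable", {
  set.seed(5)
  pts <- rbind(matrix(rnorm(60, sd = 0.3), 30, 2), c(10, 10))
  rownames(pts) <- sprintf("s%02d", 1:31)
  dp <- densest_point(pts, grid_n = 200)
  expect_lt(sqrt(sum(dp$densest_point^2)), 0.5)
  expect_equal(dp$distances[["s31"]],
               sqrt(sum((c(10, 10) - dp$densest_point)^2)))
  # doubling the resolution moves the mode by less than a coarse cell
  dp2 <- densest_point(pts, grid_n = 400)
  expect_lt(sqrt(sum((dp$densest_point - dp2$densest_point)^2)),
            diff(dp$grid$x[1:2]))

  same <- matrix(1, 6, 2)
  expect_error(densest_point(same), "zero-variance")
  expect_error(densest_point(pts[1:3, ]), "at least 5")
})

test_that("density distances are invariant to rotation of the embedding", {
  set.seed(6)
  pts <- matrix(rnorm(40), 20, 2)
  rownames(pts) <- sprintf("s%02d", 1:20)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- pts %*% R
  rownames(rot) <- rownames(pts)
  d1 <- densest_point(pts, grid_n = 300)$distances
  d2 <- densest_point(rot, grid_n = 300)$distances
  # bandwidths are axis-wise, so invariance is approximate: the distance
  # profile must keep its order and scale
  expect_gte(cor(d1, d2, method = "spearman"), 0.9)
  expect_lt(max(abs(d1 - d2)), 0.25 * stats::sd(d1))
})

test_that("distance-trait correlation detects perfect anticorrelation", {
  tr <- trait_table(c(10, 14, 18, 22, 26, 30))
  dens <- list(distances = setNames(c(6, 5, 4, 3, 2, 1), tr$participant_id))
  out <- distance_trait_correlation(dens, tr)
  expect_equal(out$rho, -1)
  expect_lt(out$p, 0.05)
  names(dens$distances)[1] <- "zzz"
  expect_error(distance_trait_correlation(dens, tr), "mismatch")
})
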