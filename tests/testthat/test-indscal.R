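# INDSCAL weighted-Euclidean scaling.

planted_instance <- function(n_cond = 8, n_sub = 12, noise_sd = 0, seed = 3) {
  withr::with_seed(seed, {
    cfg <- matrix(rnorm(n_cond * 2), n_cond, 2,
                  dimnames = list(paste0("c", seq_len(n_cond)), NULL))
    W <- cbind(runif(n_sub, 0.3, 2), runif(n_sub, 0.3, 2))
    rownames(W) <- sprintf("s%02d", seq_len(n_sub))
    list(cfg = cfg, W = W,
         rdms = planted_rdms(cfg, W, noise_sd = noise_sd, seed = seed + 1))
  })
}

test_that("exact two-dimensional data are fitted with near-zero stress", {
  # equal subject weights: the solution is rotation-invariant, so only the
  # fit (not the axis orientation) is determined
  inst <- planted_instance(n_sub = 6, noise_sd = 0)
  equal_rdms <- planted_rdms(inst$cfg, matrix(1, 6, 2,
                             dimnames = list(rownames(inst$W), NULL)))
  sol <- fit_indscal(equal_rdms, n_dim = 2)
  expect_lt(sol$stress1, 0.01)
  expect_true(sol$converged)

  # varying weights break rotational invariance: axes are recovered up to
  # order and sign
  sol_w <- fit_indscal(inst$rdms, n_dim = 2)
  expect_lt(sol_w$stress1, 0.01)
  m <- align_axes(sol_w$config, inst$cfg)
  expect_gte(abs(cor(sol_w$config[, 1], inst$cfg[, m[1]], method = "spearman")), 0.99)
  expect_gte(abs(cor(sol_w$config[, 2], inst$cfg[, m[2]], method = "spearman")), 0.99)
})

test_that("planted subject weights are recovered at low noise", {
  inst <- planted_instance(n_sub = 15, noise_sd = 0.02)
  sol <- fit_indscal(inst$rdms, n_dim = 2)
  m <- align_axes(sol$config, inst$cfg)
  expect_gte(abs(cor(sol$weights[, 1], inst$W[, m[1]], method = "spearman")), 0.9)
  expect_gte(abs(cor(sol$weights[, 2], inst$W[, m[2]], method = "spearman")), 0.9)
})

test_that("stress reconstructs from stored fields and decreases monotonically", {
  inst <- planted_instance(n_sub = 8, noise_sd = 0.1)
  sol <- fit_indscal(inst$rdms, n_dim = 2)
  expect_equal(indscal_stress1(sol, inst$rdms), sol$stress1, tolerance = 1e-8)
  expect_true(all(diff(sol$stress_path) <= 1e-10))
})

test_that("identification constraints hold after every fit", {
  inst <- planted_instance(n_sub = 10, noise_sd = 0.15, seed = 7)
  for (transform in c("ratio", "interval", "ordinal")) {
    sol <- fit_indscal(inst$rdms, n_dim = 2, transform = transform)
    expect_true(all(sol$weights >= 0))
    expect_equal(unname(sqrt(colMeans(sol$config^2))), c(1, 1), tolerance = 1e-8)
    expect_true(all(sol$config[1, ] >= 0))
    expect_gte(sum(sol$weights[, 1]), sum(sol$weights[, 2]))
  }
})

test_that("stress is non-increasing in the number of dimensions", {
  inst <- planted_instance(n_sub = 8, noise_sd = 0.2, seed = 9)
  tab <- stress_scree(inst$rdms, dims = c(2, 3, 4))
  expect_equal(tab$n_dim, c(2L, 3L, 4L))
  expect_true(all(diff(tab$stress1) <= 1e-6))
})

test_that("permuting subjects or conditions permutes the solution accordingly", {
  inst <- planted_instance(n_sub = 6, noise_sd = 0.05, seed = 11)
  sol <- fit_indscal(inst$rdms, n_dim = 2)
  ps <- c(4, 1, 6, 2, 5, 3)
  sol_s <- fit_indscal(inst$rdms[ps], n_dim = 2)
  expect_equal(sol_s$weights, sol$weights[ps, ], tolerance = 1e-4)
  pc <- c(3, 1, 8, 2, 7, 4, 6, 5)
  rdms_c <- lapply(inst$rdms, function(D) D[pc, pc])
  sol_c <- fit_indscal(rdms_c, n_dim = 2)
  # sign fixing depends on which condition comes first; compare up to sign
  for (d in 1:2) {
    a <- sol_c$config[, d]; b <- sol$config[pc, d]
    expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-3)
  }
})

test_that("input validation catches bad dimensionality and degenerate RDMs", {
  inst <- planted_instance(n_cond = 4, n_sub = 3)
  expect_error(fit_indscal(inst$rdms, n_dim = 4), "at most")
  zero <- lapply(inst$rdms, function(D) D * 0)
  expect_error(fit_indscal(zero, n_dim = 2), "all-zero")
  expect_error(fit_indscal(inst$rdms[1], n_dim = 2), "at least 2")
})

test_that("dimension interpretation correlates the configuration with attributes", {
  inst <- planted_instance(n_sub = 8, noise_sd = 0.05, seed = 13)
  sol <- fit_indscal(inst$rdms, n_dim = 2)
  self_attr <- sol$config[, 1]
  out <- interpret_dimension(sol, self_attr, dim_index = 1)
  expect_equal(out$rho, 1)
  expect_equal(out$abs_rho, 1)
  expect_error(interpret_dimension(sol, rep(1, 8), 1), "constant")
  expect_error(interpret_dimension(sol, 1:5, 1), "length")
})

test_that("weight-trait correlation is exact for planted monotone weights", {
  cfg <- planted_instance(n_sub = 10)$cfg
  tr <- trait_table(seq(8, 26, by = 2))
  W <- cbind(0.2 + 0.1 * seq_len(10), rep(1, 10))
  rownames(W) <- tr$participant_id
  sol <- fit_indscal(planted_rdms(cfg, W), n_dim = 2)
  m <- align_axes(sol$config, cfg)
  dim_var <- which(m == 1)  # fitted axis carrying the varying weights
  out <- weights_trait_correlation(sol, tr, dim_index = dim_var)
  expect_equal(out$rho, 1, tolerance = 1e-8)
})
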