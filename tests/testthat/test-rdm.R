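# Condition RDMs, vectorization and the intersubject dissimilarity matrix.

test_that("neural_rdm computes 1 - Pearson with hand-checkable entries", {
  p <- rbind(a = c(1, 2, 3, 4),
             b = c(1, 3, 2, 4),
             c = c(2, 3, 4, 5),   # a shifted: r = 1
             d = -c(1, 2, 3, 4))  # a negated: r = -1
  D <- neural_rdm(p)
  expect_equal(D["a", "b"], 0.2)   # 1 - 0.8, hand Pearson on 4 points
  expect_equal(D["a", "c"], 0)
  expect_equal(D["a", "d"], 2)
  expect_equal(diag(D), setNames(rep(0, 4), rownames(p)))
  expect_equal(D, t(D))
  expect_true(all(D >= 0 & D <= 2))
})

test_that("neural_rdm is invariant to positive affine transforms of a row", {
  set.seed(1)
  p <- matrix(rnorm(40), 5, 8, dimnames = list(paste0("c", 1:5), NULL))
  p2 <- p
  p2[3, ] <- 2.5 * p[3, ] + 7
  expect_equal(neural_rdm(p), neural_rdm(p2), tolerance = 1e-12)
})

test_that("neural_rdm rejects degenerate inputs by name", {
  p <- rbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_error(neural_rdm(p), "zero-variance.*b")
  expect_error(neural_rdm(rbind(a = 1:3)), "2 conditions")
  expect_error(neural_rdm(matrix(c(1, 2, NA, 4, 5, 6), 2, 3)), "missing")
})

test_that("vectorize_lower follows the fixed row-major lower-triangle order", {
  M <- matrix(0, 3, 3)
  M[lower.tri(M)] <- c(21, 31, 32)  # (2,1), (3,1), (3,2) column-major
  M <- M + t(M)
  expect_equal(vectorize_lower(M), c(21, 31, 32))

  M4 <- matrix(0, 4, 4)
  M4[2, 1] <- 21; M4[3, 1] <- 31; M4[3, 2] <- 32
  M4[4, 1] <- 41; M4[4, 2] <- 42; M4[4, 3] <- 43
  M4 <- M4 + t(M4)
  expect_equal(vectorize_lower(M4), c(21, 31, 32, 41, 42, 43))

  expect_length(vectorize_lower(random_dissim(8)), 28L)
  expect_length(vectorize_lower(random_dissim(6)), 15L)

  A <- matrix(rnorm(16), 4)
  expect_error(vectorize_lower(A), "not symmetric")
})

test_that("subject_dissimilarity matches a hand rank-correlation computation", {
  mk <- function(x) {
    M <- matrix(0, 3, 3); M[lower.tri(M)] <- x; M <- M + t(M)
    dimnames(M) <- list(letters[1:3], letters[1:3]); M
  }
  rdms <- list(p1 = mk(c(0.1, 0.5, 0.9)),
               p2 = mk(c(0.2, 0.4, 0.3)),
               p3 = mk(c(0.9, 0.5, 0.1)))
  D <- subject_dissimilarity(rdms)
  # for 3 untied values, Spearman rho = 1 - sum(rank diff^2) / 4
  sp <- function(x, y) 1 - sum((rank(x) - rank(y))^2) / 4
  expect_equal(D["p1", "p2"], 1 - sp(c(.1, .5, .9), c(.2, .4, .3)))
  expect_equal(D["p1", "p3"], 2)   # exact rank reversal
  expect_equal(D["p1", "p1"], 0)
  expect_true(isSymmetric(unname(D)))
})

test_that("subject_dissimilarity is invariant to monotone transforms of an RDM", {
  set.seed(2)
  rdms <- lapply(1:4, function(i) random_dissim(6, ids = paste0("c", 1:6)))
  names(rdms) <- paste0("p", 1:4)
  rdms2 <- rdms
  rdms2[[2]] <- rdms2[[2]]^2          # strictly monotone on non-negative entries
  rdms2[[4]] <- log1p(rdms2[[4]])
  expect_equal(subject_dissimilarity(rdms), subject_dissimilarity(rdms2),
               tolerance = 1e-12)
})

test_that("permuting participants permutes the dissimilarity matrix rows/columns", {
  set.seed(3)
  rdms <- lapply(1:5, function(i) random_dissim(5, ids = paste0("c", 1:5)))
  names(rdms) <- paste0("p", 1:5)
  D <- subject_dissimilarity(rdms)
  perm <- c(3, 1, 5, 2, 4)
  Dp <- subject_dissimilarity(rdms[perm])
  expect_equal(Dp, D[perm, perm], ignore_attr = TRUE)
})

test_that("subject_dissimilarity names the participant with a constant RDM", {
  ok <- random_dissim(4, seed = 4, ids = paste0("c", 1:4))
  flat <- matrix(1, 4, 4, dimnames = dimnames(ok)); diag(flat) <- 0
  expect_error(subject_dissimilarity(list(pA = ok, pB = flat)), "pB")
})

test_that("univariate control distances are absolute level differences", {
  lv <- rbind(s1 = c(1, 1, 1), s2 = c(0, 3, 4))
  colnames(lv) <- c("c1", "c2", "c3")
  rd <- univariate_distance(lv)
  expect_equal(unname(rd$s1), matrix(0, 3, 3), ignore_attr = TRUE)
  expect_equal(vectorize_lower(rd$s2), c(3, 4, 1))
  expect_equal(attr(rd$s2, "metric"), "euclidean_univariate")
  lv[1, 2] <- NA
  expect_error(univariate_distance(lv), "missing")
})

test_that("ROI extraction follows ascending linear voxel order and validates masks", {
  vol <- array(seq_len(64), c(4, 4, 4))
  mask <- array(0, c(4, 4, 4))
  keep <- c(2L, 7L, 20L, 33L, 60L)
  mask[keep] <- 1
  P <- extract_roi_patterns(list(condA = vol, condB = vol * 2), mask)
  expect_equal(dim(P), c(2L, 5L))
  expect_equal(unname(P["condA", ]), as.numeric(keep))
  expect_equal(unname(P["condB", ]), 2 * keep)

  expect_error(extract_roi_patterns(list(a = vol), array(0, c(4, 4, 4))),
               "fewer than 3")
  expect_error(extract_roi_patterns(list(a = array(0, c(3, 4, 4))), mask),
               "grid mismatch")
})
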