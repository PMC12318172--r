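# Synthetic-data generator: design presets, trait scores, planted structure.

test_that("design presets produce the full valence-by-target crossing", {
  d1 <- make_design("study1")
  expect_equal(nrow(d1$conditions), 8L)
  expect_equal(d1$trials_per_run, 16L)
  expect_equal(d1$n_runs, 10L)
  expect_setequal(
    d1$conditions$condition_id,
    as.vector(outer(c("positive", "neutral", "negative", "death"),
                    c("self", "partner"), paste, sep = "_")))

  d2 <- make_design("study2")
  expect_equal(nrow(d2$conditions), 6L)
  expect_equal(d2$trials_per_run, 12L)
  expect_false("death" %in% d2$conditions$valence)

  expect_error(make_design("study3"))
})

test_that("trait scores are integer sums in 6..30, reproducible, non-degenerate", {
  tr <- sample_trait_scores(37, seed = 1)
  expect_equal(nrow(tr), 37L)
  expect_true(all(tr$optimism >= 6 & tr$optimism <= 30))
  expect_true(all(tr$optimism == round(tr$optimism)))
  expect_identical(tr, sample_trait_scores(37, seed = 1))
  expect_gt(length(unique(sample_trait_scores(3, seed = 2)$optimism)), 1L)
  expect_error(sample_trait_scores(1), "n must be")

  # uniform-sum construction: mean of 6 items on 1..5 is 18
  big <- sample_trait_scores(1000, seed = 7)
  expect_gt(mean(big$optimism), 16)
  expect_lt(mean(big$optimism), 20)
})

test_that("pattern generation is deterministic and validates its inputs", {
  tr <- sample_trait_scores(8, seed = 2)
  st <- planted_structure("annak", seed = 11)
  ds1 <- generate_patterns(make_design("study1"), tr, st, n_voxels = 20)
  ds2 <- generate_patterns(make_design("study1"), tr, st, n_voxels = 20)
  expect_identical(ds1$patterns, ds2$patterns)
  expect_equal(names(ds1$patterns), tr$participant_id)
  expect_equal(dim(ds1$patterns[[1]]), c(8L, 20L))
  expect_error(
    generate_patterns(make_design("study1"), tr, st, n_voxels = 5),
    "n_voxels")
})

test_that("noiseless equal-weight planting makes all participants identical", {
  tr <- trait_table(c(10, 14, 18, 22, 26))
  st <- planted_structure("annak", noise_sd = 0,
                          weight_trait_slope_dim1 = 0,
                          weight_trait_slope_dim2 = 0, seed = 3)
  ds <- generate_patterns(make_design("study1"), tr, st, n_voxels = 20)
  rdms <- lapply(ds$patterns, neural_rdm)
  # the two top-trait participants (indeed all) share one RDM exactly
  expect_equal(rdms[["s04"]], rdms[["s05"]], tolerance = 1e-12)
  # patterns differ only by a positive scalar, so after absorbing
  # last-bit rounding the Spearman subject dissimilarity is exactly zero
  rounded <- lapply(rdms, round, digits = 9)
  D <- subject_dissimilarity(rounded)
  expect_equal(D["s04", "s05"], 0)
})

test_that("planted annak structure yields dissimilarity decreasing in mean trait rank", {
  ds <- simulate_dataset("study1", n_subjects = 25, kind = "annak",
                         seed = 19, n_voxels = 40)
  D <- subject_dissimilarity(lapply(ds$patterns, neural_rdm))
  u <- ds$truth$u[rownames(D)]
  mean_rank <- outer(u, u, `+`)[upper.tri(D)] / 2
  expect_lt(cor(vectorize_lower(D), mean_rank, method = "spearman"), -0.5)
})

test_that("null structure is exchangeable with respect to traits", {
  # same patterns regardless of trait values under kind = null
  d <- make_design("study2")
  st <- planted_structure("null", seed = 5)
  p1 <- generate_patterns(d, trait_table(c(8, 12, 20, 28)), st, n_voxels = 15)
  p2 <- generate_patterns(d, trait_table(c(28, 8, 20, 12)), st, n_voxels = 15)
  expect_identical(p1$patterns, p2$patterns)
})

test_that("tsv fixtures round-trip bitwise and record bookkeeping", {
  ds <- simulate_dataset("study2", n_subjects = 4, seed = 9, n_voxels = 12)
  dir <- withr::local_tempdir()
  write_fixture(ds, dir, format = "tsv")
  back <- read_fixture(dir, from = "tsv")
  expect_equal(back$patterns, ds$patterns)
  expect_equal(back$manifest$n_participants, nrow(ds$traits))
  expect_equal(back$traits$optimism, ds$traits$optimism)
  expect_equal(back$design$trials_per_run, ds$design$trials_per_run)
})

test_that("nifti fixtures reproduce the written patterns through ROI extraction", {
  ds <- simulate_dataset("study2", n_subjects = 3, seed = 13, n_voxels = 10)
  dir <- withr::local_tempdir()
  write_fixture(ds, dir, format = "nifti+tsv")
  back <- read_fixture(dir, from = "nifti")
  expect_equal(back$patterns, ds$patterns, tolerance = 1e-6)
})
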