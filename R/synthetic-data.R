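#' Condition design for an episodic future-thinking experiment
#'
#' Builds the full crossing of emotional valence and referential target used
#' by the two study presets. The `study1` preset crosses four valence levels
#' (positive, neutral, negative, death) with two referential targets
#' (self, partner) for 8 conditions and 16 trials per run; `study2` drops the
#' death-related valence level for 6 conditions and 12 trials per run. Both
#' presets use 10 runs with 2 trials per condition per run.
#'
#' The `valence_score` column carries a mean rated valence per condition on a
#' 1 (extremely positive) to 8 (extremely negative) scale, emulating ratings
#' by an independent stimulus-validation sample; it is the condition
#' attribute used when interpreting recovered scaling dimensions.
#'
#' @param study `"study1"` or `"study2"`.
#' @return An object of class `ft_design`: a list with elements `conditions`
#'   (data.frame with `condition_id`, `valence`, `target`, `valence_score`,
#'   `target_code`), `n_runs`, `trials_per_condition_per_run`, and
#'   `trials_per_run`.
#' @examples
#' d <- make_design("study1")
#' d$trials_per_run # 16
#' @export
make_design <- function(study = c("study1", "study2")) {
  study <- match.arg(study)
  valences <- switch(study,
    study1 = c("positive", "neutral", "negative", "death"),
    study2 = c("positive", "neutral", "negative"))
  # mean rated valence, 1 = extremely positive .. 8 = extremely negative
  valence_scores <- c(positive = 2, neutral = 4.5, negative = 6.5, death = 7.5)
  targets <- c("self", "partner")
  grid <- expand.grid(valence = valences, target = targets,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  conditions <- data.frame(
    condition_id = paste(grid$valence, grid$target, sep = "_"),
    valence = grid$valence,
    target = grid$target,
    valence_score = unname(valence_scores[grid$valence]),
    target_code = ifelse(grid$target == "self", 1, -1),
    stringsAsFactors = FALSE)
  tpc <- 2L
  out <- list(
    study = study,
    conditions = conditions,
    n_runs = 10L,
    trials_per_condition_per_run = tpc,
    trials_per_run = nrow(conditions) * tpc)
  class(out) <- "ft_design"
  out
}

#' @export
print.ft_design <- function(x, ...) {
  cat(sprintf("<ft_design> %s: %d conditions (%s x %s), %d runs, %d trials/run\n",
              x$study, nrow(x$conditions),
              paste(unique(x$conditions$valence), collapse = "/"),
              paste(unique(x$conditions$target), collapse = "/"),
              x$n_runs, x$trials_per_run))
  invisible(x)
}

#' Sample integer trait scores emulating a summed 6-item questionnaire
#'
#' Draws `n` optimism-like scores, each the sum of six items scored 1-5
#' (so scores lie in 6..30 with mean 18). Degenerate draws in which all
#' participants tie on the total are resampled, because both trait
#' dissimilarity models are undefined for constant scores.
#'
#' @param n Number of participants (>= 2).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @return Data frame with columns `participant_id` and `optimism`.
#' @examples
#' tr <- sample_trait_scores(10, seed = 1)
#' range(tr$optimism)
#' @export
sample_trait_scores <- function(n, seed = NULL) {
  if (length(n) != 1L || !is.finite(n) || n < 2)
    stop_input("n must be a single integer >= 2")
  n <- as.integer(n)
  scores <- with_seed_if(seed, {
    repeat {
      s <- vapply(seq_len(n),
                  function(i) sum(sample.int(5L, 6L, replace = TRUE)),
                  integer(1L))
      if (length(unique(s)) >= 2L) break
    }
    s
  })
  data.frame(participant_id = sprintf("sub%03d", seq_len(n)),
             optimism = scores, stringsAsFactors = FALSE)
}

#' Describe a planted intersubject structure
#'
#' Container for the ground truth the synthetic generator plants in voxel
#' patterns. Three kinds are supported:
#' \describe{
#'   \item{`annak`}{high-trait participants share a common signal while
#'     low-trait participants receive idiosyncratic noise: the pattern of
#'     participant \eqn{k} is \eqn{a(u_k) S_k + (1 - u_k)\,\sigma E_k},
#'     where \eqn{u_k} is the normalized trait rank, \eqn{a(u) = 0.15 +
#'     0.85u} (floored so the lowest-ranked participant keeps a nonzero
#'     signal), \eqn{S_k} is the participant's embedding of the shared 2-D
#'     configuration scaled by the participant's planted dimension weights,
#'     and \eqn{E_k} is a fixed participant-unique Gaussian template.}
#'   \item{`nn`}{neural similarity tracks trait-score proximity regardless
#'     of level: patterns interpolate between two shared templates along
#'     the min-max-normalized score.}
#'   \item{`null`}{patterns are exchangeable with respect to the trait
#'     (common signal plus independent noise).}
#' }
#' The planted subject weights are \eqn{w_{kd} = \max(w_{min},\ 1 +
#' \beta_d (u_k - 1/2))}; the defaults \eqn{\beta_1 = 1.2} (valence axis)
#' and \eqn{\beta_2 = -0.8} (target axis) make high-trait participants
#' stretch the valence dimension and compress the self/other dimension.
#'
#' @param kind `"annak"`, `"nn"` or `"null"`.
#' @param noise_sd Scale of the idiosyncratic/measurement noise relative to
#'   the unit-RMS signal. Default 1.
#' @param weight_trait_slope_dim1,weight_trait_slope_dim2 Linear slopes of
#'   the planted subject weights in the normalized trait rank.
#' @param run_noise_sd Independent Gaussian noise added to each run-level
#'   pattern. Default 0.5.
#' @param seed Integer seed governing every random draw of the generator.
#' @return An object of class `planted_structure`.
#' @export
planted_structure <- function(kind = c("annak", "nn", "null"),
                              noise_sd = 1,
                              weight_trait_slope_dim1 = 1.2,
                              weight_trait_slope_dim2 = -0.8,
                              run_noise_sd = 0.5,
                              seed = 1L) {
  kind <- match.arg(kind)
  if (noise_sd < 0) stop_input("noise_sd must be non-negative")
  out <- list(kind = kind, noise_sd = noise_sd,
              weight_trait_slope_dim1 = weight_trait_slope_dim1,
              weight_trait_slope_dim2 = weight_trait_slope_dim2,
              run_noise_sd = run_noise_sd,
              signal_floor = 0.15,
              weight_floor = 0.05,
              seed = as.integer(seed))
  class(out) <- "planted_structure"
  out
}

# Shared 2-D configuration implied by a design: dim 1 = standardized rated
# valence, dim 2 = standardized referential-target code.
design_config <- function(design) {
  cfg <- cbind(valence = scale(design$conditions$valence_score)[, 1L],
               target = scale(design$conditions$target_code)[, 1L])
  rownames(cfg) <- design$conditions$condition_id
  cfg
}

# Planted per-participant dimension weights under an annak structure.
planted_weights <- function(structure, u) {
  w1 <- pmax(structure$weight_floor,
             1 + structure$weight_trait_slope_dim1 * (u - 0.5))
  w2 <- pmax(structure$weight_floor,
             1 + structure$weight_trait_slope_dim2 * (u - 0.5))
  cbind(dim1 = w1, dim2 = w2)
}

# Normalized trait rank u in [0, 1] (average ranks for ties).
trait_rank_u <- function(scores) {
  n <- length(scores)
  (rank(scores, ties.method = "average") - 1) / (n - 1)
}

#' Generate per-participant voxel patterns with planted structure
#'
#' Simulates one region's condition-by-voxel t-statistic patterns for every
#' participant, with the intersubject structure described by a
#' [planted_structure()]. The shared two-dimensional configuration is the
#' design's standardized valence and target codes, embedded into voxel
#' space by a random orthonormal map (orthogonal to the constant vector, so
#' condition correlations reflect the planted weighted geometry). All
#' randomness flows from `structure$seed`.
#'
#' @param design An [make_design()] object.
#' @param traits A trait table as returned by [sample_trait_scores()].
#' @param structure A [planted_structure()].
#' @param n_voxels Number of voxels (>= number of conditions + 2).
#' @param return_runs If `TRUE`, also simulate `design$n_runs` run-level
#'   pattern matrices per participant (participant pattern plus independent
#'   run noise).
#' @return An object of class `isrsa_dataset`: list with `design`, `traits`,
#'   `structure`, `patterns` (named list of condition x voxel matrices),
#'   `run_patterns` (if requested), and `truth` (planted normalized ranks,
#'   subject weights and configuration).
#' @export
generate_patterns <- function(design, traits, structure, n_voxels = 60L,
                              return_runs = FALSE) {
  stopifnot(inherits(design, "ft_design"), inherits(structure, "planted_structure"))
  n_cond <- nrow(design$conditions)
  if (n_voxels < n_cond + 2)
    stop_input("n_voxels must be at least the number of conditions + 2")
  if (anyDuplicated(traits$participant_id))
    stop_input("participant_ids must be unique")
  n <- nrow(traits)
  cfg <- design_config(design)
  u <- trait_rank_u(traits$optimism)
  W <- planted_weights(structure, u)
  rownames(W) <- traits$participant_id

  dat <- with_seed_if(structure$seed, {
    # orthonormal 2-column voxel basis orthogonal to the constant vector
    Q <- matrix(stats::rnorm(n_voxels * 3L), n_voxels, 3L)
    Q[, 1L] <- 1
    Q <- qr.Q(qr(Q))[, 2:3, drop = FALSE]
    shared_template <- function(w) {
      S <- (sqrt(w[1L]) * cfg[, 1L]) %o% Q[, 1L] +
           (sqrt(w[2L]) * cfg[, 2L]) %o% Q[, 2L]
      S / sqrt(mean(S^2))
    }
    S0 <- shared_template(c(1, 1))
    S1 <- {
      # independent second template for the nn structure
      A <- matrix(stats::rnorm(n_cond * n_voxels), n_cond, n_voxels)
      A / sqrt(mean(A^2))
    }
    v <- if (diff(range(traits$optimism)) > 0)
      (traits$optimism - min(traits$optimism)) / diff(range(traits$optimism))
    else rep(0.5, n)
    pats <- vector("list", n)
    for (k in seq_len(n)) {
      E <- matrix(stats::rnorm(n_cond * n_voxels), n_cond, n_voxels)
      P <- switch(structure$kind,
        annak = {
          a <- structure$signal_floor + (1 - structure$signal_floor) * u[k]
          a * shared_template(W[k, ]) + (1 - u[k]) * structure$noise_sd * E
        },
        nn = {
          th <- pi / 2 * v[k]
          cos(th) * S0 + sin(th) * S1 + 0.5 * structure$noise_sd * E
        },
        null = S0 + structure$noise_sd * E)
      dimnames(P) <- list(design$conditions$condition_id,
                          sprintf("v%04d", seq_len(n_voxels)))
      pats[[k]] <- P
    }
    names(pats) <- traits$participant_id
    runs <- NULL
    if (return_runs) {
      runs <- lapply(pats, function(P) {
        lapply(seq_len(design$n_runs), function(r) {
          P + structure$run_noise_sd *
            matrix(stats::rnorm(length(P)), nrow(P), ncol(P),
                   dimnames = dimnames(P))
        })
      })
    }
    list(patterns = pats, run_patterns = runs)
  })

  out <- list(design = design, traits = traits, structure = structure,
              patterns = dat$patterns, run_patterns = dat$run_patterns,
              truth = list(u = stats::setNames(u, traits$participant_id),
                           weights = W, config = cfg))
  class(out) <- "isrsa_dataset"
  out
}

#' Simulate a complete multi-subject dataset
#'
#' Convenience wrapper: trait scores, design preset and planted structure in
#' one call. Trait scores are drawn from `seed + 1` and the pattern
#' generator from `seed`, so a single integer reproduces the whole dataset.
#'
#' @param study Design preset passed to [make_design()].
#' @param n_subjects Number of participants.
#' @param kind,noise_sd,... Passed to [planted_structure()].
#' @param n_voxels,return_runs Passed to [generate_patterns()].
#' @param seed Master seed.
#' @return An `isrsa_dataset`; see [generate_patterns()].
#' @export
simulate_dataset <- function(study = "study1", n_subjects = 37L,
                             kind = "annak", noise_sd = 1, n_voxels = 60L,
                             return_runs = FALSE, seed = 1L, ...) {
  design <- make_design(study)
  traits <- sample_trait_scores(n_subjects, seed = seed + 1L)
  structure <- planted_structure(kind = kind, noise_sd = noise_sd,
                                 seed = seed, ...)
  generate_patterns(design, traits, structure, n_voxels = n_voxels,
                    return_runs = return_runs)
}

#' @export
print.isrsa_dataset <- function(x, ...) {
  cat(sprintf("<isrsa_dataset> %s, %d participants, %d conditions x %d voxels, planted '%s'%s\n",
              x$design$study, nrow(x$traits), nrow(x$design$conditions),
              ncol(x$patterns[[1L]]), x$structure$kind,
              if (is.null(x$run_patterns)) "" else
                sprintf(", %d runs", x$design$n_runs)))
  invisible(x)
}

#' Exact weighted-Euclidean RDMs from a planted configuration
#'
#' Builds, for each participant, the condition-by-condition matrix of
#' weighted Euclidean distances \eqn{d_{ab}^{(k)} = \sqrt{\sum_d w_{kd}
#' (x_{ad} - x_{bd})^2}} implied by a configuration and per-subject
#' dimension weights, optionally perturbed by symmetric Gaussian noise.
#' These are exact realizations of the individual-differences scaling
#' model, used as ground truth in recovery checks.
#'
#' @param config Condition x n_dim coordinate matrix.
#' @param weights Participant x n_dim non-negative weight matrix.
#' @param noise_sd Standard deviation of additive noise on the distances
#'   (applied symmetrically; negative entries truncated at 0).
#' @param seed Optional seed for the noise.
#' @return Named list of symmetric zero-diagonal matrices.
#' @export
planted_rdms <- function(config, weights, noise_sd = 0, seed = NULL) {
  config <- as.matrix(config)
  weights <- as.matrix(weights)
  if (ncol(config) != ncol(weights))
    stop_input("config and weights must agree in the number of dimensions")
  if (any(weights < 0)) stop_input("weights must be non-negative")
  ids <- rownames(weights)
  if (is.null(ids)) ids <- sprintf("sub%03d", seq_len(nrow(weights)))
  with_seed_if(seed, {
    out <- lapply(seq_len(nrow(weights)), function(k) {
      Y <- sweep(config, 2L, sqrt(weights[k, ]), `*`)
      D <- as.matrix(stats::dist(Y))
      if (noise_sd > 0) {
        Ns <- matrix(0, nrow(D), ncol(D))
        Ns[upper.tri(Ns)] <- stats::rnorm(sum(upper.tri(Ns)), sd = noise_sd)
        D <- pmax(D + Ns + t(Ns), 0)
        diag(D) <- 0
      }
      dimnames(D) <- list(rownames(config), rownames(config))
      D
    })
    names(out) <- ids
    out
  })
}
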