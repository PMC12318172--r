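# End-to-end orchestration: patterns -> condition RDMs -> intersubject
# dissimilarity -> {model Mantel tests with Bonferroni; MDS + density;
# INDSCAL scree, interpretation and weight-trait correlations}, collected
# into one machine-readable report.

model_fun <- function(tag) {
  switch(tag,
    nn = nn_model,
    annak_rank = annak_rank_model,
    annak_mean = annak_mean_model,
    stop_input("unknown model tag '", tag, "'"))
}

#' Run the full intersubject analysis pipeline
#'
#' Executes the complete analysis on a simulated or loaded dataset: per
#' participant condition RDMs (1 - Pearson), the intersubject Spearman
#' dissimilarity matrix, Mantel tests of every requested trait model with
#' Bonferroni correction across regions, nonmetric MDS of the focal
#' region's intersubject matrix with kernel-density convergence analysis,
#' and an INDSCAL scree with dimension interpretation (against rated
#' valence and the referential-target code) and weight-trait correlations.
#' Every permutation seed is derived deterministically from the single
#' master seed and the roi/model tag, so the report is reproducible and
#' independent of evaluation order.
#'
#' @param dataset An `isrsa_dataset` (single region), or a list with
#'   `design`, `traits` and `patterns` where `patterns` may be a named
#'   list of regions, each a named list of participant matrices.
#' @param models Character vector of trait model tags among `"nn"`,
#'   `"annak_rank"`, `"annak_mean"`.
#' @param n_perm Mantel permutations (default 1000).
#' @param seed Master seed.
#' @param tail Mantel tail, `"upper"` or `"two_sided"`.
#' @param n_tests Bonferroni denominator; defaults to the number of
#'   regions analyzed.
#' @param mds_grid Kernel-density grid resolution.
#' @param indscal_dims Dimensionalities for the INDSCAL scree; the first
#'   entry is used for interpretation and weight correlations.
#' @param transform INDSCAL disparity transform.
#' @param focal_roi Region used for the MDS and INDSCAL stages (default:
#'   first region).
#' @param out_dir If non-NULL, write `report.json` plus TSV artifacts
#'   (intersubject matrices, MDS coordinates, INDSCAL configuration and
#'   weights) under this directory.
#' @return The report, an object of class `isrsa_report` (a nested list).
#' @export
run_pipeline <- function(dataset, models = c("nn", "annak_rank"),
                         n_perm = 1000L, seed = 1L,
                         tail = "upper", n_tests = NULL,
                         mds_grid = 200L, indscal_dims = c(2L, 3L),
                         transform = "ratio", focal_roi = NULL,
                         out_dir = NULL) {
  design <- dataset$design
  traits <- dataset$traits
  rois <- dataset$patterns
  if (is.matrix(rois[[1L]])) rois <- list(roi1 = rois)
  if (is.null(focal_roi)) focal_roi <- names(rois)[1L]
  if (!focal_roi %in% names(rois)) stop_input("unknown focal_roi '", focal_roi, "'")
  if (is.null(n_tests)) n_tests <- length(rois)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_input("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  model_mats <- stage("trait_models",
    lapply(stats::setNames(models, models), function(m) model_fun(m)(traits)))

  roi_rdms <- stage("neural_rdm", lapply(rois, function(p) lapply(p, neural_rdm)))
  roi_dissim <- stage("subject_dissimilarity",
                      lapply(roi_rdms, subject_dissimilarity))

  isrsa_results <- list()
  for (m in models) {
    per_roi <- lapply(names(rois), function(rn) {
      mantel_test(roi_dissim[[rn]], model_mats[[m]], n_perm = n_perm,
                  tail = tail, seed = derive_seed(seed, paste(rn, m)),
                  method = "sampled", tag = paste(rn, m))
    })
    names(per_roi) <- names(rois)
    tab <- bonferroni_correct(per_roi, n_tests = max(n_tests, length(per_roi)))
    isrsa_results[[m]] <- tab
  }

  D_focal <- roi_dissim[[focal_roi]]
  emb <- stage("nonmetric_mds", nonmetric_mds(D_focal, n_dim = 2L))
  dens <- stage("densest_point", densest_point(emb, grid_n = mds_grid))
  conv <- stage("distance_trait_correlation",
                distance_trait_correlation(dens, traits))

  focal_rdms <- roi_rdms[[focal_roi]]
  scree <- stage("stress_scree",
                 stress_scree(focal_rdms, dims = indscal_dims,
                              transform = transform))
  sol <- stage("fit_indscal",
               fit_indscal(focal_rdms, n_dim = indscal_dims[1L],
                           transform = transform))
  cond <- design$conditions[match(rownames(sol$config),
                                  design$conditions$condition_id), ]
  interp <- list(
    valence = interpret_dimension(sol, cond$valence_score, dim_index = 1L),
    target = interpret_dimension(sol, cond$target_code,
                                 dim_index = min(2L, sol$n_dim)))
  wcor <- lapply(seq_len(sol$n_dim), function(d)
    weights_trait_correlation(sol, traits, dim_index = d))

  report <- list(
    config = list(models = models, n_perm = as.integer(n_perm),
                  seed = as.integer(seed), tail = tail,
                  n_tests = as.integer(max(n_tests, length(rois))),
                  mds_grid = as.integer(mds_grid),
                  indscal_dims = as.integer(indscal_dims),
                  transform = transform, focal_roi = focal_roi,
                  package_version = as.character(utils::packageVersion("isrsa"))),
    data = list(study = design$study,
                n_participants = nrow(traits),
                n_conditions = nrow(design$conditions),
                rois = names(rois)),
    isrsa = isrsa_results,
    mds = list(stress1 = emb$stress1, converged = emb$converged,
               densest_point = dens$densest_point,
               distance_trait_rho = conv$rho, distance_trait_p = conv$p),
    indscal = list(scree = scree, stress1 = sol$stress1,
                   n_dim = sol$n_dim, converged = sol$converged,
                   dimension_interpretation = interp,
                   weight_trait = wcor))
  class(report) <- c("isrsa_report", "list")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         dataframe = "rows")
    for (rn in names(roi_dissim))
      write_matrix_tsv(roi_dissim[[rn]],
                       file.path(out_dir, paste0("subject_dissim_", rn, ".tsv")))
    write_matrix_tsv(emb$coords, file.path(out_dir, "mds_coords.tsv"))
    write_matrix_tsv(sol$config, file.path(out_dir, "indscal_config.tsv"))
    write_matrix_tsv(sol$weights, file.path(out_dir, "indscal_weights.tsv"))
  }
  report
}

#' @export
print.isrsa_report <- function(x, ...) {
  cat(sprintf("<isrsa_report> %s, n = %d, regions: %s\n",
              x$data$study, x$data$n_participants,
              paste(x$data$rois, collapse = ", ")))
  for (m in names(x$isrsa)) {
    tab <- x$isrsa[[m]]
    cat(sprintf("  %-11s rho = %s, corrected p = %s\n", m,
                paste(sprintf("%.3f", tab$rho), collapse = "/"),
                paste(sprintf("%.4f", tab$p_corrected), collapse = "/")))
  }
  cat(sprintf("  MDS stress-1 = %.3f, distance-trait rho = %.3f (p = %.4g)\n",
              x$mds$stress1, x$mds$distance_trait_rho, x$mds$distance_trait_p))
  cat(sprintf("  INDSCAL stress-1 (%s) = %s; weight-trait rho = %s\n",
              paste(x$indscal$scree$n_dim, collapse = "/"),
              paste(sprintf("%.3f", x$indscal$scree$stress1), collapse = "/"),
              paste(sprintf("%.3f",
                            vapply(x$indscal$weight_trait, `[[`, 0, "rho")),
                    collapse = "/")))
  invisible(x)
}
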