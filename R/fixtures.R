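# Fixture writer/reader: serialize a simulated dataset to plain-text TSV
# (optionally with toy NIfTI volumes) and read it back losslessly.

design_table <- function(design) {
  cbind(design$conditions,
        n_runs = design$n_runs,
        trials_per_condition_per_run = design$trials_per_condition_per_run,
        study = design$study)
}

# Smallest cubic grid holding n voxels.
fixture_grid_dim <- function(n_voxels) {
  side <- ceiling(n_voxels^(1 / 3))
  rep(as.integer(side), 3L)
}

#' Write a simulated dataset to disk
#'
#' Serializes a dataset's design table, trait table and per-participant
#' pattern matrices as TSV files with a JSON manifest. Under
#' `format = "nifti+tsv"`, each participant's patterns are additionally
#' written as a 4-D NIfTI volume (conditions along the fourth dimension)
#' on a toy cubic grid together with a binary region mask occupying the
#' first `n_voxels` linear indices, so that mask extraction reproduces the
#' TSV matrices exactly.
#'
#' @param dataset An `isrsa_dataset`.
#' @param out_dir Output directory (created if missing).
#' @param format `"tsv"` or `"nifti+tsv"`.
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(dataset, out_dir, format = c("tsv", "nifti+tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "isrsa_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_input("cannot create output directory ", out_dir)
  utils::write.table(design_table(dataset$design),
                     file.path(out_dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(dataset$traits, file.path(out_dir, "traits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  pat_dir <- file.path(out_dir, "patterns")
  dir.create(pat_dir, showWarnings = FALSE)
  for (id in names(dataset$patterns))
    write_matrix_tsv(dataset$patterns[[id]], file.path(pat_dir, paste0(id, ".tsv")))
  nifti <- format == "nifti+tsv"
  if (nifti) {
    nv <- ncol(dataset$patterns[[1L]])
    gd <- fixture_grid_dim(nv)
    mask <- array(0, gd)
    mask[seq_len(nv)] <- 1
    nii_dir <- file.path(out_dir, "nifti")
    dir.create(nii_dir, showWarnings = FALSE)
    RNifti::writeNifti(RNifti::asNifti(mask), file.path(nii_dir, "mask.nii"))
    for (id in names(dataset$patterns)) {
      P <- dataset$patterns[[id]]
      vol <- array(0, c(gd, nrow(P)))
      for (cnd in seq_len(nrow(P))) {
        v3 <- array(0, gd)
        v3[seq_len(nv)] <- P[cnd, ]
        vol[, , , cnd] <- v3
      }
      RNifti::writeNifti(RNifti::asNifti(vol),
                         file.path(nii_dir, paste0(id, ".nii")))
    }
  }
  manifest <- list(
    format = format,
    study = dataset$design$study,
    n_participants = nrow(dataset$traits),
    n_conditions = nrow(dataset$design$conditions),
    n_voxels = ncol(dataset$patterns[[1L]]),
    structure_kind = dataset$structure$kind,
    noise_sd = dataset$structure$noise_sd,
    seed = dataset$structure$seed,
    participants = names(dataset$patterns),
    condition_order = rownames(dataset$patterns[[1L]]))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read a dataset fixture written by [write_fixture()]
#'
#' @param dir Fixture directory.
#' @param from `"tsv"` (read the pattern TSVs) or `"nifti"` (re-extract
#'   the patterns from the NIfTI volumes through the mask).
#' @return List with `design`, `traits`, `patterns`, `manifest`.
#' @export
read_fixture <- function(dir, from = c("tsv", "nifti")) {
  from <- match.arg(from)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  design <- read_design(file.path(dir, "design.tsv"))
  traits <- read_traits(file.path(dir, "traits.tsv"))
  ids <- manifest$participants
  if (from == "tsv") {
    patterns <- lapply(ids, function(id)
      read_matrix_tsv(file.path(dir, "patterns", paste0(id, ".tsv"))))
  } else {
    mask <- RNifti::readNifti(file.path(dir, "nifti", "mask.nii"))
    patterns <- lapply(ids, function(id) {
      vol <- RNifti::readNifti(file.path(dir, "nifti", paste0(id, ".nii")))
      P <- extract_roi_patterns(vol, mask,
                                condition_ids = manifest$condition_order)
      colnames(P) <- sprintf("v%04d", seq_len(ncol(P)))
      P
    })
  }
  names(patterns) <- ids
  list(design = design, traits = traits, patterns = patterns,
       manifest = manifest)
}
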