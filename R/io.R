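# Strict TSV readers and writers. Matrix files carry both row and column
# labels; label order is authoritative.

#' Write a labeled matrix as TSV
#'
#' @param M Numeric matrix with row and column names.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(M, path) {
  if (is.null(rownames(M)) || is.null(colnames(M)))
    stop_input("matrix must carry row and column labels")
  df <- data.frame(id = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a labeled matrix from TSV
#'
#' @param path Input file written by [write_matrix_tsv()] (first column =
#'   row labels, header = column labels).
#' @param symmetric If `TRUE`, validate symmetry (tolerance 1e-10) and
#'   report the offending cell on failure.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path, symmetric = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop_input(path, ": expected a label column plus data columns")
  M <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(M)) stop_input(path, ": non-numeric cells in matrix body")
  rownames(M) <- df[[1L]]
  if (anyNA(M)) {
    ij <- which(is.na(M), arr.ind = TRUE)[1L, ]
    stop_input(path, ": missing value at row ", ij[1L], ", column ", ij[2L])
  }
  if (symmetric) check_square_symmetric(M, path)
  M
}

#' Read a participant trait table
#'
#' @param path TSV with columns `participant_id` and `optimism` (optional
#'   extra covariate columns are kept).
#' @return Data frame.
#' @export
read_traits <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("participant_id", "optimism") %in% names(df)))
    stop_input(path, ": required columns participant_id, optimism")
  if (anyDuplicated(df$participant_id))
    stop_input(path, ": duplicate participant_id '",
               df$participant_id[duplicated(df$participant_id)][1L], "'")
  if (anyNA(df$optimism)) stop_input(path, ": missing optimism scores")
  df
}

#' Read a condition design table
#'
#' @param path TSV with columns `condition_id`, `valence`, `target`,
#'   `valence_score`, `target_code`, plus attributes `n_runs` and
#'   `trials_per_condition_per_run` encoded as columns of constants.
#' @return An `ft_design` object.
#' @export
read_design <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("condition_id", "valence", "target", "valence_score",
            "target_code", "n_runs", "trials_per_condition_per_run")
  if (!all(need %in% names(df)))
    stop_input(path, ": required columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$condition_id)) stop_input(path, ": duplicate condition_id")
  out <- list(
    study = if ("study" %in% names(df)) df$study[1L] else "custom",
    conditions = df[, c("condition_id", "valence", "target", "valence_score",
                        "target_code")],
    n_runs = as.integer(df$n_runs[1L]),
    trials_per_condition_per_run = as.integer(df$trials_per_condition_per_run[1L]))
  out$trials_per_run <- nrow(out$conditions) * out$trials_per_condition_per_run
  class(out) <- "ft_design"
  out
}

#' Read a condition rating table
#'
#' @param path TSV with a `condition_id` column and one or more numeric
#'   rating columns (e.g., mean rated valence by an independent sample).
#' @return Data frame.
#' @export
read_ratings <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!"condition_id" %in% names(df))
    stop_input(path, ": required column condition_id")
  df
}
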