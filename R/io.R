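#' Read a parcellated timeseries with its region metadata
#'
#' The signal matrix is tab-separated plain text with regions as rows and
#' timepoints as columns (no header, no row names). The metadata sidecar is
#' a tab-separated table with a header containing at least the columns
#' `region_name` and `network_label`, one row per region, in row order of
#' the matrix.
#'
#' @param path path to the TSV signal matrix.
#' @param metadata_path path to the TSV region-metadata table.
#' @param tr_seconds sampling interval in seconds (not stored in the TSV).
#' @param subject_id subject identifier; defaults to the matrix file stem.
#'
#' @return A [parcellated_timeseries].
#' @export
read_timeseries <- function(path, metadata_path, tr_seconds = 2,
                            subject_id = NULL) {
  if (!file.exists(path)) stop("timeseries file not found: ", path)
  if (!file.exists(metadata_path))
    stop("metadata file not found: ", metadata_path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  mat <- suppressWarnings(
    matrix(as.numeric(as.matrix(raw)), nrow = nrow(raw)))
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell in ", path, " at row ", bad[["row"]],
         ", column ", bad[["col"]], ": '",
         as.matrix(raw)[bad[["row"]], bad[["col"]]], "'")
  }
  meta <- utils::read.table(metadata_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  need <- c("region_name", "network_label")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(meta) != nrow(mat))
    stop("dimension mismatch: matrix has ", nrow(mat),
         " region rows but metadata has ", nrow(meta), " rows")
  if (is.null(subject_id))
    subject_id <- tools::file_path_sans_ext(basename(path))
  parcellated_timeseries(mat, meta$region_name, meta$network_label,
                         tr_seconds = tr_seconds, subject_id = subject_id)
}

#' Read a subject covariates table
#'
#' Tab-separated with header columns `subject_id`, `group`, `age`, `sex`.
#'
#' @param path path to the TSV covariates table.
#' @return A `data.frame` with one row per subject; `group` and `sex` are
#'   factors, `age` numeric.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("covariates file not found: ", path)
  cov <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "sex")
  miss <- setdiff(need, names(cov))
  if (length(miss))
    stop("covariates missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(cov$subject_id))
    stop("duplicate subject_id in covariates table")
  cov$group <- factor(cov$group)
  cov$sex <- factor(cov$sex)
  cov$age <- as.numeric(cov$age)
  if (anyNA(cov$age)) stop("non-numeric age values in covariates")
  cov
}

# TSV matrix writer: full double precision so write->read round-trips to
# >= 12 significant digits.
write_matrix_tsv <- function(m, path) {
  txt <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(txt, path)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

# JSON scalar serialization: 10 significant digits, Inf encoded as "inf".
json_ready <- function(x) {
  if (is.list(x)) return(lapply(x, json_ready))
  if (is.numeric(x)) {
    out <- as.list(signif(x, 10))
    out[vapply(out, function(v) is.infinite(v) && v > 0, logical(1))] <- "inf"
    out[vapply(out, function(v) is.numeric(v) && is.infinite(v) && v < 0,
               logical(1))] <- "-inf"
    if (length(out) == 1L && is.null(names(x))) return(out[[1L]])
    names(out) <- names(x)
    return(out)
  }
  x
}

write_json_summary <- function(x, path) {
  jsonlite::write_json(json_ready(x), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write pipeline results to a directory
#'
#' Matrices (static FC, temporal-stability matrices, partitions, density
#' matrices) are written as tab-separated text; scalar summaries and
#' group-comparison reports as JSON. Filenames are deterministic:
#' `<subject_id>_<stage>.<ext>` where the stage name is the element's name
#' in `results`.
#'
#' @param results named list. Elements that are matrices go to TSV; lists
#'   go to JSON. An empty list writes nothing and succeeds.
#' @param out_dir output directory, created if missing.
#' @param subject_id identifier prefixed to every filename.
#' @return Invisibly, the character vector of files written.
#' @export
write_results <- function(results, out_dir, subject_id = "subject") {
  stopifnot(is.list(results))
  if (length(results) && is.null(names(results)))
    stop("`results` must be a named list")
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  if (file.access(out_dir, mode = 2L) != 0L)
    stop("output directory is not writable: ", out_dir)
  written <- character(0)
  for (stage in names(results)) {
    obj <- results[[stage]]
    if (inherits(obj, "temporal_stability_matrix")) obj <- obj$phi
    if (inherits(obj, "static_fc")) obj <- obj$z_matrix
    if (is.matrix(obj)) {
      f <- file.path(out_dir, paste0(subject_id, "_", stage, ".tsv"))
      write_matrix_tsv(obj, f)
    } else if (is.data.frame(obj)) {
      f <- file.path(out_dir, paste0(subject_id, "_", stage, ".tsv"))
      utils::write.table(obj, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    } else if (is.list(obj) || is.numeric(obj)) {
      f <- file.path(out_dir, paste0(subject_id, "_", stage, ".json"))
      write_json_summary(unclass(obj), f)
    } else {
      stop("do not know how to serialize stage '", stage, "' of class ",
           paste(class(obj), collapse = "/"))
    }
    written <- c(written, f)
  }
  invisible(written)
}
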