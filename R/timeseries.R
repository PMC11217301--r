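#' Parcellated BOLD-like timeseries
#'
#' Container for one subject's region-by-timepoint signal matrix together
#' with region names, resting-state-network labels and the sampling
#' interval (TR). This is the input type of both analysis branches:
#' static connectivity / block-model community detection, and
#' phase-coherence dynamic connectivity / temporal stability.
#'
#' @param data numeric matrix, regions in rows, timepoints in columns.
#'   At least 2 regions and 4 timepoints; no missing values.
#' @param region_names character vector of unique region names, one per row.
#' @param network_labels character vector assigning each region to a
#'   resting-state network; treated as opaque strings.
#' @param tr_seconds positive sampling interval in seconds.
#' @param subject_id subject identifier used in output filenames.
#'
#' @return An object of class `parcellated_timeseries` with fields
#'   `subject_id`, `data`, `region_names`, `network_labels`, `tr_seconds`.
#' @export
#' @examples
#' x <- matrix(rnorm(40), nrow = 4)
#' ts <- parcellated_timeseries(x, paste0("R", 1:4), rep(c("A", "B"), 2))
parcellated_timeseries <- function(data, region_names, network_labels,
                                   tr_seconds = 2, subject_id = "subject") {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (regions x timepoints)")
  n <- nrow(data)
  t_len <- ncol(data)
  if (n < 2L) stop("need at least 2 regions, got ", n)
  if (t_len < 4L) stop("need at least 4 timepoints, got ", t_len)
  if (anyNA(data) || any(!is.finite(data)))
    stop("`data` contains missing or non-finite values")
  region_names <- as.character(region_names)
  network_labels <- as.character(network_labels)
  if (length(region_names) != n)
    stop("length of `region_names` (", length(region_names),
         ") does not match number of rows (", n, ")")
  if (length(network_labels) != n)
    stop("length of `network_labels` (", length(network_labels),
         ") does not match number of rows (", n, ")")
  dup <- region_names[duplicated(region_names)]
  if (length(dup))
    stop("duplicate region names: ", paste(unique(dup), collapse = ", "))
  if (anyNA(network_labels))
    stop("every region needs a network label")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("`tr_seconds` must be a single positive number")
  rownames(data) <- region_names
  structure(
    list(subject_id = as.character(subject_id)[1L],
         data = data,
         region_names = region_names,
         network_labels = network_labels,
         tr_seconds = as.numeric(tr_seconds)),
    class = "parcellated_timeseries")
}

#' @export
print.parcellated_timeseries <- function(x, ...) {
  cat("<parcellated_timeseries> subject:", x$subject_id,
      "|", nrow(x$data), "regions x", ncol(x$data), "timepoints",
      "| TR", x$tr_seconds, "s\n")
  cat("networks:", paste(unique(x$network_labels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.parcellated_timeseries <- function(x) dim(x$data)
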