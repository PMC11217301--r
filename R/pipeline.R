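#' Per-subject temporal-stability measures for a cohort
#'
#' Runs the phase-coherence / dominant-subspace / landscape pipeline on
#' every subject and collects the whole-brain stability summary.
#'
#' @param subjects list of [parcellated_timeseries].
#' @inheritParams stability_matrix
#' @inheritParams entropy_ts
#' @return data.frame with one row per subject: `subject_id`, `entropy`,
#'   `ts`, `global_temporal_distance`, `ts_global`.
#' @export
cohort_stability <- function(subjects, k = 2L,
                             mode = c("largest", "smallest", "mean"),
                             n_bins = 256L) {
  mode <- match.arg(mode)
  rows <- lapply(subjects, function(ts) {
    s <- subject_stability(ts, k = k, mode = mode, n_bins = n_bins)$summary
    data.frame(subject_id = ts$subject_id, entropy = s$entropy,
               ts = s$ts,
               global_temporal_distance = s$global_temporal_distance,
               ts_global = s$ts_global, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Group comparison of a stability measure across a synthetic cohort
#'
#' End-to-end analysis: per-subject stability measures, age/sex
#' residualization over the pooled sample, normality-gated two-sample
#' test between the two groups.
#'
#' @param cohort list with `subjects` and `covariates` from
#'   [gen_cohort()].
#' @param measure column of the per-subject stability table to compare
#'   (default `"global_temporal_distance"`).
#' @inheritParams cohort_stability
#' @return List with `comparison` (a `group_comparison`), `table` (the
#'   per-subject measures joined with covariates).
#' @export
compare_cohort_stability <- function(cohort,
                                     measure = "global_temporal_distance",
                                     k = 2L, n_bins = 256L) {
  tab <- cohort_stability(cohort$subjects, k = k, n_bins = n_bins)
  tab <- merge(tab, cohort$covariates, by = "subject_id", sort = FALSE)
  groups <- unique(as.character(tab$group))
  if (length(groups) != 2L) stop("expected exactly 2 groups")
  resid <- suppressWarnings(
    residualize(tab[[measure]], tab[, c("age", "sex")]))
  x <- resid[tab$group == groups[1]]
  y <- resid[tab$group == groups[2]]
  cmp <- compare_groups(x, y, measure = measure)
  list(comparison = cmp, table = tab)
}
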