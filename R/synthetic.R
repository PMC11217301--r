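#' Specification of a planted weighted block-model graph
#'
#' Describes a signed, weighted, undirected graph whose edge weights are
#' drawn blockwise-normally around planted community structure — the
#' generative counterpart of the weighted stochastic block model fitted by
#' [fit_wsbm()].
#'
#' @param community_sizes integer vector (length K >= 2) of community
#'   sizes; their sum is the number of nodes.
#' @param block_means symmetric K x K matrix of signed edge-weight means.
#' @param block_sds symmetric K x K matrix of nonnegative edge-weight
#'   standard deviations (0 gives deterministic weights).
#' @param seed integer seed.
#' @return A `block_graph_spec` list.
#' @export
block_graph_spec <- function(community_sizes, block_means, block_sds,
                             seed = 1L) {
  community_sizes <- as.integer(community_sizes)
  k <- length(community_sizes)
  if (k < 2L) stop("need at least 2 communities")
  if (any(community_sizes < 1L)) stop("community sizes must be >= 1")
  block_means <- as.matrix(block_means)
  block_sds <- as.matrix(block_sds)
  if (!all(dim(block_means) == c(k, k)) || !all(dim(block_sds) == c(k, k)))
    stop("block_means and block_sds must be K x K with K = ",
         k, " communities")
  if (!isSymmetric(unname(block_means), tol = 0) ||
      !isSymmetric(unname(block_sds), tol = 0))
    stop("block_means and block_sds must be symmetric")
  if (any(block_sds < 0)) stop("block_sds must be nonnegative")
  structure(list(n_nodes = sum(community_sizes),
                 community_sizes = community_sizes,
                 block_means = block_means, block_sds = block_sds,
                 seed = as.integer(seed)),
            class = "block_graph_spec")
}

#' Generate a weighted signed graph with planted block structure
#'
#' Each edge weight (i < j) is drawn independently from
#' Normal(block_means\[z_i, z_j\], block_sds\[z_i, z_j\]); the matrix is
#' symmetrized and the diagonal set to zero.
#'
#' @param spec a [block_graph_spec()].
#' @return A list with `adjacency` (N x N signed symmetric, zero diagonal)
#'   and `truth`, the planted partition (fields `labels`, `K`).
#' @export
#' @examples
#' g <- gen_weighted_sbm(block_graph_spec(c(3, 3),
#'   matrix(c(1, 0, 0, 1), 2), matrix(1e-9, 2, 2)))
gen_weighted_sbm <- function(spec) {
  stopifnot(inherits(spec, "block_graph_spec"))
  n <- spec$n_nodes
  z <- rep(seq_along(spec$community_sizes), spec$community_sizes)
  set.seed(spec$seed)
  a <- matrix(0, n, n)
  idx <- which(upper.tri(a))
  rows <- row(a)[idx]; cols <- col(a)[idx]
  mu <- spec$block_means[cbind(z[rows], z[cols])]
  sd <- spec$block_sds[cbind(z[rows], z[cols])]
  a[idx] <- stats::rnorm(length(idx), mean = mu, sd = sd)
  a <- a + t(a)
  diag(a) <- 0
  list(adjacency = a,
       truth = list(labels = z, K = length(spec$community_sizes)))
}

#' Specification of a phase-coupled oscillator cohort member
#'
#' Describes synthetic BOLD-like signals: each region oscillates at a
#' common frequency with a community-shared random phase offset,
#' per-region phase jitter whose spread shrinks linearly with
#' `coupling_strength`, and additive measurement noise. Setting
#' `switch_period` re-draws the community phase offsets every that many
#' samples, emulating spontaneous large-scale reconfiguration of the
#' coupling structure; the default (no switching) gives a temporally
#' stable connectome.
#'
#' @param n_regions number of regions (default 30).
#' @param n_timepoints number of samples (default 150).
#' @param tr_seconds sampling interval (default 2 s).
#' @param community_assignment community label per region; default 3 equal
#'   communities.
#' @param coupling_strength within-community phase alignment in \[0, 1\];
#'   jitter sd is `(1 - coupling_strength) * pi` radians (default 0.8).
#' @param jitter_ar lag-1 autocorrelation of the per-region phase jitter
#'   (default 0.9): jitter evolves as a stationary AR(1) process, so the
#'   phase noise is slow, as BOLD fluctuations are, rather than white.
#'   0 gives independent jitter per sample.
#' @param noise_sd additive measurement noise sd (default 0.1).
#' @param switch_period `NULL` (no switching) or integer in
#'   \[2, n_timepoints\]: offsets re-drawn every `switch_period` samples.
#' @param oscillation_freq_hz oscillation frequency (default 0.05 Hz, the
#'   slow resting-state band with TR = 2 s).
#' @param seed integer seed.
#' @return An `oscillator_spec` list.
#' @export
oscillator_spec <- function(n_regions = 30L, n_timepoints = 150L,
                            tr_seconds = 2, community_assignment = NULL,
                            coupling_strength = 0.8, noise_sd = 0.1,
                            switch_period = NULL,
                            oscillation_freq_hz = 0.05, jitter_ar = 0.9,
                            seed = 1L) {
  n_regions <- as.integer(n_regions)
  n_timepoints <- as.integer(n_timepoints)
  if (n_regions < 2L) stop("need at least 2 regions")
  if (n_timepoints < 4L) stop("need at least 4 timepoints")
  if (is.null(community_assignment))
    community_assignment <- sort(rep(1:3, length.out = n_regions))
  if (length(community_assignment) != n_regions)
    stop("community_assignment must have one entry per region")
  if (coupling_strength < 0 || coupling_strength > 1)
    stop("coupling_strength must be in [0, 1]")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (!is.null(switch_period)) {
    switch_period <- as.integer(switch_period)
    if (switch_period < 2L || switch_period > n_timepoints)
      stop("switch_period must lie in [2, n_timepoints]")
  }
  if (tr_seconds <= 0 || oscillation_freq_hz <= 0)
    stop("tr_seconds and oscillation_freq_hz must be positive")
  if (jitter_ar < 0 || jitter_ar >= 1)
    stop("jitter_ar must lie in [0, 1)")
  structure(list(n_regions = n_regions, n_timepoints = n_timepoints,
                 tr_seconds = tr_seconds,
                 community_assignment = community_assignment,
                 coupling_strength = coupling_strength,
                 noise_sd = noise_sd, switch_period = switch_period,
                 oscillation_freq_hz = oscillation_freq_hz,
                 jitter_ar = jitter_ar,
                 seed = as.integer(seed)),
            class = "oscillator_spec")
}

#' Generate phase-coupled oscillatory timeseries
#'
#' Region i's signal is
#' `cos(2*pi*f*t*TR + theta_c(t) + eps_i(t)) + measurement noise`, where
#' `theta_c` is a random phase offset shared by community c (re-drawn each
#' regime when `switch_period` is set) and `eps_i(t)` is per-region phase
#' jitter: a stationary AR(1) process with marginal sd
#' `(1 - coupling_strength) * pi` and lag-1 correlation `jitter_ar`.
#' Deterministic given the spec's seed.
#'
#' @param spec an [oscillator_spec()].
#' @param subject_id identifier for the produced timeseries.
#' @return A [parcellated_timeseries] with attribute `"provenance"`: a
#'   list of the spec fields plus `n_regime_changes`.
#' @export
gen_oscillator_timeseries <- function(spec, subject_id = "sim") {
  stopifnot(inherits(spec, "oscillator_spec"))
  set.seed(spec$seed)
  n <- spec$n_regions; t_len <- spec$n_timepoints
  comm <- spec$community_assignment
  comm_ids <- unique(comm)
  # regime index per sample: 0-based blocks of switch_period samples
  regime <- if (is.null(spec$switch_period)) rep(0L, t_len) else
    (seq_len(t_len) - 1L) %/% spec$switch_period
  n_regimes <- length(unique(regime))
  # community-shared offsets, one draw per (community, regime)
  offsets <- matrix(stats::runif(length(comm_ids) * n_regimes, 0, 2 * pi),
                    nrow = length(comm_ids))
  rownames(offsets) <- as.character(comm_ids)
  jitter_sd <- (1 - spec$coupling_strength) * pi
  tt <- (seq_len(t_len) - 1L) * spec$tr_seconds
  carrier <- 2 * pi * spec$oscillation_freq_hz * tt
  theta_c <- offsets[as.character(comm), regime + 1L, drop = FALSE]
  eps <- matrix(0, n, t_len)
  if (jitter_sd > 0) {
    rho <- spec$jitter_ar
    eps[, 1L] <- stats::rnorm(n, sd = jitter_sd)
    innov_sd <- jitter_sd * sqrt(1 - rho^2)
    for (t in 2:t_len)
      eps[, t] <- rho * eps[, t - 1L] + stats::rnorm(n, sd = innov_sd)
  }
  phase <- sweep(theta_c + eps, 2L, carrier, `+`)
  x <- cos(phase)
  if (spec$noise_sd > 0)
    x <- x + matrix(stats::rnorm(n * t_len, sd = spec$noise_sd), n, t_len)
  ts <- parcellated_timeseries(
    x, region_names = sprintf("R%03d", seq_len(n)),
    network_labels = paste0("N", comm),
    tr_seconds = spec$tr_seconds, subject_id = subject_id)
  attr(ts, "provenance") <- c(unclass(spec),
                              list(n_regime_changes = n_regimes - 1L))
  ts
}

#' Specification of a two-group synthetic cohort
#'
#' @param n_per_group subjects per group (>= 2).
#' @param group_a_spec,group_b_spec [oscillator_spec()] templates (their
#'   `seed` fields are ignored; per-subject seeds are derived from
#'   `master_seed`).
#' @param group_labels length-2 character vector of group names.
#' @param age_range ages drawn uniformly in this range.
#' @param master_seed integer master seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group, group_a_spec, group_b_spec,
                        group_labels = c("A", "B"),
                        age_range = c(20, 50), master_seed = 1L) {
  stopifnot(inherits(group_a_spec, "oscillator_spec"),
            inherits(group_b_spec, "oscillator_spec"))
  n_per_group <- as.integer(n_per_group)
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 2L)
  if (any(n_per_group < 2L)) stop("need at least 2 subjects per group")
  structure(list(n_per_group = n_per_group,
                 group_a_spec = group_a_spec, group_b_spec = group_b_spec,
                 group_labels = as.character(group_labels),
                 age_range = age_range,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

# Deterministic per-subject seed from (master_seed, index): a small
# splitmix-style integer mix kept below 2^31.
derive_seed <- function(master_seed, index) {
  x <- (as.double(master_seed) * 2654435761 + as.double(index) * 40503) %%
    2147483647
  as.integer(x)
}

#' Generate a two-group synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @return List with `subjects` (list of [parcellated_timeseries]) and
#'   `covariates` (data.frame: subject_id, group, age, sex).
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  templates <- list(spec$group_a_spec, spec$group_b_spec)
  subjects <- list()
  rows <- list()
  idx <- 0L
  for (g in 1:2) {
    for (s in seq_len(spec$n_per_group[g])) {
      idx <- idx + 1L
      sid <- sprintf("sub-%s%03d", spec$group_labels[g], s)
      tpl <- templates[[g]]
      tpl$seed <- derive_seed(spec$master_seed, idx)
      subjects[[sid]] <- gen_oscillator_timeseries(tpl, subject_id = sid)
      set.seed(derive_seed(spec$master_seed, 100000L + idx))
      rows[[sid]] <- data.frame(
        subject_id = sid, group = spec$group_labels[g],
        age = round(stats::runif(1, spec$age_range[1], spec$age_range[2]), 1),
        sex = sample(c("F", "M"), 1L),
        stringsAsFactors = FALSE)
    }
  }
  list(subjects = subjects,
       covariates = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}
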