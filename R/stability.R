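#' Dominant subspace of a connectivity pattern
#'
#' Extracts the eigenvectors of a symmetric time-slice belonging to its
#' `k` largest eigenvalues (by signed value) — the dominant pattern
#' D_t of the time-resolved connectivity at one timepoint. Phase-coherence
#' slices have exact rank <= 2, so `k = 2` captures them losslessly.
#'
#' Eigenvalue ties are broken deterministically: components ordered by
#' descending eigenvalue, and each eigenvector's first component of
#' magnitude above 1e-12 is made positive.
#'
#' @param slice N x N symmetric numeric matrix.
#' @param k number of components, `1 <= k <= N`; requesting more
#'   components than the slice's numerical rank (singular values above
#'   `1e-8` of the leading one) is an error.
#' @return List with `basis` (N x k, orthonormal columns) and
#'   `explained_variance` (the k retained eigenvalues).
#' @export
dominant_subspace <- function(slice, k = 2L) {
  if (!is.matrix(slice) || !isSymmetric(unname(slice), tol = 1e-8))
    stop("`slice` must be a symmetric matrix")
  n <- nrow(slice)
  k <- as.integer(k)
  if (k < 1L || k > n) stop("`k` must lie in [1, N]")
  e <- eigen((slice + t(slice)) / 2, symmetric = TRUE)
  rank_num <- sum(abs(e$values) > 1e-8 * max(abs(e$values), .Machine$double.eps))
  if (k > rank_num)
    stop("requested k = ", k, " components but numerical rank is ",
         rank_num)
  basis <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    lead <- which(abs(basis[, j]) > 1e-12)[1L]
    if (!is.na(lead) && basis[lead, j] < 0) basis[, j] <- -basis[, j]
  }
  list(basis = basis, explained_variance = e$values[seq_len(k)])
}

#' Principal angle between two subspaces
#'
#' The canonical (principal) angles between the column spans of two
#' orthonormal bases are `acos` of the singular values of `t(b1) %*% b2`,
#' each in `[0, pi/2]`. `mode` selects which angle summarizes the pair:
#' `"largest"` (default; the most conservative measure of subspace
#' discrepancy, spanning the full `[0, pi/2]` range), `"smallest"`, or
#' `"mean"`.
#'
#' @param b1,b2 N x k matrices with orthonormal columns (deviation of
#'   `t(b) %*% b` from the identity above `1e-8` is an error).
#' @param mode one of `"largest"`, `"smallest"`, `"mean"`.
#' @return Angle in radians, in `[0, pi/2]`.
#' @export
#' @examples
#' angular_distance(diag(2)[, 1, drop = FALSE], diag(2)[, 2, drop = FALSE])
angular_distance <- function(b1, b2,
                             mode = c("largest", "smallest", "mean")) {
  mode <- match.arg(mode)
  check_orthonormal(b1); check_orthonormal(b2)
  if (nrow(b1) != nrow(b2))
    stop("bases must have the same ambient dimension")
  sv <- svd(crossprod(b1, b2), nu = 0, nv = 0)$d
  sv <- pmin(pmax(sv, 0), 1)
  ang <- acos(sv)
  switch(mode,
         largest = max(ang),
         smallest = min(ang),
         mean = mean(ang))
}

check_orthonormal <- function(b) {
  if (!is.matrix(b)) stop("basis must be a matrix")
  g <- crossprod(b)
  if (max(abs(g - diag(ncol(b)))) > 1e-8)
    stop("basis columns are not orthonormal")
  invisible(b)
}

#' Time-by-time temporal stability matrix (the temporal landscape)
#'
#' Builds the T x T matrix of principal angles `phi(t_x, t_y)` between the
#' dominant subspaces of the dynamic connectivity patterns at every pair
#' of timepoints. Low angles mean similarly configured connectivity; the
#' matrix as a whole visualizes the temporal landscape of the scan.
#'
#' @param dfc a `dfc_stack` from [phase_coherence_dfc()].
#' @param k dominant-subspace dimension (default 2, the exact rank of
#'   phase-coherence slices; use 1 for the leading eigenvector only).
#' @param mode principal-angle summary, see [angular_distance()].
#' @return Object of class `temporal_stability_matrix`: list with `phi`
#'   (T x T symmetric, zero diagonal, entries in `[0, pi/2]`),
#'   `subspace_dim` and `mode`.
#' @export
stability_matrix <- function(dfc, k = 2L,
                             mode = c("largest", "smallest", "mean")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dfc, "dfc_stack"))
  k <- as.integer(k)
  t_len <- dim(dfc$tensor)[3]
  n <- dim(dfc$tensor)[1]
  bases <- lapply(seq_len(t_len),
                  function(t) dominant_subspace(dfc$tensor[, , t], k)$basis)
  phi <- pairwise_principal_angles(bases, n, k, mode)
  structure(list(phi = phi, subspace_dim = k, mode = mode),
            class = "temporal_stability_matrix")
}

# All-pairs principal angles from a list of N x k orthonormal bases.
# For k <= 2 the k x k cross-Gram singular values have a closed form,
# evaluated vectorized over all T^2 pairs; larger k falls back to svd
# per pair.
pairwise_principal_angles <- function(bases, n, k, mode) {
  t_len <- length(bases)
  big <- matrix(unlist(bases), nrow = n)         # N x (k * T)
  g <- crossprod(big)                            # (kT) x (kT)
  if (k == 1L) {
    sv <- pmin(abs(g), 1)
    phi <- acos(sv)
  } else if (k == 2L) {
    o <- seq(1L, 2L * t_len, by = 2L)
    m11 <- g[o, o]; m12 <- g[o, o + 1L]
    m21 <- g[o + 1L, o]; m22 <- g[o + 1L, o + 1L]
    fro2 <- m11^2 + m12^2 + m21^2 + m22^2
    det2 <- (m11 * m22 - m12 * m21)^2
    disc <- sqrt(pmax(fro2^2 - 4 * det2, 0))
    s1 <- sqrt(pmin(pmax((fro2 + disc) / 2, 0), 1))  # larger sv
    s2 <- sqrt(pmin(pmax((fro2 - disc) / 2, 0), 1))  # smaller sv
    phi <- switch(mode,
                  largest = acos(s2),
                  smallest = acos(s1),
                  mean = (acos(s1) + acos(s2)) / 2)
  } else {
    phi <- matrix(0, t_len, t_len)
    for (x in seq_len(t_len - 1L)) {
      ix <- ((x - 1L) * k + 1L):(x * k)
      for (y in (x + 1L):t_len) {
        iy <- ((y - 1L) * k + 1L):(y * k)
        sv <- pmin(pmax(svd(g[ix, iy, drop = FALSE], nu = 0, nv = 0)$d,
                        0), 1)
        ang <- acos(sv)
        phi[x, y] <- phi[y, x] <- switch(mode, largest = max(ang),
                                         smallest = min(ang),
                                         mean = mean(ang))
      }
    }
  }
  phi <- (phi + t(phi)) / 2
  diag(phi) <- 0
  phi
}

#' Entropy of the temporal landscape
#'
#' Entries of the stability matrix are mapped linearly from `[0, pi/2]`
#' to `[0, 1]` and binned into a uniform histogram (256 bins by default,
#' mirroring an 8-bit image-histogram computation); the entropy of the
#' normalized counts, in bits, measures disorder of the landscape. All
#' T^2 entries, including the zero diagonal, are counted by default.
#' Overall temporal stability is the inverse entropy, `Inf` when a single
#' bin holds all mass.
#'
#' @param m a `temporal_stability_matrix`.
#' @param n_bins number of histogram bins (default 256).
#' @param include_diagonal count the zero diagonal entries (default TRUE).
#' @return List with `entropy` (bits) and `ts` (`1/entropy`, `Inf` when
#'   entropy is 0).
#' @export
entropy_ts <- function(m, n_bins = 256L, include_diagonal = TRUE) {
  stopifnot(inherits(m, "temporal_stability_matrix"))
  vals <- if (include_diagonal) as.vector(m$phi) else
    m$phi[row(m$phi) != col(m$phi)]
  u <- pmin(pmax(vals / (pi / 2), 0), 1)
  idx <- pmin(floor(u * n_bins) + 1L, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  p <- counts / length(u)
  p <- p[p > 0]
  e <- -sum(p * log2(p))
  list(entropy = e, ts = if (e > 0) 1 / e else Inf)
}

#' Global temporal distance and global temporal stability
#'
#' The mean principal angle between dominant subspaces at successive
#' timepoints — the mean of the stability matrix's superdiagonal. Its
#' inverse is the global temporal stability. A flag averages all
#' off-diagonal entries instead, for sensitivity comparison.
#'
#' @param m a `temporal_stability_matrix` with T >= 2.
#' @param all_offdiagonal average every off-diagonal entry instead of the
#'   successive-timepoint superdiagonal (default FALSE).
#' @return List with `global_temporal_distance` (radians) and `ts_global`
#'   (`Inf` when the distance is 0).
#' @export
global_temporal_distance <- function(m, all_offdiagonal = FALSE) {
  stopifnot(inherits(m, "temporal_stability_matrix"))
  phi <- m$phi
  t_len <- nrow(phi)
  if (t_len < 2L) stop("need at least 2 timepoints")
  gtd <- if (all_offdiagonal)
    mean(phi[row(phi) != col(phi)])
  else
    mean(phi[cbind(seq_len(t_len - 1L), seq_len(t_len - 1L) + 1L)])
  list(global_temporal_distance = gtd,
       ts_global = if (gtd > 0) 1 / gtd else Inf)
}

#' Summarize a temporal landscape
#'
#' Bundles [entropy_ts()] and [global_temporal_distance()] into the
#' standard stability summary for one scope (whole brain or one network).
#'
#' @inheritParams entropy_ts
#' @param scope label recorded in the summary (default "whole-brain").
#' @return Object of class `stability_summary`: list with fields
#'   `entropy`, `ts`, `global_temporal_distance`, `ts_global`, `scope`.
#' @export
summarize_stability <- function(m, n_bins = 256L,
                                include_diagonal = TRUE,
                                scope = "whole-brain") {
  e <- entropy_ts(m, n_bins = n_bins, include_diagonal = include_diagonal)
  g <- global_temporal_distance(m)
  structure(list(entropy = e$entropy, ts = e$ts,
                 global_temporal_distance = g$global_temporal_distance,
                 ts_global = g$ts_global, scope = scope),
            class = "stability_summary")
}

#' Temporal stability of one resting-state network
#'
#' Restricts the dFC tensor to the member regions of one network label
#' and reruns the stability pipeline (subspace extraction, landscape,
#' entropy, global temporal distance) on the restriction, so the summary
#' reflects only that network's internal dynamics.
#'
#' @param dfc a `dfc_stack` (carries the per-region network labels).
#' @param network one network label present among the stack's regions,
#'   with at least 2 member regions.
#' @inheritParams stability_matrix
#' @inheritParams entropy_ts
#' @return A `stability_summary` with `scope` set to the network label.
#' @export
network_stability <- function(dfc, network, k = 2L,
                              mode = c("largest", "smallest", "mean"),
                              n_bins = 256L) {
  mode <- match.arg(mode)
  stopifnot(inherits(dfc, "dfc_stack"))
  members <- which(dfc$network_labels == network)
  if (length(members) == 0L)
    stop("unknown network label: ", network)
  if (length(members) < 2L)
    stop("network '", network, "' has a single region; stability is undefined")
  sub <- structure(list(
    tensor = dfc$tensor[members, members, , drop = FALSE],
    phases = dfc$phases[members, , drop = FALSE],
    region_names = dfc$region_names[members],
    network_labels = dfc$network_labels[members],
    subject_id = dfc$subject_id), class = "dfc_stack")
  m <- stability_matrix(sub, k = k, mode = mode)
  summarize_stability(m, n_bins = n_bins, scope = network)
}

#' Whole-brain temporal stability for one subject
#'
#' End-to-end convenience wrapper: phases, phase-coherence dFC, stability
#' matrix and summary, optionally per network.
#'
#' @param ts a [parcellated_timeseries].
#' @inheritParams stability_matrix
#' @inheritParams entropy_ts
#' @param per_network also compute one summary per network label with
#'   >= 2 member regions (default FALSE).
#' @return List with `matrix` (the `temporal_stability_matrix`),
#'   `summary` (whole-brain `stability_summary`) and, when requested,
#'   `network_summaries` (named list).
#' @export
subject_stability <- function(ts, k = 2L,
                              mode = c("largest", "smallest", "mean"),
                              n_bins = 256L, per_network = FALSE) {
  mode <- match.arg(mode)
  dfc <- phase_coherence_dfc(ts)
  m <- stability_matrix(dfc, k = k, mode = mode)
  out <- list(matrix = m,
              summary = summarize_stability(m, n_bins = n_bins))
  if (per_network) {
    labs <- names(which(table(ts$network_labels) >= 2))
    out$network_summaries <- stats::setNames(
      lapply(labs, function(l)
        network_stability(dfc, l, k = k, mode = mode, n_bins = n_bins)),
      labs)
  }
  out
}
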