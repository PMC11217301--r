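#' Community interaction densities
#'
#' Within-community density `omega_rr = sum_{i,j in r} A_ij / (N_r * N_r)`
#' and between-community density
#' `omega_rs = sum_{i in s, j in r} A_ij / (N_r * N_s)`. The squared
#' denominator keeps the diagonal positions in the count (they contribute
#' zero weight since `A_ii = 0`); a flag switches to the
#' off-diagonal-pairs denominator `N_r (N_r - 1)` for sensitivity checks.
#' Within-densities of singleton communities are undefined (`NA`) and the
#' community is marked not retained; downstream motif code excludes it.
#'
#' @param A symmetric zero-diagonal adjacency matrix.
#' @param partition list with `labels` (integer community per node) and
#'   `K`, e.g. from [map_partition()].
#' @param offdiag_denominator use `N_r (N_r - 1)` for within-densities
#'   (default FALSE).
#' @return Object of class `community_density_matrix`: `omega` (K x K
#'   symmetric), `community_sizes`, `retained` (logical, size >= 2).
#' @export
community_densities <- function(A, partition, offdiag_denominator = FALSE) {
  check_adjacency(A)
  z <- partition$labels
  K <- partition$K
  if (length(z) != nrow(A)) stop("partition length does not match A")
  if (K < 1L || any(z < 1L | z > K)) stop("labels out of range 1..K")
  sizes <- tabulate(z, nbins = K)
  if (all(sizes == 0L)) stop("empty partition")
  omega <- matrix(NA_real_, K, K)
  for (r in seq_len(K)) {
    if (sizes[r] == 0L) next
    ir <- which(z == r)
    for (s in r:K) {
      if (sizes[s] == 0L) next
      is <- which(z == s)
      tot <- sum(A[ir, is, drop = FALSE])
      denom <- if (r == s) {
        if (sizes[r] < 2L) { omega[r, r] <- NA_real_; next }
        if (offdiag_denominator) sizes[r] * (sizes[r] - 1) else sizes[r]^2
      } else sizes[r] * sizes[s]
      omega[r, s] <- omega[s, r] <- tot / denom
    }
  }
  structure(list(omega = omega, community_sizes = sizes,
                 retained = sizes >= 2L),
            class = "community_density_matrix")
}

check_adjacency <- function(A) {
  if (!is.matrix(A) || !is.numeric(A)) stop("`A` must be a numeric matrix")
  if (!isSymmetric(unname(A), tol = 1e-10)) stop("`A` must be symmetric")
  if (any(diag(A) != 0)) stop("`A` must have a zero diagonal")
  invisible(A)
}

#' Classify one community-pair interaction motif
#'
#' Assortative when both within-densities exceed the between-density;
#' core-periphery when the between-density lies strictly between them
#' (the denser community is the core); disassortative when the
#' between-density exceeds both. Equalities fall through the rules in
#' that order and, when no strict rule applies, the pair is labelled
#' `"degenerate"` and excluded from motif profiles.
#'
#' @param w_rr,w_ss within-community densities of the two communities.
#' @param w_rs between-community density.
#' @return List with `class` (one of `"assortative"`, `"core-periphery"`,
#'   `"disassortative"`, `"degenerate"`) and `core_side` (`"r"` or `"s"`
#'   when core-periphery, otherwise `NA`).
#' @export
#' @examples
#' classify_motif(0.8, 0.6, 0.2)  # assortative
#' classify_motif(0.8, 0.1, 0.4)  # core-periphery, core r
classify_motif <- function(w_rr, w_ss, w_rs) {
  stopifnot(is.finite(w_rr), is.finite(w_ss), is.finite(w_rs))
  if (min(w_rr, w_ss) > w_rs)
    list(class = "assortative", core_side = NA_character_)
  else if (w_rr > w_rs && w_rs > w_ss)
    list(class = "core-periphery", core_side = "r")
  else if (w_ss > w_rs && w_rs > w_rr)
    list(class = "core-periphery", core_side = "s")
  else if (w_rs > max(w_rr, w_ss))
    list(class = "disassortative", core_side = NA_character_)
  else
    list(class = "degenerate", core_side = NA_character_)
}

# Pairwise motif table over retained communities.
motif_pair_table <- function(dens) {
  ret <- which(dens$retained)
  if (length(ret) < 2L)
    stop("need at least 2 non-singleton communities")
  pairs <- utils::combn(ret, 2L)
  out <- data.frame(r = pairs[1L, ], s = pairs[2L, ])
  out$w_rr <- dens$omega[cbind(out$r, out$r)]
  out$w_ss <- dens$omega[cbind(out$s, out$s)]
  out$w_rs <- dens$omega[cbind(out$r, out$s)]
  cl <- mapply(function(a, b, c) classify_motif(a, b, c),
               out$w_rr, out$w_ss, out$w_rs, SIMPLIFY = FALSE)
  out$class <- vapply(cl, `[[`, character(1), "class")
  out$core_side <- vapply(cl, `[[`, character(1), "core_side")
  out$core_community <- ifelse(
    out$class == "core-periphery",
    ifelse(out$core_side == "r", out$r, out$s), NA_integer_)
  out
}

#' Motif-class profile and diversity index per community
#'
#' For each retained (non-singleton) community r, the frequencies
#' `P_a, P_c, P_p, P_d` with which its pairwise interactions are
#' assortative, core (r is the denser side of a core-periphery pair),
#' periphery (r is the sparser side), or disassortative, over its
#' retained, non-degenerate pairs. The diversity index is the entropy
#' `H_r = -(P_a log P_a + P_c log P_c + P_p log P_p)` (natural log;
#' zero-frequency terms drop): 0 when the community participates in a
#' single class, maximal (`log 3`) when it participates in all three
#' equally. The disassortative frequency is tallied and reported but not
#' part of `H_r` unless `include_disassortative = TRUE`.
#'
#' @inheritParams community_densities
#' @param include_disassortative include `P_d` in the entropy
#'   (default FALSE).
#' @return List with `profile` (data.frame: community, P_a, P_c, P_p,
#'   P_d, H_r), `pairs` (the pair classification table) and
#'   `mean_diversity` (mean `H_r` over retained communities).
#' @export
community_motif_profile <- function(A, partition,
                                    include_disassortative = FALSE,
                                    offdiag_denominator = FALSE) {
  dens <- community_densities(A, partition,
                              offdiag_denominator = offdiag_denominator)
  pairs <- motif_pair_table(dens)
  usable <- pairs[pairs$class != "degenerate", , drop = FALSE]
  if (nrow(usable) == 0L) stop("all community pairs are degenerate")
  ret <- which(dens$retained)
  rows <- lapply(ret, function(r) {
    mine <- usable[usable$r == r | usable$s == r, , drop = FALSE]
    if (nrow(mine) == 0L)
      return(data.frame(community = r, P_a = NA_real_, P_c = NA_real_,
                        P_p = NA_real_, P_d = NA_real_, H_r = NA_real_))
    p_a <- mean(mine$class == "assortative")
    p_d <- mean(mine$class == "disassortative")
    cp <- mine$class == "core-periphery"
    p_c <- mean(cp & mine$core_community == r)
    p_p <- mean(cp & mine$core_community != r)
    probs <- c(p_a, p_c, p_p, if (include_disassortative) p_d)
    probs <- probs[probs > 0]
    h <- if (length(probs)) -sum(probs * log(probs)) + 0 else 0  # +0 kills -0
    data.frame(community = r, P_a = p_a, P_c = p_c, P_p = p_p, P_d = p_d,
               H_r = h)
  })
  profile <- do.call(rbind, rows)
  list(profile = profile, pairs = pairs,
       mean_diversity = mean(profile$H_r, na.rm = TRUE))
}

#' Subject-level motif participation summary
#'
#' Mean assortative, core and periphery participation frequencies across
#' retained communities — the per-subject assortativity, coreness and
#' peripheryness scores.
#'
#' @inheritParams community_motif_profile
#' @return Named list `assortativity`, `coreness`, `peripheryness`, each
#'   in `[0, 1]`, plus `mean_diversity`.
#' @export
subject_motif_summary <- function(A, partition,
                                  offdiag_denominator = FALSE) {
  prof <- community_motif_profile(A, partition,
                                  offdiag_denominator = offdiag_denominator)
  p <- prof$profile
  list(assortativity = mean(p$P_a, na.rm = TRUE),
       coreness = mean(p$P_c, na.rm = TRUE),
       peripheryness = mean(p$P_p, na.rm = TRUE),
       mean_diversity = prof$mean_diversity)
}

#' Regional assortativity scores
#'
#' A region's connection density to community r is
#' `a_ir = (1/n_r) sum_{j in r} A_ij`; its regional assortativity is its
#' density to its own community minus its maximal density to any other
#' retained community, `Assr_reg = a_{i z_i} - max_{r != z_i} a_ir`.
#' Regions in singleton communities get `NA` scores (singleton
#' communities are excluded throughout).
#'
#' @inheritParams community_densities
#' @return Object of class `regional_scores`: `a` (N x K density-to-
#'   community matrix over retained communities, `NA` elsewhere),
#'   `assr_reg` (length-N), `labels`.
#' @export
regional_assortativity <- function(A, partition) {
  check_adjacency(A)
  z <- partition$labels
  K <- partition$K
  sizes <- tabulate(z, nbins = K)
  retained <- sizes >= 2L
  if (sum(retained) < 2L)
    stop("need at least 2 non-singleton communities")
  n <- nrow(A)
  a <- matrix(NA_real_, n, K)
  for (r in which(retained))
    a[, r] <- rowSums(A[, z == r, drop = FALSE]) / sizes[r]
  assr <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!retained[z[i]]) next
    others <- setdiff(which(retained), z[i])
    assr[i] <- a[i, z[i]] - max(a[i, others])
  }
  structure(list(a = a, assr_reg = assr, labels = z,
                 retained = retained),
            class = "regional_scores")
}

#' Community morphospace coordinates
#'
#' One point per retained community pair with coordinates
#' `(omega_rr, omega_rs, omega_ss)`, communities ordered within each pair
#' so the first within-density is the larger, and the motif class
#' attached for coloring.
#'
#' @inheritParams community_densities
#' @return data.frame with columns `r`, `s`, `w_rr`, `w_rs`, `w_ss`,
#'   `class` (one row per retained pair; `w_rr >= w_ss`).
#' @export
morphospace <- function(A, partition, offdiag_denominator = FALSE) {
  dens <- community_densities(A, partition,
                              offdiag_denominator = offdiag_denominator)
  pairs <- motif_pair_table(dens)
  flip <- pairs$w_ss > pairs$w_rr
  out <- data.frame(
    r = ifelse(flip, pairs$s, pairs$r),
    s = ifelse(flip, pairs$r, pairs$s),
    w_rr = pmax(pairs$w_rr, pairs$w_ss),
    w_rs = pairs$w_rs,
    w_ss = pmin(pairs$w_rr, pairs$w_ss),
    class = pairs$class,
    stringsAsFactors = FALSE)
  out
}
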