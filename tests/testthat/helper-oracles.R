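# Independent brute-force oracles and fixture builders. The oracles are
# written as literal double loops over the defining formulas, deliberately
# sharing no code with the package implementations they check.

random_symmetric_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(rnorm(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  a
}

random_partition <- function(n, K, seed) {
  set.seed(seed)
  repeat {
    z <- sample.int(K, n, replace = TRUE)
    if (length(unique(z)) == K) return(list(labels = z, K = K))
  }
}

# community densities by literal double summation
oracle_densities <- function(A, z, K) {
  omega <- matrix(NA_real_, K, K)
  for (r in 1:K) for (s in 1:K) {
    ir <- which(z == r); is <- which(z == s)
    if (!length(ir) || !length(is)) next
    if (r == s && length(ir) < 2) next
    tot <- 0
    for (i in is) for (j in ir) tot <- tot + A[i, j]
    omega[r, s] <- tot / (length(ir) * length(is))
  }
  omega
}

# regional density-to-community and assortativity by literal loops
oracle_regional <- function(A, z, K) {
  n <- nrow(A)
  sizes <- tabulate(z, K)
  retained <- which(sizes >= 2)
  a <- matrix(NA_real_, n, K)
  for (i in 1:n) for (r in retained) {
    tot <- 0
    for (j in which(z == r)) tot <- tot + A[i, j]
    a[i, r] <- tot / sizes[r]
  }
  assr <- rep(NA_real_, n)
  for (i in 1:n) {
    if (!(z[i] %in% retained)) next
    best <- -Inf
    for (r in setdiff(retained, z[i])) best <- max(best, a[i, r])
    assr[i] <- a[i, z[i]] - best
  }
  list(a = a, assr_reg = assr)
}

# histogram entropy (bits) of a stability matrix by explicit counting;
# bins are left-closed [(b-1)/nb, b/nb), last bin closed at 1
oracle_entropy_bits <- function(phi, n_bins) {
  u <- as.vector(phi) / (pi / 2)
  counts <- rep(0, n_bins)
  for (v in u) {
    placed <- FALSE
    for (b in seq_len(n_bins - 1)) {
      if (v >= (b - 1) / n_bins && v < b / n_bins) {
        counts[b] <- counts[b] + 1; placed <- TRUE; break
      }
    }
    if (!placed) counts[n_bins] <- counts[n_bins] + 1
  }
  p <- counts / length(u)
  -sum(ifelse(p > 0, p * log2(p), 0))
}

oracle_angle_1d <- function(v1, v2) {
  v1 <- v1 / sqrt(sum(v1^2)); v2 <- v2 / sqrt(sum(v2^2))
  acos(min(1, abs(sum(v1 * v2))))
}

# small deterministic timeseries fixture
make_ts <- function(n = 6, t_len = 40, seed = 1, tr = 2,
                    networks = NULL) {
  set.seed(seed)
  x <- matrix(rnorm(n * t_len), n, t_len)
  parcellated_timeseries(
    x, sprintf("R%02d", 1:n),
    networks %||% rep(c("A", "B"), length.out = n),
    tr_seconds = tr, subject_id = sprintf("fix%d", seed))
}

# dfc_stack built directly from a phase matrix (bypasses the Hilbert step)
stack_from_phases <- function(ph) {
  n <- nrow(ph); t_len <- ncol(ph)
  tensor <- array(0, c(n, n, t_len))
  for (t in 1:t_len)
    tensor[, , t] <- cos(outer(ph[, t], ph[, t], `-`))
  structure(list(tensor = tensor, phases = ph,
                 region_names = sprintf("R%02d", 1:n),
                 network_labels = rep("A", n),
                 subject_id = "phases"),
            class = "dfc_stack")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cumulative phase unwrap (adds 2*pi whenever a jump exceeds pi)
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

# best-permutation label alignment for small K (used in parameter recovery)
align_labels <- function(z_ref, z, K) {
  perms <- matrix(unlist(combinat_perms(seq_len(K))), ncol = K, byrow = TRUE)
  best <- NULL; best_hits <- -1
  for (i in seq_len(nrow(perms))) {
    mapped <- perms[i, ][z]
    hits <- sum(mapped == z_ref)
    if (hits > best_hits) { best_hits <- hits; best <- perms[i, ] }
  }
  best
}

combinat_perms <- function(v) {
  if (length(v) == 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in combinat_perms(v[-i])) out <- c(out, list(c(v[i], p)))
  out
}
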