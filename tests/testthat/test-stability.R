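test_that("dominant subspace of a rank-1 pattern is its generator", {
  set.seed(3)
  v <- rnorm(7); v <- v / sqrt(sum(v^2))
  ds <- dominant_subspace(tcrossprod(v), k = 1)
  # sign convention: first component of magnitude > 1e-12 positive
  want <- if (v[which(abs(v) > 1e-12)[1]] < 0) -v else v
  expect_equal(as.vector(ds$basis), want, tolerance = 1e-10)
  expect_equal(ds$explained_variance, 1, tolerance = 1e-10)
})

test_that("two components capture a phase-coherence slice completely", {
  set.seed(5)
  ph <- matrix(runif(9 * 6, -pi, pi), 9, 6)
  d <- stack_from_phases(ph)
  s <- d$tensor[, , 3]
  ds <- dominant_subspace(s, k = 2)
  expect_equal(sum(ds$explained_variance), sum(diag(s)), tolerance = 1e-6)
  expect_equal(crossprod(ds$basis), diag(2), tolerance = 1e-10)
  # requesting beyond the numerical rank fails
  expect_error(dominant_subspace(s, k = 3), "rank")
})

test_that("full-degeneracy tie case is deterministic", {
  d1 <- dominant_subspace(diag(5), k = 1)
  d2 <- dominant_subspace(diag(5), k = 1)
  expect_identical(d1$basis, d2$basis)
  expect_equal(sum(d1$basis^2), 1, tolerance = 1e-12)
})

test_that("angular distance reproduces the canonical-angle limits", {
  e1 <- matrix(c(1, 0, 0), 3); e2 <- matrix(c(0, 1, 0), 3)
  expect_equal(angular_distance(e1, e1), 0)
  expect_equal(angular_distance(e1, e2), pi / 2)
  mid <- matrix(c(1, 1, 0) / sqrt(2), 3)
  expect_equal(angular_distance(e1, mid), pi / 4, tolerance = 1e-12)
  expect_error(angular_distance(e1 * 2, e2), "orthonormal")
})

test_that("1-D angular distance equals the direct inner-product oracle", {
  set.seed(8)
  for (i in 1:25) {
    v1 <- rnorm(6); v2 <- rnorm(6)
    b1 <- matrix(v1 / sqrt(sum(v1^2))); b2 <- matrix(v2 / sqrt(sum(v2^2)))
    expect_equal(angular_distance(b1, b2), oracle_angle_1d(v1, v2),
                 tolerance = 1e-10)
  }
})

test_that("identical patterns give an all-zero landscape", {
  ph <- matrix(c(0, 0.7, 1.9, 2.4), nrow = 4, ncol = 6)  # constant in time
  m <- stability_matrix(stack_from_phases(ph), k = 2)
  expect_equal(m$phi, matrix(0, 6, 6))
  s <- summarize_stability(m)
  expect_equal(s$entropy, 0)
  expect_identical(s$ts, Inf)
})

test_that("alternating orthogonal patterns give a checkerboard landscape", {
  n <- 6; t_len <- 8
  b1 <- rep(c(1, 0), 3); b2 <- rep(c(0, 1), 3)
  tensor <- array(0, c(n, n, t_len))
  for (t in 1:t_len) {
    v <- if (t %% 2 == 1) b1 else b2
    tensor[, , t] <- tcrossprod(v / sqrt(sum(v^2)))
  }
  stk <- structure(list(tensor = tensor,
                        phases = matrix(0, n, t_len),
                        region_names = sprintf("R%d", 1:n),
                        network_labels = rep("A", n),
                        subject_id = "alt"), class = "dfc_stack")
  m <- stability_matrix(stk, k = 1)
  want <- outer(1:t_len, 1:t_len,
                function(x, y) ifelse((x - y) %% 2 == 0, 0, pi / 2))
  # acos near sigma = 1 resolves angles only to sqrt(machine eps)
  expect_equal(m$phi, want, tolerance = 1e-6)
})

test_that("vectorized 2-D angles agree with pairwise svd calls", {
  set.seed(13)
  ph <- matrix(runif(10 * 12, -pi, pi), 10, 12)
  d <- stack_from_phases(ph)
  for (mode in c("largest", "smallest", "mean")) {
    m <- stability_matrix(d, k = 2, mode = mode)
    bases <- lapply(1:12, function(t)
      dominant_subspace(d$tensor[, , t], 2)$basis)
    for (pair in list(c(1, 2), c(3, 9), c(5, 12))) {
      direct <- angular_distance(bases[[pair[1]]], bases[[pair[2]]],
                                 mode = mode)
      expect_equal(m$phi[pair[1], pair[2]], direct, tolerance = 1e-8)
    }
  }
})

test_that("a T = 150 stack yields a 150 x 150 landscape", {
  ts <- gen_oscillator_timeseries(oscillator_spec(n_regions = 10,
                                                  n_timepoints = 150,
                                                  seed = 2))
  m <- stability_matrix(phase_coherence_dfc(ts), k = 2)
  expect_equal(dim(m$phi), c(150L, 150L))
})

test_that("landscape entropy matches the brute-force histogram oracle", {
  set.seed(17)
  for (i in 1:5) {
    ph <- matrix(runif(6 * 10, -pi, pi), 6, 10)
    m <- stability_matrix(stack_from_phases(ph), k = 2)
    e <- entropy_ts(m, n_bins = 256)
    expect_equal(e$entropy, oracle_entropy_bits(m$phi, 256),
                 tolerance = 1e-12)
    e32 <- entropy_ts(m, n_bins = 32)
    expect_equal(e32$entropy, oracle_entropy_bits(m$phi, 32),
                 tolerance = 1e-12)
  }
})

test_that("entropy hits its analytic values on constructed landscapes", {
  # half the entries 0, half pi/2: two equal bins, 1 bit
  t_len <- 4
  phi <- rbind(c(0, 0, pi / 2, pi / 2),
               c(0, 0, pi / 2, pi / 2),
               c(pi / 2, pi / 2, 0, 0),
               c(pi / 2, pi / 2, 0, 0))
  m <- structure(list(phi = phi, subspace_dim = 1L, mode = "largest"),
                 class = "temporal_stability_matrix")
  expect_equal(entropy_ts(m)$entropy, 1)
  # entries filling all 256 bins equally: 8 bits
  centers <- (seq_len(256) - 0.5) / 256 * pi / 2
  phi_u <- matrix(rep(centers, 4), 32, 32)
  m_u <- structure(list(phi_u = NULL, phi = phi_u, subspace_dim = 1L,
                        mode = "largest"),
                   class = "temporal_stability_matrix")
  expect_equal(entropy_ts(m_u)$entropy, 8)
})

test_that("global temporal distance is the successive-pair mean", {
  phi <- matrix(0, 3, 3)
  phi[1, 2] <- phi[2, 1] <- 0.2
  phi[2, 3] <- phi[3, 2] <- 0.4
  phi[1, 3] <- phi[3, 1] <- 1.5
  m <- structure(list(phi = phi, subspace_dim = 1L, mode = "largest"),
                 class = "temporal_stability_matrix")
  g <- global_temporal_distance(m)
  expect_equal(g$global_temporal_distance, 0.3)
  expect_equal(g$ts_global, 1 / 0.3)
  # the all-off-diagonal flag includes phi[1, 3]
  g_all <- global_temporal_distance(m, all_offdiagonal = TRUE)
  expect_equal(g_all$global_temporal_distance, mean(c(0.2, 0.4, 1.5)))
  # zero landscape: sentinel
  m0 <- structure(list(phi = matrix(0, 3, 3), subspace_dim = 1L,
                       mode = "largest"),
                  class = "temporal_stability_matrix")
  expect_identical(global_temporal_distance(m0)$ts_global, Inf)
})

test_that("duplicating a timepoint cannot increase the distance", {
  set.seed(23)
  for (i in 1:5) {
    ph <- matrix(runif(5 * 8, -pi, pi), 5, 8)
    ins <- sample(2:7, 1)
    ph_dup <- cbind(ph[, 1:ins], ph[, ins], ph[, (ins + 1):8])
    g1 <- global_temporal_distance(
      stability_matrix(stack_from_phases(ph), k = 2))
    g2 <- global_temporal_distance(
      stability_matrix(stack_from_phases(ph_dup), k = 2))
    expect_lte(g2$global_temporal_distance,
               g1$global_temporal_distance + 1e-12)
  }
})

test_that("network restriction is local and the full label is the whole brain", {
  sp <- oscillator_spec(n_regions = 12, n_timepoints = 40,
                        community_assignment = rep(1:2, each = 6),
                        seed = 6)
  ts <- gen_oscillator_timeseries(sp)
  dfc <- phase_coherence_dfc(ts)
  # restriction to all regions reproduces the whole-brain summary
  all_lab <- parcellated_timeseries(ts$data, ts$region_names,
                                    rep("ALL", 12), ts$tr_seconds)
  dfc_all <- phase_coherence_dfc(all_lab)
  whole <- summarize_stability(stability_matrix(dfc_all, k = 2))
  net <- network_stability(dfc_all, "ALL", k = 2)
  expect_equal(net$entropy, whole$entropy)
  expect_equal(net$global_temporal_distance, whole$global_temporal_distance)
  expect_identical(net$scope, "ALL")

  # locality: permuting the *other* network's signals leaves a network's
  # summary unchanged
  s1 <- network_stability(dfc, "N1", k = 2)
  perm <- c(1:6, 12:7)
  ts_p <- parcellated_timeseries(ts$data[perm, ], ts$region_names[perm],
                                 ts$network_labels[perm], ts$tr_seconds)
  s1_p <- network_stability(phase_coherence_dfc(ts_p), "N1", k = 2)
  expect_equal(s1$entropy, s1_p$entropy, tolerance = 1e-10)
  expect_equal(s1$global_temporal_distance, s1_p$global_temporal_distance,
               tolerance = 1e-10)

  expect_error(network_stability(dfc, "nope"), "unknown")
  ts_s <- parcellated_timeseries(ts$data, ts$region_names,
                                 c("solo", rep("rest", 11)), ts$tr_seconds)
  expect_error(network_stability(phase_coherence_dfc(ts_s), "solo"),
               "single region")
})

test_that("landscape range and symmetry hold across random stacks", {
  set.seed(31)
  for (i in 1:100) {
    ph <- matrix(runif(5 * 7, -pi, pi), 5, 7)
    m <- stability_matrix(stack_from_phases(ph), k = 2)
    expect_true(isSymmetric(m$phi))
    expect_true(all(m$phi >= 0 & m$phi <= pi / 2 + 1e-12))
    expect_equal(diag(m$phi), rep(0, 7))
  }
})

test_that("switching lowers temporal stability relative to static coupling", {
  # module-level check at 3 seed pairs; the full 10-pair version runs in
  # the acceptance suite
  gtd_for <- function(sp) {
    ts <- gen_oscillator_timeseries(sp)
    m <- stability_matrix(phase_coherence_dfc(ts), k = 2)
    global_temporal_distance(m)$global_temporal_distance
  }
  wins <- sapply(1:3, function(s) {
    gtd_for(oscillator_spec(switch_period = 20, seed = s)) >
      gtd_for(oscillator_spec(seed = s))
  })
  expect_true(all(wins))
})
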