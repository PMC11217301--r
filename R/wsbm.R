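#' Prior hyperparameters for the weighted stochastic block model
#'
#' Weakly informative conjugate defaults: symmetric Dirichlet(1) over
#' community proportions, and a Normal-Gamma prior (mean 0, pseudo-count
#' 1, shape 1, rate 1) on each block's weight mean and precision.
#'
#' @param dirichlet Dirichlet concentration per community.
#' @param mu0 prior mean of block weight means.
#' @param kappa0 prior pseudo-count on the mean.
#' @param shape0,rate0 Gamma prior on the weight precision.
#' @return A `wsbm_prior` list.
#' @export
wsbm_prior <- function(dirichlet = 1, mu0 = 0, kappa0 = 1,
                       shape0 = 1, rate0 = 1) {
  stopifnot(dirichlet > 0, kappa0 > 0, shape0 > 0, rate0 > 0)
  structure(list(dirichlet = dirichlet, mu0 = mu0, kappa0 = kappa0,
                 shape0 = shape0, rate0 = rate0), class = "wsbm_prior")
}

#' Fit a weighted stochastic block model by variational Bayes
#'
#' Groups the nodes of a signed, weighted, undirected adjacency matrix
#' into `K` communities by stochastic equivalence of their weighted
#' connection profiles. Each node carries a latent community label; each
#' unordered node pair contributes its weight through a normal law whose
#' mean and precision depend only on the pair's community labels
#' (weight-only likelihood on the complete graph: functional connectivity
#' adjacencies are dense and signed, so an edge-presence component would
#' carry no information). The mean-field posterior over labels, mixing
#' proportions and block parameters is optimized by coordinate ascent:
#' block and proportion factors in closed conjugate form, then one
#' sequential sweep of label updates per iteration, which makes the
#' evidence lower bound (ELBO) non-decreasing within a restart.
#'
#' Label responsibilities are initialized uniformly at random per
#' restart (restart r seeds its RNG from `(seed, r)`); the restart with
#' the highest final ELBO is returned.
#'
#' @param A N x N symmetric finite numeric matrix with zero diagonal
#'   (e.g. the Fisher-z static connectivity from [static_fc()]).
#' @param K number of communities, `2 <= K <= N`.
#' @param restarts number of random restarts (default 30).
#' @param seed integer seed governing all restarts.
#' @param tol convergence threshold on the relative ELBO change
#'   (default 1e-6).
#' @param max_iter iteration cap per restart (default 500).
#' @param prior a [wsbm_prior()].
#' @return Object of class `wsbm_model`: `K`, `label_posteriors`
#'   (N x K, rows sum to 1), `block_mean`, `block_mean_sd`,
#'   `block_var_mean` (posterior expected weight variance), `elbo`,
#'   `elbo_trace` (best restart), `restart_elbos`, `n_restarts`, `seed`,
#'   `converged`, `n_iter`.
#' @export
fit_wsbm <- function(A, K, restarts = 30L, seed = 1L, tol = 1e-6,
                     max_iter = 500L, prior = wsbm_prior()) {
  if (inherits(A, "static_fc")) A <- A$z_matrix
  if (!is.matrix(A) || !is.numeric(A)) stop("`A` must be a numeric matrix")
  if (any(!is.finite(A))) stop("`A` contains non-finite entries")
  if (!isSymmetric(unname(A), tol = 1e-10)) stop("`A` must be symmetric")
  if (any(diag(A) != 0)) stop("`A` must have a zero diagonal")
  n <- nrow(A)
  K <- as.integer(K)
  if (K < 2L) stop("K must be at least 2")
  if (K > n) stop("K cannot exceed the number of nodes")
  restarts <- as.integer(restarts)
  if (restarts < 1L) stop("need at least 1 restart")

  best <- NULL
  restart_elbos <- numeric(restarts)
  for (r in seq_len(restarts)) {
    set.seed(derive_seed(seed, r))
    fit <- wsbm_single_run(A, K, tol, max_iter, prior)
    restart_elbos[r] <- fit$elbo
    if (is.null(best) || fit$elbo > best$elbo) best <- fit
  }
  structure(c(best,
              list(K = K, n_restarts = restarts, seed = as.integer(seed),
                   restart_elbos = restart_elbos)),
            class = "wsbm_model")
}

wsbm_single_run <- function(A, K, tol, max_iter, prior) {
  n <- nrow(A)
  A2 <- A * A
  # init: cluster nodes by their weighted connection profiles (k-means on
  # adjacency rows, random centers per restart). Label-space random inits
  # leave every block with the same weight distribution -- a symmetric
  # fixed point of the mean-field updates -- so symmetry must be broken
  # in node space.
  z0 <- tryCatch(
    stats::kmeans(A, centers = K, iter.max = 10L, nstart = 1L)$cluster,
    error = function(e) sample.int(K, n, replace = TRUE))
  tau <- matrix(0.1 / K, n, K)
  tau[cbind(seq_len(n), z0)] <- tau[cbind(seq_len(n), z0)] + 0.9
  elbo_trace <- numeric(0)
  converged <- FALSE
  params <- NULL
  for (iter in seq_len(max_iter)) {
    params <- wsbm_block_update(A, A2, tau, prior)
    gam <- prior$dirichlet + colSums(tau)
    elog_pi <- digamma(gam) - digamma(sum(gam))
    # sequential label sweep (exact coordinate updates given q(theta), q(pi))
    nvec <- colSums(tau)
    for (i in seq_len(n)) {
      w <- A[, i]; w2 <- A2[, i]
      u2 <- crossprod(tau, w2)
      u1 <- crossprod(tau, w)
      u0 <- nvec - tau[i, ]
      lt <- elog_pi + as.vector(params$a %*% u2 + params$b %*% u1 +
                                params$cc %*% u0)
      lt <- lt - max(lt)
      new_tau <- exp(lt) / sum(exp(lt))
      nvec <- nvec - tau[i, ] + new_tau
      tau[i, ] <- new_tau
    }
    elbo <- wsbm_elbo(A, A2, tau, params, gam, elog_pi, prior)
    elbo_trace <- c(elbo_trace, elbo)
    if (iter > 1L) {
      delta <- elbo - elbo_trace[iter - 1L]
      if (abs(delta) / (abs(elbo) + .Machine$double.eps) < tol) {
        converged <- TRUE
        break
      }
    }
  }
  list(label_posteriors = tau,
       block_mean = params$mu_n,
       block_mean_sd = sqrt(params$beta_n /
                              (params$kappa_n * pmax(params$alpha_n - 1, 0.5))),
       block_var_mean = params$beta_n / pmax(params$alpha_n - 1, 0.5),
       elbo = elbo_trace[length(elbo_trace)],
       elbo_trace = elbo_trace,
       converged = converged,
       n_iter = length(elbo_trace))
}

# Expected sufficient statistics over unordered node pairs per unordered
# block (r, s), and the conjugate Normal-Gamma posterior update. All
# returned matrices are K x K symmetric; entry (r, s) refers to the
# unordered block.
wsbm_block_stats <- function(A, A2, tau) {
  nvec <- colSums(tau)
  m1 <- crossprod(tau)
  h1 <- crossprod(tau, A %*% tau)
  h2 <- crossprod(tau, A2 %*% tau)
  cnt <- outer(nvec, nvec) - m1
  diag(cnt) <- diag(cnt) / 2
  s1 <- h1; diag(s1) <- diag(s1) / 2
  s2 <- h2; diag(s2) <- diag(s2) / 2
  cnt <- pmax((cnt + t(cnt)) / 2, 0)
  list(cnt = cnt, s1 = (s1 + t(s1)) / 2, s2 = (s2 + t(s2)) / 2)
}

wsbm_block_update <- function(A, A2, tau, prior) {
  st <- wsbm_block_stats(A, A2, tau)
  kappa_n <- prior$kappa0 + st$cnt
  mu_n <- (prior$kappa0 * prior$mu0 + st$s1) / kappa_n
  alpha_n <- prior$shape0 + st$cnt / 2
  beta_n <- prior$rate0 +
    (st$s2 + prior$kappa0 * prior$mu0^2 - kappa_n * mu_n^2) / 2
  beta_n <- pmax(beta_n, prior$rate0 * 1e-12)
  e_tau <- alpha_n / beta_n
  e_log_tau <- digamma(alpha_n) - log(beta_n)
  a <- -e_tau / 2
  b <- e_tau * mu_n
  cc <- (e_log_tau - log(2 * pi)) / 2 - (e_tau * mu_n^2 + 1 / kappa_n) / 2
  list(kappa_n = kappa_n, mu_n = mu_n, alpha_n = alpha_n, beta_n = beta_n,
       e_tau = e_tau, e_log_tau = e_log_tau, a = a, b = b, cc = cc)
}

wsbm_elbo <- function(A, A2, tau, params, gam, elog_pi, prior) {
  st <- wsbm_block_stats(A, A2, tau)
  term <- params$a * st$s2 + params$b * st$s1 + params$cc * st$cnt
  lik <- sum(term[upper.tri(term, diag = TRUE)])
  nvec <- colSums(tau)
  ez <- sum(nvec * elog_pi)
  hz <- -sum(tau[tau > 0] * log(tau[tau > 0]))
  K <- ncol(tau)
  a0 <- prior$dirichlet
  dir_term <- (lgamma(K * a0) - K * lgamma(a0) + sum((a0 - 1) * elog_pi)) -
    (lgamma(sum(gam)) - sum(lgamma(gam)) + sum((gam - 1) * elog_pi))
  # Normal-Gamma: E_q[log p(theta)] - E_q[log q(theta)] per unordered block
  kn <- params$kappa_n; mn <- params$mu_n
  an <- params$alpha_n; bn <- params$beta_n
  etau <- params$e_tau; eltau <- params$e_log_tau
  ng <- 0.5 * log(prior$kappa0 / kn) -
    prior$kappa0 / 2 * (etau * (mn - prior$mu0)^2 + 1 / kn) + 0.5 +
    prior$shape0 * log(prior$rate0) - lgamma(prior$shape0) -
    (an * log(bn) - lgamma(an)) +
    (prior$shape0 - an) * eltau - (prior$rate0 - bn) * etau
  ng_term <- sum(ng[upper.tri(ng, diag = TRUE)])
  lik + ez + hz + dir_term + ng_term
}

#' Maximum-a-posteriori partition from a fitted model
#'
#' Reads out each node's most probable community; ties broken toward the
#' smallest community index. Communities left empty by the fit are
#' tracked in the `K` field, not renumbered.
#'
#' @param model a `wsbm_model` from [fit_wsbm()].
#' @return List with `labels` (length-N integer vector in `1..K`) and
#'   `K`.
#' @export
map_partition <- function(model) {
  if (!inherits(model, "wsbm_model") || is.null(model$label_posteriors))
    stop("`model` must be a fitted wsbm_model")
  list(labels = max.col(model$label_posteriors, ties.method = "first"),
       K = model$K)
}

#' @export
print.wsbm_model <- function(x, ...) {
  cat("<wsbm_model> K =", x$K, "| N =", nrow(x$label_posteriors),
      "| ELBO =", format(x$elbo), "|", x$n_restarts, "restarts",
      if (x$converged) "(converged)" else "(iteration cap)", "\n")
  invisible(x)
}
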