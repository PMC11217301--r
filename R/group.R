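#' Jarque-Bera normality test
#'
#' Moment-based test of normality: `JB = n (S^2/6 + (K - 3)^2/24)` with
#' sample skewness `S` and kurtosis `K`, referred to a chi-squared
#' distribution with 2 degrees of freedom.
#'
#' @param x numeric sample (n >= 8 recommended; the asymptotic reference
#'   distribution is poor below that).
#' @return List with `statistic` and `p_value`.
#' @export
jarque_bera_test <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4L) stop("sample too small for a moment-based normality test")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero-variance sample")
  s <- mean((x - m)^3) / m2^1.5
  k <- mean((x - m)^4) / m2^2
  stat <- n * (s^2 / 6 + (k - 3)^2 / 24)
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 2, lower.tail = FALSE))
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the normalized skewness statistic (D'Agostino's
#' transformation) and normalized kurtosis statistic (Anscombe-Glynn's
#' transformation) into `K2 = Z_s^2 + Z_k^2`, referred to a chi-squared
#' distribution with 2 degrees of freedom.
#'
#' @param x numeric sample with at least 8 observations (the kurtosis
#'   normalization requires it).
#' @return List with `statistic` and `p_value`.
#' @export
dagostino_pearson_test <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) stop("omnibus test requires at least 8 observations")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("zero-variance sample")
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2
  # skewness (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z_s <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis (Anscombe & Glynn 1983)
  e_g2 <- 3 * (n - 1) / (n + 1)
  var_g2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (g2 - e_g2) / sqrt(var_g2)
  sqrt_b1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  aa <- 6 + 8 / sqrt_b1 * (2 / sqrt_b1 + sqrt(1 + 4 / sqrt_b1^2))
  z_k <- ((1 - 2 / (9 * aa)) -
            ((1 - 2 / aa) / (1 + xk * sqrt(2 / (aa - 4))))^(1 / 3)) /
    sqrt(2 / (9 * aa))
  stat <- z_s^2 + z_k^2
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 2, lower.tail = FALSE))
}

#' Normality gate for the two-sample comparison protocol
#'
#' Returns `TRUE` (use the parametric path) only when both samples pass
#' both the Jarque-Bera and the D'Agostino-Pearson omnibus test at
#' `alpha`. Samples with fewer than 8 observations cannot be gated and
#' fall back to the nonparametric path with a warning. The combination
#' rule is configurable to `"either"` (one passing test per sample
#' suffices).
#'
#' @param x,y the two samples.
#' @param alpha significance level of the normality tests (default 0.05).
#' @param rule `"both"` (default) or `"either"`.
#' @return Logical: `TRUE` for the parametric (t-test) path.
#' @export
normality_gate <- function(x, y, alpha = 0.05, rule = c("both", "either")) {
  rule <- match.arg(rule)
  if (length(x) < 8L || length(y) < 8L) {
    warning("sample(s) below 8 observations; using the nonparametric path")
    return(FALSE)
  }
  verdict <- function(s) {
    p <- c(jarque_bera_test(s)$p_value, dagostino_pearson_test(s)$p_value)
    if (rule == "both") all(p > alpha) else any(p > alpha)
  }
  verdict(x) && verdict(y)
}

#' Two-group comparison with normality-gated test choice
#'
#' Parametric path: two-sided unpaired pooled-variance t-test.
#' Nonparametric path: two-sided Wilcoxon rank-sum test with normal
#' approximation and tie correction. If the pooled data are degenerate
#' (zero variance) under the t-test, the rank-sum fallback is used.
#'
#' @param x,y the two samples.
#' @param gate logical from [normality_gate()], or `NULL` to run the
#'   gate here.
#' @param measure name recorded in the result.
#' @param alpha gate significance level when `gate` is `NULL`.
#' @return Object of class `group_comparison`: `measure`, `test_used`,
#'   `statistic`, `p_value`, `group_means`, `group_medians`,
#'   `n_per_group`, `parametric`.
#' @export
compare_groups <- function(x, y, gate = NULL, measure = "measure",
                           alpha = 0.05) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  if (is.null(gate))
    gate <- suppressWarnings(normality_gate(x, y, alpha = alpha))
  if (gate && stats::var(c(x, y)) == 0) gate <- FALSE
  if (gate) {
    ht <- stats::t.test(x, y, var.equal = TRUE)
    test_used <- "t-test"
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    test_used <- "rank-sum"
  }
  structure(list(measure = measure, test_used = test_used,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 group_means = c(mean(x), mean(y)),
                 group_medians = c(stats::median(x), stats::median(y)),
                 n_per_group = c(length(x), length(y)),
                 parametric = gate),
            class = "group_comparison")
}

#' Regress covariates out of a per-subject measure
#'
#' Ordinary least squares of the values on intercept + age + sex (sex as
#' indicator) over the pooled sample; returns the residuals. Collinear
#' or constant covariate columns are dropped with a warning.
#'
#' @param values numeric vector, one per subject.
#' @param covariates data.frame with columns `age` and `sex` aligned with
#'   `values`.
#' @return Numeric residual vector.
#' @export
residualize <- function(values, covariates) {
  if (length(values) != nrow(covariates))
    stop("values and covariates are misaligned")
  if (anyNA(values) || anyNA(covariates$age) || anyNA(covariates$sex))
    stop("covariates must be complete for all subjects")
  df <- data.frame(y = as.numeric(values),
                   age = as.numeric(covariates$age),
                   sex = factor(covariates$sex))
  keep <- c("age", "sex")
  if (length(unique(df$sex)) < 2L) {
    warning("constant sex column dropped from the design")
    keep <- setdiff(keep, "sex")
  }
  if (stats::var(df$age) == 0) {
    warning("constant age column dropped from the design")
    keep <- setdiff(keep, "age")
  }
  form <- if (length(keep))
    stats::reformulate(keep, response = "y") else y ~ 1
  stats::resid(stats::lm(form, data = df))
}

#' Region-wise group comparison with covariate control
#'
#' For each region, the pooled scores of both groups are residualized on
#' age and sex and compared with the unpaired pooled-variance t-test (the
#' protocol used for regional assortativity maps); Benjamini-Hochberg
#' q-values are appended across regions.
#'
#' @param scores_a,scores_b region x subject matrices with identical row
#'   (region) sets.
#' @param covariates_a,covariates_b data.frames with `age` and `sex`
#'   columns, one row per subject, aligned with the score columns.
#' @return Object of class `regionwise_report`: data.frame with one row
#'   per region (`region`, `statistic`, `p_value`, `fdr_q`) and attribute
#'   `covariates_removed`.
#' @export
regionwise_compare <- function(scores_a, scores_b,
                               covariates_a, covariates_b) {
  scores_a <- as.matrix(scores_a); scores_b <- as.matrix(scores_b)
  if (nrow(scores_a) != nrow(scores_b))
    stop("region mismatch between the two score matrices")
  if (!is.null(rownames(scores_a)) && !is.null(rownames(scores_b)) &&
      !identical(rownames(scores_a), rownames(scores_b)))
    stop("region mismatch between the two score matrices")
  n_a <- ncol(scores_a); n_b <- ncol(scores_b)
  cov_pool <- rbind(covariates_a[, c("age", "sex"), drop = FALSE],
                    covariates_b[, c("age", "sex"), drop = FALSE])
  res <- lapply(seq_len(nrow(scores_a)), function(i) {
    pooled <- c(scores_a[i, ], scores_b[i, ])
    r <- suppressWarnings(residualize(pooled, cov_pool))
    cmp <- compare_groups(r[seq_len(n_a)], r[n_a + seq_len(n_b)],
                          gate = TRUE)
    c(statistic = cmp$statistic, p_value = cmp$p_value)
  })
  out <- as.data.frame(do.call(rbind, res))
  out <- cbind(region = rownames(scores_a) %||% seq_len(nrow(scores_a)),
               out)
  out$fdr_q <- stats::p.adjust(out$p_value, method = "BH")
  attr(out, "covariates_removed") <- c("age", "sex")
  class(out) <- c("regionwise_report", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
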