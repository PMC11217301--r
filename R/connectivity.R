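#' Static functional connectivity (Fisher-z Pearson correlation)
#'
#' Computes the whole-scan Pearson correlation between every pair of
#' region timeseries and applies the r-to-z (inverse hyperbolic tangent)
#' transform, yielding the signed weighted adjacency matrix used for
#' community detection. Correlations are clipped to
#' `[-1 + 1e-12, 1 - 1e-12]` before `atanh` so duplicated signals give a
#' large finite weight rather than infinity; the diagonal is set to 0
#' (self-connections are excluded everywhere downstream).
#'
#' @param ts a [parcellated_timeseries] with at least 3 timepoints.
#' @return An object of class `static_fc` with field `z_matrix`
#'   (N x N symmetric, zero diagonal, finite).
#' @export
static_fc <- function(ts) {
  stopifnot(inherits(ts, "parcellated_timeseries"))
  x <- ts$data
  if (ncol(x) < 3L) stop("static FC needs at least 3 timepoints")
  v <- apply(x, 1L, stats::var)
  if (any(v == 0))
    stop("zero-variance region(s): ",
         paste(ts$region_names[v == 0], collapse = ", "))
  r <- stats::cor(t(x))
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2
  dimnames(z) <- list(ts$region_names, ts$region_names)
  structure(list(z_matrix = z, subject_id = ts$subject_id),
            class = "static_fc")
}

# FFT-based analytic signal of one real vector (discrete Hilbert
# transform): zero out negative frequencies, double positive ones.
analytic_signal <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phase of each region's signal
#'
#' Each region's signal is mean-centered (the phase of a non-zero-mean
#' signal is ill-defined), optionally band-pass filtered, and its analytic
#' signal formed by the Hilbert transform; the phase is the argument of
#' the analytic signal, reported in `(-pi, pi]`.
#'
#' @param ts a [parcellated_timeseries] with at least 4 timepoints.
#' @param bandpass `NULL` (default, no filtering) or a length-2 numeric
#'   vector of band edges in Hz (e.g. `c(0.01, 0.1)`), applied as a
#'   zero-phase Butterworth filter before the transform.
#' @param bandpass_order Butterworth order (default 2).
#' @return N x T numeric matrix of phases in radians.
#' @export
instantaneous_phase <- function(ts, bandpass = NULL, bandpass_order = 2L) {
  stopifnot(inherits(ts, "parcellated_timeseries"))
  x <- ts$data
  if (ncol(x) < 4L) stop("phase estimation needs at least 4 timepoints")
  x <- x - rowMeans(x)
  dead <- apply(x, 1L, function(r) all(r == 0))
  if (any(dead))
    stop("constant signal (zero after centering) in region(s): ",
         paste(ts$region_names[dead], collapse = ", "))
  if (!is.null(bandpass)) {
    nyq <- 1 / (2 * ts$tr_seconds)
    if (length(bandpass) != 2L || any(bandpass <= 0) ||
        bandpass[2] <= bandpass[1] || bandpass[2] >= nyq)
      stop("bandpass must be increasing band edges in (0, Nyquist = ",
           signif(nyq, 4), ") Hz")
    bf <- signal::butter(bandpass_order, bandpass / nyq, type = "pass")
    x <- t(apply(x, 1L, function(r) signal::filtfilt(bf, r)))
  }
  ph <- t(apply(x, 1L, function(r) {
    a <- analytic_signal(r)
    Arg(a)
  }))
  # Arg() returns (-pi, pi]; fold the boundary value -pi (possible from
  # signed zeros) onto pi for a reproducible stored representation
  ph[ph <= -pi] <- ph[ph <= -pi] + 2 * pi
  dimnames(ph) <- list(ts$region_names, NULL)
  ph
}

#' Time-resolved dynamic functional connectivity by phase coherence
#'
#' For instantaneous phases `theta(n, t)` the dFC tensor is
#' `dFC(n, p, t) = cos(theta(n, t) - theta(p, t))`. Every time slice is
#' symmetric with unit diagonal, entries in \[-1, 1\], and has exact rank
#' at most 2 (`cos(a - b) = cos a cos b + sin a sin b`).
#'
#' @inheritParams instantaneous_phase
#' @return An object of class `dfc_stack`: list with `tensor`
#'   (N x N x T), `phases` (N x T), `region_names`, `network_labels`,
#'   `subject_id`.
#' @export
phase_coherence_dfc <- function(ts, bandpass = NULL, bandpass_order = 2L) {
  ph <- instantaneous_phase(ts, bandpass = bandpass,
                            bandpass_order = bandpass_order)
  n <- nrow(ph); t_len <- ncol(ph)
  tensor <- array(0, dim = c(n, n, t_len))
  cph <- cos(ph); sph <- sin(ph)
  for (t in seq_len(t_len)) {
    # cos(theta_n - theta_p) = c c' + s s' -- rank <= 2 by construction
    s <- tcrossprod(cph[, t]) + tcrossprod(sph[, t])
    tensor[, , t] <- (s + t(s)) / 2
  }
  structure(list(tensor = tensor, phases = ph,
                 region_names = ts$region_names,
                 network_labels = ts$network_labels,
                 subject_id = ts$subject_id),
            class = "dfc_stack")
}

#' @export
print.dfc_stack <- function(x, ...) {
  d <- dim(x$tensor)
  cat("<dfc_stack> subject:", x$subject_id, "|", d[1], "x", d[2],
      "regions x", d[3], "timepoints\n")
  invisible(x)
}
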