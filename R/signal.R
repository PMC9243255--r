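#' Construct a BOLD time-series object
#'
#' @param values node x time numeric matrix (one row per parcel).
#' @param tr repetition time in seconds.
#' @param geometry optional `"parcellation"` the rows refer to.
#' @param band `NULL` for raw data, or `c(low, high)` in Hz once bandpassed.
#' @return object of class `"bold_ts"`.
#' @export
bold_ts <- function(values, tr, geometry = NULL, band = NULL) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), tr > 0)
  if (any(!is.finite(values))) stop("non-finite values in BOLD matrix")
  structure(list(values = values, tr = tr, geometry = geometry, band = band),
            class = "bold_ts")
}

#' @export
print.bold_ts <- function(x, ...) {
  cat("BOLD time series:", nrow(x$values), "nodes x", ncol(x$values),
      "volumes, TR =", x$tr, "s\n")
  if (!is.null(x$band)) {
    cat("  bandpassed to", x$band[1], "-", x$band[2], "Hz\n")
  }
  invisible(x)
}

#' Zero-phase narrowband filter for BOLD signals
#'
#' Demeans each node and applies a Butterworth bandpass forward-backward
#' (zero phase distortion), the standard narrowband used for phase analyses
#' of resting-state BOLD (0.008-0.08 Hz by default).
#'
#' @param ts a `"bold_ts"`.
#' @param low_hz,high_hz band edges in Hz; `high_hz` must be below the
#'   Nyquist frequency `1/(2*tr)`.
#' @param order Butterworth order (default 2).
#' @return a `"bold_ts"` with the `band` field set.
#' @export
bandpass_bold <- function(ts, low_hz = 0.008, high_hz = 0.08, order = 2) {
  stopifnot(inherits(ts, "bold_ts"))
  fs <- 1 / ts$tr
  nyq <- fs / 2
  if (!(low_hz > 0 && low_hz < high_hz)) {
    stop("need 0 < low_hz < high_hz")
  }
  if (high_hz >= nyq) {
    stop("high_hz (", high_hz, " Hz) must be below the Nyquist frequency ",
         nyq, " Hz implied by tr = ", ts$tr, " s")
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  v <- ts$values - rowMeans(ts$values)
  out <- t(apply(v, 1, function(x) signal::filtfilt(bf, x)))
  bold_ts(out, tr = ts$tr, geometry = ts$geometry, band = c(low_hz, high_hz))
}

#' Instantaneous phases of narrowband BOLD
#'
#' Computes the analytic signal of each node's (already narrowband) series
#' via the Hilbert transform and returns its instantaneous phase in
#' `[-pi, pi)`. A symmetric edge region is excluded from the valid window to
#' avoid filter and Hilbert edge effects. Constant (zero-variance) nodes are
#' flagged and given phase 0.
#'
#' @param ts a `"bold_ts"`, normally bandpassed (a warning is emitted
#'   otherwise unless `force = TRUE`).
#' @param edge_discard number of volumes to trim at each end (default 10).
#' @param force suppress the not-bandpassed warning.
#' @return object of class `"phase_field"`: list with `phases` (node x time,
#'   radians in `[-pi, pi)`), `valid_window = c(first, last)` retained time
#'   indices, `flagged_nodes`, `tr`, `geometry`.
#' @export
extract_phases <- function(ts, edge_discard = 10, force = FALSE) {
  stopifnot(inherits(ts, "bold_ts"))
  if (is.null(ts$band) && !force) {
    warning("extracting phases from a signal without a recorded bandpass")
  }
  v <- ts$values
  nt <- ncol(v)
  flagged <- unname(which(apply(v, 1, function(x) sd(x) == 0)))
  ph <- matrix(0, nrow(v), nt)
  for (n in seq_len(nrow(v))) {
    if (n %in% flagged) next
    ph[n, ] <- Arg(analytic_signal(v[n, ]))
  }
  ph <- ((ph + pi) %% (2 * pi)) - pi  # wrap to [-pi, pi)
  w <- c(edge_discard + 1L, nt - edge_discard)
  if (w[2] - w[1] + 1 < 10) {
    w <- c(max(1L, (nt - 9L) %/% 2L), min(nt, (nt - 9L) %/% 2L + 9L))
  }
  structure(list(phases = ph, valid_window = w, flagged_nodes = flagged,
                 tr = ts$tr, geometry = ts$geometry),
            class = "phase_field")
}

#' Analytic signal via the discrete Hilbert transform
#'
#' Frequency-domain construction: zero the negative frequencies, double the
#' positive ones (DC and Nyquist kept as-is) and invert the FFT. The
#' imaginary part is the Hilbert transform of the input; the argument is
#' the instantaneous phase.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Columns of the phase matrix inside the valid window.
window_idx <- function(field) {
  seq(field$valid_window[1], field$valid_window[2])
}

#' Per-node intrinsic frequencies from the power spectrum
#'
#' Estimates each node's dominant frequency as the peak of a smoothed
#' periodogram restricted to the analysis band; returns both the peak in Hz
#' and the angular frequency `omega = 2*pi*f` used by the whole-brain model.
#'
#' @param ts a `"bold_ts"` bandpassed to `band`.
#' @param band `c(low, high)` in Hz.
#' @param spans smoothing span passed to [stats::spec.pgram()].
#' @return object of class `"node_frequencies"`: list with `f_peak` (Hz) and
#'   `omega` (rad/s), one entry per node.
#' @export
estimate_node_frequencies <- function(ts, band = c(0.008, 0.08), spans = 3) {
  stopifnot(inherits(ts, "bold_ts"))
  n <- nrow(ts$values)
  f_peak <- numeric(n)
  for (i in seq_len(n)) {
    sp <- spec.pgram(ts$values[i, ], spans = spans, taper = 0,
                     detrend = TRUE, plot = FALSE)
    freq_hz <- sp$freq / ts$tr
    keep <- freq_hz >= band[1] & freq_hz <= band[2]
    if (!any(keep)) keep <- rep(TRUE, length(freq_hz))
    pw <- sp$spec[keep]; fq <- freq_hz[keep]
    if (max(pw) - min(pw) <= .Machine$double.eps * max(pw)) {
      warning("flat in-band spectrum at node ", i, "; taking lowest bin")
      f_peak[i] <- fq[1]
    } else {
      f_peak[i] <- fq[which.max(pw)]
    }
  }
  structure(list(f_peak = f_peak, omega = 2 * pi * f_peak),
            class = "node_frequencies")
}
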