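#' Specify an in-silico perturbation protocol
#'
#' Two protocols probe a fitted whole-brain model at its optimal coupling:
#' * `periodic_force` — an additive periodic drive `F0 cos(omega0 t)` /
#'   `F0 sin(omega0 t)` on the x/y equations of every node, with `omega0`
#'   the node-average intrinsic frequency;
#' * `bifurcation_shift` — each trial redraws the local bifurcation
#'   parameters `a_n` uniformly in `a_range` (kept subcritical, i.e.
#'   within `(-Inf, 0]`).
#'
#' @param kind `"periodic_force"` or `"bifurcation_shift"`.
#' @param F0 forcing amplitude (periodic_force); default 5e-4.
#' @param a_range `c(low, high)` for the redraw (bifurcation_shift);
#'   default c(-0.02, 0).
#' @param n_trials number of perturbed/unperturbed trial pairs (>= 2).
#' @param lambda_s spatial scale of the readout local order parameter.
#' @param seed protocol seed; trial seeds are derived from it.
#' @return object of class `"perturbation_protocol"`.
#' @export
perturbation_protocol <- function(kind = c("periodic_force", "bifurcation_shift"),
                                  F0 = 5e-4, a_range = c(-0.02, 0),
                                  n_trials = 10, lambda_s = 0.12, seed = 1) {
  kind <- match.arg(kind)
  stopifnot(n_trials >= 2, lambda_s > 0)
  if (kind == "bifurcation_shift" && any(a_range > 0)) {
    stop("a_range must stay within (-Inf, 0] (subcritical regime)")
  }
  structure(list(kind = kind, F0 = F0, a_range = a_range,
                 n_trials = n_trials, lambda_s = lambda_s, seed = seed),
            class = "perturbation_protocol")
}

# Local order modulus at lambda_s from a simulated signal:
# bandpass -> Hilbert phases -> kernel-weighted order parameter.
readout_modulus <- function(ts, kernels, lambda_s, edge_discard, band) {
  tsf <- bandpass_bold(ts, band[1], band[2])
  ph <- extract_phases(tsf, edge_discard = edge_discard)
  local_kuramoto(ph, kernels, lambda_s)
}

#' Run a perturbation protocol on a Hopf whole-brain system
#'
#' For each trial, simulates one unperturbed and one perturbed run with
#' paired noise seeds (identical noise streams, so the perturbation alone
#' drives the difference), computes the local order modulus at `lambda_s`
#' from the simulated signal phases, and summarises the per-trial, per-node
#' shift of the time-mean modulus as susceptibility `chi` and information
#' encoding capability `I`.
#'
#' @param system a `"hopf_system"` at its fitted working point (e.g. from
#'   [fitted_system()]).
#' @param protocol a `"perturbation_protocol"`.
#' @param dist node x node distance matrix (builds the readout kernel).
#' @param duration_volumes simulation length per run.
#' @param edge_discard volumes trimmed per end before the phase readout.
#' @param band bandpass for the readout, Hz.
#' @return object of class `"perturbation_result"`: `chi`,
#'   `info_capability`, `diffs` (trial x node matrix of time-mean modulus
#'   shifts), `protocol`, `seeds`.
#' @export
run_protocol <- function(system, protocol, dist, duration_volumes = 150,
                         edge_discard = 10, band = c(0.008, 0.08)) {
  stopifnot(inherits(system, "hopf_system"),
            inherits(protocol, "perturbation_protocol"))
  kernels <- build_kernels(dist, protocol$lambda_s)
  n <- system$n_nodes
  diffs <- matrix(NA_real_, protocol$n_trials, n)
  seeds <- integer(protocol$n_trials)
  for (tr_i in seq_len(protocol$n_trials)) {
    for (attempt in 1:3) {
      s <- derive_seed(protocol$seed, tr_i * 10 + attempt, "trial")
      res <- tryCatch({
        base <- simulate_hopf(system, duration_volumes, seed = s)
        if (protocol$kind == "periodic_force") {
          fs <- forcing_spec(F0 = protocol$F0,
                             omega0 = mean(system$omega))
          pert <- simulate_hopf(system, duration_volumes, seed = s,
                                forcing = fs)
        } else {
          sys_p <- system
          set.seed(derive_seed(protocol$seed, tr_i, "ashift"))
          sys_p$a <- runif(n, protocol$a_range[1], protocol$a_range[2])
          pert <- simulate_hopf(sys_p, duration_volumes, seed = s)
        }
        m0 <- readout_modulus(base, kernels, protocol$lambda_s,
                              edge_discard, band)
        m1 <- readout_modulus(pert, kernels, protocol$lambda_s,
                              edge_discard, band)
        idx <- window_idx(m0)
        rowMeans(m1$modulus[, idx, drop = FALSE]) -
          rowMeans(m0$modulus[, idx, drop = FALSE])
      }, error = function(e) e)
      if (!inherits(res, "error")) { diffs[tr_i, ] <- res; seeds[tr_i] <- s; break }
      if (attempt == 3) stop("trial ", tr_i, " failed after 3 attempts: ",
                             conditionMessage(res))
    }
  }
  structure(list(chi = susceptibility_from_diffs(diffs),
                 info_capability = information_capability_from_diffs(diffs),
                 diffs = diffs, protocol = protocol, seeds = seeds),
            class = "perturbation_result")
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat("Perturbation (", x$protocol$kind, ", ", x$protocol$n_trials,
      " trials, lambda_s = ", x$protocol$lambda_s, ")\n", sep = "")
  cat("  susceptibility chi =", signif(x$chi, 5),
      "  information capability I =", signif(x$info_capability, 5), "\n")
  invisible(x)
}

susceptibility_from_diffs <- function(diffs) {
  mean(colMeans(diffs))  # trials then space
}

information_capability_from_diffs <- function(diffs) {
  if (nrow(diffs) < 2) stop("information capability needs >= 2 trials")
  # across-trial population variance of the shift, averaged over space,
  # square root taken outside the spatial average (centred form for
  # numerical stability)
  ctr <- sweep(diffs, 2, colMeans(diffs))
  sqrt(mean(colMeans(ctr^2)))
}

#' Susceptibility of the model to a perturbation
#'
#' `chi` is the shift in the time-mean local order modulus induced by the
#' perturbation, averaged across trials and then across space:
#' `chi = < < <R~>_t - <R>_t >_trials >_x`.
#'
#' @param perturbed,unperturbed trial x node x time arrays of the local
#'   order modulus (perturbed / unperturbed runs, paired by trial).
#' @return scalar `chi`.
#' @export
susceptibility <- function(perturbed, unperturbed) {
  if (!identical(dim(perturbed), dim(unperturbed))) {
    stop("perturbed and unperturbed arrays must have identical shape")
  }
  d <- apply(perturbed, c(1, 2), mean) - apply(unperturbed, c(1, 2), mean)
  susceptibility_from_diffs(d)
}

#' Information encoding capability
#'
#' The across-trial population variance of the perturbation-induced shift
#' in the time-mean modulus, averaged across space, with the square root
#' taken outside the spatial average:
#' `I = sqrt( < Var_trials( <R~>_t - <R>_t ) >_x )`.
#'
#' @param perturbed,unperturbed trial x node x time arrays (>= 2 trials).
#' @return scalar `I >= 0`.
#' @export
information_capability <- function(perturbed, unperturbed) {
  if (!identical(dim(perturbed), dim(unperturbed))) {
    stop("perturbed and unperturbed arrays must have identical shape")
  }
  if (dim(perturbed)[1] < 2) stop("information capability needs >= 2 trials")
  d <- apply(perturbed, c(1, 2), mean) - apply(unperturbed, c(1, 2), mean)
  information_capability_from_diffs(d)
}

#' Normalised Lempel-Ziv complexity of a BOLD matrix
#'
#' Binarises each node's signal at its own threshold (median or mean),
#' concatenates the node sequences in node order, counts LZ76 phrases and
#' normalises by the random-sequence asymptote `n / log2(n)`, so an i.i.d.
#' fair-coin sequence scores near 1 and a constant sequence near 0.
#'
#' @param ts a `"bold_ts"` (or a numeric matrix / vector).
#' @param binarization `"median"` or `"mean"`.
#' @return scalar normalised complexity in `(0, ~1.1]`.
#' @export
lempel_ziv <- function(ts, binarization = c("median", "mean")) {
  binarization <- match.arg(binarization)
  v <- if (inherits(ts, "bold_ts")) ts$values else rbind(as.matrix(ts))
  if (is.vector(v)) v <- matrix(v, 1)
  if (ncol(v) < 64 && nrow(v) == 1) stop("sequence too short (need T >= 64)")
  bits <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    thr <- if (binarization == "median") median(v[i, ]) else mean(v[i, ])
    b <- as.integer(v[i, ] > thr)
    if (all(b == b[1])) {
      warning("constant signal at node ", i,
              "; contributes minimal complexity")
    }
    bits[i] <- paste(b, collapse = "")
  }
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  c76 <- lz76_phrase_count(s)
  c76 * log2(n) / n
}

# LZ76 phrase count (Lempel & Ziv 1976 exhaustive-history parsing): each new
# phrase is the shortest prefix of the remaining sequence that cannot be
# reproduced from the history that precedes it (overlap allowed).
lz76_phrase_count <- function(s) {
  n <- nchar(s)
  i <- 1L; cnt <- 0L
  while (i <= n) {
    l <- 0L
    # extend while s[i..i+l] occurs as a substring starting within the history
    repeat {
      if (i + l > n) break
      cand <- substr(s, i, i + l)
      hist_plus <- substr(s, 1, i + l - 1)  # history + reproduced prefix
      if (i == 1L || !grepl(cand, hist_plus, fixed = TRUE)) break
      l <- l + 1L
    }
    cnt <- cnt + 1L
    i <- i + l + 1L
  }
  cnt
}
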