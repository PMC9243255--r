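#' Default spatial-scale grid
#'
#' Eleven scales from 0.01 (about 100 mm) to 0.30 (about 3 mm) in steps of
#' 0.03, the grid used throughout the analyses. The grid contains the three
#' reference scales 0.01, 0.12 and 0.30 at which states are conventionally
#' compared.
#'
#' @return numeric vector of lambda values in 1/mm.
#' @export
default_lambda_grid <- function() c(0.01, seq(0.03, 0.30, by = 0.03))

#' Build exponential spatial kernels over a scale grid
#'
#' For each scale `lambda` the kernel is `C_lambda[n,p] = exp(-lambda *
#' r(n,p))` with unit self-weight (r = 0 on the diagonal), together with the
#' per-node normalisation `sum_q C_lambda[n,q]` used by the local Kuramoto
#' order parameter.
#'
#' @param dist node x node distance matrix in mm.
#' @param lambdas positive scale grid in 1/mm; default [default_lambda_grid()].
#' @return object of class `"kernel_set"`: `lambdas`, `weights` (list of
#'   matrices), `norms` (list of row-sum vectors).
#' @export
build_kernels <- function(dist, lambdas = default_lambda_grid()) {
  stopifnot(all(lambdas > 0), is.matrix(dist))
  weights <- lapply(lambdas, function(l) exp(-l * dist))
  norms <- lapply(weights, rowSums)
  structure(list(lambdas = lambdas, weights = weights, norms = norms),
            class = "kernel_set")
}

kernel_index <- function(kernels, lam) {
  i <- which(abs(kernels$lambdas - lam) < 1e-9)
  if (length(i) != 1) stop("lambda = ", lam, " not in the kernel grid")
  i
}

#' Local Kuramoto order parameter field at one scale
#'
#' The node-level order parameter is the kernel-weighted spatial average of
#' the complex phase factors,
#' \deqn{R_n(t) e^{i \nu_n(t)} = \sum_p \frac{C^{\lambda}_{np}}
#'   {\sum_q C^{\lambda}_{nq}} e^{i \phi_p(t)},}
#' whose modulus `R in [0,1]` measures local synchronisation around node n
#' at spatial scale `lambda`. The self-node (p = n, weight 1) is included in
#' the sum; set `include_self = FALSE` to exclude it.
#'
#' @param phases a `"phase_field"`.
#' @param kernels a `"kernel_set"` built on the same geometry.
#' @param lam scale, must belong to `kernels$lambdas`.
#' @param include_self include the node's own phase factor (default TRUE).
#' @return object of class `"local_order_field"`: `modulus`, `phase`
#'   (node x time), `lam`, `valid_window`.
#' @export
local_kuramoto <- function(phases, kernels, lam, include_self = TRUE) {
  stopifnot(inherits(phases, "phase_field"), inherits(kernels, "kernel_set"))
  i <- kernel_index(kernels, lam)
  W <- kernels$weights[[i]]
  if (!include_self) diag(W) <- 0
  W <- W / rowSums(W)
  idx <- window_idx(phases)
  if (any(is.na(phases$phases[, idx]))) {
    stop("NaN phases inside the valid window")
  }
  Z <- W %*% exp(1i * phases$phases)
  dimnames(Z) <- NULL
  structure(list(modulus = pmin(abs(Z), 1),
                 phase = ((Arg(Z) + pi) %% (2 * pi)) - pi,
                 lam = lam, valid_window = phases$valid_window),
            class = "local_order_field")
}

#' Amplitude turbulence at one scale
#'
#' The population standard deviation of the local order modulus across all
#' nodes and time points in the valid window,
#' `D = sqrt(<R^2> - <R>^2)`; the core discriminative measure between brain
#' states. Zero for a fully synchronised field, at most 0.5 for a
#' `[0,1]`-bounded modulus.
#'
#' @param field a `"local_order_field"`.
#' @return scalar `D >= 0`.
#' @export
amplitude_turbulence <- function(field) {
  v <- field$modulus[, window_idx(field), drop = FALSE]
  if (length(v) < 2) stop("amplitude turbulence needs at least 2 samples")
  # population std via the centred form (numerically stable near synchrony)
  sqrt(mean((v - mean(v))^2))
}

#' Amplitude turbulence across the scale grid
#'
#' @param phases a `"phase_field"`.
#' @param kernels a `"kernel_set"`.
#' @return data.frame with columns `lambda`, `D`.
#' @export
turbulence_profile <- function(phases, kernels) {
  D <- vapply(kernels$lambdas, function(l) {
    amplitude_turbulence(local_kuramoto(phases, kernels, l))
  }, 0)
  data.frame(lambda = kernels$lambdas, D = D)
}

#' Information cascade flow between two consecutive scales
#'
#' Per node, the Pearson correlation over time between the local order
#' modulus at scale `lambda` shifted by `dt_steps` and the modulus at the
#' next coarser scale `lambda - delta`, averaged over nodes:
#' `F(lambda) = < corr_t( R_lambda(x, t + dt), R_{lambda-delta}(x, t) ) >_x`.
#' Nodes with zero temporal variance in either field are excluded (count
#' reported via attribute `"n_excluded"`).
#'
#' @param field_hi `"local_order_field"` at scale lambda.
#' @param field_lo `"local_order_field"` at scale lambda - delta.
#' @param dt_steps time shift in volumes (>= 1, default 1 TR).
#' @return scalar in `[-1, 1]`.
#' @export
information_cascade_flow <- function(field_hi, field_lo, dt_steps = 1) {
  stopifnot(dt_steps >= 1,
            identical(field_hi$valid_window, field_lo$valid_window))
  idx <- window_idx(field_hi)
  t_hi <- idx[(dt_steps + 1):length(idx)]
  t_lo <- idx[1:(length(idx) - dt_steps)]
  n <- nrow(field_hi$modulus)
  r <- vapply(seq_len(n), function(nd) {
    a <- field_hi$modulus[nd, t_hi]; b <- field_lo$modulus[nd, t_lo]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }, 0)
  if (all(is.na(r))) stop("all nodes have zero-variance modulus")
  out <- mean(r, na.rm = TRUE)
  attr(out, "n_excluded") <- sum(is.na(r))
  out
}

#' Information cascade flow over the full scale grid
#'
#' Computes `F(lambda)` for every scale that has a coarser predecessor on
#' the grid (the lowest lambda has none and is skipped).
#'
#' @param phases a `"phase_field"`.
#' @param kernels a `"kernel_set"`.
#' @param dt_steps time shift in volumes.
#' @return data.frame with columns `lambda`, `flow`.
#' @export
cascade_flows <- function(phases, kernels, dt_steps = 1) {
  K <- length(kernels$lambdas)
  if (K < 2) stop("cascade flow needs at least two scales")
  fields <- lapply(kernels$lambdas, function(l) local_kuramoto(phases, kernels, l))
  flow <- vapply(2:K, function(k) {
    as.numeric(information_cascade_flow(fields[[k]], fields[[k - 1]], dt_steps))
  }, 0)
  data.frame(lambda = kernels$lambdas[2:K], flow = flow)
}

#' Information cascade
#'
#' The arithmetic mean of the information cascade flow across scales.
#'
#' @param flows numeric vector of per-scale flows (or the data.frame from
#'   [cascade_flows()]).
#' @return scalar mean flow.
#' @export
information_cascade <- function(flows) {
  if (is.data.frame(flows)) flows <- flows$flow
  flows <- flows[is.finite(flows)]
  if (length(flows) == 0) stop("no valid cascade flows to average")
  mean(flows)
}

#' Spatial transfer correlation at one scale
#'
#' Correlates the local order modulus over time for every node pair, bins
#' pairs by Euclidean distance inside the inertial subrange, and fits
#' `log(mean corr) = A * log(r) + B` across bin centres. The slope `A`
#' measures how far information travels across space at this scale (steeper
#' negative slope = shorter-range transfer). Bins with non-positive mean
#' correlation are dropped (logs undefined); their count is reported.
#'
#' @param field a `"local_order_field"`.
#' @param dist node x node distance matrix, mm.
#' @param r_range inertial subrange `c(min, max)` in mm (default 8-34 mm).
#' @param n_bins equal-width distance bins inside `r_range`.
#' @return list with `A` (slope), `B` (intercept), `n_bins_used`,
#'   `n_dropped_bins`, `bin_centres`, `bin_corr`.
#' @export
transfer_correlation <- function(field, dist, r_range = c(8, 34), n_bins = 20) {
  m <- field$modulus[, window_idx(field), drop = FALSE]
  cc <- suppressWarnings(cor(t(m)))
  ut <- upper.tri(dist)
  d <- dist[ut]; r <- cc[ut]
  keep <- is.finite(r) & d >= r_range[1] & d <= r_range[2]
  d <- d[keep]; r <- r[keep]
  breaks <- seq(r_range[1], r_range[2], length.out = n_bins + 1)
  bin <- cut(d, breaks, include.lowest = TRUE, labels = FALSE)
  centres <- (head(breaks, -1) + tail(breaks, -1)) / 2
  mcor <- vapply(seq_len(n_bins), function(b) {
    if (!any(bin == b)) return(NA_real_)
    mean(r[bin == b])
  }, 0)
  usable <- which(is.finite(mcor))
  dropped <- sum(mcor[usable] <= 0)
  usable <- usable[mcor[usable] > 0]
  if (length(usable) < 3) {
    stop("fewer than 3 usable distance bins inside r_range = [",
         r_range[1], ", ", r_range[2], "] mm")
  }
  fit <- lm(log(mcor[usable]) ~ log(centres[usable]))
  list(A = unname(coef(fit)[2]), B = unname(coef(fit)[1]),
       n_bins_used = length(usable), n_dropped_bins = dropped,
       bin_centres = centres[usable], bin_corr = mcor[usable])
}

#' Node-level metastability
#'
#' Per node, the population standard deviation across time of the local
#' order modulus: the regional variability of local synchronisation.
#'
#' @param field a `"local_order_field"` with a valid window of length >= 2.
#' @return numeric vector, one value per node, each in `[0, 0.5]`.
#' @export
node_level_metastability <- function(field) {
  idx <- window_idx(field)
  if (length(idx) < 2) stop("valid window shorter than 2 volumes")
  m <- field$modulus[, idx, drop = FALSE]
  sqrt(rowMeans((m - rowMeans(m))^2))
}

#' Node-level metastability across the scale grid
#'
#' @param phases a `"phase_field"`.
#' @param kernels a `"kernel_set"`.
#' @return node x lambda matrix (columns named by lambda).
#' @export
nlm_profile <- function(phases, kernels) {
  out <- vapply(kernels$lambdas, function(l) {
    node_level_metastability(local_kuramoto(phases, kernels, l))
  }, numeric(nrow(phases$phases)))
  colnames(out) <- format(kernels$lambdas)
  out
}

#' Slope of mean turbulence across ordered states, per scale
#'
#' At each scale, fits ordinary least squares of the state-mean measure
#' against the state rank (1..S in the supplied order) and returns the
#' slope: a compact summary of how the measure evolves across brain states.
#'
#' @param mean_D state x lambda matrix of group means (rownames = states).
#' @param state_order character vector giving the state ordering.
#' @return data.frame with columns `lambda` (taken from `colnames(mean_D)`
#'   if numeric, else the column index) and `slope`.
#' @export
state_slope_profile <- function(mean_D, state_order = rownames(mean_D)) {
  stopifnot(length(state_order) >= 2, all(state_order %in% rownames(mean_D)))
  m <- mean_D[state_order, , drop = FALSE]
  if (any(!is.finite(m))) stop("missing state means at some lambda")
  rank_x <- seq_along(state_order)
  slope <- apply(m, 2, function(y) unname(coef(lm(y ~ rank_x))[2]))
  lam <- suppressWarnings(as.numeric(colnames(mean_D)))
  if (anyNA(lam)) lam <- seq_len(ncol(mean_D))
  data.frame(lambda = lam, slope = slope, row.names = NULL)
}
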