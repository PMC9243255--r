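#' Define a coupled Stuart-Landau (Hopf) whole-brain system
#'
#' Each node n follows the normal form of a supercritical Hopf bifurcation,
#' coupled diffusively through the structural connectome:
#' \deqn{dx_n/dt = (a_n - x_n^2 - y_n^2) x_n - \omega_n y_n +
#'   G \sum_p C_{np} (x_p - x_n) + \nu \eta_n(t)}
#' and the symmetric equation for y with `+omega_n x_n`. For `a_n > 0` the
#' uncoupled noiseless node settles on a limit cycle of radius `sqrt(a_n)`
#' with frequency `omega_n / (2*pi)`; for `a_n < 0` it decays to a fixed
#' point and is noise-driven.
#'
#' @param connectome a `"connectome"` or a node x node weight matrix.
#' @param a per-node bifurcation parameter (recycled); default -0.02, the
#'   subcritical regime used during fitting.
#' @param omega per-node angular frequency in rad/s (recycled).
#' @param G global coupling scalar.
#' @param noise_sd additive Gaussian noise standard deviation (nu); the
#'   discrete increment is `noise_sd * sqrt(dt) * N(0,1)` per component.
#' @param dt integration step in seconds (<= 0.1 and < tr).
#' @param tr output sampling period in seconds.
#' @return object of class `"hopf_system"`.
#' @export
hopf_system <- function(connectome, a = -0.02, omega = 2 * pi * 0.05,
                        G = 1, noise_sd = 0.01, dt = 0.1, tr = 2) {
  C <- if (inherits(connectome, "connectome")) connectome$weights else as.matrix(connectome)
  n <- nrow(C)
  stopifnot(ncol(C) == n, noise_sd >= 0, dt < tr, dt <= 0.1, G >= 0)
  a <- rep_len(a, n); omega <- rep_len(omega, n)
  structure(list(C = C, a = a, omega = omega, G = G, noise_sd = noise_sd,
                 dt = dt, tr = tr, n_nodes = n),
            class = "hopf_system")
}

#' @export
print.hopf_system <- function(x, ...) {
  cat("Hopf whole-brain system:", x$n_nodes, "nodes, G =", x$G,
      ", noise sd =", x$noise_sd, "\n")
  cat("  a in [", min(x$a), ",", max(x$a), "], f in [",
      round(min(x$omega) / (2 * pi), 4), ",",
      round(max(x$omega) / (2 * pi), 4), "] Hz\n")
  invisible(x)
}

#' Specify external periodic forcing
#'
#' Adds `F0 * cos(omega0 t)` to the x-equation and `F0 * sin(omega0 t)` to
#' the y-equation of every node (per-node amplitudes allowed).
#'
#' @param F0 forcing amplitude, scalar or per-node (>= 0).
#' @param omega0 forcing angular frequency in rad/s; conventionally the mean
#'   of the system's node frequencies.
#' @return object of class `"forcing_spec"`.
#' @export
forcing_spec <- function(F0 = 5e-4, omega0 = 2 * pi * 0.04) {
  stopifnot(all(F0 >= 0))
  structure(list(F0 = F0, omega0 = omega0, enabled = any(F0 > 0)),
            class = "forcing_spec")
}

#' Simulate the Hopf whole-brain model
#'
#' Stochastic runs use Euler-Maruyama at step `dt` with independent Gaussian
#' increments `noise_sd * sqrt(dt) * N(0,1)` on each component; noiseless
#' runs (`noise_sd == 0`) are integrated with an adaptive ODE solver
#' ([deSolve::ode()]) so closed-form properties of the deterministic system
#' (limit-cycle radius `sqrt(a)`) hold to high precision. The x component,
#' subsampled at the TR after a transient discard, is returned as the BOLD
#' proxy.
#'
#' @param system a `"hopf_system"`.
#' @param duration_volumes number of output volumes (>= 1).
#' @param seed integer seed (ignored for noiseless runs).
#' @param forcing optional `"forcing_spec"`.
#' @param transient_s transient discarded before sampling, seconds.
#' @param init optional list with `x`, `y` initial conditions; defaults to
#'   small seeded random values.
#' @param keep_xy return the full-state matrix at TR resolution as attribute.
#' @return a `"bold_ts"` (node x duration_volumes).
#' @export
simulate_hopf <- function(system, duration_volumes, seed = 1, forcing = NULL,
                          transient_s = 20, init = NULL, keep_xy = FALSE) {
  stopifnot(inherits(system, "hopf_system"), duration_volumes >= 1)
  n <- system$n_nodes
  dt <- system$dt; tr <- system$tr
  sub <- round(tr / dt)
  n_trans <- ceiling(transient_s / dt)
  n_steps <- n_trans + sub * duration_volumes
  wC <- system$G * system$C
  srow <- rowSums(wC)
  a <- system$a; om <- system$omega; nu <- system$noise_sd
  F0 <- 0; om0 <- 0
  if (!is.null(forcing) && isTRUE(forcing$enabled)) {
    F0 <- rep_len(forcing$F0, n); om0 <- forcing$omega0
  } else if (!is.null(forcing)) {
    F0 <- rep_len(forcing$F0, n); om0 <- forcing$omega0  # F0 may be all zero
  }
  set.seed(derive_seed(seed, tag = "hopf-init"))
  if (is.null(init)) {
    x <- rnorm(n, 0, 0.1); y <- rnorm(n, 0, 0.1)
  } else {
    x <- rep_len(init$x, n); y <- rep_len(init$y, n)
  }

  if (nu == 0) {
    deriv <- function(t, state, parms) {
      x <- state[1:n]; y <- state[(n + 1):(2 * n)]
      r2 <- x * x + y * y
      fx <- if (any(F0 > 0)) F0 * cos(om0 * t) else 0
      fy <- if (any(F0 > 0)) F0 * sin(om0 * t) else 0
      dx <- (a - r2) * x - om * y + drop(wC %*% x) - srow * x + fx
      dy <- (a - r2) * y + om * x + drop(wC %*% y) - srow * y + fy
      list(c(dx, dy))
    }
    times <- seq(0, n_steps * dt, by = dt)
    sol <- deSolve::ode(c(x, y), times, deriv, parms = NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-12)
    xs <- t(sol[, 2:(n + 1), drop = FALSE])
    ys <- t(sol[, (n + 2):(2 * n + 1), drop = FALSE])
    take <- n_trans + sub * seq_len(duration_volumes) + 1L  # +1: t=0 column
    out <- xs[, take, drop = FALSE]
    xy <- if (keep_xy) list(x = xs[, take, drop = FALSE],
                            y = ys[, take, drop = FALSE]) else NULL
  } else {
    set.seed(derive_seed(seed, tag = "hopf-noise"))
    out <- matrix(NA_real_, n, duration_volumes)
    xy <- if (keep_xy) list(x = out, y = out) else NULL
    sq <- nu * sqrt(dt)
    k <- 0L
    for (i in seq_len(n_steps)) {
      r2 <- x * x + y * y
      tcur <- (i - 1) * dt
      dx <- (a - r2) * x - om * y + drop(wC %*% x) - srow * x
      dy <- (a - r2) * y + om * x + drop(wC %*% y) - srow * y
      if (any(F0 > 0)) {
        dx <- dx + F0 * cos(om0 * tcur)
        dy <- dy + F0 * sin(om0 * tcur)
      }
      x <- x + dt * dx + sq * rnorm(n)
      y <- y + dt * dy + sq * rnorm(n)
      if (i > n_trans && (i - n_trans) %% sub == 0) {
        k <- k + 1L
        out[, k] <- x
        if (keep_xy) { xy$x[, k] <- x; xy$y[, k] <- y }
      }
      if (i %% 200L == 0L && (!all(is.finite(x)) || max(abs(x)) > 1e6)) {
        stop("Hopf simulation diverged at step ", i,
             " (G = ", system$G, ", max|x| = ", max(abs(x)), ")")
      }
    }
    if (!all(is.finite(out)) || max(abs(out)) > 1e6) {
      stop("Hopf simulation diverged (G = ", system$G, ")")
    }
  }
  res <- bold_ts(out, tr = tr)
  if (keep_xy) attr(res, "xy") <- xy
  res
}

#' @export
simulate.hopf_system <- function(object, nsim = 200, seed = 1, ...) {
  simulate_hopf(object, duration_volumes = nsim, seed = seed, ...)
}

#' Functional connectivity as a function of Euclidean distance
#'
#' Standardises each node's signal, computes pairwise Pearson correlations
#' over time, and averages them within distance bins. The companion
#' Kolmogorov structure function is `S(r) = 2 * (FC(0) - FC(r))` with
#' `FC(0) = 1` for standardised signals.
#'
#' @param ts a `"bold_ts"`.
#' @param dist node x node distance matrix (mm).
#' @param breaks bin edges in mm, or `NULL` to build `n_bins` equal-width
#'   bins spanning the observed distances (or `r_range` if given).
#' @param n_bins number of bins when `breaks` is `NULL`.
#' @param r_range optional `c(min, max)` restriction in mm.
#' @param min_pairs bins with fewer pairs are dropped (reported in `dropped`).
#' @return object of class `"fc_distance"`: `bin_centres`, `fc`, `s`,
#'   `counts`, `breaks`, `dropped`.
#' @export
fc_of_distance <- function(ts, dist, breaks = NULL, n_bins = 20,
                           r_range = NULL, min_pairs = 2) {
  stopifnot(inherits(ts, "bold_ts"))
  v <- ts$values
  cc <- suppressWarnings(cor(t(v)))
  ut <- upper.tri(dist)
  d <- dist[ut]; r <- cc[ut]
  ok <- is.finite(r)
  d <- d[ok]; r <- r[ok]
  if (!is.null(r_range)) {
    keep <- d >= r_range[1] & d <= r_range[2]
    d <- d[keep]; r <- r[keep]
  }
  if (is.null(breaks)) {
    rng <- if (!is.null(r_range)) r_range else range(d)
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  }
  bin <- cut(d, breaks, include.lowest = TRUE, labels = FALSE)
  counts <- tabulate(bin, nbins = length(breaks) - 1)
  centres <- (head(breaks, -1) + tail(breaks, -1)) / 2
  fc <- vapply(seq_along(centres), function(b) {
    if (counts[b] >= min_pairs) mean(r[bin == b]) else NA_real_
  }, 0)
  keep <- !is.na(fc)
  structure(list(bin_centres = centres[keep], fc = fc[keep],
                 s = 2 * (1 - fc[keep]), counts = counts[keep],
                 breaks = breaks, dropped = sum(!keep)),
            class = "fc_distance")
}

#' Fitting error between simulated and empirical FC(r)
#'
#' Euclidean norm of the difference between the two FC(r) curves restricted
#' to the inertial subrange, normalised by the square root of the number of
#' bins compared (an RMS distance).
#'
#' @param sim,emp `"fc_distance"` objects on the same bin grid.
#' @param r_range optional `c(min, max)` in mm restricting the comparison.
#' @return scalar error (>= 0).
#' @export
fc_fit_error <- function(sim, emp, r_range = NULL) {
  cs <- sim$bin_centres; ce <- emp$bin_centres
  common <- intersect(round(cs, 9), round(ce, 9))
  if (length(common) == 0) stop("FC(r) bin grids do not match")
  if (!is.null(r_range)) {
    common <- common[common >= r_range[1] & common <= r_range[2]]
    if (length(common) == 0) stop("no common bins inside r_range")
  }
  fs <- sim$fc[match(common, round(cs, 9))]
  fe <- emp$fc[match(common, round(ce, 9))]
  sqrt(mean((fs - fe)^2))
}

#' Fit the global coupling G of a Hopf whole-brain model
#'
#' Sweeps the global coupling over `g_grid`; for each value runs `n_reps`
#' simulations with distinct derived seeds, computes simulated FC(r) on the
#' empirical bin grid, and scores the mean [fc_fit_error()] against the
#' empirical curve within the inertial subrange. The optimal working point
#' `g_opt` is the grid value minimising the mean error (ties broken toward
#' smaller G).
#'
#' @param emp empirical `"fc_distance"` curve to match.
#' @param template a `"hopf_system"`; its `G` field is overridden per sweep
#'   point.
#' @param dist distance matrix used to bin simulated FC (mm).
#' @param g_grid coupling values to evaluate (ascending).
#' @param n_reps simulations per grid value.
#' @param duration_volumes length of each simulation.
#' @param r_range inertial subrange for the error, mm.
#' @param bandpass logical; filter simulated signals to `band` before FC
#'   (default TRUE, matching the treatment of empirical data).
#' @param band bandpass edges in Hz.
#' @param seed root seed; per-run seeds are derived from it.
#' @return object of class `"hopf_fit"` with the error curve, `g_opt`,
#'   per-G mean simulated FC(r) and the call; see [coef.hopf_fit()],
#'   [plot.hopf_fit()], [simulate.hopf_fit()].
#' @export
hopf_fit <- function(emp, template, dist, g_grid = seq(0, 3, by = 0.25),
                     n_reps = 5, duration_volumes = 200,
                     r_range = c(8, 34), bandpass = TRUE,
                     band = c(0.008, 0.08), seed = 1) {
  stopifnot(inherits(emp, "fc_distance"), inherits(template, "hopf_system"),
            length(g_grid) >= 1, n_reps >= 1)
  g_grid <- sort(g_grid)
  err <- numeric(length(g_grid))
  sim_fc <- matrix(NA_real_, length(g_grid), length(emp$bin_centres))
  seeds <- matrix(0L, length(g_grid), n_reps)
  for (gi in seq_along(g_grid)) {
    sys_g <- template; sys_g$G <- g_grid[gi]
    errs <- rep(NA_real_, n_reps)
    fcs <- matrix(NA_real_, n_reps, length(emp$bin_centres))
    for (rep_i in seq_len(n_reps)) {
      s <- derive_seed(seed, gi * 1000 + rep_i, "gsweep")
      seeds[gi, rep_i] <- s
      ts <- tryCatch(simulate_hopf(sys_g, duration_volumes, seed = s),
                     error = function(e) NULL)
      if (is.null(ts)) next
      if (bandpass) ts <- bandpass_bold(ts, band[1], band[2])
      fc <- fc_of_distance(ts, dist, breaks = emp$breaks, min_pairs = 1)
      m <- match(round(emp$bin_centres, 9), round(fc$bin_centres, 9))
      fcs[rep_i, ] <- fc$fc[m]
      errs[rep_i] <- fc_fit_error(fc, emp, r_range = r_range)
    }
    err[gi] <- if (all(is.na(errs))) NA_real_ else mean(errs, na.rm = TRUE)
    sim_fc[gi, ] <- colMeans(fcs, na.rm = TRUE)
  }
  if (all(is.na(err))) stop("all couplings diverged; no fit possible")
  g_opt <- g_grid[which.min(err)]  # which.min skips NA, first min = smaller G
  structure(list(g_grid = g_grid, fit_error = err, g_opt = g_opt,
                 n_reps = n_reps, seeds = seeds, sim_fc = sim_fc,
                 emp = emp, template = template, r_range = r_range,
                 bandpass = bandpass, band = band,
                 duration_volumes = duration_volumes,
                 call = match.call()),
            class = "hopf_fit")
}

#' @export
print.hopf_fit <- function(x, ...) {
  cat("Hopf whole-brain coupling fit\n")
  cat("  G grid: [", min(x$g_grid), ",", max(x$g_grid), "] (",
      length(x$g_grid), " values), ", x$n_reps, " reps each\n", sep = "")
  cat("  optimal coupling g_opt =", x$g_opt,
      "(fit error", signif(min(x$fit_error, na.rm = TRUE), 4), ")\n")
  invisible(x)
}

#' @export
summary.hopf_fit <- function(object, ...) {
  out <- list(g_opt = object$g_opt,
              min_error = min(object$fit_error, na.rm = TRUE),
              curve = data.frame(G = object$g_grid, error = object$fit_error),
              n_reps = object$n_reps, r_range = object$r_range)
  class(out) <- "summary.hopf_fit"
  out
}

#' @export
print.summary.hopf_fit <- function(x, ...) {
  cat("Hopf coupling fit: g_opt =", x$g_opt, " (RMS FC(r) error",
      signif(x$min_error, 4), "in", x$r_range[1], "-", x$r_range[2], "mm)\n")
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' @describeIn hopf_fit optimal coupling as a named coefficient.
#' @param object,... method arguments.
#' @export
coef.hopf_fit <- function(object, ...) c(G = object$g_opt)

#' @export
plot.hopf_fit <- function(x, ...) {
  plot(x$g_grid, x$fit_error, type = "b", pch = 16,
       xlab = "global coupling G", ylab = "FC(r) fit error (RMS)", ...)
  abline(v = x$g_opt, lty = 2)
  invisible(x)
}

#' @export
predict.hopf_fit <- function(object, G = object$g_opt, ...) {
  gi <- which.min(abs(object$g_grid - G))
  data.frame(r = object$emp$bin_centres, fc = object$sim_fc[gi, ])
}

#' @export
residuals.hopf_fit <- function(object, ...) {
  gi <- which.min(abs(object$g_grid - object$g_opt))
  object$sim_fc[gi, ] - object$emp$fc
}

#' @export
fitted.hopf_fit <- function(object, ...) {
  gi <- which.min(abs(object$g_grid - object$g_opt))
  object$sim_fc[gi, ]
}

#' @export
simulate.hopf_fit <- function(object, nsim = NULL, seed = 1, ...) {
  sys <- object$template
  sys$G <- object$g_opt
  simulate_hopf(sys, duration_volumes = nsim %||% object$duration_volumes,
                seed = seed, ...)
}

#' Extract the fitted system at the optimal coupling
#'
#' @param fit a `"hopf_fit"`.
#' @return the template `"hopf_system"` with `G = g_opt`.
#' @export
fitted_system <- function(fit) {
  stopifnot(inherits(fit, "hopf_fit"))
  sys <- fit$template
  sys$G <- fit$g_opt
  sys
}
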