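# Small in-code fixtures shared across test files.

# A parcellation from explicit coordinates (mm).
geom_from_coords <- function(coords, networks = NULL) {
  ids <- sprintf("n%03d", seq_len(nrow(coords)))
  rownames(coords) <- ids
  colnames(coords) <- c("x", "y", "z")
  structure(list(node_ids = ids, coords = coords,
                 network = factor(networks %||% rep("net1", nrow(coords)))),
            class = "parcellation")
}

# A phase field built directly from a phase matrix (full valid window).
phase_field_from <- function(phases, tr = 2, window = NULL) {
  structure(list(phases = phases,
                 valid_window = window %||% c(1L, ncol(phases)),
                 flagged_nodes = integer(0), tr = tr, geometry = NULL),
            class = "phase_field")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent analytic-signal oracle: direct frequency-domain construction
# written against the textbook definition (kept separate from the package's
# implementation on purpose).
analytic_oracle <- function(x) {
  n <- length(x)
  X <- fft(x)
  keep <- rep(0 + 0i, n)
  keep[1] <- X[1]
  pos <- 2:ceiling(n / 2)
  keep[pos] <- 2 * X[pos]
  if (n %% 2 == 0) keep[n / 2 + 1] <- X[n / 2 + 1]
  fft(keep, inverse = TRUE) / n
}

# A 1-node uncoupled Hopf system.
single_node_system <- function(a, f_hz = 0.05, noise_sd = 0, tr = 2) {
  hopf_system(matrix(0, 1, 1), a = a, omega = 2 * pi * f_hz, G = 0,
              noise_sd = noise_sd, tr = tr)
}

# Default 100-node study system used by the model-based tests.
study_system <- function(G, n = 100, seed_geom = 1, seed_freq = 11) {
  geom <- generate_parcellation(n, seed = seed_geom)
  d <- pairwise_distances(geom)
  conn <- build_connectome(d, lambda_c = 0.18)
  set.seed(seed_freq)
  f_n <- runif(n, 0.01, 0.07)
  list(geom = geom, dist = d,
       system = hopf_system(conn, a = -0.02, omega = 2 * pi * f_n, G = G,
                            noise_sd = 0.01, tr = 2))
}

# A modulus field over isolated node pairs whose within-pair time
# correlations equal c_amp * r^exponent exactly at the bin centres of a
# 13-bin grid over (8, 34) mm. Pairs are separated by >> 34 mm so no
# cross-pair distance lands in the fitting range.
exact_powerlaw_field <- function(c_amp = 0.8, exponent = -0.5, nt = 50) {
  centres <- seq(9, 33, by = 2)            # 13 bin centres, width-2 bins
  set.seed(99)
  u <- rnorm(nt); u <- u - mean(u); u <- u / sqrt(sum(u^2))
  v <- rnorm(nt); v <- v - mean(v); v <- v - sum(u * v) * u
  v <- v / sqrt(sum(v^2))
  coords <- NULL; mods <- NULL
  for (k in seq_along(centres)) {
    base <- c(1000 * k, 0, 0)              # clusters 1000 mm apart
    coords <- rbind(coords, base, base + c(centres[k], 0, 0))
    rho <- c_amp * centres[k]^exponent
    a <- 0.5 + 0.1 * u
    b <- 0.5 + 0.1 * (rho * u + sqrt(1 - rho^2) * v)
    mods <- rbind(mods, a, b)
  }
  dist <- pairwise_distances(geom_from_coords(coords))
  field <- structure(list(modulus = mods, phase = mods * 0, lam = 0.12,
                          valid_window = c(1L, nt)),
                     class = "local_order_field")
  list(field = field, dist = dist, centres = centres)
}
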