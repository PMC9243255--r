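test_that("kernel weights follow the exponential closed form", {
  d <- rbind(c(0, 100), c(100, 0))
  ker <- build_kernels(d, c(0.01, 0.3))
  expect_equal(ker$weights[[1]][1, 2], exp(-1), tolerance = 1e-12)
  expect_true(all(diag(ker$weights[[1]]) == 1))
  d3 <- rbind(c(0, 3), c(3, 0))
  k3 <- build_kernels(d3, 0.3)
  expect_equal(k3$weights[[1]][1, 2], exp(-0.9), tolerance = 1e-12)
  # element-wise oracle on a random distance matrix
  set.seed(3)
  coords <- matrix(rnorm(30 * 3, sd = 25), ncol = 3)
  dm <- pairwise_distances(geom_from_coords(coords))
  kk <- build_kernels(dm, c(0.05, 0.12))
  for (li in 1:2) {
    lam <- kk$lambdas[li]
    brute <- matrix(0, 30, 30)
    for (i in 1:30) for (j in 1:30) brute[i, j] <- exp(-lam * dm[i, j])
    expect_equal(unname(kk$weights[[li]]), brute, tolerance = 1e-14)
    expect_equal(kk$norms[[li]], rowSums(kk$weights[[li]]))
  }
})

test_that("default lambda grid has 11 scales including the reference scales", {
  g <- default_lambda_grid()
  expect_length(g, 11)
  expect_true(all(c(0.01, 0.12, 0.30) %in% g))
  expect_true(all(abs(diff(g)[-1] - 0.03) < 1e-12))
})

test_that("local order parameter: synchrony, antiphase and oracle", {
  # full synchrony: modulus 1 everywhere at every scale
  set.seed(4)
  coords <- matrix(rnorm(12 * 3, sd = 25), ncol = 3)
  dm <- pairwise_distances(geom_from_coords(coords))
  ker <- build_kernels(dm, default_lambda_grid())
  pf_sync <- phase_field_from(matrix(0.7, 12, 20))
  for (lam in ker$lambdas) {
    f <- local_kuramoto(pf_sync, ker, lam)
    expect_true(all(abs(f$modulus - 1) < 1e-12))
    expect_lt(amplitude_turbulence(f), 1e-12)
    expect_true(all(node_level_metastability(f) < 1e-12))
  }
  # two antiphase nodes at distance r: closed form (1-e^-lr)/(1+e^-lr)
  d2 <- rbind(c(0, 10), c(10, 0))
  k2 <- build_kernels(d2, c(0.12, 0.3))
  pf2 <- phase_field_from(rbind(rep(0, 15), rep(pi, 15)))
  for (lam in c(0.12, 0.3)) {
    f2 <- local_kuramoto(pf2, k2, lam)
    e <- exp(-lam * 10)
    expect_equal(unname(f2$modulus[, 1]), rep((1 - e) / (1 + e), 2),
                 tolerance = 1e-12)
  }
  # brute-force double-loop oracle, random phases
  set.seed(6)
  n <- 40; nt <- 15
  coords <- matrix(rnorm(n * 3, sd = 30), ncol = 3)
  dm <- pairwise_distances(geom_from_coords(coords))
  kern <- build_kernels(dm, 0.3)
  ph <- matrix(runif(n * nt, -pi, pi), n, nt)
  f <- local_kuramoto(phase_field_from(ph), kern, 0.3)
  for (nn in seq_len(n)) {
    for (t in c(1, 8, 15)) {
      z <- 0 + 0i; norm <- 0
      for (p in seq_len(n)) {
        w <- exp(-0.3 * dm[nn, p])
        z <- z + w * exp(1i * ph[p, t]); norm <- norm + w
      }
      z <- z / norm
      expect_equal(f$modulus[nn, t], Mod(z), tolerance = 1e-12)
      expect_equal(f$phase[nn, t], Arg(z), tolerance = 1e-12)
    }
  }
})

test_that("modulus is bounded in [0,1] for arbitrary phases (property)", {
  set.seed(7)
  coords <- matrix(rnorm(25 * 3, sd = 30), ncol = 3)
  ker <- build_kernels(pairwise_distances(geom_from_coords(coords)),
                       default_lambda_grid())
  for (rep_i in 1:10) {
    ph <- matrix(runif(25 * 10, -pi, pi), 25, 10)
    lam <- sample(ker$lambdas, 1)
    f <- local_kuramoto(phase_field_from(ph), ker, lam)
    expect_true(all(f$modulus >= 0 & f$modulus <= 1))
  }
})

test_that("kernel limit: at very large lambda the modulus approaches 1", {
  # well-separated nodes: the kernel collapses onto the self-node
  coords <- 50 * as.matrix(expand.grid(0:1, 0:1, 0:1))
  ker <- build_kernels(pairwise_distances(geom_from_coords(coords)), 50)
  set.seed(8)
  ph <- matrix(runif(8 * 10, -pi, pi), 8, 10)
  f <- local_kuramoto(phase_field_from(ph), ker, 50)
  expect_true(all(abs(f$modulus - 1) < 1e-3))
})

test_that("amplitude turbulence: degenerate and exact cases", {
  f <- structure(list(modulus = matrix(c(0, 1), 4, 10),
                      phase = matrix(0, 4, 10), lam = 0.1,
                      valid_window = c(1L, 10L)),
                 class = "local_order_field")
  expect_equal(amplitude_turbulence(f), 0.5)  # Bernoulli(1/2) std
  set.seed(9)
  m <- matrix(runif(60), 6, 10)
  fr <- structure(list(modulus = m, phase = m * 0, lam = 0.1,
                       valid_window = c(1L, 10L)),
                  class = "local_order_field")
  expect_equal(amplitude_turbulence(fr),
               sqrt(mean(m^2) - mean(m)^2), tolerance = 1e-14)
  expect_equal(node_level_metastability(fr),
               apply(m, 1, function(x) sqrt(mean(x^2) - mean(x)^2)),
               tolerance = 1e-14)
  f1 <- fr; f1$valid_window <- c(1L, 1L)
  expect_error(node_level_metastability(f1), "window")
})

test_that("turbulence profile separates synchronised from noise subjects", {
  geom <- generate_parcellation(30, seed = 10)
  ker <- build_kernels(pairwise_distances(geom), default_lambda_grid())
  prof_of <- function(regime, params) {
    ts <- generate_bold(geom, regime, params, duration_volumes = 150, seed = 2)
    ph <- extract_phases(bandpass_bold(ts))
    turbulence_profile(ph, ker)
  }
  sync <- prof_of("global_sync", list(noise_sd = 1e-4))
  noise <- prof_of("independent_noise", list())
  expect_equal(nrow(sync), 11)
  expect_true(all(sync$D < 0.05))
  expect_true(all(noise$D > sync$D))
})

test_that("cascade flow recovers lag-1 autocorrelation of a shared field", {
  set.seed(11)
  n <- 20; nt <- 500; rho <- 0.6
  m <- matrix(0, n, nt)
  m[, 1] <- rnorm(n)
  for (t in 2:nt) m[, t] <- rho * m[, t - 1] + sqrt(1 - rho^2) * rnorm(n)
  m <- 0.5 + 0.2 * m  # keep inside [0,1]-ish range; correlation unaffected
  mk <- function(mod) structure(list(modulus = mod, phase = mod * 0,
                                     lam = 0.1, valid_window = c(1L, nt)),
                                class = "local_order_field")
  fl <- information_cascade_flow(mk(m), mk(m), dt_steps = 1)
  expect_equal(as.numeric(fl), rho, tolerance = 3 / sqrt(nt))
  # independent white noise: near-zero flow
  a <- mk(matrix(runif(n * nt), n, nt)); b <- mk(matrix(runif(n * nt), n, nt))
  expect_lt(abs(as.numeric(information_cascade_flow(a, b))), 3 / sqrt(nt))
  expect_true(abs(as.numeric(fl)) <= 1)
  # degenerate: all nodes constant
  cf <- mk(matrix(0.5, n, nt))
  expect_error(information_cascade_flow(cf, cf), "zero-variance")
})

test_that("information cascade is the plain average of flows", {
  expect_equal(information_cascade(c(0.2, 0.4)), 0.3)
  expect_equal(information_cascade(rep(0.7, 5)), 0.7)
  expect_equal(information_cascade(c(0.4, 0.2)), 0.3)  # order-invariant
  expect_error(information_cascade(numeric(0)), "no valid")
})

test_that("transfer correlation recovers an exact power law", {
  # 13 isolated node pairs, one per distance bin centre; within each pair
  # the time correlation of the modulus is set exactly to c * r^(-1/2), so
  # every bin mean sits exactly on the power law.
  cpl <- exact_powerlaw_field(c_amp = 0.8, exponent = -0.5)
  tc <- transfer_correlation(cpl$field, cpl$dist, r_range = c(8, 34),
                             n_bins = 13)
  expect_equal(tc$n_bins_used, 13)
  expect_equal(tc$A, -0.5, tolerance = 1e-6)
  expect_equal(tc$B, log(0.8), tolerance = 1e-6)
})

test_that("transfer correlation on fields: flat input gives zero slope", {
  # two groups of perfectly correlated node series -> all pair correlations 1
  set.seed(13)
  n <- 30; nt <- 60
  coords <- matrix(runif(n * 3, 0, 40), ncol = 3)
  dm <- pairwise_distances(geom_from_coords(coords))
  base <- runif(nt)
  m <- matrix(rep(base, each = n), n, nt) +
    matrix(rep(runif(n, 0, 0.1), nt), n, nt)  # node offsets keep corr = 1
  f <- structure(list(modulus = m, phase = m * 0, lam = 0.1,
                      valid_window = c(1L, nt)),
                 class = "local_order_field")
  tc <- transfer_correlation(f, dm, r_range = c(5, 60), n_bins = 10)
  expect_equal(tc$A, 0, tolerance = 1e-9)
  expect_equal(tc$B, 0, tolerance = 1e-9)  # log(1)
  expect_error(transfer_correlation(f, dm, r_range = c(0.0, 0.1)), "r_range")
})

test_that("simulated turbulent fields show decaying spatial correlation", {
  st <- study_system(G = 1.5, n = 60)
  ts <- simulate_hopf(st$system, 200, seed = 3)
  ph <- extract_phases(bandpass_bold(ts))
  ker <- build_kernels(st$dist, 0.12)
  f <- local_kuramoto(ph, ker, 0.12)
  tc <- transfer_correlation(f, st$dist, r_range = c(8, 34))
  expect_lt(tc$A, 0)
})

test_that("state slope profiles follow closed-form OLS", {
  m <- rbind(s1 = c(1, 3), s2 = c(2, 1), s3 = c(3, 2))
  colnames(m) <- c("0.01", "0.12")
  sl <- state_slope_profile(m, c("s1", "s2", "s3"))
  expect_equal(sl$slope[1], 1)      # exact line 1,2,3
  expect_equal(sl$slope[2], -0.5)   # OLS of {3,1,2} on {1,2,3}
  two <- state_slope_profile(m[1:2, ], c("s1", "s2"))
  expect_equal(two$slope, as.numeric(m["s2", ] - m["s1", ]))
  m_bad <- m; m_bad[2, 1] <- NA
  expect_error(state_slope_profile(m_bad, rownames(m_bad)), "missing")
})
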