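test_that("uncoupled noiseless node settles on the sqrt(a) limit cycle", {
  sys <- single_node_system(a = 0.25)
  ts <- simulate_hopf(sys, 30, transient_s = 60, keep_xy = TRUE,
                      init = list(x = 0.3, y = 0))
  xy <- attr(ts, "xy")
  radius <- sqrt(xy$x^2 + xy$y^2)
  expect_true(all(abs(radius - 0.5) < 1e-6))
})

test_that("noiseless subcritical node decays to the fixed point", {
  sys <- single_node_system(a = -0.1)
  ts <- simulate_hopf(sys, 64, transient_s = 0, keep_xy = TRUE,
                      init = list(x = 0.3, y = 0))
  xy <- attr(ts, "xy")
  radius <- as.vector(sqrt(xy$x^2 + xy$y^2))
  expect_lt(radius[length(radius)], 1e-3)
  expect_true(all(diff(radius) <= 1e-12))
})

test_that("stochastic runs are seed-deterministic", {
  st <- study_system(G = 1, n = 20)
  a <- simulate_hopf(st$system, 80, seed = 5)
  b <- simulate_hopf(st$system, 80, seed = 5)
  expect_identical(a$values, b$values)
  c <- simulate_hopf(st$system, 80, seed = 6)
  expect_false(identical(a$values, c$values))
})

test_that("stationary variance grows with the noise level", {
  sys0 <- single_node_system(a = -0.02, noise_sd = 0)
  vars <- sapply(c(0.005, 0.01, 0.02), function(nu) {
    sys <- sys0; sys$noise_sd <- nu
    mean(sapply(1:5, function(s) var(simulate_hopf(sys, 150, seed = s)$values[1, ])))
  })
  expect_true(all(diff(vars) > 0))
})

test_that("validation rejects inconsistent systems", {
  expect_error(hopf_system(matrix(0, 2, 2), a = -0.02, omega = 1, G = 1,
                           noise_sd = 0.01, dt = 3, tr = 2), "dt")
  expect_error(hopf_system(matrix(0, 2, 3)), "ncol")
})

test_that("FC(r): perfect correlation, null data, and brute-force oracle", {
  set.seed(20)
  coords <- matrix(runif(20 * 3, 0, 60), ncol = 3)
  d <- pairwise_distances(geom_from_coords(coords))
  tt <- (0:199) * 2
  shared <- sin(2 * pi * 0.03 * tt)
  ident <- bold_ts(matrix(rep(shared, each = 20), 20, 200) * runif(20, 0.5, 2),
                   tr = 2)
  fc1 <- fc_of_distance(ident, d, n_bins = 8)
  expect_true(all(abs(fc1$fc - 1) < 1e-12))
  expect_true(all(abs(fc1$s) < 1e-12))
  # independent noise: correlations near zero in every bin
  noise <- bold_ts(matrix(rnorm(20 * 500), 20, 500), tr = 2)
  fc0 <- fc_of_distance(noise, d, n_bins = 5)
  expect_true(all(abs(fc0$fc) < 3 / sqrt(500)))
  # oracle: bin means equal a direct double-loop per-pair computation
  set.seed(21)
  v <- matrix(rnorm(20 * 100), 20, 100)
  fc <- fc_of_distance(bold_ts(v, tr = 2), d, n_bins = 6)
  width <- diff(fc$breaks)[1]
  for (b in seq_along(fc$bin_centres)) {
    lo <- fc$bin_centres[b] - width / 2; hi <- fc$bin_centres[b] + width / 2
    acc <- c()
    for (i in 1:19) for (j in (i + 1):20) {
      inside <- d[i, j] > lo && d[i, j] <= hi
      if (b == 1) inside <- inside || d[i, j] == lo
      if (inside) acc <- c(acc, cor(v[i, ], v[j, ]))
    }
    expect_equal(fc$fc[b], mean(acc), tolerance = 1e-9)
    expect_equal(fc$counts[b], length(acc))
  }
})

test_that("fit error: identity, constant offset, and random oracle", {
  mk <- function(fc) structure(list(bin_centres = seq(5, 50, by = 5),
                                    fc = fc, s = 2 * (1 - fc),
                                    counts = rep(10, 10),
                                    breaks = seq(2.5, 52.5, by = 5),
                                    dropped = 0),
                               class = "fc_distance")
  a <- mk(seq(0.9, 0.1, length.out = 10))
  expect_equal(fc_fit_error(a, a), 0)
  b <- mk(a$fc + 0.07)
  expect_equal(fc_fit_error(b, a), 0.07, tolerance = 1e-12)
  set.seed(22)
  x <- mk(runif(10)); y <- mk(runif(10))
  expect_equal(fc_fit_error(x, y), sqrt(mean((x$fc - y$fc)^2)),
               tolerance = 1e-12)
  expect_equal(fc_fit_error(x, y, r_range = c(8, 34)),
               sqrt(mean((x$fc - y$fc)[2:6]^2)), tolerance = 1e-12)
  z <- mk(runif(10)); z$bin_centres <- z$bin_centres + 100
  expect_error(fc_fit_error(x, z), "match")
})

test_that("self-fit at G = 0 recovers zero coupling", {
  st <- study_system(G = 0, n = 30)
  ts <- simulate_hopf(st$system, 150, seed = 9)
  tsf <- bandpass_bold(ts)
  emp <- fc_of_distance(tsf, st$dist, n_bins = 12, min_pairs = 1)
  fit <- hopf_fit(emp, st$system, st$dist, g_grid = c(0, 0.5, 1),
                  n_reps = 2, duration_volumes = 100, seed = 3)
  expect_equal(unname(coef(fit)), 0)
  expect_length(fit$fit_error, 3)
  expect_s3_class(fit, "hopf_fit")
  # methods behave
  expect_output(print(fit), "g_opt")
  expect_equal(summary(fit)$g_opt, 0)
  expect_equal(nrow(predict(fit)), length(emp$bin_centres))
  expect_length(residuals(fit), length(emp$bin_centres))
  sim <- simulate(fit, nsim = 64, seed = 1)
  expect_s3_class(sim, "bold_ts")
  expect_equal(fitted_system(fit)$G, 0)
})

test_that("coupling increases simulated coherence on the same connectome", {
  st <- study_system(G = 0, n = 30)
  mean_fc <- function(G) {
    sys <- st$system; sys$G <- G
    mean(sapply(1:3, function(s) {
      cc <- cor(t(simulate_hopf(sys, 120, seed = s)$values))
      mean(cc[upper.tri(cc)])
    }))
  }
  expect_gt(mean_fc(2), mean_fc(0))
})
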