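test_that("rank-sum test matches exhaustive enumeration on small samples", {
  # A = {1,2,3} vs B = {4,5,6}: A's ranks are minimal; under exchangeability
  # the probability of a rank-sum this extreme (either tail) is 2/choose(6,3)
  res <- wilcoxon_ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p.value, 2 / choose(6, 3))
  # full enumeration oracle for an arbitrary small case
  a <- c(1.2, 3.4, 0.2); b <- c(2.2, 5.1, 4.4)
  obs <- sum(rank(c(a, b))[1:3])
  all_sums <- apply(combn(6, 3), 2, function(ix) sum(rank(c(a, b))[ix]))
  centre <- mean(all_sums)
  p_exact <- mean(abs(all_sums - centre) >= abs(obs - centre))
  expect_equal(wilcoxon_ranksum(a, b)$p.value, p_exact)
})

test_that("rank-sum test is symmetric and degenerate-safe", {
  set.seed(40)
  a <- rnorm(8); b <- rnorm(9) + 0.5
  expect_equal(wilcoxon_ranksum(a, b)$p.value,
               wilcoxon_ranksum(b, a)$p.value)
  expect_equal(wilcoxon_ranksum(rep(2, 5), rep(2, 6))$p.value, 1)
  expect_equal(wilcoxon_ranksum(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
})

test_that("rank-sum type-I error is calibrated at the nominal level", {
  set.seed(41)
  rej <- mean(replicate(1000, {
    wilcoxon_ranksum(rnorm(10), rnorm(10))$p.value < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("BH correction equals hand-computed and brute-force step-up", {
  res <- fdr_correct(c(0.01, 0.02, 0.03, 0.5), q = 0.05)
  expect_equal(sort(res$rejected), 1:3)
  expect_equal(res$adjusted, c(0.04, 0.04, 0.04, 0.5))
  expect_equal(fdr_correct(rep(1, 6))$rejected, integer(0))
  one <- fdr_correct(0.04)
  expect_equal(one$adjusted, 0.04); expect_equal(one$rejected, 1L)
  expect_length(fdr_correct(numeric(0))$adjusted, 0)
  # brute-force step-up oracle on random p-lists
  set.seed(42)
  for (rep_i in 1:20) {
    p <- runif(sample(3:20, 1))^2
    q <- 0.05
    res <- fdr_correct(p, q)
    m <- length(p); s <- sort(p)
    kmax <- suppressWarnings(max(which(s <= (seq_len(m) / m) * q)))
    brute <- if (is.finite(kmax)) which(p <= s[kmax]) else integer(0)
    expect_equal(sort(res$rejected), sort(brute))
  }
})

test_that("KS distance: trivial cases, metric properties, ks.test agreement", {
  expect_equal(ks_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_distance(c(0, 1), c(10, 11)), 1)
  expect_equal(ks_distance(c(1, 2, 3, 4), c(3, 4, 5, 6)), 0.5)
  set.seed(43)
  for (rep_i in 1:10) {
    a <- rnorm(sample(5:30, 1)); b <- rnorm(sample(5:30, 1), mean = 1)
    d_ab <- ks_distance(a, b)
    expect_equal(d_ab, ks_distance(b, a))
    expect_gte(d_ab, 0); expect_lte(d_ab, 1)
    expect_equal(d_ab, unname(ks.test(a, b)$statistic), tolerance = 1e-12)
  }
  kc <- ks_compare(rnorm(20), rnorm(20, 3))
  expect_lt(kc$p.value, 0.01)
})

test_that("top-quantile node selection finds planted differences", {
  a <- rep(0, 100); b <- rep(0, 100)
  b[11:20] <- 1  # planted signal at 10 nodes
  sel <- top_quantile_nodes(a, b, q = 0.15)
  expect_equal(sort(sel$nodes), 11:20)  # exactly the planted nodes
  # with distinct values, exactly 15 of 100 nodes are selected
  set.seed(44)
  d2 <- top_quantile_nodes(runif(100), runif(100), q = 0.15)
  expect_length(d2$nodes, 15)
  expect_false(d2$tied)
  # degenerate all-equal differences: everything ties
  d3 <- top_quantile_nodes(rep(1, 10), rep(0, 10), q = 0.15)
  expect_length(d3$nodes, 10)
  expect_true(d3$tied)
  # network tallies
  nets <- rep(c("x", "y"), each = 50)
  d4 <- top_quantile_nodes(a, b, q = 0.15, networks = nets)
  expect_equal(unname(d4$network_counts["x"]), sum(d4$nodes <= 50))
})

test_that("report assembles one BH family per measure and state pair", {
  set.seed(45)
  lambdas <- default_lambda_grid()
  subj <- expand.grid(subject_id = sprintf("s%02d", 1:10),
                      lambda = lambdas)
  subj$state <- ifelse(as.integer(sub("s", "", subj$subject_id)) <= 5,
                       "A", "B")
  subj$D <- runif(nrow(subj), 0.1, 0.2) +
    ifelse(subj$state == "A", 0.3, 0)   # strong separation
  rep1 <- build_report(subj[, c("subject_id", "state", "lambda", "D")])
  expect_equal(nrow(rep1$tests), 11)     # 2 states, 11 lambdas, 1 measure
  expect_true(all(rep1$tests$significant))
  expect_true(all(rep1$tests$stars != ""))
  # determinism: regenerating from the same table gives the same report
  rep2 <- build_report(subj[, c("subject_id", "state", "lambda", "D")])
  expect_identical(rep1$tests, rep2$tests)
})

test_that("null cohorts rarely produce significant flags after FDR", {
  set.seed(46)
  lambdas <- default_lambda_grid()
  n_reps <- 50
  n_any <- 0
  for (rep_i in seq_len(n_reps)) {
    subj <- expand.grid(subject_id = sprintf("s%02d", 1:20),
                        lambda = lambdas)
    subj$state <- ifelse(as.integer(sub("s", "", subj$subject_id)) <= 10,
                         "A", "B")
    subj$D <- rnorm(nrow(subj))  # no true group difference
    rep0 <- build_report(subj[, c("subject_id", "state", "lambda", "D")])
    n_any <- n_any + any(rep0$tests$significant)
  }
  # under the null, a family rejects anything with probability <= ~q
  expect_lte(n_any / n_reps, 0.1)
})

test_that("report carries KSD per scale and top-node attribution", {
  set.seed(47)
  lambdas <- c(0.01, 0.12)
  subj <- expand.grid(subject_id = sprintf("s%02d", 1:8), lambda = lambdas)
  subj$state <- ifelse(as.integer(sub("s", "", subj$subject_id)) <= 4,
                       "A", "B")
  subj$D <- runif(nrow(subj))
  nlm <- list(A = matrix(runif(40 * 2), 40, 2),
              B = matrix(runif(40 * 2, 0.5, 1.5), 40, 2))
  rp <- build_report(subj[, c("subject_id", "state", "lambda", "D")],
                     nlm = nlm, lambda_attr = 0.12,
                     networks = rep(c("u", "v"), 20))
  expect_equal(nrow(rp$ksd), 2)
  expect_true(all(rp$ksd$ksd >= 0 & rp$ksd$ksd <= 1))
  expect_length(rp$top_nodes, 1)
  expect_equal(rp$top_nodes[[1]]$pair, c("A", "B"))
  expect_length(rp$top_nodes[[1]]$nodes, 6)  # 15% of 40
})
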