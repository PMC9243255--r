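#' Wilcoxon rank-sum test between two groups
#'
#' Two-sided rank-sum (Mann-Whitney) test. Exact enumeration is used for
#' combined sample sizes up to 12 without ties; otherwise the tie-corrected
#' normal approximation with continuity correction. Degenerate input where
#' every value is identical across both groups returns p = 1.
#'
#' @param a,b numeric vectors (each length >= 2).
#' @return list with `statistic` (Mann-Whitney W for the first group) and
#'   `p.value`.
#' @export
wilcoxon_ranksum <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2, all(is.finite(c(a, b))))
  if (length(unique(c(a, b))) == 1) {
    return(list(statistic = length(a) * length(b) / 2, p.value = 1))
  }
  exact <- (length(a) + length(b) <= 12) && !anyDuplicated(c(a, b))
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = min(wt$p.value, 1))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjustment; a hypothesis is rejected when its adjusted p-value
#' is at most `q`.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return list with `adjusted` (same length/order as input) and `rejected`
#'   (integer indices).
#' @export
fdr_correct <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) return(list(adjusted = numeric(0), rejected = integer(0)))
  stopifnot(all(pvals >= 0 & pvals <= 1))
  adj <- p.adjust(pvals, method = "BH")
  list(adjusted = adj, rejected = which(adj <= q))
}

#' Kolmogorov-Smirnov distance between two samples
#'
#' The maximal absolute difference between the two empirical cumulative
#' distribution functions (the two-sample KS statistic), in `[0, 1]`.
#'
#' @param values_a,values_b numeric samples (each length >= 1).
#' @return scalar KSD.
#' @export
ks_distance <- function(values_a, values_b) {
  stopifnot(length(values_a) >= 1, length(values_b) >= 1)
  pts <- sort(unique(c(values_a, values_b)))
  max(abs(ecdf(values_a)(pts) - ecdf(values_b)(pts)))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Distance plus the asymptotic p-value from [stats::ks.test()].
#'
#' @param values_a,values_b numeric samples.
#' @return list with `ksd` and `p.value`.
#' @export
ks_compare <- function(values_a, values_b) {
  kt <- suppressWarnings(ks.test(values_a, values_b))
  list(ksd = unname(kt$statistic), p.value = kt$p.value)
}

#' Nodes in the top quantile of absolute between-state differences
#'
#' Ranks nodes by `|mean_a - mean_b|` and returns those at or above the
#' `(1 - q)` quantile, optionally tallied by network label — the procedure
#' used to attribute state differences in node-level metastability to
#' resting-state networks.
#'
#' @param nlm_a,nlm_b per-node group means (matching node order).
#' @param q top fraction to select (0 < q < 1; default 0.15).
#' @param networks optional per-node labels (factor/character).
#' @return list with `nodes` (indices), `abs_diff`, `threshold`, `tied`
#'   (TRUE when ties at the threshold inflate the selection), and
#'   `network_counts` when `networks` is supplied.
#' @export
top_quantile_nodes <- function(nlm_a, nlm_b, q = 0.15, networks = NULL) {
  stopifnot(length(nlm_a) == length(nlm_b), q > 0, q < 1)
  d <- abs(nlm_a - nlm_b)
  thr <- quantile(d, 1 - q, names = FALSE, type = 1)
  sel <- which(d > thr)
  tied <- FALSE
  if (length(sel) == 0) {          # degenerate: everything ties at the cut
    sel <- which(d == thr)
    tied <- TRUE
  } else if (length(sel) != round(q * length(d))) {
    tied <- TRUE                   # ties at the threshold shift the count
  }
  out <- list(nodes = sel, abs_diff = d, threshold = thr, tied = tied)
  if (!is.null(networks)) {
    out$network_counts <- table(factor(networks)[sel])
  }
  out
}

sig_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Group-comparison report across states, measures and scales
#'
#' For every pair of states and every scale, runs two-sided Wilcoxon
#' rank-sum tests on each per-subject measure, applies Benjamini-Hochberg
#' FDR across the scale grid within each (measure, state pair) family (or
#' across all measures pooled when `family = "pooled"`), and, when
#' node-level metastability tables are provided, computes the
#' Kolmogorov-Smirnov distance between the pooled node-value distributions
#' per scale and the top-quantile node attribution at `lambda_attr`.
#'
#' @param measures data.frame with columns `subject_id`, `state`, `lambda`
#'   and one column per scalar measure (e.g. `D`, `A`).
#' @param nlm optional list per state of node x lambda x subject arrays (or
#'   node x lambda matrices of subject means) for the KSD/attribution step.
#' @param q FDR level.
#' @param family `"per_measure"` (default) or `"pooled"`.
#' @param lambda_attr scale at which the top-node attribution is computed.
#' @param top_q top fraction for node attribution.
#' @param networks optional per-node network labels.
#' @return object of class `"state_comparison"`: `tests` (data.frame with
#'   statistic, p_raw, p_fdr, significant, stars), `ksd` (data.frame or
#'   NULL), `top_nodes` (list or NULL), `q`.
#' @export
build_report <- function(measures, nlm = NULL, q = 0.05,
                         family = c("per_measure", "pooled"),
                         lambda_attr = 0.12, top_q = 0.15, networks = NULL) {
  family <- match.arg(family)
  states <- unique(measures$state)
  if (length(states) < 2) stop("need >= 2 states to compare")
  meas_cols <- setdiff(names(measures), c("subject_id", "state", "lambda"))
  lambdas <- sort(unique(measures$lambda))
  pairs <- utils::combn(states, 2, simplify = FALSE)

  rows <- list()
  for (pr in pairs) {
    for (mc in meas_cols) {
      for (lam in lambdas) {
        va <- measures[measures$state == pr[1] & measures$lambda == lam, mc]
        vb <- measures[measures$state == pr[2] & measures$lambda == lam, mc]
        va <- va[is.finite(va)]; vb <- vb[is.finite(vb)]
        if (length(va) < 2 || length(vb) < 2) next
        wt <- wilcoxon_ranksum(va, vb)
        rows[[length(rows) + 1]] <- data.frame(
          state_a = pr[1], state_b = pr[2], measure = mc, lambda = lam,
          statistic = wt$statistic, p_raw = wt$p.value)
      }
    }
  }
  tests <- do.call(rbind, rows)
  tests$p_fdr <- NA_real_
  fam_key <- if (family == "per_measure") {
    paste(tests$state_a, tests$state_b, tests$measure)
  } else {
    paste(tests$state_a, tests$state_b)
  }
  for (fk in unique(fam_key)) {
    idx <- fam_key == fk
    tests$p_fdr[idx] <- fdr_correct(tests$p_raw[idx], q)$adjusted
  }
  tests$significant <- tests$p_fdr <= q
  tests$stars <- sig_stars(tests$p_fdr)

  ksd_df <- NULL; top_nodes <- NULL
  if (!is.null(nlm)) {
    pool <- function(x, li) {
      # node x lambda matrix, or node x lambda x subject array
      if (length(dim(x)) == 3) as.vector(x[, li, ]) else x[, li]
    }
    krows <- list()
    nlam <- if (length(dim(nlm[[1]])) == 3) dim(nlm[[1]])[2] else ncol(nlm[[1]])
    stopifnot(nlam == length(lambdas))
    for (pr in pairs) {
      for (li in seq_along(lambdas)) {
        kc <- ks_compare(pool(nlm[[pr[1]]], li), pool(nlm[[pr[2]]], li))
        krows[[length(krows) + 1]] <- data.frame(
          state_a = pr[1], state_b = pr[2], lambda = lambdas[li],
          ksd = kc$ksd, p = kc$p.value)
      }
    }
    ksd_df <- do.call(rbind, krows)
    li <- which.min(abs(lambdas - lambda_attr))
    node_mean <- function(x) {
      if (length(dim(x)) == 3) rowMeans(x[, li, , drop = FALSE]) else x[, li]
    }
    top_nodes <- lapply(pairs, function(pr) {
      tq <- top_quantile_nodes(node_mean(nlm[[pr[1]]]), node_mean(nlm[[pr[2]]]),
                               q = top_q, networks = networks)
      tq$pair <- pr
      tq
    })
  }
  structure(list(tests = tests, ksd = ksd_df, top_nodes = top_nodes, q = q),
            class = "state_comparison")
}

#' @export
print.state_comparison <- function(x, ...) {
  cat("State comparison report:", nrow(x$tests), "tests, FDR q =", x$q, "\n")
  sig <- x$tests[x$tests$significant, ]
  cat(" ", nrow(sig), "significant after FDR\n")
  if (nrow(sig) > 0) print(head(sig, 20), row.names = FALSE)
  invisible(x)
}
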