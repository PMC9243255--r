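#' Default pipeline configuration
#'
#' A nested list covering every stage: signal band and filter order, the
#' scale grid, cascade time step, inertial subrange, synthetic-cohort
#' design, Hopf model and coupling sweep, perturbation protocol, and the
#' statistics family. Values mirror the package defaults; override any
#' entry before passing to the `pipeline_*` stages.
#'
#' @return a config list.
#' @export
default_config <- function() {
  list(
    seed = 1,
    geometry = list(n_nodes = 100, layout = "uniform_ball", radius = 70,
                    n_networks = 8),
    cohort = list(
      states = list(list(label = "stateA", n_subjects = 5, G = 2.0),
                    list(label = "stateB", n_subjects = 5, G = 0.5)),
      duration_volumes = 200, tr = 2, regime = "hopf_forward"),
    signal = list(low_hz = 0.008, high_hz = 0.08, order = 2,
                  edge_discard = 10),
    turbulence = list(lambdas = default_lambda_grid(), dt_steps = 1,
                      r_range = c(8, 34), n_bins = 20),
    hopf = list(a = -0.02, noise_sd = 0.01, dt = 0.1, lambda_c = 0.18,
                g_grid = seq(0, 3, by = 0.25), n_reps = 5,
                duration_volumes = 200),
    perturbation = list(kind = "periodic_force", F0 = 5e-4,
                        a_range = c(-0.02, 0), n_trials = 10,
                        lambda_s = 0.12, duration_volumes = 150),
    stats = list(q = 0.05, family = "per_measure", lambda_attr = 0.12,
                 top_q = 0.15)
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads the file, overlays it on [default_config()] (missing keys keep
#' their defaults) and validates the result.
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- modify_list_deep(default_config(), user)
  validate_config(cfg)
  cfg
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]]) && nm != "states") {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

#' Validate a pipeline configuration
#'
#' Checks every field the stages rely on and reports violations with their
#' field path before any computation.
#'
#' @param config a config list.
#' @return the config, invisibly, on success.
#' @export
validate_config <- function(config) {
  fail <- function(path, msg) stop("config error at `", path, "`: ", msg,
                                   call. = FALSE)
  cg <- config
  if (!is.numeric(cg$seed)) fail("seed", "must be numeric")
  if (cg$geometry$n_nodes < 2) fail("geometry.n_nodes", "must be >= 2")
  nyq <- 1 / (2 * cg$cohort$tr)
  if (cg$signal$low_hz <= 0) fail("signal.low_hz", "must be > 0")
  if (cg$signal$high_hz <= cg$signal$low_hz) {
    fail("signal.high_hz", "must exceed signal.low_hz")
  }
  if (cg$signal$high_hz >= nyq) {
    fail("signal.high_hz", paste0("must be below the Nyquist frequency ",
                                  nyq, " Hz implied by cohort.tr"))
  }
  if (any(cg$turbulence$lambdas <= 0) ||
      is.unsorted(cg$turbulence$lambdas, strictly = TRUE)) {
    fail("turbulence.lambdas", "must be a strictly increasing positive grid")
  }
  if (diff(cg$turbulence$r_range) <= 0) {
    fail("turbulence.r_range", "must be an increasing pair (mm)")
  }
  labs <- vapply(cg$cohort$states, function(s) s$label, "")
  if (anyDuplicated(labs)) fail("cohort.states", "duplicate state labels")
  if (cg$cohort$duration_volumes < 64) {
    fail("cohort.duration_volumes", "must be >= 64")
  }
  if (cg$hopf$dt >= cg$cohort$tr) fail("hopf.dt", "must be below cohort.tr")
  if (cg$perturbation$n_trials < 2) {
    fail("perturbation.n_trials", "must be >= 2")
  }
  invisible(config)
}

config_lambdas <- function(config) config$turbulence$lambdas

#' Model-free measures for one subject
#'
#' Bandpasses, extracts phases, and computes the full model-free measure
#' set over the scale grid: amplitude turbulence `D`, cascade flow, the
#' scalar information cascade, transfer-correlation slope `A` and intercept
#' `B`, and the node x lambda metastability matrix.
#'
#' @param ts a `"bold_ts"`.
#' @param kernels a `"kernel_set"`.
#' @param dist distance matrix, mm.
#' @param config pipeline config (signal + turbulence sections used).
#' @return list with `profile` (data.frame: lambda, D, flow, A, B,
#'   cascade), `nlm` (node x lambda matrix).
#' @export
subject_measures <- function(ts, kernels, dist, config = default_config()) {
  sg <- config$signal; tb <- config$turbulence
  tsf <- bandpass_bold(ts, sg$low_hz, sg$high_hz, sg$order)
  ph <- extract_phases(tsf, edge_discard = sg$edge_discard)
  lambdas <- kernels$lambdas
  fields <- lapply(lambdas, function(l) local_kuramoto(ph, kernels, l))
  D <- vapply(fields, amplitude_turbulence, 0)
  flow <- rep(NA_real_, length(lambdas))
  for (k in seq_along(lambdas)[-1]) {
    flow[k] <- as.numeric(
      information_cascade_flow(fields[[k]], fields[[k - 1]], tb$dt_steps))
  }
  AB <- vapply(fields, function(f) {
    tc <- tryCatch(transfer_correlation(f, dist, tb$r_range, tb$n_bins),
                   error = function(e) list(A = NA_real_, B = NA_real_))
    c(tc$A, tc$B)
  }, numeric(2))
  nlm <- vapply(fields, node_level_metastability,
                numeric(nrow(ph$phases)))
  colnames(nlm) <- format(lambdas)
  casc <- information_cascade(flow[is.finite(flow)])
  list(profile = data.frame(lambda = lambdas, D = D, flow = flow,
                            A = AB[1, ], B = AB[2, ], cascade = casc),
       nlm = nlm)
}

write_stage_manifest <- function(out_dir, stage, info) {
  path <- file.path(out_dir, "run_manifest.tsv")
  row <- data.frame(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                    stage = stage, info = info)
  write.table(row, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = !file.exists(path), append = file.exists(path))
  invisible(path)
}

#' Pipeline stage: generate a synthetic cohort
#'
#' @param config pipeline config.
#' @param out_dir output directory; the cohort, its manifest and the
#'   resolved config are written there.
#' @return the `"cohort"`, invisibly returned and written to disk.
#' @export
pipeline_generate <- function(config = default_config(), out_dir) {
  validate_config(config)
  geom <- generate_parcellation(config$geometry$n_nodes,
                                config$geometry$layout,
                                n_networks = config$geometry$n_networks,
                                seed = derive_seed(config$seed, tag = "geom"),
                                radius = config$geometry$radius)
  states <- lapply(config$cohort$states, function(s) {
    s$a <- s$a %||% config$hopf$a
    s$noise_sd <- s$noise_sd %||% config$hopf$noise_sd
    s$lambda_c <- s$lambda_c %||% config$hopf$lambda_c
    s
  })
  cohort <- generate_cohort(states, geom,
                            duration_volumes = config$cohort$duration_volumes,
                            tr = config$cohort$tr,
                            regime = config$cohort$regime,
                            seed = derive_seed(config$seed, tag = "cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(cohort, file.path(out_dir, "cohort"))
  yaml::write_yaml(config, file.path(out_dir, "resolved_config.yaml"))
  write_stage_manifest(out_dir, "generate",
                       paste(length(cohort$subjects), "subjects"))
  invisible(cohort)
}

#' Pipeline stage: model-free measures for every subject
#'
#' @param config pipeline config.
#' @param cohort a `"cohort"` (e.g. from [pipeline_generate()] or
#'   [read_cohort()]).
#' @param out_dir optional; when given, writes `measures.tsv` and per-state
#'   NLM tables.
#' @return list with `measures` (long data.frame) and `nlm` (list per
#'   state of node x lambda x subject arrays).
#' @export
pipeline_measure <- function(config = default_config(), cohort,
                             out_dir = NULL) {
  validate_config(config)
  dist <- pairwise_distances(cohort$geometry)
  kernels <- build_kernels(dist, config_lambdas(config))
  rows <- list(); nlm_by_state <- list()
  for (s in cohort$subjects) {
    sm <- subject_measures(s$ts, kernels, dist, config)
    rows[[length(rows) + 1]] <- cbind(
      data.frame(subject_id = s$id, state = s$state), sm$profile)
    nlm_by_state[[s$state]] <- c(nlm_by_state[[s$state]] %||% list(),
                                 list(sm$nlm))
  }
  measures <- do.call(rbind, rows)
  nlm <- lapply(nlm_by_state, function(lst) {
    arr <- array(unlist(lst), dim = c(dim(lst[[1]]), length(lst)))
    arr
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(measures, file.path(out_dir, "measures.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (st in names(nlm)) {
      write.table(apply(nlm[[st]], c(1, 2), mean),
                  file.path(out_dir, paste0("nlm_mean_", st, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }
    write_stage_manifest(out_dir, "measure", paste(nrow(measures), "rows"))
  }
  list(measures = measures, nlm = nlm)
}

# State-pooled empirical FC(r): mean of per-subject FC(r) curves on a
# common bin grid.
state_fc_of_distance <- function(cohort, state, dist, config) {
  sg <- config$signal
  subs <- Filter(function(s) s$state == state, cohort$subjects)
  rng <- range(dist[upper.tri(dist)])
  breaks <- seq(rng[1], rng[2], length.out = config$turbulence$n_bins + 1)
  curves <- lapply(subs, function(s) {
    tsf <- bandpass_bold(s$ts, sg$low_hz, sg$high_hz, sg$order)
    fc_of_distance(tsf, dist, breaks = breaks, min_pairs = 1)
  })
  fc <- Reduce(`+`, lapply(curves, function(c) c$fc)) / length(curves)
  out <- curves[[1]]
  out$fc <- fc
  out$s <- 2 * (1 - fc)
  out
}

#' Pipeline stage: fit the Hopf model per state
#'
#' Pools each state's empirical FC(r) (mean of subject curves) and fits the
#' global coupling with [hopf_fit()]. Node frequencies are estimated from
#' the state's bandpassed data via [estimate_node_frequencies()].
#'
#' @param config pipeline config.
#' @param cohort a `"cohort"`.
#' @param out_dir optional; writes one JSON + error-curve TSV per state.
#' @return named list of `"hopf_fit"` objects, one per state.
#' @export
pipeline_fit <- function(config = default_config(), cohort, out_dir = NULL) {
  validate_config(config)
  dist <- pairwise_distances(cohort$geometry)
  conn <- build_connectome(dist, lambda_c = config$hopf$lambda_c)
  states <- unique(vapply(cohort$subjects, function(s) s$state, ""))
  sg <- config$signal
  fits <- list()
  for (st in states) {
    emp <- state_fc_of_distance(cohort, st, dist, config)
    sub1 <- Filter(function(s) s$state == st, cohort$subjects)[[1]]
    tsf <- bandpass_bold(sub1$ts, sg$low_hz, sg$high_hz, sg$order)
    nf <- estimate_node_frequencies(tsf, c(sg$low_hz, sg$high_hz))
    template <- hopf_system(conn, a = config$hopf$a, omega = nf$omega,
                            G = 1, noise_sd = config$hopf$noise_sd,
                            dt = config$hopf$dt, tr = config$cohort$tr)
    fits[[st]] <- hopf_fit(emp, template, dist,
                           g_grid = config$hopf$g_grid,
                           n_reps = config$hopf$n_reps,
                           duration_volumes = config$hopf$duration_volumes,
                           r_range = config$turbulence$r_range,
                           band = c(sg$low_hz, sg$high_hz),
                           seed = derive_seed(config$seed, tag = paste0("fit-", st)))
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write.table(data.frame(G = fits[[st]]$g_grid,
                             error = fits[[st]]$fit_error),
                  file.path(out_dir, paste0("fit_curve_", st, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(state = st, g_opt = fits[[st]]$g_opt,
                                n_reps = fits[[st]]$n_reps),
                           file.path(out_dir, paste0("fit_", st, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  if (!is.null(out_dir)) write_stage_manifest(out_dir, "fit",
                                              paste(length(fits), "states"))
  fits
}

#' Pipeline stage: perturb the fitted models
#'
#' @param config pipeline config.
#' @param fits named list of `"hopf_fit"` objects (from [pipeline_fit()]).
#' @param dist distance matrix of the cohort geometry.
#' @param out_dir optional; writes one JSON per state.
#' @return named list of `"perturbation_result"` objects.
#' @export
pipeline_perturb <- function(config = default_config(), fits, dist,
                             out_dir = NULL) {
  validate_config(config)
  pc <- config$perturbation
  res <- list()
  for (st in names(fits)) {
    proto <- perturbation_protocol(
      kind = pc$kind, F0 = pc$F0, a_range = pc$a_range,
      n_trials = pc$n_trials, lambda_s = pc$lambda_s,
      seed = derive_seed(config$seed, tag = paste0("perturb-", st)))
    res[[st]] <- run_protocol(fitted_system(fits[[st]]), proto, dist,
                              duration_volumes = pc$duration_volumes,
                              edge_discard = config$signal$edge_discard,
                              band = c(config$signal$low_hz,
                                       config$signal$high_hz))
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(
        list(state = st, kind = pc$kind, chi = res[[st]]$chi,
             info_capability = res[[st]]$info_capability,
             seeds = res[[st]]$seeds),
        file.path(out_dir, paste0("perturbation_", st, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
  }
  if (!is.null(out_dir)) write_stage_manifest(out_dir, "perturb",
                                              paste(length(res), "states"))
  res
}

#' Pipeline stage: group comparison report
#'
#' @param config pipeline config.
#' @param measured output of [pipeline_measure()] (or a compatible list
#'   with `measures` and optional `nlm`).
#' @param networks optional per-node network labels for attribution.
#' @param out_dir optional; writes the test table and a JSON summary.
#' @return a `"state_comparison"`.
#' @export
pipeline_compare <- function(config = default_config(), measured,
                             networks = NULL, out_dir = NULL) {
  validate_config(config)
  sc <- config$stats
  rep <- build_report(measured$measures[, c("subject_id", "state", "lambda",
                                            "D", "A", "flow")],
                      nlm = measured$nlm, q = sc$q, family = sc$family,
                      lambda_attr = sc$lambda_attr, top_q = sc$top_q,
                      networks = networks)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(rep$tests, file.path(out_dir, "comparison_tests.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(rep$ksd)) {
      write.table(rep$ksd, file.path(out_dir, "comparison_ksd.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(list(n_tests = nrow(rep$tests),
                              n_significant = sum(rep$tests$significant)),
                         file.path(out_dir, "comparison_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    write_stage_manifest(out_dir, "compare",
                         paste(nrow(rep$tests), "tests"))
  }
  rep
}

#' Run the full pipeline: generate, measure, fit, perturb, compare
#'
#' @param config pipeline config.
#' @param out_dir output directory for all stages.
#' @return list with `cohort`, `measured`, `fits`, `perturbations`,
#'   `report`.
#' @export
pipeline_run <- function(config = default_config(), out_dir) {
  validate_config(config)
  cohort <- pipeline_generate(config, out_dir)
  measured <- pipeline_measure(config, cohort, out_dir)
  dist <- pairwise_distances(cohort$geometry)
  fits <- pipeline_fit(config, cohort, out_dir)
  perturbations <- pipeline_perturb(config, fits, dist, out_dir)
  report <- pipeline_compare(config, measured,
                             networks = cohort$geometry$network, out_dir)
  invisible(list(cohort = cohort, measured = measured, fits = fits,
                 perturbations = perturbations, report = report))
}
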