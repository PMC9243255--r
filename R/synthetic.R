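#' Generate a synthetic BOLD time series
#'
#' Three regimes with known ground truth:
#' * `independent_noise` — i.i.d. Gaussian noise per node (null data);
#' * `global_sync` — one shared narrowband sinusoid plus tiny per-node
#'   noise (fully synchronised limit);
#' * `hopf_forward` — a forward run of the coupled Stuart-Landau
#'   whole-brain model on an EDR connectome built from the geometry, the
#'   regime whose statistical structure the analysis assumes.
#'
#' @param geom a `"parcellation"`.
#' @param regime one of `"independent_noise"`, `"global_sync"`,
#'   `"hopf_forward"`.
#' @param params regime parameters: `noise_sd`; for `global_sync` also `f`
#'   (Hz); for `hopf_forward`: `G`, `a`, `f_range` (Hz), `lambda_c`,
#'   `connectome` (optional, overrides EDR construction).
#' @param duration_volumes number of volumes (>= 64).
#' @param tr repetition time in seconds.
#' @param seed integer seed; output is a pure function of the arguments.
#' @return a `"bold_ts"` with attribute `"ground_truth"`.
#' @export
generate_bold <- function(geom, regime = c("hopf_forward", "independent_noise",
                                           "global_sync"),
                          params = list(), duration_volumes = 200, tr = 2,
                          seed = 1) {
  regime <- match.arg(regime)
  stopifnot(duration_volumes >= 64, tr > 0)
  n <- length(geom$node_ids)
  p <- params
  if (regime == "independent_noise") {
    set.seed(derive_seed(seed, tag = "noise"))
    v <- matrix(rnorm(n * duration_volumes, sd = p$noise_sd %||% 1),
                n, duration_volumes)
    gt <- list(regime = regime, noise_sd = p$noise_sd %||% 1, seed = seed)
  } else if (regime == "global_sync") {
    f <- p$f %||% 0.04
    noise_sd <- p$noise_sd %||% 0.01
    tt <- (seq_len(duration_volumes) - 1) * tr
    common <- sin(2 * pi * f * tt)
    set.seed(derive_seed(seed, tag = "sync"))
    v <- matrix(rep(common, each = n), n, duration_volumes) +
      matrix(rnorm(n * duration_volumes, sd = noise_sd), n, duration_volumes)
    gt <- list(regime = regime, f = f, noise_sd = noise_sd, seed = seed)
  } else {
    G <- p$G %||% 1
    a <- p$a %||% -0.02
    f_range <- p$f_range %||% c(0.01, 0.07)
    noise_sd <- p$noise_sd %||% 0.01
    lambda_c <- p$lambda_c %||% 0.18
    conn <- p$connectome %||%
      build_connectome(pairwise_distances(geom), lambda_c = lambda_c)
    set.seed(derive_seed(seed, tag = "omega"))
    f_n <- runif(n, f_range[1], f_range[2])
    sys <- hopf_system(conn, a = a, omega = 2 * pi * f_n, G = G,
                       noise_sd = noise_sd, tr = tr)
    ts <- simulate_hopf(sys, duration_volumes,
                        seed = derive_seed(seed, tag = "fwd"))
    v <- ts$values
    gt <- list(regime = regime, G = G, a = a, f_n = f_n,
               noise_sd = noise_sd, lambda_c = lambda_c, seed = seed)
  }
  out <- bold_ts(v, tr = tr, geometry = geom)
  attr(out, "ground_truth") <- gt
  out
}

#' Generate a state-labelled synthetic cohort
#'
#' Builds a cohort whose states differ only in the generating parameters
#' (typically the global coupling `G`), the effect the downstream analysis
#' is designed to detect. Every subject shares the same geometry; the
#' ground truth recorded on the object suffices to regenerate the cohort
#' bit-identically from the seed.
#'
#' @param states list of state specifications, each a list with `label`,
#'   `n_subjects`, and generator parameters (`G`, plus anything accepted by
#'   [generate_bold()]'s `params`).
#' @param geom a `"parcellation"` shared by all subjects.
#' @param duration_volumes,tr passed to [generate_bold()].
#' @param regime generating regime for all subjects.
#' @param seed root seed; per-subject seeds are derived from it.
#' @return object of class `"cohort"`: `subjects` (list of
#'   `list(id, state, ts)`), `geometry`, `ground_truth` (data.frame),
#'   `seed`.
#' @export
generate_cohort <- function(states, geom, duration_volumes = 200, tr = 2,
                            regime = "hopf_forward", seed = 1) {
  labels <- vapply(states, function(s) s$label, "")
  if (anyDuplicated(labels)) stop("duplicate state labels in cohort spec")
  if (length(states) < 2) {
    warning("fewer than 2 states; comparison workflows need >= 2")
  }
  subjects <- list()
  gt_rows <- list()
  k <- 0L
  for (st in states) {
    for (i in seq_len(st$n_subjects)) {
      k <- k + 1L
      sid <- sprintf("%s_sub%02d", st$label, i)
      s_seed <- derive_seed(seed, k, "cohort")
      prm <- st[setdiff(names(st), c("label", "n_subjects"))]
      ts <- generate_bold(geom, regime = regime, params = prm,
                          duration_volumes = duration_volumes, tr = tr,
                          seed = s_seed)
      subjects[[k]] <- list(id = sid, state = st$label, ts = ts)
      gt_rows[[k]] <- data.frame(subject_id = sid, state = st$label,
                                 G = st$G %||% NA_real_,
                                 a = st$a %||% -0.02,
                                 noise_sd = st$noise_sd %||% 0.01,
                                 tr = tr, n_volumes = duration_volumes,
                                 seed = s_seed)
    }
  }
  structure(list(subjects = subjects, geometry = geom,
                 ground_truth = do.call(rbind, gt_rows), seed = seed),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(vapply(x$subjects, function(s) s$state, ""))
  cat("Synthetic cohort:", length(x$subjects), "subjects,",
      length(x$geometry$node_ids), "nodes\n")
  print(tab)
  invisible(x)
}

#' Write a cohort to disk (TSV time series + manifest + sidecar JSON)
#'
#' One TSV per subject (nodes x time, tab-separated, no header), a
#' tab-separated manifest with one row per subject (`subject_id, state,
#' path, tr, n_volumes, seed`), the geometry coordinates, and a JSON
#' sidecar with all generation parameters.
#'
#' @param cohort a `"cohort"`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$subjects, function(s) {
    path <- file.path(dir, paste0(s$id, ".tsv"))
    write.table(format(s$ts$values, digits = 10, trim = TRUE, scientific = FALSE),
                path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    data.frame(subject_id = s$id, state = s$state, path = basename(path),
               tr = s$ts$tr, n_volumes = ncol(s$ts$values),
               seed = cohort$ground_truth$seed[
                 cohort$ground_truth$subject_id == s$id])
  })
  manifest <- file.path(dir, "manifest.tsv")
  write.table(do.call(rbind, rows), manifest, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_coordinates(cohort$geometry, file.path(dir, "coordinates.tsv"))
  sidecar <- list(seed = cohort$seed,
                  n_nodes = length(cohort$geometry$node_ids),
                  ground_truth = cohort$ground_truth)
  jsonlite::write_json(sidecar, file.path(dir, "generation.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `manifest.tsv` and subject TSVs.
#' @return a `"cohort"` (without ground-truth regeneration parameters
#'   beyond those recorded in the manifest/sidecar).
#' @export
read_cohort <- function(dir) {
  manifest <- read.table(file.path(dir, "manifest.tsv"), header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE)
  coords <- read_coordinates(file.path(dir, "coordinates.tsv"))
  geom <- structure(list(node_ids = rownames(coords), coords = coords,
                         network = factor(rep("net1", nrow(coords)))),
                    class = "parcellation")
  subjects <- lapply(seq_len(nrow(manifest)), function(i) {
    v <- as.matrix(read.table(file.path(dir, manifest$path[i]), sep = "\t"))
    dimnames(v) <- NULL
    list(id = manifest$subject_id[i], state = manifest$state[i],
         ts = bold_ts(v, tr = manifest$tr[i], geometry = geom))
  })
  structure(list(subjects = subjects, geometry = geom,
                 ground_truth = manifest, seed = NA_integer_),
            class = "cohort")
}
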