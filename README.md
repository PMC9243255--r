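# brainturb

Turbulence-based characterisation of whole-brain dynamical states from
parcellated BOLD time series.

## What it is for

Different brain states — wakeful rest, meditation, deep sleep, disorders
of consciousness — are hard to tell apart from raw resting-state fMRI.
`brainturb` implements a framework that distinguishes them by treating
the instantaneous phase field of narrowband BOLD as a turbulent medium,
and by fitting and perturbing a whole-brain oscillator model. It is
aimed at computational neuroscientists working with parcellated
node × time BOLD matrices plus parcel coordinates.

**Model-free side.** From phases `φ_p(t)` (Hilbert transform of
0.008–0.08 Hz bandpassed signals) the local Kuramoto order parameter at
spatial scale λ is

    R_n^λ(t) e^{iν_n(t)} = Σ_p [ C^λ_np / Σ_q C^λ_nq ] e^{iφ_p(t)},
    C^λ_np = exp(−λ r(n,p))

with `r(n,p)` the Euclidean distance in mm. On top of the modulus field
the package computes amplitude turbulence `D_λ` (std of R over space and
time), information cascade flow and cascade (lagged correlation between
consecutive scales and its mean), the spatial transfer correlation `A^λ`
(log-log slope of pair correlation vs distance in the inertial
subrange), and node-level metastability (temporal std of R per node).

**Model-based side.** A coupled Stuart-Landau (supercritical Hopf)
system on an exponential-distance-rule connectome,

    dx_n/dt = (a_n − x_n² − y_n²) x_n − ω_n y_n + G Σ_p C_np (x_p − x_n) + ν η_n(t)

is fitted to each state by sweeping the global coupling `G` and matching
functional connectivity as a function of distance, `FC(r)` (equivalently
the structure function `S(r) = 2(1 − FC(r))`). The fitted model is then
probed in silico — periodic forcing at `F0 = 5e-4` or subcritical
bifurcation-parameter shifts in `[−0.02, 0]` — and summarised by
susceptibility `χ` and information encoding capability `I`.

**Statistics.** Wilcoxon rank-sum per scale with Benjamini-Hochberg FDR,
Kolmogorov-Smirnov distances between metastability distributions, and
top-quantile node/network attribution.

A synthetic-cohort generator (geometry, EDR connectome, state-labelled
forward-model cohorts with known ground truth) makes the whole pipeline
testable without any external data.

## Worked example

Generate a two-state cohort whose states differ only in the generating
coupling, measure amplitude turbulence, compare groups, fit the model to
one state and perturb it:

```r
library(brainturb)

geom   <- generate_parcellation(100, seed = 1)
dist   <- pairwise_distances(geom)
cohort <- generate_cohort(
  list(list(label = "highG", n_subjects = 5, G = 2.0),
       list(label = "lowG",  n_subjects = 5, G = 0.5)),
  geom, duration_volumes = 200, seed = 1)

kernels  <- build_kernels(dist, default_lambda_grid())
measures <- do.call(rbind, lapply(cohort$subjects, function(s) {
  ph <- extract_phases(bandpass_bold(s$ts))
  cbind(data.frame(subject_id = s$id, state = s$state),
        turbulence_profile(ph, kernels))
}))
report <- build_report(measures)
subset(report$tests, lambda %in% c(0.01, 0.12, 0.30))
#>  measure lambda statistic       p_raw       p_fdr stars
#>        D   0.01        25 0.007936508 0.007936508    **
#>        D   0.12         0 0.007936508 0.007936508    **
#>        D   0.30         0 0.007936508 0.007936508    **
```

Turbulence separates the two couplings at every scale: with 5 subjects
per group the rank-sum statistic hits its extreme (0 or 25), giving the
smallest exact two-sided p-value (2/choose(10,5) ≈ 0.0079), which
survives FDR across the 11-scale family.

```r
sub    <- Filter(function(s) s$state == "highG", cohort$subjects)
rng    <- range(dist[upper.tri(dist)])
breaks <- seq(rng[1], rng[2], length.out = 21)
curves <- lapply(sub, function(s)
  fc_of_distance(bandpass_bold(s$ts), dist, breaks = breaks, min_pairs = 1))
emp    <- curves[[1]]
emp$fc <- Reduce(`+`, lapply(curves, function(c) c$fc)) / length(curves)

conn <- build_connectome(dist, 0.18)
set.seed(2); f_n <- runif(100, 0.01, 0.07)
template <- hopf_system(conn, a = -0.02, omega = 2 * pi * f_n,
                        G = 1, noise_sd = 0.01, tr = 2)
fit <- hopf_fit(emp, template, dist, g_grid = seq(0, 3, 0.25),
                n_reps = 2, duration_volumes = 150, seed = 3)
fit
#> Hopf whole-brain coupling fit
#>   G grid: [0,3] (13 values), 2 reps each
#>   optimal coupling g_opt = 2 (fit error 0.01991 )
```

The sweep recovers the generating coupling (`G* = 2.0`) exactly on the
0.25-step grid. The fitted model's response to the standard periodic
forcing:

```r
proto <- perturbation_protocol("periodic_force", F0 = 5e-4,
                               n_trials = 10, seed = 4)
run_protocol(fitted_system(fit), proto, dist, duration_volumes = 150)
#> Perturbation (periodic_force, 10 trials, lambda_s = 0.12)
#>   susceptibility chi = 0.046338   information capability I = 0.029678
```

`chi > 0` says the forcing measurably raises local synchronisation at
the readout scale; lower-coupling states yield smaller `chi`.

The same workflow is available as staged commands over a YAML config:

```sh
Rscript inst/scripts/brainturb-pipeline.R all --config inst/config/demo.yaml --out demo_out
```

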