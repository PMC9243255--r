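---
title: "Distinguishing brain states through turbulent whole-brain dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing brain states through turbulent whole-brain dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainturb)
```

## The problem

Resting-state fMRI yields one BOLD time series per brain parcel. Conscious
wakefulness, meditation, deep sleep and pathological low-consciousness
states all produce superficially similar signals, yet differ in how local
synchronisation is organised across spatial scales and in how strongly the
underlying network is effectively coupled. `brainturb` implements a
two-sided framework for quantifying those differences:

* a **model-free** side that treats the instantaneous phase field of
  narrowband BOLD as a turbulent medium and measures its spatiotemporal
  synchronisation structure, and
* a **model-based** side that fits a coupled Stuart-Landau (Hopf)
  whole-brain model to each state and probes the fitted model with
  in-silico perturbations.

Both sides reduce to scalar measures per subject (or per state) that are
compared across groups with rank statistics under FDR control.

## Model-free measures

All model-free measures derive from the **local Kuramoto order
parameter**. Given instantaneous phases $\varphi_p(t)$ (Hilbert transform
of 0.008–0.08 Hz bandpassed BOLD) and pairwise Euclidean distances
$r(n,p)$ in mm, the complex order field at spatial scale $\lambda$
(units 1/mm) is

$$R_n^{\lambda}(t)\, e^{i\nu_n(t)} \;=\; \sum_p
  \frac{C^{\lambda}_{np}}{\sum_q C^{\lambda}_{nq}}\; e^{i\varphi_p(t)},
  \qquad C^{\lambda}_{np} = e^{-\lambda\, r(n,p)} .$$

The modulus $R \in [0,1]$ measures synchronisation in a neighbourhood of
size $\sim 1/\lambda$ around node $n$. On top of it:

* **Amplitude turbulence** $D_\lambda = \sqrt{\langle R^2\rangle_{x,t} -
  \langle R\rangle_{x,t}^2}$, the population standard deviation of the
  modulus over nodes and time — the core discriminative measure.
* **Information cascade flow** $\mathcal{F}(\lambda) = \langle
  \mathrm{corr}_t(R_\lambda(x, t+\Delta t), R_{\lambda-\Delta\lambda}(x,
  t))\rangle_x$, the lagged correlation between consecutive scales; its
  mean over scales is the **information cascade**.
* **Transfer correlation** $A^\lambda$: the slope of
  $\log \mathrm{corr}_t(R^\lambda_n, R^\lambda_p)$ against $\log r(n,p)$
  within the inertial subrange; a steeper negative slope means
  information travels shorter distances at that scale.
* **Node-level metastability** $\mathrm{NLM}(n,\lambda)$: the temporal
  standard deviation of $R^\lambda_n(t)$ per node, whose distributions
  are compared across states with the Kolmogorov-Smirnov distance and
  attributed to networks through the top-15%-quantile node selection.

### Parameter choices that matter

* **Scale grid** — `default_lambda_grid()` returns the eleven scales
  $\{0.01, 0.03, 0.06, \ldots, 0.30\}$ 1/mm, covering neighbourhood sizes
  from roughly 100 mm down to 3 mm and containing the three reference
  scales 0.01, 0.12 and 0.30 at which states are conventionally compared.
  The cascade step $\Delta\lambda$ is the grid spacing and the time lag
  $\Delta t$ is one TR.
* **Band** — 0.008–0.08 Hz, the standard low-frequency window for
  phase analyses of BOLD; a second-order Butterworth applied
  forward-backward (`signal::filtfilt`) keeps the output zero-phase,
  which matters because the phases *are* the analysis object. Each node
  is demeaned first; no global-signal regression is applied.
* **Edge handling** — the Hilbert transform and the filter distort both
  ends of the series; `extract_phases()` trims 10 volumes per end by
  default (configurable), never letting the valid window fall below 10
  volumes.
* **Self-coupling** — the kernel sum includes the node itself with
  weight $e^0 = 1$ (toggleable via `include_self`); the normalisation
  makes the field an average, so the modulus is bounded by 1 regardless.
* **Inertial subrange** — the power-law fit of the transfer correlation
  needs a distance window; the default is 8–34 mm with 20 equal-width
  bins. Binning is unavoidable: real coordinates make "pairs at equal
  distance" a measure-zero event. Bins whose mean correlation is not
  positive are dropped (their count is reported) because the log is
  undefined there; at least 3 usable bins are required.
* **Conventions** — Pearson correlations and *population* standard
  deviations (denominator $n$) throughout. The transfer correlation is
  reported as the raw slope $A^\lambda$ (and its magnitude), not as the
  shifted constant-minus-magnitude display sometimes used for plotting.

## The Hopf whole-brain model

Each node follows the normal form of a supercritical Hopf bifurcation,
coupled diffusively through a structural connectome $C_{np}$:

$$\dot x_n = (a_n - x_n^2 - y_n^2)\,x_n - \omega_n y_n +
  G \sum_p C_{np}(x_p - x_n) + \nu\,\eta_n(t)$$

and symmetrically for $y_n$ with $+\omega_n x_n$. For $a_n > 0$ an
uncoupled noiseless node oscillates on a limit cycle of radius
$\sqrt{a_n}$ at $f_n = \omega_n/2\pi$; for $a_n < 0$ it is a noise-driven
damped oscillator. The connectome is the exponential distance rule
$C_{np} = e^{-\lambda_c r(n,p)}$ (default $\lambda_c = 0.18$ 1/mm, a
literature-typical structural decay scale), optionally with additive
long-range entries standing in for tractography-derived connections; the
mixing rule for such entries is not canonical, so the package simply adds
them symmetrically and records the provenance.

**Fitting.** The single fitted parameter is the global coupling $G$.
Following Kolmogorov's structure-function view, the fitting target is the
functional connectivity as a function of distance: pairwise signal
correlations averaged in distance bins, $FC(r)$, with
$S(r) = 2\,(1 - FC(r))$ for standardised signals. `hopf_fit()` sweeps a
grid of $G$ values, runs `n_reps` simulations per value, and scores the
RMS difference between simulated and empirical $FC(r)$ inside the
inertial subrange; the optimum is the grid argmin (ties toward smaller
$G$). Empirical and simulated signals are both bandpassed before the
comparison, so the two curves see the same filtering. Node frequencies
$\omega_n$ are estimated as smoothed-periodogram peaks of the bandpassed
data; $a_n = -0.02$ for all nodes during fitting, keeping every oscillator
subcritical, consistent with the bifurcation-shift perturbation range
below.

**Integration.** Stochastic runs use Euler-Maruyama at $dt = 0.1$ s with
increments $\nu\sqrt{dt}\,N(0,1)$ per component ($\nu = 0.01$ by
default); the BOLD proxy is $x_n$ subsampled at the TR after a 20 s
transient discard, with no hemodynamic convolution, matching practice in
this modelling family. Noiseless runs ($\nu = 0$) go through an adaptive
ODE solver (`deSolve::ode`, lsoda, rtol $10^{-10}$) instead: a
fixed-step Euler scheme biases the deterministic limit-cycle radius by
$O(dt\,\omega^2)$, and the closed-form properties of the deterministic
system are exactly the cases one wants to verify sharply. Divergence
($|x| > 10^6$) raises an error naming the step and coupling.

## In-silico perturbations

Two protocols probe a fitted model at its working point:

* **Periodic forcing** adds $F_0\cos(\omega_0 t)$ / $F_0\sin(\omega_0 t)$
  to the $x$/$y$ equations of every node, with $F_0 = 5\times10^{-4}$ and
  $\omega_0$ the unweighted mean of the node frequencies.
* **Bifurcation shift** redraws each $a_n$ uniformly in $[-0.02, 0]$ per
  trial, staying subcritical.

Each trial pairs one perturbed and one unperturbed simulation on
*identical noise streams*, a deliberate variance-reduction choice: any
difference is attributable to the perturbation, and a no-op perturbation
yields exactly zero. The readout is the local order modulus at
$\lambda_s = 0.12$ (mid-grid; the choice of readout scale is not
canonical and is configurable) computed from the simulated signals by the
same bandpass–Hilbert–kernel pipeline as for data. With $d_{k,n}$ the
shift in the time-mean modulus for trial $k$ and node $n$:

$$\chi = \big\langle \langle d \rangle_{trials} \big\rangle_x,
  \qquad
  I = \sqrt{\big\langle \mathrm{Var}_{trials}(d) \big\rangle_x}.$$

$\chi$ (susceptibility) is the mean shift; $I$ (information encoding
capability) is the across-trial variability of that shift, averaged over
space under the square root — note the root is taken *outside* the
spatial average, so $I$ is the RMS across-trial spread, not a mean of
per-node spreads. Trials default to 10; a diverged trial is rerun with a
fresh derived seed up to 3 times.

As a complementary signal-complexity reference, `lempel_ziv()` computes
normalised LZ76 complexity: per-node median binarisation, concatenation
in node order, phrase counting, and normalisation by the
$n/\log_2 n$ random-sequence asymptote, so an i.i.d. fair coin scores
near 1 and constant input near 0.

## Group statistics

Scalar measures are compared per scale with two-sided Wilcoxon rank-sum
tests (exact enumeration for combined $n \le 12$ without ties,
tie-corrected normal approximation otherwise; identical inputs return
$p = 1$). The FDR family is, by default, the set of scales within one
(measure, state-pair) combination — the correction family is not
canonical, so it is explicit and can be pooled across measures instead.
Node-level metastability distributions are compared per scale with the
two-sample KS distance (and `stats::ks.test` p-value); node attribution
takes the top 15% of absolute between-state differences, where the
selection uses strict exceedance of a type-1 quantile so that a planted
minority of truly different nodes is returned exactly and full ties are
returned whole with a tie flag. The slope-across-states summary encodes
states as ordinal ranks 1..S in the user-supplied order — the natural
choice when states form an ordered severity/arousal axis — and fits OLS
per scale.

## The synthetic cohort generator

`generate_parcellation()` places parcels uniformly in a 70 mm-radius
ball (default 100 nodes; configurable to 1000), a desk-scale stand-in
for a cortical parcellation that preserves mm-scale distance statistics.
Network labels come from seeded k-means on the coordinates.
`generate_cohort()` builds state-labelled cohorts whose states differ in
the generating global coupling $G^\ast$ — the effect the downstream
analysis is designed to detect — using the forward Hopf model itself
(`hopf_forward`), plus `independent_noise` and `global_sync` regimes as
null and degenerate references. Default conditions: TR = 2 s, 200
volumes per subject (within the 150–450 range typical of resting-state
acquisitions), $a_n = -0.02$, $\nu = 0.01$, node frequencies uniform in
0.01–0.07 Hz (inside the analysis band), contrasted couplings
$G^\ast = 2.0$ vs $0.5$.

What the generator does *not* emulate: hemodynamic convolution, scanner
and motion artefacts, regional heterogeneity of $a_n$ and of noise, and
empirical tractography (long-range entries are available but synthetic).
Passing tests on these cohorts therefore demonstrate the internal
consistency and discriminative power of the measures under the model's
own assumptions — not robustness to real-data confounds, which upstream
preprocessing must handle.

## Numerical choices

* Variances use the centred form $\mathrm{mean}((v - \bar v)^2)$, not
  $\mathrm{mean}(v^2) - \bar v^2$: near full synchrony the one-pass form
  loses all significant digits and the square root amplifies the error
  to $\sim 10^{-8}$.
* The order-parameter modulus is clipped to $[0,1]$ against rounding.
* Flat in-band spectra resolve frequency ties to the lowest bin with a
  warning; constant nodes are flagged and given phase 0 rather than
  propagating NaN.
* Coupling-sweep ties break toward smaller $G$; grid values diverging in
  every repetition are excluded from the argmin.
* All randomness flows from one root seed through tagged 31-bit
  sub-streams (`derive_seed`), so every artefact is reproducible
  bit-identically and paired perturbation trials share noise exactly.

## Problem sizes

The package's own test battery and the bundled acceptance script run the
full framework at the scale a single workstation handles comfortably:
100-node geometries, 200-volume subjects, coupling sweeps over
$G \in [0,3]$ in 0.25 steps with 5 repetitions, and 10-trial
perturbation protocols. The original-scale analysis (1000 areas, $G$ up
to 7 in 0.1 steps, 100 repetitions) is the same code via configuration;
it is simply a cluster-scale run.

## Worked example

```{r, eval = FALSE}
geom <- generate_parcellation(100, seed = 1)
dist <- pairwise_distances(geom)
cohort <- generate_cohort(
  list(list(label = "highG", n_subjects = 5, G = 2.0),
       list(label = "lowG",  n_subjects = 5, G = 0.5)),
  geom, duration_volumes = 200, seed = 1)

kernels <- build_kernels(dist, default_lambda_grid())
ph <- extract_phases(bandpass_bold(cohort$subjects[[1]]$ts))
turbulence_profile(ph, kernels)        # D per scale for one subject
```

See the README for a complete run with its printed output.

## Known limitations

* The measures assume a spatially embedded parcellation; surface-based
  geodesic distances are not supported (Euclidean only).
* The Hopf fitting objective uses binned FC(r); extremely coarse
  parcellations (few pairs per bin) make the objective noisy.
* Susceptibility under weak forcing is resolvable only thanks to paired
  noise streams; unpaired designs would need far more trials.
* The Wilcoxon exact path is limited to combined samples of 12; larger
  samples use the tie-corrected normal approximation, which is mildly
  conservative.
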