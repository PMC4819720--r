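---
title: "Mapping electrophysiological networks onto haemodynamic networks with a multivariate Taylor expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping electrophysiological networks onto haemodynamic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taylorconn)
```

## The model

Resting-state functional connectivity can be measured two very different
ways: haemodynamically, as the Pearson correlation matrix $V$ of regional
BOLD signals, and electrophysiologically, as band-specific coupling
matrices $W_f$ computed from MEG-like source signals with either a phase
metric (the phase lag index, PLI) or an amplitude metric (the
leakage-corrected amplitude envelope correlation, AEC). All of these are
$P \times P$ symmetric weighted adjacency matrices with zero diagonal
and entries in $[-1, 1]$.

`taylorconn` treats the relationship between the two modalities as an
unknown matrix function $V = F(W_1, \dots, W_D)$ and approximates it by
a second-order multivariate Taylor expansion developed at zero:

$$
V \;\approx\; F(0) \;+\; \sum_{m=1}^{D} a_m W_m
\;+\; \tfrac12 \sum_{m=1}^{D}\sum_{n=1}^{D} b_{mn}\, W_m W_n
\;+\; c\,(uu^{\mathsf T} - I),
$$

where $u$ is the all-one vector. The linear terms are *direct
connectivity*: a weighted sum of electrophysiological edge strengths.
The quadratic terms are *shared connectivity*: entry $(p, q)$ of
$W_m W_n$ is the inner product of region $p$'s whole-brain connectivity
profile in matrix $m$ with region $q$'s profile in matrix $n$, i.e. an
unnormalized covariance of connectivity profiles, within one frequency
band ($m = n$) or across bands ($m \ne n$, the cross-frequency terms).
The trailing constant offsets all off-diagonal elements and absorbs the
part of the truncation error that is uniform across edges; $F(0)$ would
only offset the diagonal, which is not modelled, so the diagonal of
every fitted matrix is fixed at zero.

Developing at zero is natural here: connectivity matrices have zero
trace, so their eigenvalues are centred on zero and a spectral radius
below the (unknown) radius of convergence guarantees convergence of the
series. `spectral_check()` reports eigenvalues, traces and spectral
radii as a diagnostic and warns above radius 1; the radius of
convergence itself is not estimable from data and no attempt is made.

### Estimation

Although one can fit the expansion with an iterative nonlinear
least-squares routine, the model is *linear in its coefficients* once
the matrix products are precomputed. The default estimator is therefore
ordinary least squares on the $E = P(P-1)/2$ upper-triangle off-diagonal
elements — the identical optimum, deterministic, with no initialization
or seed. `fit_taylor(method = "iterative")` exposes a BFGS route on the
same objective for parity; the two agree to solver tolerance.

Two conventions matter for the quadratic terms:

* **Symmetrization.** The regressor for an unordered pair $\{m, n\}$ is
  $\tfrac12 (W_m W_n + W_n W_m)$, with one coefficient
  $b_{mn} = b_{nm}$. A symmetric Hessian loses no generality in a
  Taylor expansion of a symmetric target, and using the two ordered
  products separately would make the design exchange-degenerate. The
  $\tfrac12$ of the expansion is kept inside the regressor, so reported
  coefficients are the Hessian entries themselves. Whether a fit with
  ordered products treated separately absorbs the $\tfrac12$ into
  $b_{mn}$ only rescales reported values, never the fit.
* **Counting.** `count_coefficients()` reports both the gradient-plus-
  full-Hessian convention ($D + D^2$; 110 coefficients for the
  ten-matrix full model) and the distinct-coefficients convention
  actually estimated ($D + D(D+1)/2$).

$R^2$ is the coefficient of determination $1 - \mathrm{SSE}/\mathrm{SST}$
over the unique off-diagonal elements, SST taken about the mean; with
the offset column present this equals the squared correlation between
target and prediction. Confidence intervals are classical two-sided 95%
linear-model intervals. Predicted entries are *not* clipped to
$[-1, 1]$; the fit records how many fall outside instead.

### The nested model family

Five variants of increasing complexity are supported, forming a nested
sequence whose $R^2$ is necessarily non-decreasing:
single-frequency (one matrix, linear), linear (all matrices of one
metric), nonlinear (adds the within-matrix squares), nonlinear with
cross-terms (adds unordered cross products), and the full model (both
metrics together). The single-frequency entry of a sequence is chosen
as the input matrix with maximal $R^2$ on the target.
`fit_model_sequence()` verifies nesting of the regressor sets and
asserts the monotonicity numerically.

## Connectivity metrics

`build_connectivity_stack()` computes one matrix per (metric, band)
pair from broadband regional time series, over the five canonical bands
delta (1–4 Hz), theta (4–8 Hz), alpha (8–13 Hz), beta (13–30 Hz) and
gamma (30–48 Hz).

* **Filtering.** Zero-phase (forward–backward) Butterworth band-pass of
  order 4. The forward–backward pass has no phase distortion, which is
  essential for phase metrics. Edge samples — three cycles of the
  band's low edge, capped at 10% of the record — are excluded from all
  envelope/phase statistics as filter transient.
* **Analytic signal.** Envelope and instantaneous phase come from the
  FFT analytic-signal construction (negative frequencies zeroed,
  positive doubled), phases wrapped to $(-\pi, \pi]$.
* **PLI** is $\lvert \langle \operatorname{sign}
  \Delta\phi \rangle \rvert$ with the phase difference wrapped to
  $(-\pi, \pi]$; $\operatorname{sign}(0)$ contributes 0, so exactly
  zero-lag coupling — the signature of source leakage — yields PLI 0.
  PLI is computed over the full recording as one window (stationary
  connectivity).
* **AEC** is the Pearson correlation of amplitude envelopes. Leakage
  correction is pairwise and symmetric: each signal is orthogonalized
  against the other (least-squares projection removed), the two
  envelope correlations are averaged. A collinear pair has no residual
  to correlate; it returns 0 with a warning rather than an error so
  that whole-matrix construction never aborts on one degenerate pair.
  Envelopes are used at the full sampling rate; no envelope low-pass is
  applied by default.
* **Pearson** correlations (the haemodynamic metric) retain negative
  values.
* **ROI aggregation.** Voxel signals within a region collapse to one
  timecourse by the Gaussian distance weighting
  $\exp(-r^2/400)$ ($r$ in mm from the region's centre of mass), an
  unnormalized weighted sum by default exactly as the kernel is
  defined; a normalization flag divides by the summed weights, since
  the raw sum scales with voxel count. At $r = 20$ mm the weight is
  $e^{-1}$. Note a naming subtlety: this kernel's half-width at half
  maximum is $\sqrt{400 \ln 2} \approx 16.7$ mm, so its full width at
  half maximum is about 33 mm, although the kernel is sometimes
  loosely described by the ~17 mm half-width figure.

## Permutation inference

Statistical questions about the fits are answered against
spectrum-preserving surrogates. `pseudo_matrix()` eigendecomposes
$W = U \Lambda U^{\mathsf T}$, Fourier-phase-randomizes each
eigenvector's entry sequence (Hermitian-symmetric random phases, so the
amplitude spectrum of the entry sequence is preserved),
re-orthonormalizes the randomized set by QR, and reconstructs
$U' \Lambda U'^{\mathsf T}$ — an exact similarity transform, so the
eigenvalue multiset is preserved to machine precision — before zeroing
the diagonal. This choice of eigenvector randomization is the single
most consequential reconstruction decision in the package: the
randomization destroys the spatial organization of the eigenvectors
while keeping the spectral "mathematical structure" of the matrix, and
other phase-based eigenvector schemes exist that would also preserve
the spectrum but scramble structure differently.

Three tests use these surrogates, each drawing a fresh pseudo-stack per
iteration (one draw shared across models within an iteration, which
preserves within-iteration nesting):

1. **Variance explained** — observed $R^2$ against the null $R^2$
   distribution; Bonferroni threshold $0.05/5$ when run over the five
   model variants.
2. **Complexity gradient** — the least-squares slope of $R^2$ against
   model index over the nested sequence. Surrogates also gain $R^2$
   with added terms, so null slopes are positive; the test asks whether
   the real rate of improvement is larger.
3. **Increments** — each successive $\Delta R^2$ against its null,
   Bonferroni threshold $0.05/3$ for the three increments.

All p-values use the add-one rule $(1 + \#\{\text{null} \ge
\text{obs}\})/(1 + n_\text{perm})$, so they are never exactly zero and
are bounded below by $1/(n_\text{perm}+1)$. The default permutation
count is 1000; every test accepts a reduced count for desk-scale runs.
A subject-swap test compares each subject's matched-pair $R^2$ against
fits using randomly reassigned non-matching stacks, and
`mann_whitney_u()` (midranks, tie-corrected normal $Z$, optional exact
enumeration for small samples) compares metric families.

`regional_contribution()` summarizes what one band explains: the
single-frequency fit's edges ranked by absolute predicted weight, the
top $\mathrm{round}(R^2 \cdot E)$ retained (an $R^2$ of 0.1 keeps the
top 10%), ties broken by region-label lexicographic order for
determinism.

## The synthetic generator

No recordings ship with the package; every input is generated.

* **Stacks** (`gen_stack`): i.i.d. uniform edge weights on
  $[-0.5, 0.5]$ — a realistic spread for correlation-type weights with
  both signs — or a two-block modular variant with +0.3 within-block
  elevation, clipped to $[-1, 1]$.
* **Targets** (`plant_target`): the forward model above with planted
  coefficients plus symmetric Gaussian edge noise. Targets are not
  clipped to $[-1, 1]$ (clipping would bias recovery); out-of-range
  entries are counted and reported.
* **Time series** (`gen_coupled_timeseries`): each region is a sum over
  bands of band-limited carriers. A phase-lag edge shares one carrier
  across the pair with a constant analytic-signal rotation plus a 20%
  private carrier, concentrating the phase difference at the planted
  lag. An envelope-correlation edge uses a smooth FM carrier (band
  centre frequency with slow wander) whose analytic envelope is exactly
  an imposed lognormal modulator of depth $\sigma = 0.5$; the two
  modulators are mixed on the log scale at the correlation that makes
  the *lognormal* correlation equal the target $\rho$, so the planted
  value is recovered without attenuation. A plain band-limited noise
  carrier would re-inject envelope fluctuations of its own after
  re-filtering and dilute the planted correlation — this was measured
  at roughly a 40% loss before the FM-carrier design was adopted.

One master seed expands into per-component child seeds through a fixed
affine map modulo $2^{31}-1$ (`child_seed()`), so stacks, targets,
noise and permutations are independently reproducible.

What the generator does *not* emulate: 1/f spectra, biophysical neural
mass or haemodynamic dynamics, volume-conduction mixing geometry, or
head/forward models. Passing recovery tests therefore demonstrates the
estimator and inference machinery, not robustness to those features of
real recordings.

## Numerical choices and problem sizes

* Degenerate inputs: constant channels are flagged on analytic-signal
  extraction and rejected by Pearson connectivity; collinear AEC pairs
  return 0 with a warning; rank-deficient designs are reported with the
  offending regressor labels and solved by minimum norm; constant
  targets make $R^2$ undefined and raise an error rather than return a
  value.
* Symmetry is enforced to $10^{-12}$ on construction, with float-noise
  averaging; matrix files are written at 17 significant digits so
  read/write round trips are exact.
* Test and verification problem sizes are deliberately modest — stacks
  of $P$ = 15–20 regions, $D$ = 3–5 matrices, 100 replicate null
  calibrations at 200 permutations, 120–300 s synthetic recordings at
  200 Hz — chosen so the full verification cycle runs in minutes on one
  core while leaving every statistical check well-powered.

## Limitations

* The fitted mapping is correlational; shared-connectivity terms are an
  interpretation of matrix products, not a causal claim.
* Coefficients are scale-bound to their dataset: matrices with
  different overall connectivity ranges yield rescaled coefficients,
  so cross-dataset comparison should use correlation of coefficient
  patterns, not direct transfer.
* Third- and higher-order terms are deliberately out of scope: the
  tensor bookkeeping explodes and second-order terms already carry a
  clean interpretation.
* The eigenvector-randomization null preserves the spectrum but not
  other constraints one might want (e.g. exact entry-range bounds);
  zeroing the surrogate diagonal perturbs the spectrum slightly, as it
  does for real matrices.
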