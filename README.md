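# taylorconn

Predicting haemodynamic functional-connectivity networks from
electrophysiological ones with a multivariate Taylor expansion.

## The problem

Resting-state brain networks are measured two ways that rarely meet: as
the Pearson correlation matrix **V** of regional fMRI (BOLD) signals,
and as band-specific MEG coupling matrices **W**<sub>f</sub> — phase
coupling (phase lag index, PLI) or amplitude coupling
(leakage-corrected amplitude envelope correlation, AEC) — computed per
frequency band (delta, theta, alpha, beta, gamma). Visual similarity
between the two has been reported many times; `taylorconn` is for
researchers who want a *quantitative* mapping instead: how much of the
haemodynamic network is explained by direct electrophysiological
coupling, by overlap of connectivity profiles within a band, and by
overlap across bands?

## The model

The package treats the mapping as an unknown matrix function
V = F(W₁, …, W_D) and fits its second-order Taylor expansion about
zero:

```
V  ≈  Σₘ aₘ Wₘ  +  ½ Σₘ Σₙ bₘₙ Wₘ Wₙ  +  c (u uᵀ − I)
```

Linear terms are **direct connectivity** (a weighted sum of edge
strengths); quadratic terms are **shared connectivity** — entry (p, q)
of WₘWₙ is the covariance of region p's and region q's whole-brain
connectivity profiles, within one band (m = n) or across bands
(m ≠ n, the cross-frequency terms); c is a constant off-diagonal
offset. The model is linear in its coefficients, so they are estimated
deterministically by least squares over the P(P−1)/2 unique
off-diagonal elements, with classical 95% confidence intervals. Five
nested variants (single-frequency → linear → nonlinear →
nonlinear + cross-terms → full two-metric model) quantify what each
ingredient adds, and permutation tests against spectrum-preserving
pseudo-matrices (eigenvector-randomized surrogates) decide whether
those additions beat chance.

The package also computes the metrics themselves from regional time
series (zero-phase band-pass, analytic-signal envelope/phase, PLI,
pairwise-orthogonalized AEC, Pearson), aggregates voxels to regions
with the Gaussian kernel exp(−r²/400), and ships a synthetic-data
generator (planted-coefficient targets, coupled oscillators with
planted phase lags and envelope correlations) so every claim is
testable without external recordings.

## Worked example

```r
library(taylorconn)

# a 20-region, 3-matrix synthetic stack with planted coefficients
sp  <- synthetic_spec(P = 20, D = 3, planted_c = 0.05,
                      noise_sd = 0.05, seed = 42)
stk <- gen_stack(sp)
V   <- plant_target(stk, sp)

fits <- fit_model_sequence(V, stk, nested_variants(V, stk))
round(vapply(fits, `[[`, numeric(1), "r2"), 3)
#> single_frequency           linear        nonlinear  nonlinear_cross
#>            0.620            0.711            0.713            0.905

fits$nonlinear_cross
#> <taylor_fit> nonlinear_cross: 9 coefficients (+offset), R^2 = 0.9051
round(fits$nonlinear_cross$a, 3)      # estimated linear coefficients
#>     W1     W2     W3
#> -0.063  0.458 -0.175
round(attr(V, "planted")$a, 3)        # planted truth
#> [1] -0.056  0.465 -0.177

test_variance_explained(V, stk, model_spec("nonlinear_cross"),
                        n_perm = 200, seed = 7)
#> <permutation_result> R^2: observed = 0.9051, p = 0.004975 (200 permutations)
#>   null: mean 0.04996, sd 0.02374, 95th pct 0.09564
```

Reading: the nested R² sequence climbs from 0.62 (best single matrix)
to 0.91 once cross-terms enter, the estimated linear coefficients land
on the planted ones to within the noise, and the observed R² of 0.905
dwarfs the surrogate null (mean ≈ 0.05), giving the smallest p the
add-one rule allows at 200 permutations beyond chance level.

A thin CLI over the same functions lives at `inst/cli/taylorconn`
(subcommands `connectivity`, `fit`, `permtest`, `simulate`).

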