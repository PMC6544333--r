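---
title: "Inferring causal microbial interaction networks from abundance time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring causal microbial interaction networks from abundance time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Co-occurrence networks built from cross-sectional correlations are routinely
read as interaction networks, but correlation is neither necessary nor
sufficient for interaction: shared habitat preferences (environmental
filtering) correlate taxa that never touch, and time-delayed interactions
decorrelate taxa that do. With a long, densely sampled time series a stronger
criterion is available — causes precede and predict their effects. `gclasso`
implements that criterion for community abundance data: conditional
(multivariate) Granger causality, in which each genus is predicted from the
lagged history of *every* genus in the community, so that a link from A to B
survives only if A's past improves prediction of B beyond what B's own past
and all other taxa's pasts already provide. Conditioning on the whole
community is what removes the spurious links a pairwise Granger analysis
inherits from chains and common drivers, and it shrinks the multiple-testing
burden from one test per pair (n(n−1)/2, e.g. 253 at 23 genera and 1326 at 52)
to one model per genus (23 and 52), with expected false positives at
α = 0.05 dropping accordingly (66 → 3 at 52 genera; see
`hypothesis_budget()`).

## The model

Let $y_{i,t}$ be the processed (standardized, first-differenced relative)
abundance of genus $i$ on day $t$. Each genus is modelled as a 20-lag vector
autoregression equation

$$y_{i,t} = c_i + \sum_{j=1}^{n} \sum_{k=1}^{L} B_{ijk}\, y_{j,t-k} + \varepsilon_{i,t}, \qquad L = 20,$$

fitted equation-by-equation. A nonzero $B_{ijk}$ is a directed, signed,
lagged edge $j \to i$ at lag $k$; $j = i$ gives intraspecific
(self-regulation) edges. With $n$ genera each equation has $nL$ candidate
coefficients — far more than the ~350 daily observations — so coefficients
are estimated by the LASSO,

$$\min_{c_i, B_i} \frac{1}{2N} \sum_t \big(y_{i,t} - \hat y_{i,t}\big)^2 + \lambda \sum_{j,k} |B_{ijk}|,$$

which simultaneously shrinks and selects: a coefficient the penalty drives to
zero is "not retained", and retention after cross-validated penalty selection
is this package's operational definition of a significant Granger
coefficient. For an elementwise $\ell_1$ penalty the jointly penalized system
and the per-equation fits have the same solution, which is why fitting one
response at a time is not an approximation.

The solver is cyclic coordinate descent with an unpenalized intercept,
soft-thresholding updates, and convergence declared when no coefficient moves
by more than `tol = 1e-7` in a sweep. The objective is evaluated after every
full sweep and verified to be non-increasing. The test suite checks the
solver against three independent routes: ordinary least squares at
$\lambda = 0$, the closed-form soft-threshold solution for a single
orthonormalized predictor, exhaustive enumeration of sign patterns on small
designs, and an independent LASSO implementation (glmnet) on larger ones.

## Penalty selection by rolling-origin cross-validation

Time series must not be cross-validated with random folds: the model would be
trained on the future of its own test points. The penalty is therefore chosen
by rolling-origin (expanding-window) validation. With processed length $T'$,
let $T_1 = \lfloor T'/3 \rfloor$ and $T_2 = \lfloor 2T'/3 \rfloor$:

1. fit on observations $1..t$ for each $t$ from $T_1$ to $T_2 - 1$,
   forecasting observation $t+1$ one step ahead;
2. select the penalty minimizing the mean squared forecast error (MSFE) over
   those forecasts, taking the smallest penalty among exact ties (least
   shrinkage, deterministic);
3. report an independent validation MSFE over the final third
   ($T_2..T'-1$) at the selected penalty, without reselecting.

The grid holds 50 penalties log-spaced from $\lambda_{\max}$ (the smallest
penalty with an all-zero solution, computed on the full design so the
all-zero extreme is in range for every window) down to
$\lambda_{\max}/10^4$; both endpoints are configurable via
`lambda_grid_size` and `lambda_ratio`.

A numerical note on the rolling refits: each of the ~115 windows × 50
penalties is a warm-started lasso solve. The interim refits use an
active-set strategy with KKT-violation scans and a capped sweep budget
(`cv_maxit`, default 10, at `cv_tol = 1e-5`); near the unpenalized end of the
grid, where the design has more columns than rows and coordinate descent
converges slowly, the cap keeps the refit cost bounded. Those deep-grid
penalties produce badly overfit forecasts and are never selected, so the
MSFE *ranking* is insensitive to the cap (raising the cap leaves the
selected penalty in place on our benchmarks), and the model actually
reported is always refit on the full series at the exact `lasso_fit()`
contract. Warm starting does not change results: with a generous budget the
warm- and cold-started MSFE curves agree to numerical tolerance (asserted in
the tests).

## Preprocessing

Raw tables are genus × day abundances, one per body site. The chain, in
order:

1. **Prevalence filter** — keep genera detected on ≥ 90% of days
   (inclusive boundary). Rarely-detected taxa cannot support a 20-lag model.
2. **Absence imputation** — remaining zeros are treated as detection
   failures, not true absences, and replaced by uniform draws on
   $[10^{-5} m, 10^{-3} m]$ where $m$ is the taxon's mean abundance.
   Imputation happens on the raw scale, before closure, because the bound is
   defined against the series mean and is most interpretable there; the
   alternative (impute after closure) is a one-line change and the chain
   records its provenance either way.
3. **Closure** — per-day relative abundances (columns sum to 1).
4. **Standardization** — each genus centred and scaled by its own mean and
   sample (n−1) standard deviation, so coefficients read as
   "SD change in response per SD of cause" despite abundances spanning
   orders of magnitude.
5. **First differencing** — removes stochastic and deterministic trends.
   Differencing happens *after* standardization, so differenced series do
   not have exactly unit variance; coefficients are reported on this scale
   throughout.

Day-index gaps are permitted on input but the lag operator treats columns as
consecutive observations; a warning is raised at read time. No interpolation
is attempted.

## Edges, strong edges, timescales

The fitted coefficient tensor is materialized as an edge list (one edge per
nonzero coefficient). Because most retained coefficients are small, summaries
focus on **strong** coefficients: within each site, the top 5 percentile of
positive coefficients and the bottom 5 percentile of negative ones
(`mark_strong()`, linear-interpolation percentiles, ties kept). Per ordered
pair, lags 1–5 days are classified as a **short** interaction and 15–20 days
as **long**; a pair with opposite-signed coefficients inside one window is
marked *conflicting* and excluded from sign comparisons in that window
(`classify_timescales()`). The middle window (6–14 days) is the complement
and can be summarized separately. Summary operations mirror the natural
questions: extreme coefficients per pair, coefficient counts per
(predictor, response) pair, sign-by-lag spectra split
interspecific/intraspecific, and per-genus cause/effect counts with mean
lags (computed, by default, over edges where the genus is the cause; the
caption-level ambiguity is exposed as a `lag_role` switch).

## Reshuffling null and overlap filtering

To check that edges reflect temporal structure rather than solver artifacts,
the full fit is repeated on a null table in which each taxon's processed
series is independently permuted over time — the strongest null consistent
with "randomize the series": it preserves every marginal moment exactly
while destroying autocorrelation and all cross-lag structure (a shared
column permutation preserving same-day correlations is available as a mode).
Strong flags on the null edges use the *actual* data's sign-specific cuts,
not cuts recomputed on the null. The report compares strong-pair yields, and
`overlap_filter()` removes — at the whole ordered-pair level — any actual
strong pair that also emerges strong from the null run. One reshuffled
replicate is the default; the count is configurable.

## Correlation versus causality

`pearson_network()` computes unadjusted two-sided Pearson tests at α = 0.05
over all taxon pairs on the *same* processed series the Granger model
consumes, so the comparison is like-for-like. Each eligible ordered
interspecific pair is then cross-tabulated 3 × 3 (positive / negative /
insignificant under each method) per timescale window, excluding
conflicting-sign pairs, and tested for independence with the classical
chi-square statistic (dof 4; low-expected-count warning below 5). Ordered
pairs are the counting unit — Granger is directional, and the pair's single
Pearson value is shared by both orders. Jointly significant pairs also feed
a scatter summary whose Spearman rank correlation measures whether stronger
correlation predicts stronger causation.

## Cross-site conservation

Between two body sites, comparison is restricted to genera present in both
processed tables. An edge is **quantitatively** conserved when the same
(cause, effect, lag) appears with the same sign in both sites, and
**qualitatively** conserved when the same ordered pair has the same sign in
the same timescale window — the latter deliberately forgiving, because daily
sampling cannot pin a biological delay to the exact day and similar
processes may run at slightly different speeds in different habitats.
Conserved fractions use a Jaccard-style denominator — conserved records over
the union of both sites' in-scope records on shared taxa — because the
alternative (per-site denominators) is asymmetric; both are simple to
compute from the report and the choice is stated on the object.

## The synthetic community generator

Real long time series with known interactions do not exist, so correctness
is measured on simulated communities with planted ground truth
(`generate_community()`):

- a latent log-abundance VAR with a negative lag-1 self-coefficient on every
  taxon (default −0.4) and a sparse set of interspecific edges (default 12)
  with lags uniform on 1..20, magnitudes uniform in 0.2–0.6, and 60%
  positive signs — echoing the empirical structure this class of analysis
  reports: short negative self-regulation, interactions spread across lags;
- stationarity certified by the companion-matrix spectral radius, with
  interspecific magnitudes rescaled by $0.95/\rho$ (and a warning) when
  $\rho \ge 1$;
- taxa receive fixed log-spaced baseline abundances spanning one decade
  (smallest taxon ≈ 2% relative abundance at n = 10), so that at the default
  sequencing depth of $10^5$ reads every taxon is detected every day;
- observation: exponentiate, close to proportions, draw multinomial counts
  at the sequencing depth, zero counts below the detection floor
  (default 0), after a 200-step burn-in.

The generator reproduces the features the method assumes (linear lagged
latent dynamics) *and* the distortions real data impose (compositional
closure, counting noise, optional detection zeros). It does not emulate
nonlinear (Lotka–Volterra-type) dynamics, irregular sampling, taxonomic
misassignment, or day-to-day sampling-time jitter — so passing recovery
benchmarks demonstrates the machinery is correct under its own model class,
not that real gut data satisfy that class.

## Benchmark conditions and what the checks show

The end-to-end benchmarks (test suite and `scripts/acceptance.R`) run at:
10 taxa × 350 days, 12 interspecific edges with $|b| \in [0.3, 0.6]$,
self-coefficients −0.4, innovation SD 0.1, depth $10^5$, detection floor 0,
the full 20-lag model and 50-point grid; 5 seeds for recovery and the
reshuffling null, 10 for penalty-selection behaviour. At these conditions
the fit recovers interspecific edges at lag-window recall
(pair matched within ±1 day) well above 0.7 with sign accuracy above 0.9,
recovers every planted self-edge as a negative lag-1 coefficient, and the
reshuffled null yields far fewer strong pairs than the actual data. These
sizes keep a complete run in minutes on one core while leaving the
statistical margins wide; they are not tuned to any particular outcome.

Degenerate inputs are contract errors, not silent repairs: constant series
(standardization undefined), all-zero taxa (imputation undefined), zero
column sums (closure undefined), series shorter than $3(L+2)$ (rolling
thirds undefined), and empty sign classes in `mark_strong()` (that cut is
`NA` and no edge of that sign is flagged).

## Known limitations

- Compositional closure induces dependence among relative abundances; no
  log-ratio or SparCC-style correction is applied, matching the analysis
  this package operationalizes. The LASSO's aggressive pruning and the
  strong-coefficient cut mitigate but do not remove this.
- Retention by LASSO is a selection event, not a calibrated test; no
  per-coefficient p-values or confidence intervals are produced.
- The lag operator assumes daily, evenly spaced sampling; gaps are warned
  about, not modelled.
- Conservation fractions depend on the (stated) denominator convention;
  comparisons with other conventions require recomputation, for which the
  report retains the raw conserved sets.
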