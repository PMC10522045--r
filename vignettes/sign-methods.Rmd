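---
title: "Sign and rank methods for differential abundance: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sign and rank methods for differential abundance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signda)
```

## Why signs instead of log-ratios

Amplicon count tables are compositional: the library size is a technical
ceiling, so only relative abundances are informative, and any valid analysis
must be scale invariant, subcompositionally coherent and permutation
invariant. Log-ratio transforms satisfy these principles but are undefined
at zero, and microbiome tables are mostly zeros; pseudocounts fix the
arithmetic at the price of an arbitrary constant that leaks into every
downstream inference.

The transforms used here keep the reference-frame idea of log-ratio
analysis but replace the ratio with a tie-aware comparison
$I\{a \preceq b\} = I\{a < b\} + \tfrac{1}{2} I\{a = b\}$:

* the **S-sign** compares a taxon's count to an adjusted per-sample
  reference, $I_i^S = I\{N_i \preceq \tilde R_i\}$;
* the **R-sign** compares reference-scaled abundances between samples,
  $I_{ij}^R = I\{N_i / R_i \preceq N_j / R_j\}$, computed as
  $I\{R_j N_i \preceq R_i N_j\}$ so that zeros and exact ties are handled
  in integer arithmetic, never through division.

Ties land on $\tfrac12$; an abundance of zero is simply a very small value.
Many zeros therefore produce many *uninformative* signs (ties), which costs
power but never validity. Scale invariance, subcompositional coherence and
permutation invariance hold exactly for both transforms and are asserted as
property tests in the suite, as is the identity that column sums of an
R-sign matrix reproduce midranks of the relative abundances (shifted by
$\tfrac12$).

## The reference frame

All signs are relative to a reference frame (RF): a set of taxa assumed
approximately invariant across samples and conditions, summarized per
sample by the median count $R_i$. The package deliberately treats RF choice
as pluggable:

* `user_reference_frame()` / `read_reference_frame()` accept prior
  knowledge (the exact-control path);
* `select_reference_frame()` implements a simple invariance selector:
  candidates must be present in at least 80% of samples with mean count
  above 5 (defaults; drop the prevalence to ~60% for very sparse data), all
  candidate pairs get a log-ratio variance computed over samples where both
  counts are positive, pairs below the `ratio_var_quantile` (default 0.25)
  of those variances are connected in a graph, and the largest connected
  component of size at least `min_size` (default 3) is the RF. Ties between
  equally large components break deterministically toward the smallest
  taxon index, and exactly proportional pairs get a small floor (1e-10) on
  the variance threshold so floating-point noise cannot disconnect them.

This selector is intentionally simpler than published network-based
invariant-taxon methods; the testing machinery is agnostic to how the RF
was obtained, and the user-supplied path is the recommended one whenever
stable taxa are known. The candidate filter's pairwise variances use no
pseudocounts — candidates are high-prevalence by construction, and
doubly-positive samples suffice.

Because the raw $R_i$ typically dwarfs an individual taxon's counts, the
S-sign reference is rescaled per target taxon by
$\mathrm{median}_i(N_i) / \mathrm{median}_i(R_i)$. Two conventions matter
here and are fixed deliberately:

* medians are taken over **all samples pooled** — a group-specific
  adjustment would shift the null hypothesis itself;
* for majority-zero taxa the median numerator is zero, which would
  degenerate every S-sign to a tie or a one; the arithmetic mean of the
  target's counts is used instead and the result flagged.

R-signs use the **raw** $R_i$: any taxon-specific rescaling factor cancels
in the pairwise cross-multiplied comparison (tested exactly).

RF members are excluded from testing by default (`include_rf = FALSE`):
testing a taxon against a reference that contains it biases the comparison.
Even-length medians are the mean of the two middle order statistics
throughout.

## Estimation

### S-signs: logistic regression

Marginal (`s-marg`) and conditional (`s-cond`) S-sign tests are logistic
regressions of $I^S$ on $A$, optionally with $L$ and further covariates.
The engine is a Newton–Raphson maximizer of the Bernoulli log-likelihood
evaluated at fractional responses, so ties (0.5) contribute half a success:
this preserves the estimating-equation mean structure $E[I^S] = p$ and
reduces to ordinary ML when no ties occur. Numerical policy: start at
$\beta = 0$, step-halving, convergence at max |score| < 1e-8, 50 iterations
(100 for Firth); covariates are centered and scaled internally and reported
on the original scale; rank-deficient designs error out rather than
silently dropping columns (except covariates with zero variance, which are
dropped with a record, so that a constant library size degrades gracefully
to the marginal model).

Separation — the group indicator perfectly predicting the signs, common for
rare taxa — is detected as a coefficient beyond ±15 or fitted probabilities
within 1e-8 of 0/1 at every non-tied observation. The default policy
(`firth = "auto"`) fits ML first and refits with Firth's penalized
likelihood $\ell(\beta) + \tfrac12 \log \det I(\beta)$ only on detected
separation or non-convergence, flagging `firth_used`; `always`/`never`
force either path. On an intercept-only model the Firth estimate is
logit$((k+\tfrac12)/(n+1))$ and on a saturated 2×2 table it equals adding
$\tfrac12$ to each cell — both checked against closed forms in the tests.

### R-signs: probabilistic index models

R-sign tests fit a probabilistic index model by estimating equations on
pairwise pseudo-observations, $U(\beta) = \sum Z_{ij}(I_{ij}^R -
\mathrm{expit}(Z_{ij}^T\beta)) = 0$, with pair covariates
$Z_{ij} = (A_j - A_i,\ L_j - L_i,\ \dots)$. Each unordered pair enters
once, oriented by sample index: for a logit-linear antisymmetric design the
reverse orientation is algebraically redundant ($I_{ji} = 1 - I_{ij}$,
$Z_{ji} = -Z_{ij}$), which halves the work and is verified by an
orientation-flip invariance test. Same-group pairs carry zero group
contrast; they are skipped in the purely marginal model (zero score) and
retained in conditional models where they inform the library-size
coefficient.

The variance is a U-statistic sandwich $A^{-1} B A^{-T}$, where $B$ sums
score cross-products over pair couples sharing at least one sample
(including each pair with itself), computed in $O(\text{pairs})$ by
per-sample aggregation. Because the per-sample score sums are centered by
the estimating equation, their empirical second moment is deflated in small
samples; $B$ therefore carries the unbiased-divisor factor $n_g/(n_g-1)$
per treatment group — the same convention DeLong-type estimators use for
two-sample probabilistic-index variances — which vanishes as groups grow.
On tie-free null data the resulting variance agrees with the analytic
Mann–Whitney variance $(n_0 + n_1 + 1)/(12 n_0 n_1)$ (Monte-Carlo test),
and the marginal fit itself satisfies
$\mathrm{expit}(\hat\beta_A) = \frac{1}{n_0 n_1}\sum I_{ij}^R$ exactly — the
Mann–Whitney proportion — which the suite checks by brute-force enumeration
on random small datasets.

A degenerate probabilistic index (all informative pseudo-observations 0 or
1) has no finite estimate; it is capped at ±15 on the logit scale, flagged
non-converged, and propagates as a missing p-value rather than a fake one.

### Regression imputation

Conditional models answer a conditional question; the marginal effect often
remains the quantity of interest even when covariates are available. The RI
(standardized / augmented) estimators use covariates only to reduce
variance while still targeting the marginal estimand:

* **S family**: fit the conditional logistic model, average the
  counterfactual predictions $\hat p(a, L_i)$ over the empirical covariate
  distribution to get $\hat\pi(a)$, and report the marginal log odds ratio
  of $\hat\pi(1)$ against $\hat\pi(0)$; the variance is
  $n^{-2}\sum_i IC_i^2$ from the influence curve combining
  inverse-probability residuals with standardization residuals. At the ML
  solution the influence values average to zero by construction (asserted
  at 1e-6).
* **R family**: fit the conditional PIM and average its predictions over
  all ordered sample pairs, $\hat\beta_A^{RI} = [n(n-1)]^{-1}\sum_{i}
  \sum_{j\neq i} \hat p(L_j, L_i)$, an estimate of the marginal
  probabilistic index; the Wald statistic is
  $(\hat\beta_A^{RI} - 0.5)/\hat\sigma$. The influence curve combines
  group-weighted pair averages of the R-signs, a $-2\hat\beta_A^{RI}$
  centering term and an $(A_i - \delta)$ model-prediction correction; its
  empirical *second moment* (squared influence values) is used as the
  variance. Squaring is a deliberate choice: an influence-function variance
  requires second moments — the unsquared sum is essentially zero by the
  centering argument above — and the S-family formula is unambiguous on
  this point. The choice is validated internally by agreement with a
  nonparametric bootstrap (within 15% at $n = 100$ in the acceptance
  properties).

Both estimators rely on the group assignment being independent of the
auxiliary covariates. For the library size alone this holds by design —
sequencing depth is technical — which is why `library_size` is the default
and only automatic auxiliary covariate; adding biological covariates shifts
the burden to an actual randomization assumption and is the user's explicit
decision.

When $L$ is constant both RI estimators collapse *exactly* to their
marginal counterparts (degenerate covariates are dropped before fitting);
this reduction is tested.

## Multiplicity and the driver

`run_all_taxa()` applies one method to every non-RF taxon, adjusts raw
p-values with Benjamini–Hochberg within the run, and flags discoveries at
`p_adj <= alpha` (default 0.05). Failed fits (degenerate signs, diverged
PIMs) are kept as rows with missing statistics and excluded from the BH
family, keeping the FDR denominator honest. Output is sorted by adjusted
p-value then taxon ID, deterministically.

## The simulator: what it emulates, and what it does not

`simulate_dataset()` draws per-taxon (mean, overdispersion) pairs jointly
from a pool, preserving the mean–dispersion relationship; marks
`round(da_fraction * n_taxa)` taxa as differentially abundant with group-1
means multiplied by `fold_change`; resamples library sizes with replacement
from a library pool; and draws counts as negative binomial with variance
$\mu + \phi\mu^2$ around expected count $L_i \pi_{g,t}$. With
`compositional_renorm = TRUE` (default) group proportions are renormalized
to sum to one, so raising some taxa suppresses the rest — the compositional
effect that makes naive count comparisons misleading.

The default pool (`default_parameter_pool()`) is synthetic: heavy-tailed
log-means spanning roughly four orders of magnitude (clamped $t_3$ on the
log10 scale), overdispersion decreasing in the mean with log-normal noise,
and log-normal library sizes with median 10,000 and log-SD 0.6 — magnitudes
a practitioner would recognize from moderately deep 16S runs. A pool
estimated from real data can be supplied through `read_parameter_pool()`.
DA direction is symmetric by default (`prop_up = 0.5`); setting it near 0
or 1 creates a strong compositional compensation effect in which a
one-sided shift of many taxa displaces every null taxon the other way.

What the simulator does **not** emulate: taxon–taxon correlation,
zero-inflation beyond what the NB with resampled library sizes produces,
batch structure, or covariate-dependent depth. Passing operating
characteristics under this generator therefore demonstrate correct
calibration under overdispersed, sparse, compositionally renormalized
counts with varying depth — not robustness to ecological network structure
or confounded designs.

Problem sizes in the shipped tests and acceptance script were chosen as the
smallest that make the Monte-Carlo error bands meaningful: 100 replicates
of 250-taxon, 25-per-group datasets for the type-I and FDR checks, 15
replicates for the directional RF-contamination check, and $n = 100$ with
500 bootstrap resamples for the variance cross-validation.

## Known limitations

* The automatic RF selector assumes most taxa are not differentially
  abundant. When the majority shift one way (70% DA with strong
  compensation), it demonstrably admits DA taxa into the RF and FDR control
  is lost — the acceptance suite reproduces this failure mode on purpose.
  Prior knowledge through `user_reference_frame()` is the escape hatch.
* `ratio_var_quantile` (default 0.25) is a heuristic with no
  data-adaptive justification; it trades RF size against invariance purity
  and is exposed as a knob.
* Wald inference uses normal quantiles; at very small group sizes
  (< ~10 per group) some residual anti-conservatism of sandwich-based
  z-tests remains.
* Only two-group designs are supported; multi-level factors enter only as
  covariates.
* The RI-R estimator inherits the conditional PIM's linearity in
  $L^* - L$; grossly nonlinear depth effects would call for a transformed
  covariate.
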