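---
title: "Detecting transitions of gene-regulation activity in time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transitions of gene-regulation activity in time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regushift)
```

## The model

A time-course experiment with `|T|` time points and a regulatory network
over `|G|` regulated genes is summarized by an intensity matrix `M`:
`M[g, t]` is signed evidence that gene `g`'s expression is being controlled
by its upstream regulators at time `t` (positive: the regulation explains
the data there; negative: it does not). The dynamics are modeled by

* a binary activity matrix `Act` (`1` = regulation of `g` active at `t`),
* a break set `Tra` of boundaries between consecutive *periods*, with the
  constraint that every row of `Act` is constant within every period.

The fitted model maximizes

```
Score(Act) = sum(M * Act) - c * |Tra| * ln(|G| * |T|)
```

The first term rewards switching a regulation on exactly where its
intensity evidence is positive. The second is a BIC-style complexity
penalty: each break adds `|G|` potential state changes, and the `ln(|G|·|T|)`
factor is the usual log-sample-size term for this grid. The method's
executed form initializes each break level at `-2·k·ln(|T|·|G|)`, i.e.
`c = 2`; the score as printed in its defining equation corresponds to
`c = 1`. Both are supported through `penalty_factor`, with `c = 2` the
default because it is what the search actually subtracts per break. Results
record the factor used.

Two further conventions matter and are both supported:

* **Penalty counting** (`penalty_mode`): `"declared"` (default) charges all
  `k` declared breaks even if some gene pattern does not use one, matching
  the search procedure; `"effective"` charges only breaks realized by
  `Act`, matching the score's definition (`Tra` derived from `Act`). At the
  exhaustive optimum these coincide: an unused declared break could be
  dropped for a strictly better score, and the tests assert exactly that.
* **Break convention**: break `j` ends a period at the j-th time point and
  starts the next at the (j+1)-th. Reported breakpoint labels give the time
  value of the last point of the earlier period, with both flanking time
  values attached, since a printed single label is otherwise ambiguous.

## Optimization

For a *fixed* break set, the optimum over `Act` decomposes: each gene
activates each period independently, exactly when the period's intensity
sum is positive (`best_row_activity()`); a zero sum ties to inactive,
preferring the sparser model. The search over break sets is then either

* `search_exhaustive()`: all `choose(|T|-1, k)` break sets per k — faithful
  to the stepwise procedure, including its greedy early stop (quit once the
  best score at k fails to beat k−1). The stopping rule is *not* globally
  optimal: on `M = [5, −5, 5]` with `c = 1` every k = 1 model scores below
  k = 0, so the early stop settles for the one-period model even though
  k = 2 scores higher; the tests pin this behavior down. After a stop, two
  further break counts are still tabulated "for reference" (flagged in
  `score_table()`, never selected as best).
* `search_dp()`: an exact dynamic program. The gain of a candidate period
  `[a, b]` is `sum over genes of max(0, sum(M[g, a:b]))`, memoized for all
  (start, end) pairs from per-gene prefix sums; `F(m, b)`, the best gain of
  the first `b` points in `m` segments, satisfies
  `F(m, b) = max_a F(m-1, a-1) + gain(a, b)`. Per-k scores equal the
  exhaustive ones (declared mode) to floating-point accuracy; the
  equivalence is asserted on 200 random instances in the acceptance suite.

Tie-breaks are deterministic everywhere: smallest k first, then the
lexicographically smallest break set in the exhaustive search; the dynamic
program resolves value ties toward the earliest last-segment start, which
can differ from the exhaustive choice only when two distinct optima tie
exactly (probability zero for continuous intensities).

`|G|` in the penalty is the number of rows of `M` — all-zero rows still
count, since the matrix declares them as modeled genes.

## The intensity estimator

The canonical route for real data is to ingest an externally computed
intensity matrix (`read_intensity()`). The built-in estimator
`loo_intensity()` is this package's own construction of the leave-one-out
idea: hold out each time point in turn, fit the regulated gene on its
parents over the remaining points, and score the held-out point by how
well the parent model predicts it.

Concretely, for gene `g` with parent design `X` and held-out point `j`:

1. Fit `y ~ 1 + X` on all points except `j`. By default the fit is a
   high-breakdown MM-estimator (`MASS::rlm`): in a time course the
   regulation may be *off* for a contiguous block of points, and those
   points must act as outliers to the fit rather than drag it — ordinary
   least squares attenuates the slope as soon as a sizeable block is
   decoupled, washing out the very contrast the segmentation needs.
   `fit = "huber"` and `fit = "ols"` are available; the OLS core
   (`fit_parent_model()`) uses pivoting for rank-deficient designs (a
   constant parent leaves the intercept at the child mean, flagged
   degenerate) and is also the numeric fallback when the robust fit fails,
   e.g. on exactly collinear data.
2. Let `s_model` be the robust residual scale (MAD; RSS-based for OLS),
   `s_null` the scale of the child's own variation, both floored at
   `sigma_floor`, and `rho_j` the held-out residual divided by
   `s_model · sqrt(1 + h_j)` — the externally studentized form, with the
   leverage term keeping end-of-ramp points from being spuriously flagged.
3. The intensity is

   ```
   M[g, j] = lambda * max(0, 1 - (s_model / s_null)^2) - min(rho_j^2, rho_cap^2)
   ```

The first factor is the (robust) fraction of the child's variance the
parents explain: near 1 when the gene genuinely tracks its regulators,
near 0 when it is decoupled from them — this is what makes a gene that
ignores a strongly varying parent score *negative* on average, which a
pure residual statistic cannot do (any residual standardized by its own
fit's scale has mean square ≈ 1 regardless of coupling). The second term
is the held-out surprise; under active regulation its mean is ≈ 1, so with
the default `lambda = 2` well-explained points score ≈ +1 and poorly
explained points negative. The cap (`rho_cap = 5`) bounds the influence of
any single aberrant measurement at `lambda − 25`, so one artifact cannot
veto a whole period on its own.

Properties that hold by construction and are asserted in the tests: exact
regulation gives `M ≡ lambda`; the estimate is invariant to affine
rescaling of the child; permuting time points permutes columns identically
(no temporal smoothing); a child decoupled from a strongly varying parent
has negative mean intensity.

Requirements: every regulated gene and all its parents in the profile, and
`|T| ≥ p + 3` for `p` parents. Edge signs are carried as metadata but not
constrained in the fit. A gene's self-loop is excluded from its own parent
design.

## Parameters at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `penalty_factor` (c) | 2 | per-break charge multiplier of `ln(|G|·|T|)`; 1 = plain score definition |
| `penalty_mode` | declared | which breaks are charged (see above) |
| `early_stop` | TRUE (exhaustive) | greedy stop once score stops improving |
| `lambda_offset` | 2 | intensity of a perfectly explained point |
| `sigma_floor` | 1e-8 | lower bound on estimated scales |
| `fit` | mm | leave-one-out regression flavor |
| `rho_cap` | 5 | cap on the studentized residual |

Units: time labels are numeric with an optional unit suffix (`min`, `h`);
all comparisons use the numeric value, so minute- and hour-scaled courses
are handled alike. Replicate columns sharing a time label are averaged at
load.

## Synthetic data and what the tests show

`planted_truth()` fixes a break set, a binary gene-by-period plan, active
and inactive intensity means (+1/−1 by default), a noise level (0.3) and
one seed; all generator randomness derives from that seed, so outputs are
bit-reproducible.

* `generate_intensity()` draws `M` directly:
  `Normal(mu_act, sigma)` in active cells, `Normal(mu_inact, sigma)`
  otherwise. The default plan is random but repaired so every break flips
  at least one gene — a break no gene crosses is unidentifiable by
  construction. Note that identifiability additionally requires the break
  *gain* (flipped genes × period length × |mu|) to exceed the penalty
  `c·ln(|G|·|T|)`; a single-gene flip over a short period is correctly
  rejected by the score, which is a feature of the BIC trade-off, not a
  failure. The recovery benchmark uses 20 genes × 20 points with breaks
  {5, 10, 15}, where random plans flip ~10 genes per break.
* `generate_expression()` emulates the upstream data: root genes follow a
  chosen signal (random walk by default, step sd = `signal_scale`; ramp
  and sine available), and each regulated gene follows a positively
  weighted combination of its parents plus `Normal(0, sigma_expr)` noise in
  active periods, or an *independent, freshly randomized* draw of the same
  signal family in inactive periods — independence is what makes
  inactivity detectable; a deterministic ramp re-draw would be an affine
  function of the parent and hence indistinguishable from regulation.

The end-to-end benchmark (expression → `loo_intensity` → `search_dp`) uses
one regulator driving four targets over 20 points, all targets active
through point 13 and decoupled after — an active-majority wave, the regime
a leave-one-out outlier-style estimator is designed for; with the break at
the midpoint neither regime dominates the fit and no estimator of this
family can anchor. At these settings the break is localized within ±1
index in ≥ 90 of 100 seeded replicates.

What passing these tests does **not** show about real data: microarray or
RNA-seq noise is neither Gaussian nor homoscedastic, real regulation is
nonlinear and lagged, networks are incomplete and partly wrong, and real
intensity matrices may come from a different estimator entirely. The
segmentation layer is agnostic to `M`'s origin, which is why ingesting an
externally computed matrix is the canonical real-data route.

## Numerical choices and degenerate inputs

* Period sums via per-gene prefix sums; the DP is `O(|T|^2·|G|)` for the
  gain table plus `O(k·|T|^2)` for the recursion.
* Zero period sum → inactive; zero period mean → "not controlled" in
  reports, consistently.
* `|T| = 1`: only the trivial k = 0 segmentation exists.
* Readers reject non-numeric cells, NaN, duplicate gene ids and
  non-increasing times with located errors rather than coercing.
* Intensities are written with 17 significant digits so TSV round-trips
  are value-exact.

## Problem sizes

The shipped test and acceptance runs use: 200 random instances with
`|G| ≤ 6`, `|T| ≤ 8` for the DP/brute-force equivalence; 100 replicates of
the 20×20 three-break recovery; 500 simulations of the decoupled-gene
calibration; 100 replicates of the 20-point end-to-end benchmark — sizes
at which exhaustive enumeration is still a practical oracle and the whole
suite runs in about a minute, while exercising every code path the larger
regimes use.

## Known limitations

* One activity state per gene (not per edge); a gene with several
  regulators gets a single on/off call.
* No uncertainty on break positions; the score surface near ties can be
  flat, and only the deterministic argmax is reported.
* The greedy early stop can under-segment (by design, to match the
  stepwise procedure); use `early_stop = FALSE` or `search_dp()` for the
  global optimum.
* The built-in intensity estimator assumes linear, lag-free regulation and
  an active majority of time points per gene; heavily inactive genes drift
  toward the "decoupled" regime where only the sign of the evidence, not
  its calibration, is meaningful.
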