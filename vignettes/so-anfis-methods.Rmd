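---
title: "Methods: season-optimized fuzzy models for irrigation analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: season-optimized fuzzy models for irrigation analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soanfis)
```

## The estimation problem

Orchard irrigation experiments produce small tabular datasets: one row per
monitored record with seasonal water consumption `Ir` (m³/ha), temperature
`T_emp` (°C), average relative humidity `RH_avg` (%), sunshine hours `S_sh`
(h) and rainfall `P_e` (mm), and a response — either economic yield (kg/ha)
or water-use efficiency (WUE, kg/m³). The response surface is smooth but
nonlinear and interacts across inputs, the sample is small (order 100 rows),
and the practitioner also wants to know *which* inputs matter. `soanfis`
addresses this with a Takagi–Sugeno–Kang (TSK) fuzzy rule base — a small
number of locally linear models blended by Gaussian memberships — trained by
a population metaheuristic, plus an input-combination selection workflow.

## Model and training procedure

A model has $n$ rules over $m$ inputs. Rule $i$ carries Gaussian premise
parameters $(c_{ij}, \sigma_{ij})$ per input and a linear consequent
$f_i(x) = s_{i1}x_1 + \dots + s_{im}x_m + s_{i0}$; the prediction is the
normalized firing-strength-weighted average of the $f_i$. Assumptions worth
stating explicitly:

* **Smoothness.** Gaussian memberships make the surface infinitely smooth;
  discontinuous responses are out of scope.
* **Local linearity.** Each rule is affine, so the model interpolates within
  the convex hull of rule outputs at each query point; it extrapolates
  linearly (with the nearest rule dominating) outside the data.
* **Homoscedastic noise.** Training minimizes unweighted RMSE.

Training alternates two estimators, following the classic neuro-fuzzy
decomposition:

1. **Premises** are searched by Seasons Optimization (SO) over the vector of
   all $(c_{ij}, \sigma_{ij})$ — dimension $D = 2nm$ — bounded per feature:
   centers within the observed `[min, max]`, widths within 1–100% of the
   feature range. Fuzzy c-means (FCM) provides the starting premises and
   that start vector is injected into the initial SO forest, so the
   metaheuristic can only improve on the deterministic initializer (the
   reference training loop is silent on seeding; this is our choice and it
   makes "optimizer never degrades the start" a testable invariant).
2. **Consequents** are re-solved *inside every* strength evaluation by
   ridge-regularized least squares on the global design matrix of normalized
   firing weights times $[x, 1]$. The normalization couples rules, so a
   global solve is the correct linear subproblem; per-rule local fitting was
   rejected. The ridge ($10^{-8}$ by default) exists purely to guarantee a
   finite solution for degenerate firings or more parameters than samples.

The strength function is $-\mathrm{RMSE}$ on the training partition (the
optimizer maximizes; negation preserves ordering and stays affine in the
criterion). Data are split once, uniformly at random with a seed, into
$\lceil 0.8n\rceil$ training and the remaining test rows — no
cross-validation, mirroring the single-split protocol the method was
published with.

## The Seasons Optimization metaheuristic

SO evolves a "forest" of $N$ candidate vectors through four operators per
generation: **renew** (spring: $\lceil p_r A\rceil$ uniform-random
immigrants, where $A$ is last autumn's seed count; skipped in generation 0),
**competition** (summer: the $\lceil p_c N\rceil$ strongest trees each claim
their nearest weaker trees as a neighborhood; neighbors take a Gaussian
growth step damped by a crowding index and the cored tree is replaced by its
strongest neighbor on a tie-or-better), **seeding** (autumn: the
$\lceil p_s N\rceil$ fittest each produce one offspring with 1 to $D-1$
components re-drawn across the full bound range) and **resistance** (winter:
the $\lceil p_w N\rceil$ weakest are removed and the forest is trimmed back
to capacity $N$ keeping the strongest). A single seeded generator drives all
randomness; the per-generation incumbent trace is non-decreasing by
construction.

Parameters, defaults, and why:

| parameter | default | meaning / rationale |
|---|---|---|
| `population_size` $N$ | 50 | reference setting for the estimation study |
| `fe_budget` | 3000 | total strength evaluations, counting initialization |
| `renew_rate` $p_r$ | 0.4 | mid-range; source gives no value |
| `competition_rate` $p_c$ | 0.3 | mid-range; fraction of cored trees |
| `seeding_rate` $p_s$ | 0.3 | mid-range; elitist offspring fraction |
| `resistance_rate` $p_w$ | $= p_s$ | the printed removal rate reduces algebraically to $p_s$; an override is exposed in case the identity is a typo |
| `asymmetry` $\gamma$ | 0.5 | discount of a weaker neighbor's crowding pressure |
| `growth_scale` $g$ | 0.01 | growth-step s.d. as a fraction of each bound width |

### Numerical choices where the published description is open

* **The growth step $\theta$** is undefined in the source. We use a
  per-dimension zero-mean Gaussian with s.d. $g\,(u_j - l_j)$ — a
  bound-scaled local move.
* **Damping placement.** The printed competition update divides the whole
  *position* by (crowding + 1), which is origin-dependent and collapses
  bounded domains toward zero. We damp only the increment,
  $T_j \leftarrow T_j + \theta/(\Lambda_j + 1)$, which is
  translation-invariant; `literal_growth = TRUE` reproduces the printed
  form (clamped) for comparison.
* **Negative-strength objectives.** The printed normalized strength
  $\tau_i = (S_i - \min S)/\sum S$ assumes positive strengths (as with a raw
  RMSE "strength"). Under the maximization convention callers pass
  $-\mathrm{RMSE}$, making the sum negative and $\tau$ non-positive — which
  would silently disable the whole competition phase. We therefore take the
  denominator in absolute value, and the damping as $1/(|\Lambda_j|+1)$;
  both reduce exactly to the printed formulas whenever strengths are
  positive. $\tau$ remains scale-dependent by construction — that is a
  property of the published rule, kept as printed.
* **Coincident trees** would make the inverse-square distance in the
  crowding index singular; distances are floored at $10^{-12}$.
* **Neighbor choice** ("neighborhood zone" is otherwise unspecified): the
  $Z_i$ nearest non-cored trees by Euclidean distance, drawn without
  replacement globally (strongest cored tree first), ties broken by index.
* **Budget accounting.** Every strength evaluation counts, including
  initialization; phases truncate their batch sizes so a run never exceeds
  the budget by more than one cycle.
* **Non-finite strengths** (e.g. a failed consequent solve) demote the
  candidate to $-\infty$ with a warning instead of aborting the run.

## Evaluation criteria

`compute_metrics()` implements $R^2$ (squared Pearson correlation), RMSE,
scatter index $SI = \mathrm{RMSE}/\bar w$, relative absolute error
$\delta\% = \sum|z_i - w_i| / \sum w_i \times 100$, and a Nash–Sutcliffe-style
efficiency. The published NSE variant normalizes by deviations of the
observations from the **predicted** mean $\bar z$ rather than the observed
mean; since this differs from the textbook definition, both are provided —
`nse_mode = "as-printed"` (default, recorded in the report) and
`"standard"`. `evaluate_combos()` trains the six candidate input sets on one
shared split and seed and flags the winner by test RMSE, breaking ties by
higher test $R^2$ then declaration order (our rule; none is published).
Where results and conclusion of the source disagree about which combination
won, the package takes no side: it reports all rows.

## Agronomy formulas

* **WUE** $= Y/(P_e + I + SW)$ with all water terms in m³/ha. $SW$ (soil
  depletion) is an *input*; no water-balance simulation is attempted.
* **Application efficiency** $= D_z/D_{app} \times 100$; `applied_depth()`
  converts inlet volume over area (1 L/m² = 1 mm).
* **Narrow-strip daily requirement**: the printed equation carries a
  spurious "=" between $ET_c$ and the shading factor; the only
  dimensionally sensible reading, implemented here, is
  $R_r = ET_c\,(h_s + 0.15(1 - h_s))$. Shading fractions outside the
  typical 0.5–0.7 orchard window warn rather than error.
* **Treatment comparison**: yield increases are expressed relative to the
  *reference* treatment's yield — the only base consistent with the printed
  8.57%/14.30% pair — and the relative mean-AE increase uses the reference
  mean as denominator (matches the printed "about 62.40%" to < 0.1 pp).
  The packaged per-event table is stored exactly as printed; some
  basin/furrow cells are internally inconsistent with $I_n/I_g$ and the
  package never silently "corrects" them.
* **CV classes**: `< 15` low, `15–35` moderate (boundaries included, "between
  15 and 35"), `> 35` great.

## The synthetic-data generator

The study's 120-record field table is not deposited, so everything
model-shaped is validated against synthetic tables from
`generator_spec()`/`generate_table()`:

* Features are drawn **independently and uniformly** within configured
  ranges. Only the `Ir` range ([3950, 4945.2] m³/ha) is anchored to the
  published descriptive statistics; the climate ranges (12–34 °C, 30–75%,
  6–14 h, 0–60 mm) are invented, plausible mid-latitude growing-season
  values. An optional Gaussian-copula correlation matrix exists but
  defaults off — no covariance structure is published.
* The target is a **planted 3-rule TSK surface** over the `w2` inputs
  (`Ir`, `P_e`, `RH_avg`, `S_sh`) plus Gaussian noise with s.d. = 2% of the
  clean target range by default. Consequent slopes are scaled by inverse
  feature range so each input carries comparable variance; the planted
  model is returned with the table so recovery is checkable.
* What a green test therefore establishes: the pipeline recovers a known
  surface of the assumed functional family from data with calibrated noise,
  and identifies the planted input set. What it does **not** establish:
  performance on real orchard records, with their correlations, monthly
  structure, measurement error and non-uniform marginals — none of which
  the generator emulates.

## Known limitations

* **Non-separable valleys.** The seeding operator redraws whole coordinates
  across their full range, which is effective on separable objectives
  (sphere-like; premise centers/widths are nearly separable once the other
  coordinates are good) but poor along curved, non-separable valleys; and
  the competition growth step is damped by $1/(|\Lambda_j|+1)$, which
  freezes it whenever strength magnitudes are large. On the 2-D Rosenbrock
  valley the optimizer does not reliably beat equal-budget uniform random
  search; the suite asserts the random-search oracle on the sphere only.
* **Recovery rate of the optimizer.** The published operator set refines
  mainly by full-range coordinate reseeding plus undirected damped growth on
  *neighbor* trees; there is no step-size adaptation. On noiseless in-space
  data, training error keeps improving with budget but approaches zero
  slowly — the suite therefore asserts strict improvement over the FCM
  start and high $R^2$, not convergence to machine-level training error.
  At the reference budget the method comfortably meets its own end-to-end
  bar (held-out $R^2 \ge 0.95$ on 18/20 seeds; see the acceptance tests).
* **Headline field statistics are not reproducible** ($R^2 = 0.988$,
  RMSE = 0.006 on the field test set): the field table is unavailable, so
  model-fit validation is property-based by design.
* The printed per-model "c/σ" membership summaries are too ambiguous to fix
  the rule count; `n_rules` is a configuration parameter, default 3.
* The published per-event table's basin/furrow AE cells are not consistently
  $I_n/I_g$; they are shipped as printed and flagged, not repaired.
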