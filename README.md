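# soanfis

Estimating crop **yield** and **water-use efficiency (WUE)** from irrigation
and climate records is a standard task in orchard water management: given
seasonal water consumption and a handful of weather covariates, which
regression surface best predicts what a treatment will deliver, and which
inputs matter? `soanfis` implements a hybrid estimator for this problem — a
first-order **Takagi–Sugeno fuzzy inference system** whose Gaussian premise
parameters are tuned by the **Seasons Optimization (SO)** population
metaheuristic — together with the irrigation agronomy arithmetic needed to
compare surface-irrigation treatments (basin, two-sided furrow, and
narrow-strip layouts).

It is aimed at agricultural-informatics researchers who want a reproducible,
testable implementation of the method, and at irrigation engineers who need
the supporting statistics (application efficiency, shaded-strip water
requirement, treatment comparisons) without spreadsheet arithmetic.

## The model

A model with $n$ rules over $m$ inputs $x = (x_1,\dots,x_m)$ predicts

$$\hat f(x) = \frac{\sum_{i=1}^{n}\mu_i(x)\, f_i(x)}{\sum_{i=1}^{n}\mu_i(x)},
\qquad
\mu_i(x) = \prod_{j=1}^{m}\exp\!\left[-\tfrac12\left(\frac{x_j - c_{ij}}{\sigma_{ij}}\right)^2\right],
\qquad
f_i(x) = s_{i1}x_1 + \dots + s_{im}x_m + s_{i0}.$$

Premises $(c_{ij}, \sigma_{ij})$ are initialized by fuzzy c-means and then
optimized by SO — a forest of candidate premise vectors evolved through
renew/competition/seeding/resistance operators — with the negated training
RMSE as the strength function; the linear consequents $s_i$ are re-solved by
ridge-regularized least squares inside every strength evaluation. Candidate
input sets `w1`–`w6` over `Ir` (seasonal water, m³/ha), `T_emp` (°C),
`RH_avg` (%), `S_sh` (sunshine hours) and `P_e` (rainfall, mm) are compared
by five criteria: $R^2$, RMSE, scatter index $SI = \mathrm{RMSE}/\bar w$,
relative absolute error $\delta\%$, and a Nash–Sutcliffe-style efficiency.

Agronomy helpers: WUE $= Y/(P_e + I + SW)$; application efficiency
$AE = D_z/D_{app}\times 100$; narrow-strip daily requirement
$R_r = ET_c\,(h_s + 0.15(1-h_s))$; coefficient-of-variation classes.

## Worked example

```r
library(soanfis)

# A synthetic 300-row feature table from a planted 3-rule fuzzy surface
# (the study's own field table is not public), noise = 2% of target range.
tab <- generate_table(generator_spec(n_samples = 300, noise_sd = 0.02,
                                     seed = 5))

cfg <- trainer_config(so = so_config(population_size = 50, fe_budget = 3000,
                                     seed = 3))
fit <- train_so_anfis(tab, standard_combos()$w2, "yield", cfg)
fit
#> SO-trained Takagi-Sugeno model
#>   inputs : Ir, P_e, RH_avg, S_sh
#>   target : yield
#>   train  : RMSE 305.9, R2 0.9775
#>   test   : RMSE 402.21, R2 0.9632
#>   evaluations: 3000
```

The held-out RMSE (≈ 400 kg/ha on a ≈ 10,000 kg/ha target range) sits close
to the injected noise floor, and the held-out R² ≈ 0.96 shows the planted
surface was recovered from 80% of the rows.

Treatment comparison from the packaged printed tables:

```r
compare_treatments(load_fixture("table5_summary"),
                   load_fixture("table4_events"), reference = "NSI")
#> Treatment comparison (reference: NSI)
#>   reference mean AE: 71.45%
#>  treatment wue_diff_kg_m3 yield_increase_pct mean_ae_pct ae_increase_pct
#>         BI           3.13             14.286       26.82           62.46
#>       TSFI           1.90              8.571       56.12           21.45
```

i.e. the narrow-strip treatment improves WUE by 3.13 and 1.90 kg/m³ over
basin and furrow irrigation, yield by 14.3% and 8.6%, and mean application
efficiency by 62.5% and 21.4% in relative terms.

## Command line

```sh
Rscript inst/cli/soanfis simulate --n 120 --noise 0.02 --seed 7 --out data.csv --truth truth.json
Rscript inst/cli/soanfis train --data data.csv --target yield --combo w2 \
    --rules 3 --fe 3000 --pop 50 --seed 7 --out model.json --report trace.csv
Rscript inst/cli/soanfis evaluate --data data.csv --target yield \
    --combos w1,w2,w3,w4,w5,w6 --seed 7 --out report.csv
```

Every flag can also come from a YAML/JSON file via `--config`.

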