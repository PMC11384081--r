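# tiapbms

Population-based model selection for time-integrated activity (TIA) in
radiopharmaceutical dosimetry.

## The problem

Absorbed dose in molecular radiotherapy is the product of a dose factor and
the time-integrated activity — the integral of an organ's activity–time
curve. Clinical time–activity data are sparse (often three scintigraphy
points per patient), and the TIA, especially its extrapolated tail, depends
heavily on which fit function is integrated. `tiapbms` selects that
function from the data of the *whole patient population* instead of each
patient alone:

1. **Candidates.** Eleven sums of one to three exponentials
   (`f2a` … `f6b`), every biological rate carrying the physical decay
   constant additively (default half-life 6.6443 d, Lu-177), with
   constraints `A_j >= 0`, `lambda_j >= 0`, `alpha` in `[0, 1]`. Each has a
   closed-form integral for the TIA.
2. **Population fit.** Each candidate is fitted to all patients jointly
   with a non-linear mixed-effects model: individual parameters
   `P_i = TVP * exp(eta_i)`, `eta_i ~ N(0, omega^2)` (diagonal), and
   multiplicative residual error `ln y = ln f(t; P_i) + eps`,
   `eps ~ N(0, sigma^2)`. The marginal likelihood is Laplace-approximated
   at the per-patient empirical-Bayes mode (Gauss–Newton curvature,
   analytic Jacobians, compiled inner solver).
3. **Gate and weights.** Fits must converge with
   `CV_k = sqrt(exp(se_k^2) - 1) < 0.5` for every fixed effect. Survivors
   are ranked by the small-sample corrected AIC,
   `AICc = -2lnP + 2K + 2K(K+1)/(N-K-1)`, converted to Akaike weights
   `w_i ∝ exp(-Delta_i/2)`.
4. **Model averaging.** Per-patient TIAs are computed from the
   empirical-Bayes parameters of every gate-passing candidate and combined
   as `TIA_MA = sum_i w_i * TIA_i` — the reference against which the
   single-function and baseline methods are compared via relative
   deviations and their RMSE.

Baselines (per-patient individual fits, IBMS, and the shared-parameter
population fit, SP-PBMS), frequency-based TIA uncertainty propagation
(Saltelli sampling through log-normal marginals, frequency 1028, 8193
evaluations), leave-one-out selection stability (Jackknife), and a
synthetic study-design cohort generator (13 patients, 46 observations,
known truth) are included. See the methods vignette
(`vignettes/tia-model-selection.Rmd`) for the full model description and
the design choices.

## Worked example

```r
library(tiapbms)

coh <- simulate_cohort(seed = 37)   # study-design cohort with known truth
sel <- pbms_select(coh, c("f2a", "f3a", "f3b", "f3c", "f4a"),
                   control = nlme_control(n_starts = 5))
sel
#> Population-based model selection: N = 46, gate CV < 0.50
#>   fn K neg2ll  AICc delta weight_pct max_CV passed
#>  f2a 5  -6.12  5.38   0.0      64.70  0.158    yes
#>  f3a 7  -6.61 10.34    NA       0.00  1.620      -
#>  f3b 7  -8.97  7.98   2.6      17.65  0.460    yes
#>  f3c 7  -8.97  7.98   2.6      17.65  0.459    yes
#>  f4a 9  -6.94 16.06    NA       0.00 30.900      -
#> Best supported function: f2a

ma <- model_average(sel)            # Akaike-weighted per-patient TIAs (min)
head(ma$tia_ma, 4)
#>   P01   P02   P03   P04
#> 199.8 237.7 258.3 154.0

ib <- fit_ibms(coh)                 # per-patient baseline (f2a, WLS)
tia_report(list(IBMS = tia(ib)[names(ma$tia_ma)],
                "NLME-PBMS (f2a)" = sel$tia[names(ma$tia_ma), "f2a"]),
           ma$tia_ma)
#> TIA comparison against the model-averaged reference (RD in %, sample-SD RMSE)
#>           method    mean (SD)    median [min, max]  RMSE
#>             IBMS -8.6 (100.9) -34.3 [-94.1, 197.4] 101.3
#>  NLME-PBMS (f2a)  -26.6 (2.2) -26.3 [-31.5, -22.7]  26.7
```

Reading the output: three candidates pass the goodness gate; the
mono-exponential `f2a` carries 65 % of the evidence and two equivalent
bi-exponential parameterisations share the rest, so the model-averaged
TIAs blend a mono-exponential core with a heavier tail. The per-patient
IBMS baseline, fitting three noisy points per patient in isolation,
scatters from −94 % to +197 % around the population reference — the
instability that motivates population-based selection in the first place.

Other entry points: `soe_nlme()` (one population fit, with
`print`/`summary`/`coef`/`predict`/`residuals`/`simulate`/`plot`
methods), `fit_sp_pbms()` (shared-parameter baseline, e.g.
`shared_value = 0.9632`), `tia_sd()` (frequency-sampled TIA SDs),
`pbms_jackknife()` (selection stability), `run_pipeline()` /
`run_config()` (end-to-end with report files).

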