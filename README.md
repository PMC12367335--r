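# wtlstm

Real-time prediction of intensive-care-unit (ICU) length of stay (LOS)
from three bedside vital signs — heart rate, respiration rate and SaO2 —
archived as 5-minute medians. No demographics, diagnoses or laboratory
results are required, so predictions are available from the first hours of
monitoring, including for unidentified patients.

## The model

Monitor series mix a slow, clinically meaningful trend with
high-frequency noise (device error, motion, transient interventions).
Each channel is therefore passed through a **level-2 discrete wavelet
transform (DWT) filter bank**: the signal is correlated with an orthogonal
low-pass filter (Daubechies-4 by default) and downsampled by two, twice,
keeping only the approximation branch — the detail branches are discarded
as noise. The denoised, z-scored channels feed an **LSTM** with the
standard cell

    f_t = σ(X_t·U_f + H_{t−1}·W_f)        C̃_t = tanh(X_t·U_c + H_{t−1}·W_c)
    i_t = σ(X_t·U_i + H_{t−1}·W_i)        O_t = σ(X_t·U_o + H_{t−1}·W_o)
    C_t = f_t ⊙ C_{t−1} + i_t ⊙ C̃_t       H_t = O_t ⊙ tanh(C_t)

and a linear head `w_out · H_T + b_out` yielding LOS in days. Training
follows the full protocol: stratified 56.25/18.75/25 % hold-out on the LOS
target, Adam over the learning-rate grid {0.08, 0.1, 0.12, 0.15}, batch
size 16, up to 100 epochs with early stopping and best-checkpoint
restoration, and seeded repeats. Baselines: linear regression on
per-channel mean/min/max, plain LSTM, and BiLSTM. Real-time operation uses
only the samples recorded before a 3/6/12/24-hour cutoff; stays shorter
than the window contribute all their data.

Because real ICU vitals databases are credentialed, the package includes a
**synthetic cohort generator** (lognormal right-skewed LOS driven by a
latent severity that also shifts the vitals, AR(1) drift plus white
monitor noise, missing samples) so every stage is testable offline, and
ships the published benchmark MSE table for the ten most frequent ICU
admission diagnoses (`benchmark_mse()`).

## Worked example

```r
library(wtlstm)

params <- cohort_preset("signal-rich", n_stays = 300, seed = 42)
cohort <- simulate_cohort(params)
cohort
#> <cohort_table>  300 stays, median LOS 2.65 d

cfg   <- train_config(model_kind = "wtlstm", window_hours = 3,
                      hidden_dim = 16L, seed = 42L)
split <- split_holdout(cohort, cfg)          # 56.25 / 18.75 / 25 %
fit   <- train_model(split$train, split$validation, cfg)
fit
#> <wtlstm_model wtlstm>  window 3 h, hidden 16, lr 0.15, best val MSE 0.370

report <- evaluate_model(fit, split$test)
report
#> <eval_report>  n 76 | MSE 2.447 d^2 | RMSE 1.564 d | R2 0.622
round(report$prediction_quantiles, 2)
#>   5%  25%  50%  75%  95%
#> 1.14 1.86 2.75 4.10 5.83
round(report$truth_quantiles, 2)
#>   5%  25%  50%  75%  95%
#> 1.05 1.83 2.63 3.99 7.72
```

The model was trained on 3 hours of monitoring only. MSE is in squared
days; the quantile rows compare the predicted and true LOS distributions —
as expected for an MSE-trained regressor, predictions concentrate toward
the cohort average and under-reach the long upper tail (95th percentile
5.8 vs 7.7 days).

Improvement arithmetic on the published benchmark table (percent MSE
reduction of the wavelet model over the plain LSTM, 24-hour inputs, ten
diagnosis cohorts):

```r
b <- benchmark_mse()
round(improvement_pct(b$mse_lstm, b$mse_wtlstm), 2)
#>  [1]  4.34  1.21  0.18 -0.08  2.64  9.61  0.84  4.09  7.29  2.85
round(mean(improvement_pct(b$mse_lstm, b$mse_wtlstm)), 1)
#> [1] 3.3
```

## Command line

A thin Rscript wrapper over the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "wtlstm.R", package = "wtlstm"))')
Rscript $CLI simulate --out data/ --preset signal-rich --n-stays 1000 --seed 7
Rscript $CLI train    --data data/ --out fit/ --model-kind wtlstm --window-hours 3 --seed 7
Rscript $CLI predict  --model fit/model.json --vitals data/vitals.csv --out preds.csv
Rscript $CLI evaluate --model fit/model.json --vitals data/vitals.csv --stays data/stays.csv --out eval.json
Rscript $CLI ablate   --data data/ --out abl/ --models wtlstm,lstm --windows 3,6 --repeats 2 --seed 7
```

Every command writes a provenance sidecar sufficient to re-create its
output; exit codes distinguish usage (64), data (65) and runtime (70)
errors.

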