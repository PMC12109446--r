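# gaitevents

Detection of gait events — heel strike (HS) and toe-off (TO) — from
thigh-mounted smartphone inertial recordings, and everything downstream of
them: millisecond-scale timing evaluation against an insole reference,
spatiotemporal gait parameters, and single-task vs dual-task walking
statistics.

## The problem and the approach

A smartphone strapped to the thigh records nine channels at 50 Hz:
acceleration (Ax, Ay, Az), angular velocity (Gx, Gy, Gz) and orientation
(Yaw, Pitch, Roll). An insole pressure sensor provides the reference
stance/swing trace (1 = stance, 0 = swing). The pipeline:

1. **Denoise** each channel with a scalar random-walk Kalman filter and a
   zero-phase 4th-order Butterworth low-pass (10 Hz), then drop the three
   channels that barely vary during level walking (Az, Gx, Pitch).
2. **Window**: pair *t* is the ω×C matrix of samples *t…t+ω−1* (ω = 40,
   i.e. 0.8 s) with label Y = stance at sample *t+ω*; pairs are split
   60/20/20 by subject, stratified by age group.
3. **Model**: three sequence architectures map a window to a stance
   probability — TCN-GRU, BiTCN-BiGRU, and BiTCN-BiGRU with multi-head
   cross-attention (queries from the BiGRU stream, keys/values from the
   BiTCN stream). All are implemented natively in R (forward, backward and
   Adam), trained with MAE loss against the 0/1 label, keeping the best
   validation epoch.
4. **Events**: threshold the probability trace at 0.5, debounce runs
   shorter than 100 ms, read HS at 0→1 and TO at 1→0 transitions, match
   greedily to reference events within 250 ms, and report per-kind MAE
   ± SD in milliseconds.
5. **Parameters**: per cycle with stride time *T* and stance time *s* —
   stance% = 100·s/T, swing% = 100 − stance%, cadence = 120/T steps/min,
   stride length L = a + b·(1/T) (speed-adaptive linear model, shipped
   calibration a = 0.5 m, b = 0.85 m·s), walking speed = L/T.
6. **Statistics**: paired two-sided t tests per parameter across tasks
   (STW/VFT/PTW) and Bland–Altman bias ± 1.96 SD limits of agreement.

Because real recordings of this kind are not publicly shareable, the
package includes a first-class synthetic generator
(`simulate_recording()`, `simulate_cohort()`) producing 50 Hz recordings
with gait-locked harmonics on six informative channels, a heel-strike
impact transient, noise, drift, cycle-to-cycle jitter, speed and dual-task
conditions, and *exact* ground-truth event times. All bundled experiments
and tests run end to end on it.

## Worked example

```r
library(gaitevents)

res <- run_gait_experiment(
  n_subjects = 20, omega = 40, epochs = 10,
  architecture = "bitcn_bigru_crossattn", seed = 1
)
tidy(res$evaluation)
#> # A tibble: 2 × 5
#>   event speed_condition     n mae_ms sd_ms
#>   <chr> <chr>           <int>  <dbl> <dbl>
#> 1 HS    normal             10   8.38  8.79
#> 2 TO    normal             12  22.0  17.3
glance(res$model)
#> # A tibble: 1 × 6
#>   architecture          n_parameters epochs_run best_epoch best_val_mae trained
#>   <chr>                        <int>      <int>      <int>        <dbl> <lgl>
#> 1 bitcn_bigru_crossattn        17697         10          5       0.0208 TRUE
```

Twenty synthetic subjects are simulated, preprocessed and windowed; the
cross-attention model is trained for 10 epochs on the training subjects;
and events detected on the held-out test subjects are scored against the
simulator's exact ground truth. Heel strikes land within ~8 ms and
toe-offs within ~22 ms on average — about one 20 ms sample at 50 Hz, i.e.
at the resolution floor imposed by the insole's sampling clock.

Gait parameters and the dual-task contrast:

```r
dt <- dual_task_experiment(n_subjects = 25, tasks = c("STW", "VFT"), seed = 1)
dt$comparison[, c("parameter", "mean_a", "mean_b", "t", "p", "significant")]
#> 8 rows: cadence, stride time, stance/swing phase, stance/swing time,
#> stride length, walking speed — all flagged significant (p < 0.05), with
#> cadence dropping from ~100 to ~84 steps/min under the cognitive dual task.
```

Plots: `autoplot(recording)` (channels with event markers),
`plot_trace(predict_trace(model, rec), rec)` (model output vs reference
label), `autoplot(model)` (loss curves), `autoplot(bland_altman(...))`.

A command-line surface over the same stages (simulate / train / evaluate /
params / compare) ships as `system.file("cli", "gaitpipe.R", package =
"gaitevents")`.

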