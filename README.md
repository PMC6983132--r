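# tremorkit

Quantification of kinetic tremor from digitizing-tablet circle drawings.

Kinetic tremor — a 4–9 Hz, highly intermittent oscillation during
voluntary movement — is a quality-of-life-limiting motor symptom of
Parkinson's disease. Clinical ratings (UPDRS item 21, or a finer 0–10
visual *tremor score*) are coarse and rater-dependent. `tremorkit` turns a
pen trajectory recorded while tracing a 130 mm circle template
(100 samples/s x/y position in mm plus pen pressure) into a continuous
tremor score, for researchers building or validating instrumented tremor
assessment.

The package implements the full multimodal chain:

* **tQ, a spectral tremor statistic.** The trajectory's combined
  spectrogram `STFTc(f,t) = |STFTx|² + |STFTy|²` is cut into 2-s segments;
  each segment's PSD has its `b·|f|^-α` leakage background removed by a
  robust (least-absolute-residuals) log-log fit over 2–26 Hz, and the
  residual power in 26 half-Hz bins over 2–15 Hz is scored as
  `tQ = W₍₂₆₎ / mean(W₍₁..₂₃₎)` — the dominant bin against the averaged
  background, harmonics excluded.
* **23 expert time-series parameters** per recording: band power above
  3 Hz, tQ and background statistics, transverse-velocity kinematics,
  pressure statistics, and multiscale sample entropy (m = 2,
  τ ∈ {5, 10, 25, 50}) of the high-passed transverse velocity.
* **Echo-state-network parameters.** Each recording (band-passed,
  decimated, reduced to its first principal component, IQR-normalized) is
  run through fixed random reservoirs
  `x(t) = (1−α)x(t−1) + α·tanh(Win[1;u(t)] + W x(t−1))` whose largest
  Lyapunov exponent is adjusted to a target (−0.2 or −0.05 ± 0.001) by an
  iterative spectral-radius search, and whose memory capacity MC is
  estimated from delayed-input reconstruction. Each reservoir yields 4N
  parameters: per-neuron activation RMS and SD, and the readout weights
  for one-step prediction and MC/2-step reconstruction.
* **LASSO score models and ensembles.** Models `ŷ = g(f(D))` with `f`
  linear, fitted by LASSO (λ chosen by 10-time 5-fold cross-validation at
  the minimum-MSE or 1-SE rule) and `g` a smooth limiter onto the rating
  scale. Reservoir models are averaged over a 216-member hyperparameter
  grid into ensembles that trade a little peak accuracy for much lower
  initialization variance.
* **A synthetic generator** of circle drawings with controllable,
  intermittent tremor, so the whole pipeline is testable and calibratable
  without clinical data.

## Worked example

```r
library(tremorkit)

# a 100-s drawing with a 1.5 mm, 5.3 Hz tremor active half of the time
rec <- simulateDrawing(syntheticSpec(tremorAmp = 1.5, tremorFreq = 5.3,
                                     intermittency = 0.5, seed = 7))
fv <- extractFeatures(rec)
round(fv[c("avg_tQ_max_log", "f_tQ_mod", "PSDc_var_3Hz_log",
           "Vt.HP.C5_MSEn_2_50")], 3)
#> avg_tQ_max_log  f_tQ_mod  PSDc_var_3Hz_log  Vt.HP.C5_MSEn_2_50
#>          3.207     5.250            -0.205               0.127
```

`avg_tQ_max_log = 3.21` says the dominant half-Hz band in the strongest
segments carries about 1600× the averaged background power — a clear
tremor; `f_tQ_mod = 5.25` localizes it in the bin containing the injected
5.3 Hz; the entropy at scale 50 is low because the tremor makes the
transverse velocity regular at that scale.

A full synthetic study — simulate a rated dataset, fit the time-series
model and the reservoir ensembles, evaluate on a held-out stratified
40% split:

```r
cfg <- pipelineConfig(n = 150, seed = 1)   # 18-member ensembles (N = 50)
report <- runPipeline(cfg)
report$m_ts$r                 # test-set Pearson r of the time-series model
#> [1] 0.9977895
report$m_esn_ts_ensemble$r    # r of the combined-feature ensemble
#> [1] 0.9976409
```

On these synthetic conditions the models recover the generated 0–10
scores almost perfectly — the synthetic amplitude-to-score map is exactly
monotone and noise-free, unlike clinical ratings — with the ensemble
markedly less sensitive to reservoir initialization than any individual
reservoir model.

A command-line front end over the same functions (subcommands `simulate`,
`features`, `train`, `predict`, `evaluate`, `run`) is installed at
`inst/cli/tremorkit.R`.

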