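# eegnda

Noise data augmentation analysis for multi-label EEG event classification.

## What this package is for

In grasp-and-lift brain-computer-interface recordings, 32 EEG channels are
sampled at 500 Hz while a person performs six hand actions (HandStart,
FirstDigitTouch, BothStartLoadPhase, LiftOff, Replace, BothReleased), each
marked by a binary trigger channel; actions overlap, so classification is
multi-label. `eegnda` implements an end-to-end analysis of how two kinds of
*noise data augmentation* (NDA) affect a compact convolutional classifier
trained on randomly drawn windows of such data:

* **Natural NDA.** Each training example is a window of *N* samples whose
  6-bit label is read from the trigger channels at a relative **offset**
  within the window — `start + floor(offset * (N - 1))`, so offset 0 labels
  at the window start, 0.5 at the middle, 1 at the end. Growing *N* pulls in
  neighbouring, action-irrelevant signal and dilutes the physical-action
  signal-to-noise ratio; the offset controls whether that "natural noise"
  precedes or follows the labelled instant.
* **Synthetic NDA.** Additive i.i.d. Gaussian noise on the z-scored
  signals, `X'(t) = X(t) + E(t)`, `E(t) ~ N(0, sigma^2)`, with sigma swept
  over {0, 0.001, 0.01, 0.1, 0.2}.

The experiment sweeps `N x offset x sigma`, trains one single-epoch
checkpointed CNN per cell (three conv stages of 32/64/128 filters with
kernels 3/5/7 along time, batch norm, (2,1) max pooling, dropout 0.1, dense
layers, six sigmoid outputs), and reports per-class, micro and macro
ROC-AUC, LOWESS-smoothed AUC-vs-N curves and steady-region summary tables
(mean +- sd, max, range).

Signal variability is then quantified with from-scratch **detrended
fluctuation analysis**: for a series x, the profile is the cumulative sum of
x minus its mean; F(n) is the RMS residual after per-window linear
detrending at scale n; F(n) ~ n^H defines the Hurst exponent, fitted over
all scales (H_full) and in short/long bands split at n = 1000 samples
(H_low, H_high; 2 s at 500 Hz). The estimator is validated against an exact
fractional-Gaussian-noise generator (Davies-Harte circulant embedding) of
known H.

A synthetic generator (`generate_eeg()`) emulates the structure of
grasp-and-lift data — six overlapping trigger series, 0.3 s events (150
samples), class-specific anticipatory lead-in activity, pink background
noise — so the whole pipeline is testable without the external dataset, and
a reader/writer (`read_gal()`, `write_gal()`) handles the Kaggle CSV
dialect (`*_data.csv` / `*_events.csv`) for real recordings.

## Worked example

```r
library(eegnda)

# 1. simulate a grasp-and-lift style recording
cfg <- synth_config(duration = 120, n_trials_per_class = 20,
                    lead_time = 0.2, lag_time = 0.2, snr = 1.2,
                    min_gap = 0.5, seed = 7)
gal <- generate_eeg(cfg)
gal$recording
#> <eeg_recording> 32 channels x 60000 samples @ 500 Hz (120.0 s)

# 2. one experiment cell: N = 400 windows labelled at the window middle
rec <- normalize_recording(gal$recording)$recording
batch <- sample_windows(rec, gal$timeline, n_window = 400, count = 500,
                        offset = 0.5, seed = 7, enrich_positive = 0.25)
folds <- split_windows(batch, seed = 7)
model <- build_model(model_spec(window_length = 400, seed = 7))
model
#> <cnn_model> N = 400, conv 32/64/128 (kernels 3/5/7), dense 128/64 -> 6 sigmoid; 817382 parameters
trained <- train_model(model, folds$train, folds$val,
                       train_config(epochs = 2, batch_size = 32, seed = 7))
scores <- predict(trained, folds$test)   # best-validation-loss checkpoint
auc <- micro_macro_auc(folds$test$labels, scores)
round(c(auc$per_class, micro = auc$micro, macro = auc$macro), 3)
#>          HandStart    FirstDigitTouch BothStartLoadPhase            LiftOff
#>              0.581              0.994              0.994              0.965
#>            Replace       BothReleased              micro              macro
#>              0.818              0.616              0.817              0.828
```

Test-fold AUC per class: 1.0 is perfect ranking of positive windows above
negatives, 0.5 is chance. Macro AUC (0.83 here) is the unweighted mean over
classes; micro AUC pools all class-label pairs. Per-class values vary from
seed to seed at this small scale — the sweep (`run_sweep()`) averages over
the N grid and summarizes the steady region for that reason.

```r
# 3. DFA of the action-related signal, with and without Gaussian noise
dfa <- run_dfa_stage(rec, gal$timeline, sigmas = c(0, 0.2), seed = 7)
head(dfa$table, 4)
#>             class sigma h_full h_low h_high
#> 1       HandStart   0.0   0.91  0.89   0.87
#> 2       HandStart   0.2   0.82  0.78   0.89
#> 3 FirstDigitTouch   0.0   0.94  0.93   0.93
#> 4 FirstDigitTouch   0.2   0.85  0.81   0.92
```

H near 0.5 indicates an uncorrelated series, H > 0.5 persistent long-range
correlation; adding sigma = 0.2 white noise pulls the short-scale exponent
H_low toward 0.5, as expected when an uncorrelated component is mixed into
a persistent signal.

The full experiment — grid sweep, steady-region tables, smoothed curves and
the Hurst table — is also available from the shell:

```sh
Rscript inst/exec/eegnda demo --out demo_run --seed 1
```

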