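# imtscast

Forecasting irregular multivariate clinical time series with multi-scale
patches, dual-domain patch encoders, and dynamic inter-variable graphs.

## The problem

ICU monitoring data are irregular multivariate time series: each variable
$X_i = \{(t_{i,j}, v_{i,j})\}$ is sampled at its own non-uniform times, with
80–96 % of a hypothetical hourly grid missing and no alignment across
variables. Given the history $X_{[0,T]}$ of all $N$ variables over an
observation window (default $T = 24$ h), the task is to predict every
variable's value at arbitrary future query times
$\tau \in (T, T+H]$ (default $H = 24$ h). The package is aimed at
methodologists working on irregular-sampling forecasting and at anyone who
needs a fully inspectable, CPU-trainable reference implementation of this
model family with a synthetic ground-truth cohort to test against.

## The method

1. **Multi-scale patching.** Each series is cut into temporally aligned,
   non-overlapping patches at scales $\{1, 2, 4, 8, 24\}$ h; patch
   $p$ at scale $s$ spans $[(p-1)L_s, pL_s)$ and within-patch times are
   rescaled to $[0,1)$.
2. **Dual-domain encoding.** Every non-empty patch is encoded by a
   transformable time-aware convolution (a meta-network generates a
   softmax-normalized filter per observation, so filter length adapts to the
   patch: $h[k] = \sum_j f_k[j]^\top z_j$ with
   $f_k[j,d] \propto \exp F_k(z_j)[d]$) and by an irregular Fourier analysis
   layer
   $[\cos(W_p x + U_p \tilde t) \| \sin(W_p x + U_p \tilde t) \|
   \mathrm{GELU}(B + W_{\bar p}x + V_{\bar p}\tilde t)]$
   mean-pooled over observations; the two are fused by a linear projection.
   Empty patches map to learned per-scale tokens.
3. **Scale fusion + transformer.** Embeddings are aligned to the finest
   (canonical) timeline, concatenated across scales, projected with GELU,
   and contextualized per variable by a pre-norm transformer encoder.
4. **Dynamic graphs.** Per canonical interval $k$, node features (tokens
   concatenated with Lomb–Scargle powers at fixed probe frequencies) yield
   $A_k = \mathrm{rowSoftmax}(\mathrm{ReLU}(E^{src}(E^{tgt})^\top))$, and a
   GCN with self-loops and symmetric normalization,
   $\mathrm{GELU}(\bar A_k \tilde M_k W)$, mixes the variables.
5. **Time-aware prediction.** The last interval's representation plus the
   normalized future time $(\tau - T)/H$ pass through a Fourier-style output
   layer and a linear head. Training minimizes the interval-weighted loss
   $\frac{1}{|Q|}\sum (1 + \alpha(\tau - T)) (\hat y - y)^2$ over scored
   queries (Adam, early stopping on validation loss).

Everything trains end to end through a small reverse-mode autodiff tape
included in the package; every backward rule is finite-difference checked in
the test suite.

## Worked example

```r
library(imtscast)

cfg <- cohort_config(n_episodes = 60L, seed = 7L)   # 8 variables, 85 % missing
sim <- simulate_imts_cohort(cfg)
sim$cohort
#> <imts_cohort> 60 episodes, 8 variables, T = 24 h, horizon = 24 h
#>   3862 observations, 1920 queries

splits <- split_episodes(sim$cohort, seed = 1L)      # 60/20/20 by episode
fit <- train_imts(splits$train, splits$valid,
                  model_config_small(max_epochs = 10L, lr = 0.003,
                                     batch_size = 8L),
                  seed = 1L)
fit
#> <imts_fit> 5973 parameters, trained 10 epochs (best epoch 9, monitored loss 2.09893)

fc <- forecast_queries(fit, splits$test)
dplyr::slice_head(fc, n = 3)
#>   episode_id variable_id query_time_hours prediction target_value scored
#> 1 ep0005               1             24.8      1.01        0.886  TRUE
#> 2 ep0005               1             35.4     -0.617      -0.0140 TRUE
#> 3 ep0005               1             44.9     -0.490      -0.0242 TRUE

evaluate_forecasts(fc)
#>     mse   mae  rmse   mre  mape n_queries n_mape_excluded
#> 1 0.926 0.782 0.962 0.990  391.       384               0
```

Predictions and targets are in standardized units (per-variable training
mean/sd); `forecast_queries(..., rescale = TRUE)` returns the raw scale. The
MSE of 0.93 after this 10-epoch demonstration run improves to ~0.82 at the
study settings (30+ epochs), close to the cohort's information ceiling — its
slowest planted rhythms are not identifiable from a 24 h window.

The learned inter-variable structure is summarized per episode and compared
against the planted coupling graph:

```r
eg <- episode_graphs(fit, splits$test)     # mean adjacency per episode + overall
graph_recovery_auroc(eg$mean, cfg$coupling_graph)
#> [1] 0.639     # rises above 0.7 at the study settings
autoplot(eg$mean)                          # heatmap of the mean learned graph
```

`run_robustness()` re-evaluates a trained model under additional point-wise
MCAR or block-wise missingness applied to the test set only, and
`run_ablation()` trains and scores the ablation variants (`-P` pre-aligned,
`-M` single-scale, `-F` no frequency branch, `-T` no transformer, `-G` no
graph) on a shared split. `tidy()`, `glance()` and `autoplot()` work on
fitted models; see the methods vignette (`vignettes/methods.Rmd`) for the
model, the simulator's design, and all numerical choices.

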