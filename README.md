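# mambasurv

Discrete-time cancer survival prediction from paired whole-slide-image
patch-embedding bags and genomic pathway-embedding bags.

Integrating histopathology with transcriptomics improves patient risk
stratification, but the two modalities arrive as *bags* of very different
shapes — a slide becomes N patch embeddings (N in the thousands, 768-d),
a transcriptome becomes K pathway embeddings (256-d) — and naive fusion
either ignores cross-modal correlation or discards modality-specific
signal. `mambasurv` implements a dual-stream token-mixer network for this
setting, aimed at methods researchers in computational pathology who want
a fully testable, CPU-scale reference implementation:

* each modality is encoded by a **convolutional Mamba mixer**: the
  channels split into a bidirectional **selective state-space scan**
  (global token mixing, zero-order-hold discretization
  `A_bar = exp(dt A)`, `B_bar = (dt A)^{-1}(exp(dt A) - I) dt B`) running
  in parallel with an **input-dependent depthwise convolution** (local
  mixing, kernels generated by grouped softmax attention over a learnable
  tap bank), finished by a squeezed token enhancer;
* **co-attention** bridges the streams: pathology queries aggregate
  genomic content (`softmax(Q_p K_g' / sqrt(d)) V_g`) and vice versa;
* pooled intra- and cross-modal representations `h, h_hat, g, g_hat` are
  summed and mapped to per-interval hazards
  `T_1..T_t = sigmoid(MLP(h + h_hat + g + g_hat))`, with survival
  `S(j) = prod_{u<=j}(1 - T_u)` and risk `-sum_j S(j)`;
* training minimizes the censored discrete-time negative log-likelihood
  plus an L1 **representation alignment penalty**
  `l_total = l_sur + alpha * l_sim`, `alpha = 0.03` by default.

Censoring convention throughout: `censor = 0` means the death was
observed, `censor = 1` censored — the opposite of several survival
libraries' event flag.

The package also provides the evaluation stack (Harrell's C-index,
Kaplan-Meier curves, log-rank test, median-risk stratification, 8-stratum
weighted sampling, leakage-free k-fold cross-validation), a synthetic
cohort simulator with a latent risk expressed in both modalities, every
component-ablation toggle, broom-style `tidy()`/`glance()` methods and
`autoplot()`s, and a thin CLI (`inst/cli/mambasurv`) with
`simulate` / `train` / `crossval` / `evaluate` / `ablate` subcommands.
All forward *and backward* passes are implemented in the package (R with
a compiled selective-scan kernel) and verified against finite differences
and naive-recurrence oracles — no deep-learning framework is required.

## Worked example

Simulate a strong-signal cohort, cross-validate, and stratify patients by
out-of-fold risk:

```r
library(mambasurv)

params <- sim_params(n_patients = 150, beta = 3, censor_rate = 0.3, seed = 42)
cohort <- generate_cohort(params)
cohort
#> <msurv_cohort> 150 patients | 27.3 % censored | t_bins = 4

# how well the hidden latent risk itself ranks the outcomes (the oracle)
truth <- sim_truth(cohort)
tab <- cohort_table(cohort)
concordance_index(tab$time_months, tab$censor, truth$latent_risk)
#> [1] 0.8963731

config <- run_config(d_model = 32, epochs = 8, folds = 3, seed = 1)
cv <- cross_validate(cohort, config)
tidy(cv)
#> # A tibble: 3 × 4
#>    fold c_index n_val  seed
#>   <int>   <dbl> <int> <int>
#> 1     1   0.580    50     2
#> 2     2   0.780    50     3
#> 3     3   0.693    50     4
glance(cv)
#> # A tibble: 1 × 3
#>   folds mean_c_index sd_c_index
#>   <int>        <dbl>      <dbl>
#> 1     3        0.685      0.100

strat <- risk_stratification(cv$predictions)
strat
#> <msurv_strat> log-rank chi2 = 33.05 , p = 8.96e-09 (significant)
```

The oracle concordance (0.896) is the ceiling any model can reach on this
cohort; a quick 8-epoch, 100-patient-per-fold fit recovers a mean
validation C-index of 0.685, and its median-risk split separates the
Kaplan-Meier curves decisively (p < 1e-8). `autoplot(strat)` draws the
two curves; `autoplot(cv)` and `autoplot(fit)` chart fold scores and
training losses.

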