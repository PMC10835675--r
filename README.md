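# depthformer

Sequencing depth across a hybridization-capture panel is rarely uniform:
probe-to-probe differences in hybridization kinetics — a function of the
probe sequence itself — leave some oligonucleotides saturated with reads
and others starved, forcing costly over-sequencing. **depthformer**
predicts per-probe read depth from sequence alone, so extreme probes can
be flagged or rebalanced at design time, and provides the interpretation
machinery to ask *why* a probe is predicted deep or shallow.

## The model

Observed depths are normalized to \(y_i = (\log_{10}(d_i + c) - \mu)/\sigma\)
(pseudocount \(c\), population moments \(\mu, \sigma\)), and a dual-encoder
transformer regresses \(y\) from sequence:

* each probe and its reverse complement are tokenized into overlapping
  k-mers (default k = 3; `L - k + 1` tokens per strand);
* tokens are embedded (scaled by \(\sqrt{d_{model}}\)) and summed with a
  sinusoidal positional encoding
  \(PE(pos,2i)=\sin\!\big(pos/1000^{2i/d_{model}}\big)\),
  \(PE(pos,2i+1)=\cos(\cdot)\);
* two independent transformer encoder stacks — the paired attention
  module — encode the two strands, reflecting that hybridization can
  initiate from either duplex end;
* the pooled strand vectors are concatenated and a two-layer
  feed-forward head emits the scalar depth; training minimizes MSE with
  AdamW.

Accuracy is reported as RMSE and Pearson's r on log10 depth plus the
factor-of-N accuracies **F2acc** and **F3acc** — the fraction of probes
predicted within a factor of 2 (resp. 3) of the observation,
\(|\log_{10}(d_{obs}/d_{pred})| < \log_{10} 2\) (resp. \(\log_{10} 3\)).
Interpretation tools include per-layer/head attention-score aggregation,
per-token integrated gradients with an asserted completeness identity,
extreme-depth probe extraction at Gaussian tail quantiles, k-mer
enrichment of the extreme sets, and Kendall-τ rank correlation against
externally computed thermodynamic metrics. A synthetic panel generator
with a known sequence→depth law (GC effect + planted motifs + log-scale
noise) makes the whole pipeline testable without external data; see the
methods vignette (`vignettes/depth-modeling.Rmd`) for the modeling
decisions and their rationale.

## Worked example

```r
library(depthformer)

# a synthetic panel with a known depth law: GC effect 0.8, motif CTT +0.3
params <- synthetic_params(n_probes = 1200, length = 60, beta_gc = 0.8,
                           motif_effects = c(CTT = 0.3), noise_sd = 0.15,
                           seed = 42)
panel  <- simulate_panel(params)
train  <- panel$probes[1:900, ];    class(train) <- class(panel$probes)
test   <- panel$probes[901:1200, ]; class(test)  <- class(panel$probes)

cfg <- model_config(k = 3, d_model = 64, n_layers = 2, n_heads = 4,
                    ffn_dim = 128, max_len = 64, head_hidden = 64, seed = 42)
nz  <- normalize_depths(train)
fit <- train_model(depth_model(cfg), train, nz$params,
                   train_config(epochs = 20, batch_size = 64,
                                learning_rate = 1e-3, seed = 42))

pred <- predict(fit$model, test, nz$params)
compute_metrics(observed_log10(test, nz$params), pred)
#> <metrics_report> n=300  RMSE=0.1823  r=0.8718  F2acc=91.33%  F3acc=99.33%

integrated_gradients(fit$model, test[1, ], steps = 64)
#> <attribution_result> probe_00901: 59 tokens, pred 2.0808, baseline -0.3727,
#>   completeness gap 4.59e-04 (64 steps)
```

Reading the metrics: on 300 held-out probes the model explains most of
the depth variation (r = 0.87 against a generator signal-to-noise ceiling
of ~0.9); 91% of probes are predicted within a factor of two of their
observed depth and 99% within a factor of three. The attribution output
shows the per-probe integrated-gradients decomposition: the 59 token
attributions sum to the prediction minus the all-`<pad>` baseline
prediction up to a completeness gap of 5e-4.

File-based workflows use the same machinery through `cmd_simulate()`,
`cmd_train()`, `cmd_predict()`, `cmd_evaluate()`, `cmd_cv()` and
`cmd_interpret()` (every run writes a manifest with config, seed and
input checksums), or from a shell via the thin wrapper
`inst/scripts/depthformer.R`:

```sh
Rscript inst/scripts/depthformer.R simulate --out-dir panel --n-probes 3000 --seed 1
Rscript inst/scripts/depthformer.R train --fasta panel/probes.fasta \
    --depth-table panel/depths.tsv --out-dir run --seed 1
Rscript inst/scripts/depthformer.R cv --fasta panel/probes.fasta \
    --depth-table panel/depths.tsv --out-dir cv --n-folds 5
```

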