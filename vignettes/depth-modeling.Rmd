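---
title: "Modeling probe sequencing depth with a dual-strand transformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling probe sequencing depth with a dual-strand transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Hybridization-capture panels enrich genomic targets with thousands of
synthetic oligonucleotide probes before sequencing. The kinetics and
thermodynamics of hybridization differ from probe to probe, so read depth
is uneven: some probes capture far more than their share of reads, others
almost none, and the whole panel must be over-sequenced to rescue the weak
ones. Because those kinetics are a function of the probe sequence, depth
is predictable from sequence alone — and a designer who can predict depth
can drop or rebalance extreme probes before ordering the panel.

depthformer models

\[ \log_{10} d_i = D(s_i;\theta) + \varepsilon_i \]

where \(d_i\) is the observed read depth of probe \(i\), \(s_i\) its
sequence, and \(D\) a dual-encoder transformer. Observed depths are
log10-transformed (with a pseudocount, default 1, so zero-depth probes
stay finite) and z-scored to a standard normal using the **population**
standard deviation, which makes the normalized training targets have mean
0 and standard deviation exactly 1 — convenient both numerically and for
interpreting errors. The fitted normalization is stored with every
checkpoint so predictions can be mapped back to the
\(\log_{10}(d + \text{pseudocount})\) scale where all metrics live.

## Architecture

Each probe is processed twice: as given, and as its reverse complement.
The rationale is physical — hybridization can initiate from either end of
the duplex, and the two strands present different stacking contexts — so
the two views are encoded by two **independent** transformer encoder
stacks (the paired attention module). Concretely:

1. **Tokenization.** Overlapping k-mers (default k = 3), a sliding window
   of stride one, so a probe of length \(L\) yields \(L-k+1\) tokens. The
   vocabulary is the \(4^k\) k-mers in lexicographic order plus `<pad>`,
   `<unk>` (k-mers containing N) and `<cls>`.
2. **Embedding.** A learned token embedding, scaled by
   \(\sqrt{d_\text{model}}\), plus a fixed sinusoidal positional encoding
   \(PE(pos, 2i) = \sin(pos / b^{2i/d_\text{model}})\),
   \(PE(pos, 2i+1) = \cos(\cdot)\) with base \(b = 1000\) by default
   (the canonical transformer value 10000 is a config option). The
   \(\sqrt{d_\text{model}}\) factor matters: without it a 0.02-sd token
   embedding is ~2% of the unit-amplitude positional signal and the
   network starts essentially blind to sequence.
3. **Encoders.** `n_layers` post-layer-norm blocks per strand
   (multi-head self-attention, then a GELU feed-forward sublayer), with
   dropout on each sublayer output during training. Defaults:
   `d_model = 256`, 6 layers, 8 heads, feed-forward width
   \(4 d_\text{model}\), dropout 0.1.
4. **Pooling and head.** Each strand's encoder output is pooled to one
   vector, the two vectors are concatenated (\(2 d_\text{model}\)) and a
   two-layer feed-forward head (ReLU hidden layer, then linear) emits the
   scalar normalized depth. `use_pam = FALSE` drops the reverse branch for
   ablation experiments; `tie_encoders = TRUE` shares encoder weights, and
   together with `symmetric_head = TRUE` (sum instead of concatenation)
   makes the prediction exactly invariant to reverse complementation —
   a useful symmetry check, not the default, since the untied encoders are
   the point of the dual design.

Training minimizes mean squared error on the normalized scale with AdamW
(constant learning rate, global gradient-norm clipping at 1.0); shuffling
and dropout are driven by one seed, so a run is exactly reproducible on
the same hardware.

### Why mean pooling is the default

With pretrained encoder weights the conventional choice is to read the
`<cls>` position. From a **random** initialization, however, the `<cls>`
state receives sequence information only through attention outputs that
pass two freshly-initialized 0.02-sd weight matrices: at initialization
the pooled vector varies by parts in \(10^4\) between completely different
sequences. Under that signal-to-noise the cheapest way for the optimizer
to reduce MSE is to predict the panel mean, and the model reliably
collapses to a constant (we observed training loss pinned at 1.0 and
prediction variance exactly zero). Mean pooling routes token content into
the pooled vector directly through the residual stream, and the same
model trains cleanly. The package therefore defaults to mean pooling and
keeps `first_token` as the natural option when warm-starting from
pretrained weights (loading external weights is supported via the
`params` argument of `depth_model()`, but reproducing a pretrained
natural-language encoder is out of scope).

## Evaluation metrics

All metrics are computed on \(\log_{10}\) depth:

* **RMSE** — root mean squared error \(\sqrt{\tfrac1N\sum_j e_j^2}\) with
  \(e_j = \log_{10} d_{obs}(j) - \log_{10} d_{pred}(j)\);
* **Pearson's r** — the product-moment correlation;
* **F2acc / F3acc** — the fraction of probes predicted within a factor of
  2 (resp. 3) of the observation: \(|e_j| < \log_{10} 2\) (resp.
  \(\log_{10} 3\)). F3acc ≥ F2acc always, since the thresholds nest.

The factor-of-N reading of F2acc/F3acc follows the metric names; the
thresholds are configurable in `compute_metrics()`.

Cross-validation (`cross_validate()`, default 5 folds) shuffles probes
with a seeded permutation into equal-size folds, fits the depth
normalization **on the training folds only** (no leakage of held-out
depths into the targets — a property the test suite asserts by injecting
an extreme probe into a held-out fold), trains a fresh model per fold and
reports per-fold metrics, pooled out-of-fold metrics, and the standard
deviation of RMSE across folds. Both pooled and per-fold views are
reported because either convention is common.

## Interpretation machinery

**Attention aggregation.** For each branch, layer and head the package
sums the softmax attention weights over all query/key pairs and all
sequences. Because each softmax row sums to one, this aggregate is
*conserved*: one sequence of \(T\) query positions contributes exactly
\(T\) per head, and the statistic is additive over the dataset — useful
as a structural check, but by construction identical across heads and
branches. To actually compare where heads attend, the summary also
reports a **concentration** statistic, the sum of squared attention
weights, which is maximal for one-hot attention and minimal for uniform
attention; for untied trained encoders the forward and reverse
concentration profiles genuinely differ. Both are emitted in the
long-format table (`branch`, `layer`, `head`, `score`, `concentration`)
ready for heatmaps.

**Integrated gradients.** Per-token attributions are the path integral of
the model's gradient along a straight line in embedding space from a
baseline to the input, approximated by a midpoint Riemann sum (default 64
steps; exact for linear functions at any step count). The default
baseline is the all-`<pad>`-token embedding — a concrete, near
zero-information input in the model's own domain; an all-zero embedding
baseline is available. Both strand branches are attributed against the
baseline; reverse-branch values are mapped back to forward coordinates
(reverse token position \(p\) ↔ forward position \(T-1-p\)) and summed,
so one profile per probe lives on the forward token axis. The
completeness identity \(\sum_i IG_i = f(x) - f(\text{baseline})\) is
computed and stored for every attribution (tolerance used in testing: 5%
relative + 10⁻³ absolute at 128 steps) — it is asserted, never assumed.
`positional_importance()` averages \(|IG|\) per token position across
probes of equal length, the plot-ready positional profile.

**Extreme-depth analysis.** On z-scored depths, probes beyond the
standard-normal quantiles at a tail rate (default 5% *per tail*, i.e.
\(z > 1.645\) or \(z < -1.645\); the rate is configurable, since "5%"
could also be read as total) form the extreme-high and extreme-low sets.
`kmer_enrichment()` compares k-mer frequencies of a set against the
panel, guarding empty background cells with a pseudo-frequency of one
over the group's k-mer total; `sequence_composition()` reports mono- and
dinucleotide frequencies, so both readings of "CT content" (C+T base
composition versus the CT dinucleotide) can be inspected.
`thermo_correlation()` computes Kendall's τ-b (via `stats::cor`, which
handles ties) between a per-probe attribution statistic and externally
computed thermodynamic metrics, consumed as a TSV — computing free energy
or secondary-structure stability is deliberately out of scope.

## The synthetic panel generator

Real panels require external sequencing archives and full-scale training,
so the package ships a generator with a *known* sequence-to-depth law:

\[ \log_{10} d = \beta_0 + \beta_{GC}\,GC(s) +
   \sum_m \beta_m \sum_{\text{occ}} w(\text{pos}) + \varepsilon,\qquad
   \varepsilon \sim N(0, \sigma^2) \]

i.i.d. uniform-random sequences; additive effects on the log10 scale (so
multiplicative depth effects are additive here, matching the modeling
scale); overlapping motif occurrences each count; and an optional
triangular positional weight (1 mid-probe, 0 at the ends) that emulates
the empirical pattern of mid-probe nucleotides mattering most. The
standard study conditions used throughout the tests are: probes of 60 nt,
3000 training / 1000 held-out, \(\beta_{GC} = 0.8\), one planted motif
`CTT` with effect +0.3, noise sd 0.15 — which puts the correlation
between true and observed log10 depth near 0.9, i.e. a strong but not
noise-free signal. A 110 nt fixed-length panel emulates the
information-storage-style synthetic panels of real studies.

What the generator does **not** emulate: nearest-neighbor hybridization
energetics, cross-hybridization between probes, library-preparation
artifacts, and length variation within a panel. Passing the recovery
tests therefore demonstrates that the architecture, training loop and
attribution machinery work end-to-end on a planted compositional signal —
not that the model reaches any particular accuracy on real capture data.

## Numerical choices

* Training runs in single precision inside the compiled core (parameters
  and the AdamW state stay double on the R side); exactness-sensitive
  paths (gradient checks, symmetry tests) run the same templated code in
  double. Forward results agree across precisions to ~10⁻⁷ relative.
* Layer norm uses ε = 10⁻⁵; GELU is exact (erf), its derivative
  analytic; softmax is computed with the row-max subtracted.
* Weights are initialized \(N(0, 0.02^2)\), biases zero, layer-norm gains
  one; the token-embedding table is shared between branches (the strands
  read the same alphabet; the encoders, not the embeddings, are strand
  specific).
* Batches are padded with `<pad>` ids for transport only: the core
  truncates each sequence to its true length before any computation, so
  padding cannot influence predictions even in principle.
* Dropout masks come from a per-step, per-sequence seeded RNG, making
  training histories bit-reproducible for a fixed seed.

## Problem sizes in the test suite

The suite exercises full training at desk scale, chosen so everything
runs comfortably on one CPU: the recovery study trains the compact
2-layer / 64-dimensional configuration (4 heads, feed-forward width 128)
for 30 epochs on 3000 probes across three seeds; the memorization sanity
floor trains the full-size default architecture on a 16-probe panel until
it overfits (training RMSE < 0.05, reached well within 500 full-batch
steps); attribution tests use 32-128 Riemann steps. Stochastic
end-to-end checks (held-out r ≥ 0.6; attribution localizing on planted
motif positions) are majority votes over the three seeds, not single-run
assertions.

## Known limitations

* Random initialization is the only fully supported training regime;
  first-token pooling underperforms there (see above) and is intended for
  warm starts.
* The BPE-tokenization ablation baseline is not implemented: it requires
  a subword vocabulary learned from a natural-language corpus, which has
  no meaningful counterpart here.
* Attention extraction stores per-sequence per-head aggregates only;
  full \(T \times T\) maps are available in principle from the core but
  not exposed, to keep memory bounded on large panels.
* Depth is consumed from a table; alignment and depth calling from
  BAM/CRAM are out of scope, as is computing hybridization
  thermodynamics.
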