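# hdbncaen

Binary disease-risk classification for mixed-type clinical tabular data, built
around two cooperating models:

- **HDBN** — a *hybrid deep belief network*: a stack of Bernoulli restricted
  Boltzmann machines (RBMs) pretrained greedily with contrastive divergence,
  then unrolled into a logistic feed-forward network with a softmax head and
  fine-tuned on labels.
- **CAEN** — a *custom adaptive ensemble network* that aggregates the HDBN, a
  dense feed-forward network and a single-head self-attention network, with
  weights set dynamically from validation performance.

The package is aimed at methodologists who want a fully inspectable,
dependency-light reference implementation of this three-phase pipeline —
preprocessing, deep-belief feature extraction, adaptive ensembling — with
exact small-model oracles (enumerated partition functions, finite-difference
gradient checks) wired into the test suite, plus a seeded synthetic-data
generator so every stage is verifiable against known ground truth.

## The model

An RBM over binary visibles `v` and hiddens `h` has energy

    E(v, h; θ) = − Σᵢⱼ vᵢ Wᵢⱼ hⱼ − Σᵢ bᵢ vᵢ − Σⱼ cⱼ hⱼ,   θ = (W, b, c)

with Boltzmann joint `P(v, h) = exp(−E) / Z` and partition function
`Z = Σ_v Σ_h exp(−E)`. Pretraining follows contrastive divergence,

    ΔWᵢⱼ = η ( ⟨vᵢhⱼ⟩_data − ⟨vᵢhⱼ⟩_model ),

with the model term approximated by a k-step Gibbs chain started at the data.
Fine-tuning and the other learners minimize cross-entropy plus an L2 penalty,
`L = (1/N) Σ Loss(yᵢ, ŷᵢ) + λ‖W‖²`, by mini-batch gradient descent
`w ← w − η ∂L/∂w` (Adam available), with learning-rate decay, dropout and
early stopping.

The ensemble predicts `Ŷ = Σₘ wₘ Ŷₘ` over the M = 3 base learners, with
weights from the softmax adjustment rule

    wₘ = exp(−Lₘ) / Σⱼ exp(−Lⱼ),

where `Lₘ` is learner m's validation cross-entropy — lower-loss learners get
strictly higher weight, and weights are recalibrated iteratively when
aggregated validation performance falls below a threshold.

Evaluation covers the full confusion-matrix family (accuracy, precision,
recall, specificity, FPR, FNR, FDR, MCC) and segmentation overlap metrics
(Dice, SSIM, proportion of correct patches) for mask pairs.

## Worked example

```r
library(hdbncaen)

# synthetic study: 4 Gaussian features, class means 1 sd apart
spec <- synth_spec(n_samples = 2000, n_numeric = 4, mean_separation = 1, seed = 1)
data  <- synth_tabular(spec)
parts <- stratified_split(data, seed = 1)            # 70/15/15

cfg <- train_control(epochs = 40, pretrain_epochs = 10, optimizer = "adam", seed = 1)
fit <- caen(design_matrix(parts$train), parts$train$labels,
            design_matrix(parts$valid), parts$valid$labels,
            config = cfg, layer_sizes = c(16, 8))
print(fit)
#> Custom adaptive ensemble network (3 base learners)
#>   weights: hdbn 0.267, dense 0.356, attention 0.377
#>   validation cross-entropy: 0.6870, 0.3979, 0.3404
#>   recalibration iterations: 1

cm <- confusion_matrix(parts$test$labels,
                       predict(fit, design_matrix(parts$test), type = "class"))
print(classification_report(cm))
#> accuracy 89%  precision 86%  recall 93%  specificity 84%
#> FPR 0.1575  FNR 0.0719  FDR 0.1394  MCC 0.7745

bayes_accuracy(spec)   # 0.8413 — the ceiling no classifier can beat
```

The ensemble weights mirror the validation losses (the attention learner,
with the lowest cross-entropy 0.34, gets the largest weight 0.377), and the
300-row test accuracy (89%) sits at the generating model's Bayes ceiling up
to sampling noise.

A thin shell entry point wraps the same functions:

```sh
Rscript inst/cli/hdbncaen run --config cfg.yaml --out out/ --seed 1
```

with subcommands `simulate`, `run` and `evaluate`; the YAML config keys and
defaults are those of `load_run_config()`.

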