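# sdaehar

Recognising human daily activities — static postures, dynamic movements
and the short postural *transitions* between them — from six-axis
wrist-worn inertial data (tri-axial accelerometer + tri-axial gyroscope),
with a stacked denoising autoencoder (SDAE) trained from scratch.

Transitional activities (stand-to-sit, sit-to-stand, stand-to-walk,
walk-to-stand, lie-to-sit, sit-to-lie) last seconds rather than minutes,
so a segmented dataset is heavily imbalanced (~5:1) against them and a
naive classifier collapses onto the sustained classes. `sdaehar`
implements the full pipeline that addresses this, for researchers and
students in human activity recognition who want an auditable,
dependency-light reference implementation:

1. **Synthetic study generator** — labelled six-channel recordings for 12
   activities across 10 subjects (no public recordings accompany the
   package), with CSV interchange.
2. **Segmentation** — sliding windows of 512 samples (5 s at 102.4 Hz)
   with 50% overlap, flattened channel-block-wise into instances of
   length M = 6 × 512 = 3072.
3. **Rebalancing** — random oversampling, random undersampling, or SMOTE
   (synthetic minority points `x + r (xn − x)` toward one of k = 5 nearest
   same-class neighbours).
4. **Standardization** — per-feature z-score then min–max rescale to
   [0, 1] (train statistics only), the domain the reconstruction loss
   requires; random 6:2:2 train/validation/test split.
5. **SDAE** — sigmoid encoder/decoder layers (default 3072→500→500),
   masking corruption with probability a = 0.5, summed binary
   cross-entropy `L(x, z) = −Σ[x log z + (1−x) log(1−z)]` against the
   clean input, greedy layer-wise pretraining, then a softmax head
   fine-tuned end-to-end by backpropagation (decoders frozen).
6. **Evaluation** — confusion matrix and per-class / overall Accuracy,
   Precision, Recall, F1 = 2PR/(P+R), micro or support-weighted.

Every stage is deterministic under explicit seeds; all gradients are
analytic and finite-difference checked.

## Worked example

A reduced three-subject study, oversampled, trained at a reduced epoch
budget (3 pretraining epochs per layer, 25 fine-tuning epochs at rate 0.5
— with plain gradient descent, rate × epochs is what fixes training
distance):

```r
library(sdaehar)

proto <- study_protocol(n_subjects = 3, seed = 2026)
cfg <- run_config(
  protocol = proto,
  plan = resample_plan("oversample"),
  train = train_config(hidden_sizes = c(500, 500), corruption = 0.5,
                       pretrain_lr = 1e-7, pretrain_epochs = 3,
                       finetune_lr = 0.5, finetune_epochs = 25,
                       batch_size = 64, seed = 7),
  seed = 123
)
run <- har_run(cfg, quiet = TRUE)
print(run)
print(run$report)
```

```
<har_run> paper mode, acc+gyr channels
  test accuracy (micro): 97.67%
Per-class metrics (%):
         class support accuracy precision recall     f1
      standing      79   100.00      79.8 100.00  88.76
      sleeping      71   100.00     100.0 100.00 100.00
   watching_tv      73   100.00     100.0 100.00 100.00
       walking      64    68.75     100.0  68.75  81.48
       running      58   100.00     100.0 100.00 100.00
      sweeping      67   100.00     100.0 100.00 100.00
  stand_to_sit      75   100.00     100.0 100.00 100.00
  sit_to_stand      60   100.00     100.0 100.00 100.00
 stand_to_walk      75   100.00     100.0 100.00 100.00
 walk_to_stand      80   100.00     100.0 100.00 100.00
    lie_to_sit      84   100.00     100.0 100.00 100.00
    sit_to_lie      71   100.00     100.0 100.00 100.00

Overall (%):
     mode accuracy precision recall    f1
    micro    97.67     97.67  97.67 97.67
 weighted    97.67     98.14  97.67 97.58
```

Reading the table: per-class `accuracy` repeats recall (the convention of
activity-recognition result tables); a fifth of the walking windows were
taken for standing, which costs walking recall and standing precision;
micro averaging makes overall precision = recall = accuracy identically
for single-label multiclass prediction. With the default 10-subject
protocol the same configuration reaches 100% test accuracy under the
default pipeline ordering — see the vignette's discussion of why the
classical rebalance-before-split ordering inflates test scores, and the
`mode = "leakfree"` alternative.

A command-line front end wrapping the same functions lives in
`inst/cli/sdaehar` (subcommands `simulate`, `segment`, `rebalance`,
`train`, `evaluate`, `run`, `sweep`).

## Vignette

`vignettes/activity-recognition.Rmd` documents the model and its
assumptions, every default and why, what the synthetic generator does and
does not emulate, the stage-ordering/leakage trade-off, and numerical
conventions.
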