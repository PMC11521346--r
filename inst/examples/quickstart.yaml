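# Minimal end-to-end run on a simulated cohort: contrastive encoder +
# elastic-net Cox head, with the raw-expression ablation arm, evaluated by
# 2-repeat Monte-Carlo cross-validation.
seed: 1
data:
  simulate:
    "n": 150
    p: 40
    k: 3
    effect_size: 1.5
    censor_rate: 0.3
encoder:
  layer_widths: [32, 8]
  learning_rate: 1.0e-5
  max_epochs: 80
  min_epochs: 30
  patience: 40
models:
  cox_heads: [elastic_net]
  ablation: true
evaluate:
  repeats: 2
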