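# Example experiment configuration: desk-scale preset with a smaller source
# domain and a reduced balanced-fine-tuning sample. Any field not listed
# keeps its preset default. Load with load_experiment_config().
preset: desk_scale
seed: 7
scenes:
  n_source: 120
  n_target: 40
dg:
  n_sample: 30
  epochs_finetune: 10
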