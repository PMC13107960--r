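# Example run configuration for `nummolgen pretrain --config ...`
stage: pretrain
seed: 0
out_dir: runs/pretrain_demo
options:
  corpus: fixtures/corpus.smi    # one SMILES per line (from `nummolgen fixtures`)
  vocab: default
  epochs: 60
  batch_size: 32
  lr: 0.003
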