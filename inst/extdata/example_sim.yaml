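# Example synthetic-experiment configuration.
# 300 samples on 3 plates (one batch); one plate carries a strong
# B-channel shift, 2% of cells take a bubble/scratch artifact, and one
# probeset cross-hybridizes.
n_samples: 300
n_plates: 3
plates_per_batch: 3
seed: 20260912
artifact_rate: 0.02
batch_shift:
  - plate_id: P002
    shift: 1.8
    channel: B
probesets:
  - probeset_id: PS001
    true_maf: 0.005
    panel: FH
  - probeset_id: PS002
    true_maf: 0.002
    panel: FH
  - probeset_id: PS003
    true_maf: 0.005
    panel: FH
  - probeset_id: PS004
    true_maf: 0.002
    panel: FH
  - probeset_id: PS005
    true_maf: 0.0005
    panel: FH
  - probeset_id: PSXH1
    true_maf: 0.002
    cross_hyb: yes
    cross_hyb_maf: 0.04
    panel: FH
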