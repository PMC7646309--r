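# Small demonstration sweep: 20 pairs, mean change 1, 200 replicates/cell.
n: 20
mean_change: 1
sd_pre_grid: [0.5, 1, 2]
r_grid: [0, 0.5, 0.9]
replicates: 200
seed: 11
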