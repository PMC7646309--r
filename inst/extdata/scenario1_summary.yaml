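# Printed summary statistics for a season-of-training VO2max study
# (8 athletes, paired design).
n: 8
mean_pre: 3.89
mean_post: 4.13
sd_pre: 0.21
sd_post: 0.25
mean_change: 0.23
t: 3.54
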