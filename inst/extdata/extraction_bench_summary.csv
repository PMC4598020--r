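statistic,value
n_replicates,30
mean_ml,2.0
se_ml,0.4
min_ml,0.5
max_ml,5.0
reference_ml,250
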