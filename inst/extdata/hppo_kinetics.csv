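mutant,km_uM,km_err,kcat_min,kcat_err,kcat_per_km_printed
Wild-type (WT),2.08,0.11,2.97,0.15,1.43
R168S,11.33,0.93,3.32,0.22,0.29
M368Q,13.89,1.29,9.29,0.75,0.67
M368K,5.63,0.26,14.17,1.10,2.52
V170T,2.97,0.31,7.70,0.66,2.59
L166N,5.13,0.71,1.82,0.13,0.35
G169A,2.16,0.17,0.37,0.04,0.17
R97G,19.64,2.14,76.37,9.15,3.89
F331T,3.02,0.28,9.08,0.76,3.01
F331A,6.60,0.72,4.36,0.39,0.66
L334V,7.08,0.54,51.19,6.21,7.23
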