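set,mutant,ddh,minus_t_dds,ddg_calc_printed,ddg_expt_printed
mtppo,F392E,5.82,-1.34,4.48,1.34
mtppo,L356N,3.40,0.65,4.05,1.33
mtppo,L356V,4.32,-0.48,3.84,1.09
mtppo,L372N,5.97,-1.38,4.59,1.57
mtppo,L372V,6.64,0.62,7.26,2.66
mtppo,R98K,3.76,-2.45,1.31,0.47
mtppo,R98E,5.26,-0.89,4.37,1.41
mtppo,R98A,6.83,-3.56,3.28,1.16
hppo,M368Q,3.62,0.49,4.11,1.13
hppo,M368K,1.98,1.04,3.02,0.59
hppo,R168S,3.66,0.01,3.67,1.01
hppo,G169A,1.00,-0.80,0.20,0.02
hppo,V170T,-0.61,1.09,0.48,0.21
hppo,L166N,1.15,1.04,2.19,0.54
hppo,R97G,4.96,-0.22,4.74,1.33
hppo,F331T,0.13,0.41,0.54,0.22
hppo,F331A,1.57,1.06,2.63,0.69
hppo,L334V,1.87,1.25,3.12,0.73
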