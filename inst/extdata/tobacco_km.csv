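mutant,km_uM
WT,1.17
F392E,11.2
L356N,11.0
L356V,7.3
L372N,16.4
L372V,103
R98K,2.6
R98E,12.5
R98A,8.3
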