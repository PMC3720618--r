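id,docking_score,mmpbsa_energy,penalty,reaction_distance
M1,-9.10,-21.50,7.5,5.6
M2,-11.03,-24.10,8.2,5.9
M3,-9.45,-22.80,9.0,6.1
M4,-8.90,-20.30,7.1,5.2
M5,-9.80,-23.40,8.8,6.4
M6,-10.20,-26.32,9.6,5.8
M7,-9.60,-35.62,7.9,6.0
M8,-8.70,-19.80,8.4,5.5
M9,-10.40,-29.98,9.2,6.2
M10,-10.10,-42.73,7.3,5.7
M11,-9.30,-21.10,8.6,6.3
M12,-8.80,-20.90,9.4,5.4
M13,-9.20,-22.20,7.7,6.5
M14,-10.99,-44.47,2.5,4.2
M15,-11.88,-35.66,3.5,3.8
M16,-12.48,-25.60,8.1,5.3
M17,-11.20,-24.70,9.8,6.6
M18,-11.18,-23.90,7.6,5.1
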