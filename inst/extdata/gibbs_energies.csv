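id,dG_J_per_mol
h2o,-157280
o2,16400
co2,-386020
lcts,-687000
ac,-249460
lac_L,-316940
etoh,58100
for,-311040
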