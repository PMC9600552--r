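id,formula,name
lcts,C12H22O11,Lactose
ac,C2H4O2,Acetate
lac_L,C3H6O3,L-Lactate
etoh,C2H6O,Ethanol
for,CH2O2,Formate
h2o,H2O,Water
o2,O2,Oxygen
co2,CO2,Carbon dioxide
bsi1,C12H22O11,Bifid shunt intermediate 1
bsi2,C12H22O11,Bifid shunt intermediate 2
atp,C10H16N5O13P3,ATP
adp,C10H15N5O10P2,ADP
pi,H3PO4,Phosphate
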