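"file","bytes","seed"
"bifidtoy.xml",11485,1
"facantoy.xml",13119,1
"crosstoy.xml",9582,1
"badtoy_synthetic.xml",9580,1
"formulas.csv",314,1
"gibbs_energies.csv",110,1
"curation_edits.csv",348,1
"config_anaerobic_desk.json",102,1
"config_oxygen_desk.json",132,1
"config_tracer.json",78,1
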