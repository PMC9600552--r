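"model_id","action","reaction_id","payload"
"BifidToy","delete_reaction","R_PKL",""
"BifidToy","set_objective","R_ATP_DRAIN",""
"CrossToy","add_reaction","R_ACLEAK","{""stoich"":{""ac_c"":-1,""ac_e"":1},""reversible"":false}"
"FacAnToy","set_bounds","R_EX_o2_e","{""lb"":0,""ub"":0}"
"FacAnToy","set_reversible","R_LACFERM","{""reversible"":true}"
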