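structure,limit_eqd2,alpha_beta_x
brainstem,54,2
optic_chiasm,55,2
optic_nerve_L,55,2
optic_nerve_R,55,2
brain,60,2
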